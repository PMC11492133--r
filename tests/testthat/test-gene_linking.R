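mk_genes <- function(tss, chrom = "chr1", ids = NULL) {
  if (is.null(ids)) ids <- paste0("g", seq_along(tss))
  data.frame(gene_id = ids, chrom = chrom, tss = as.integer(tss),
             strand = "+", stringsAsFactors = FALSE)
}

test_that("nearest linking picks the minimum distance and keeps all ties", {
  tf <- mk_tfcrs("chr1", 9900, 10100, peak = 10000)
  g <- mk_genes(c(9000, 12000))
  ln <- link_nearest(tf, g, "tfcr_to_gene")
  expect_equal(ln$gene_id, "g1")
  expect_equal(ln$distance, 1000L)
  # exact tie: both genes retained
  ln2 <- link_nearest(tf, mk_genes(c(9000, 11000)), "tfcr_to_gene")
  expect_equal(sort(ln2$gene_id), c("g1", "g2"))
  expect_equal(ln2$distance, c(1000L, 1000L))
  # TSS inside the TFCR interval clamps to zero
  ln3 <- link_nearest(tf, mk_genes(10050), "tfcr_to_gene")
  expect_equal(ln3$distance, 0L)
})

test_that("genes on TFCR-free chromosomes become no_TFCR links", {
  tf <- mk_tfcrs("chr1", 100, 300)
  g <- rbind(mk_genes(500, "chr1", "gA"), mk_genes(500, "chr2", "gB"))
  ln <- link_nearest(tf, g, "gene_to_tfcr")
  expect_true(is.na(ln$tfcr_id[ln$gene_id == "gB"]))
  expect_false(is.na(ln$tfcr_id[ln$gene_id == "gA"]))
  expect_error(link_nearest(tf, g[0, ], "gene_to_tfcr"), "empty gene")
})

test_that("links match the O(N*M) brute-force oracle on random fixtures", {
  set.seed(21)
  for (dir in c("tfcr_to_gene", "gene_to_tfcr")) {
    pos <- sort(sample(1:500000, 50)) * 10L
    tf <- mk_tfcrs(sample(c("chr1", "chr2"), 50, replace = TRUE),
                   pos, pos + 200L)
    g <- mk_genes(sample(1:5000000, 50),
                  chrom = sample(c("chr1", "chr2"), 50, replace = TRUE))
    got <- link_nearest(tf, g, dir)
    got <- got[!is.na(got$tfcr_id), c("tfcr_id", "gene_id", "distance")]
    want <- brute_nearest(tf, g, dir)
    ord <- function(d) {
      d <- d[order(d$tfcr_id, d$gene_id), ]
      rownames(d) <- NULL
      d
    }
    expect_equal(ord(got), ord(want))
  }
})

test_that("nearest-of-nearest inequality holds between directions", {
  set.seed(5)
  pos <- sort(sample(1:100000, 20)) * 10L
  tf <- mk_tfcrs("chr1", pos, pos + 150L)
  g <- mk_genes(sample(1:1000000, 30))
  g2t <- link_nearest(tf, g, "gene_to_tfcr")
  t2g <- link_nearest(tf, g, "tfcr_to_gene")
  for (i in seq_len(nrow(g2t))) {
    t_id <- g2t$tfcr_id[i]
    expect_gte(g2t$distance[i], min(t2g$distance[t2g$tfcr_id == t_id]))
  }
})

test_that("region boundaries follow the published R1-R4 conventions", {
  d <- c(0, 2000, 2001, 27000, 27001, 50000, 50001)
  tf <- mk_tfcrs("chr1", 1000000 + d * 0, 1000000 + d * 0 + 10)  # placeholder
  links <- data.frame(tfcr_id = paste0("t", seq_along(d)),
                      gene_id = paste0("g", seq_along(d)), chrom = "chr1",
                      peak_pos = 0L, tss = d, distance = as.integer(d),
                      region = NA_character_, direction = "tfcr_to_gene",
                      stringsAsFactors = FALSE)
  out <- classify_regions(links)
  expect_equal(out$region, c("R1", "R1", "R2", "R2", "R3", "R3", "R4"))
  # the partition is total and exclusive on random distances
  set.seed(3)
  big <- links[rep(1, 10000), ]
  big$distance <- sample(0:300000, 10000, replace = TRUE)
  big <- classify_regions(big)
  expect_false(any(is.na(big$region)))
  expect_equal(sum(table(big$region)), 10000)
})

test_that("region proportions count classified links only", {
  links <- data.frame(tfcr_id = c("a", "b", "c", "d", NA),
                      gene_id = letters[1:5], chrom = "chr1", peak_pos = 0L,
                      tss = 0L, distance = c(0L, 5000L, 30000L, 60000L, NA),
                      region = c("R1", "R2", "R3", "R4", NA),
                      direction = "gene_to_tfcr", stringsAsFactors = FALSE)
  expect_equal(unname(region_proportions(links)), rep(0.25, 4))
  links$region[1:4] <- "R1"
  expect_equal(region_proportions(links)[["R1"]], 1)
  expect_error(region_proportions(links[5, ]), "no classified")
})

test_that("threshold derivation recovers planted bimodal modes, defaults otherwise", {
  set.seed(17)
  n <- 2000
  comp <- sample(c("p", "m", "f"), n, replace = TRUE, prob = c(.45, .4, .15))
  d <- ifelse(comp == "p", abs(rnorm(n, 500, 300)),
       ifelse(comp == "m", 27000 + 8000 * qnorm(runif(n, pnorm(-25/8), 1)),
              runif(n, 50001, 300000)))
  links <- data.frame(tfcr_id = "t", gene_id = "g", chrom = "chr1",
                      peak_pos = 0L, tss = 0L, distance = as.integer(d),
                      region = NA, direction = "tfcr_to_gene")
  th <- derive_thresholds(links)
  expect_equal(th$provenance, "derived")
  expect_gte(th$t1, 1000); expect_lte(th$t1, 5000)
  expect_gte(th$t2, 20000); expect_lte(th$t2, 35000)
  expect_lt(th$t2, th$t3)
  # unimodal distances fall back to the published defaults
  links$distance <- as.integer(abs(rnorm(n, 5000, 500)))
  th2 <- derive_thresholds(links)
  expect_equal(th2$provenance, "default")
  expect_equal(c(th2$t1, th2$t2, th2$t3), c(2000, 27000, 50000))
  expect_warning(th3 <- derive_thresholds(links[1:50, ]), "default")
  expect_equal(th3$provenance, "default")
})

test_that("classification is idempotent under frozen links and thresholds", {
  set.seed(9)
  links <- data.frame(tfcr_id = "t", gene_id = "g", chrom = "chr1",
                      peak_pos = 0L, tss = 0L,
                      distance = sample(0:200000, 500), region = NA,
                      direction = "tfcr_to_gene")
  th <- list(t1 = 2000, t2 = 27000, t3 = 50000)
  once <- classify_regions(links, th)
  expect_identical(classify_regions(once, th), once)
})

test_that("expression grouping schemes: HL strict at 1, E6/Q100 rank bins", {
  expr <- data.frame(gene_id = c("a", "b", "c"), fpkm = c(1.0, 1.01, 0),
                     log_expr = log10(c(1.0, 1.01, 0) + 1))
  hl <- expression_groups(expr, "HL")
  expect_equal(unname(hl[c("a", "b", "c")]), c("L", "H", "L"))
  set.seed(2)
  expr6 <- data.frame(gene_id = paste0("g", 1:600),
                      fpkm = sample(seq(0.01, 60, length.out = 600)))
  expr6$log_expr <- log10(expr6$fpkm + 1)
  e6 <- expression_groups(expr6, "E6")
  expect_equal(unname(table(e6)[paste0("E", 1:6)]), rep(100L, 6),
               ignore_attr = TRUE)
  # E1 holds the lowest values
  expect_true(max(expr6$fpkm[e6[expr6$gene_id] == "E1"]) <
              min(expr6$fpkm[e6[expr6$gene_id] == "E6"]))
  # Q100 bin means reproduce a rank-binning oracle
  expr100 <- data.frame(gene_id = paste0("g", 1:1000), fpkm = runif(1000, 0, 50))
  expr100$log_expr <- log10(expr100$fpkm + 1)
  q <- expression_groups(expr100, "Q100")
  got_means <- tapply(expr100$fpkm, q[expr100$gene_id], mean)
  ord <- order(expr100$fpkm)
  want <- tapply(expr100$fpkm[ord], rep(1:100, each = 10), mean)
  expect_equal(unname(got_means[paste0("Q", 1:100)]), unname(want),
               tolerance = 1e-12)
})
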