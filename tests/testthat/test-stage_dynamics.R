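rand_tfcrs <- function(n, stage, chroms = c("chr1", "chr2"), max_pos = 100000) {
  pos <- sort(sample(seq(1, max_pos, by = 10), n))
  mk_tfcrs(sample(chroms, n, replace = TRUE), pos, pos + sample(50:400, n,
                                                               replace = TRUE),
           stage = stage)
}

test_that("overlap pairs: half-open adjacency and the quadratic oracle", {
  a <- mk_tfcrs("chr1", 100, 200, stage = "a")
  b1 <- mk_tfcrs("chr1", 150, 250, stage = "b")
  expect_equal(nrow(overlap_pairs(a, b1)), 1)
  b2 <- mk_tfcrs("chr1", 200, 300, stage = "b")
  expect_equal(nrow(overlap_pairs(a, b2)), 0)
  set.seed(13)
  A <- rand_tfcrs(250, "A"); B <- rand_tfcrs(250, "B")
  got <- overlap_pairs(A, B)
  want <- brute_pairs(A, B)
  key <- function(d) sort(paste(d$a_id, d$b_id))
  expect_equal(key(got), key(want))
  # symmetric in its inputs
  expect_equal(sort(paste(overlap_pairs(B, A)$b_id, overlap_pairs(B, A)$a_id)),
               key(got))
})

test_that("gained/lost/kept: identical stages keep everything; brute force agrees", {
  set.seed(77)
  s1 <- rand_tfcrs(40, "s1"); s2 <- s1; s2$stage <- "s2"
  s2$tfcr_id <- sub("s1", "s2", s2$tfcr_id)
  coll <- stage_collection(list(s1 = list(tfcrs = s1), s2 = list(tfcrs = s2)))
  gl <- gained_lost(coll)
  expect_length(gl$s2$gained, 0)
  expect_length(gl$s1$lost, 0)
  expect_setequal(gl$s1$kept, s1$tfcr_id)
  # 3-stage random panel vs brute force
  st <- list(s1 = list(tfcrs = rand_tfcrs(60, "s1")),
             s2 = list(tfcrs = rand_tfcrs(60, "s2")),
             s3 = list(tfcrs = rand_tfcrs(60, "s3")))
  gl3 <- gained_lost(stage_collection(st))
  for (i in 2:3) {
    cur <- st[[i]]$tfcrs; prev <- st[[i - 1]]$tfcrs
    ov <- brute_pairs(cur, prev)
    expect_setequal(gl3[[i]]$gained, setdiff(cur$tfcr_id, ov$a_id))
  }
  for (i in 1:2) {
    cur <- st[[i]]$tfcrs; nxt <- st[[i + 1]]$tfcrs
    ov <- brute_pairs(cur, nxt)
    expect_setequal(gl3[[i]]$lost, setdiff(cur$tfcr_id, ov$a_id))
  }
  for (s in names(gl3))
    expect_length(intersect(gl3[[s]]$gained, gl3[[s]]$kept), 0)
  expect_error(gained_lost(stage_collection(list(s1 = list(tfcrs = s1)))),
               ">= 2 stages")
})

test_that("stable regions: worked 3-interval chain and the per-bp oracle", {
  st <- list(a = list(tfcrs = mk_tfcrs("chr1", 100, 200, stage = "a")),
             b = list(tfcrs = mk_tfcrs("chr1", 150, 250, stage = "b")),
             c = list(tfcrs = mk_tfcrs("chr1", 180, 300, stage = "c")))
  stab <- stable_regions(stage_collection(st))
  expect_equal(nrow(stab), 1)
  expect_equal(c(stab$start, stab$end), c(180L, 200L))
  expect_match(stab$ids_a, "a_chr1")
  # disjoint stages: nothing stable
  st$b$tfcrs <- mk_tfcrs("chr1", 500, 600, stage = "b")
  expect_equal(nrow(stable_regions(stage_collection(st))), 0)
  # 5-stage random panel equals the brute-force intersection
  set.seed(41)
  sets <- lapply(1:5, function(i) rand_tfcrs(50, paste0("s", i),
                                             max_pos = 20000))
  names(sets) <- paste0("s", 1:5)
  coll <- stage_collection(lapply(sets, function(s) list(tfcrs = s)))
  got <- stable_regions(coll)
  want <- brute_stable(sets)
  expect_equal(got[c("chrom", "start", "end")],
               want[order(want$chrom, want$start), ],
               ignore_attr = TRUE)
  # invariant to stage order
  rev_coll <- stage_collection(lapply(rev(sets), function(s) list(tfcrs = s)))
  got_rev <- stable_regions(rev_coll)
  expect_equal(got[c("chrom", "start", "end")],
               got_rev[c("chrom", "start", "end")])
})

test_that("long-range distance bins are closed-left and conserve counts", {
  d <- c(50001, 99999, 100000, 150000, 200000, 200001, 350000)
  links <- data.frame(tfcr_id = "t", gene_id = "g", chrom = "chr1",
                      peak_pos = 0L, tss = 0L, distance = as.integer(d),
                      region = "R4", direction = "tfcr_to_gene")
  bins <- lr_distance_bins(links)
  # closed-left bins: 100000 falls in 100-150k, 200000 in >200k
  expect_equal(unname(bins), c(2L, 1L, 1L, 3L))
  expect_equal(sum(bins), nrow(links))
  links$region[1] <- "R1"
  expect_error(lr_distance_bins(links), "R4")
})

test_that("trajectory matrix: nearest-TFCR TC per stage, z-standardised", {
  tc_by_stage <- list(s1 = c(gA = 1, gB = 4), s2 = c(gA = 2, gB = 4.5),
                      s3 = c(gA = 3, gB = 5))
  stages <- lapply(names(tc_by_stage), function(s) {
    tc <- tc_by_stage[[s]]
    tf <- mk_tfcrs("chr1", c(1000, 5000), c(1400, 5400), TC = unname(tc),
                   stage = s)
    links <- data.frame(tfcr_id = tf$tfcr_id, gene_id = names(tc),
                        chrom = "chr1", peak_pos = tf$peak_pos,
                        tss = c(900, 5600), distance = c(100L, 200L),
                        region = "R1", direction = "gene_to_tfcr")
    list(tfcrs = tf, links = links)
  })
  names(stages) <- names(tc_by_stage)
  mat <- tc_trajectories(stage_collection(stages))
  expect_equal(dim(mat), c(2, 3))
  expect_equal(unname(rowMeans(mat)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(mat, 1, sd)), c(1, 1), tolerance = 1e-12)
  hand <- (c(1, 2, 3) - 2) / sd(c(1, 2, 3))
  expect_equal(unname(mat["gA", ]), hand)
  # a gene absent in one stage is excluded
  stages$s2$links <- stages$s2$links[1, ]
  expect_message(mat2 <- tc_trajectories(stage_collection(stages)),
                 "excluded")
  expect_equal(rownames(mat2), "gA")
})

test_that("fuzzy c-means recovers planted trajectory shapes and is deterministic", {
  set.seed(6)
  up <- t(replicate(40, scale(c(0, 1, 2, 3, 4) + rnorm(5, 0, 0.15))[, 1]))
  down <- t(replicate(40, scale(c(4, 3, 2, 1, 0) + rnorm(5, 0, 0.15))[, 1]))
  mat <- rbind(up, down)
  rownames(mat) <- paste0("g", 1:80)
  cm <- fuzzy_cmeans(mat, c = 2, seed = 11)
  truth <- rep(1:2, each = 40)
  expect_equal(adjusted_rand(cm$cluster, truth), 1)
  expect_equal(unname(rowSums(cm$membership)), rep(1, 80), tolerance = 1e-9)
  expect_true(all(diff(cm$objective) <= 1e-8))
  cm2 <- fuzzy_cmeans(mat, c = 2, seed = 11)
  expect_identical(cm$membership, cm2$membership)
  # zero-distance degenerate point takes membership 1 (limit rule)
  mat2 <- rbind(mat, mat[1, , drop = FALSE])
  rownames(mat2)[81] <- "dup"
  cm3 <- fuzzy_cmeans(mat2, c = 2, seed = 3, max_iter = 1)
  expect_true(all(abs(rowSums(cm3$membership) - 1) < 1e-9))
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(15)
  mat <- rbind(matrix(rnorm(100, 0), 20), matrix(rnorm(100, 4), 20))
  rownames(mat) <- paste0("r", 1:40)
  ours <- fuzzy_cmeans(mat, c = 2, m = 2, seed = 2, tol = 1e-10)
  theirs <- e1071::cmeans(mat, centers = 2, m = 2, iter.max = 500)
  # same partition up to label permutation
  expect_equal(abs(adjusted_rand(ours$cluster, theirs$cluster)), 1)
  # centers match up to permutation
  perm <- if (sum((ours$centers[1, ] - theirs$centers[1, ])^2) <
              sum((ours$centers[1, ] - theirs$centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(ours$centers), unname(theirs$centers[perm, ]),
               tolerance = 0.05)
})
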