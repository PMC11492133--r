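test_that("kernel density track has unit peak contribution and exact values", {
  tfbs <- mk_tfbs(1000)
  tr <- kde_density(tfbs)[[1]]
  xs <- tr$grid_start + (seq_along(tr$values) - 1) * tr$grid_step
  # peak contribution 1.0 up to the 4-sigma continuity shift (3.35e-4)
  expect_equal(max(tr$values), 1.0, tolerance = 1e-3)
  expect_equal(xs[which.max(tr$values)], 1000)
  expect_equal(tr$values[xs == 1300], exp(-0.5), tolerance = 1e-3)
  expect_equal(tr$values[xs == 1300], exp(-0.5) - exp(-8), tolerance = 1e-12)
  # additivity: two coincident sites stack to 2.0
  tr2 <- kde_density(mk_tfbs(c(1000, 1000)))[[1]]
  expect_equal(max(tr2$values), 2.0, tolerance = 2e-3)
  expect_equal(kde_density(mk_tfbs(1000)[0, ]), list())
})

test_that("a tight cluster yields one TFCR near the weighted center", {
  mids <- c(4900, 4950, 5000, 5050, 5100)
  tfbs <- mk_tfbs(mids)
  tf <- call_tfcrs(kde_density(tfbs), tfbs)
  expect_equal(nrow(tf), 1)
  oracle <- brute_call(tfbs)
  expect_length(oracle, 1)
  expect_lte(abs(tf$peak_pos - oracle[[1]]$peak), 10)
  expect_equal(tf$n_tfbs, 5L)
})

test_that("groups separated beyond kernel reach give disjoint TFCRs", {
  tfbs <- mk_tfbs(c(1000, 1100, 11000, 11100))
  tf <- call_tfcrs(kde_density(tfbs), tfbs)
  expect_equal(nrow(tf), 2)
  sets <- lapply(tf$contrib, function(x) x$midpoint)
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  expect_setequal(unlist(sets), tfbs$midpoint)
})

test_that("contribution cutoff radius is sigma*sqrt(2 ln 10) ~ 643.8 bp", {
  for (d in c(643, 645)) {
    # mirrored probes keep the density symmetric: the peak is exactly 5000
    tfbs <- mk_tfbs(c(rep(5000, 5), 5000 - d, 5000 + d),
                    tf_family = c(LETTERS[1:5], "PROBE_L", "PROBE_R"))
    tf <- call_tfcrs(kde_density(tfbs), tfbs)
    main <- tf[which.max(tf$TC), ]
    expect_equal(main$peak_pos, 5000)
    included <- (5000 + d) %in% main$contrib[[1]]$midpoint
    expect_equal(included, d <= 643)
  }
})

test_that("complexity axioms: lone site, same-family dedup, family additivity", {
  one <- mk_tfbs(5000, tf_family = "A")
  tf <- call_tfcrs(kde_density(one), one)
  expect_equal(tf$TC, 1.0, tolerance = 1e-12)
  # overlapping same-family site leaves TC unchanged (the refined peak
  # sits between the two sites, so the max weight is 1 - O(1bp offset))
  two_same <- mk_tfbs(c(5000, 5002), tf_family = c("A", "A"))
  tf2 <- call_tfcrs(kde_density(two_same), two_same)
  expect_equal(nrow(tf2), 1)
  expect_equal(tf2$TC, 1.0, tolerance = 1e-4)
  # a second family at the same point adds exactly 1.0
  two_fam <- mk_tfbs(c(5000, 5000), tf_family = c("A", "B"))
  tf3 <- call_tfcrs(kde_density(two_fam), two_fam)
  expect_equal(tf3$TC, 2.0, tolerance = 1e-12)
  # same family at non-overlapping loci counts separately
  apart <- mk_tfbs(c(5000, 5100), tf_family = c("A", "A"))
  tf4 <- call_tfcrs(kde_density(apart), apart)
  expect_gt(tf4$TC, 1.5)
})

test_that("family-locus dedup chains transitively and keeps the max weight", {
  # three same-family sites: 1-2 overlap, 2-3 overlap, 1-3 do not: one locus
  contrib <- data.frame(
    tf_family = "A", start = c(100, 106, 112), end = c(110, 116, 122),
    weight = c(0.5, 0.9, 0.4))
  expect_equal(tfcr_complexity(contrib), 0.9)
  # adjacent (touching) intervals are different loci under half-open rules
  contrib2 <- data.frame(tf_family = "A", start = c(100, 110),
                         end = c(110, 120), weight = c(0.5, 0.4))
  expect_equal(tfcr_complexity(contrib2), 0.9)
  expect_equal(tfcr_complexity(contrib[0, ]), 0)
})

test_that("adding sites: new family never decreases TC, overlapping same-family never changes it", {
  set.seed(42)
  for (rep in 1:10) {
    mids <- 5000 + sample(-300:300, 4)
    fams <- sample(c("A", "B"), 4, replace = TRUE)
    base <- mk_tfbs(mids, tf_family = fams)
    tf <- call_tfcrs(kde_density(base), base)
    tc0 <- max(tf$TC)
    plus_new <- rbind(base, mk_tfbs(5000 + sample(-200:200, 1),
                                    tf_name = "TFX", tf_family = "NEW"))
    plus_new <- plus_new[order(plus_new$start), ]
    tc1 <- max(call_tfcrs(kde_density(plus_new), plus_new)$TC)
    expect_gte(tc1, tc0 - 1e-9)
    # coincident same-family duplicate: same locus group, same max weight;
    # the density (and hence the peak) can drift by a grid step, so TC is
    # compared at that resolution
    dup <- base[1, ]; dup$tf_name <- "TFdup"
    plus_dup <- rbind(base, dup)
    plus_dup <- plus_dup[order(plus_dup$start), ]
    tc2 <- max(call_tfcrs(kde_density(plus_dup), plus_dup)$TC)
    expect_equal(tc2, tc0, tolerance = 0.05)
  }
})

test_that("translation invariance: shifting sites shifts calls, not scores", {
  set.seed(7)
  mids <- sort(sample(2000:20000, 30))
  tfbs <- mk_tfbs(mids, tf_family = sample(LETTERS[1:5], 30, replace = TRUE))
  tf0 <- call_tfcrs(kde_density(tfbs), tfbs)
  shift <- 12340L
  tfbs2 <- tfbs
  tfbs2$start <- tfbs2$start + shift; tfbs2$end <- tfbs2$end + shift
  tfbs2$midpoint <- tfbs2$midpoint + shift
  tf1 <- call_tfcrs(kde_density(tfbs2), tfbs2)
  expect_equal(tf1$peak_pos, tf0$peak_pos + shift)
  expect_equal(tf1$start, tf0$start + shift)
  expect_equal(tf1$TC, tf0$TC, tolerance = 1e-9)
  expect_equal(tf1$TW, tf0$TW)
})

test_that("TFCR invariants hold on random calls", {
  set.seed(99)
  mids <- sort(sample(1000:50000, 60))
  tfbs <- mk_tfbs(mids, tf_family = sample(LETTERS[1:6], 60, replace = TRUE))
  tf <- call_tfcrs(kde_density(tfbs), tfbs)
  expect_true(all(tf$TW == tf$end - tf$start))
  expect_equal(tf$cw, tf$TC / tf$TW)
  expect_true(all(tf$start <= tf$peak_pos & tf$peak_pos < tf$end))
  # TC bounded by the number of contributing sites (weights <= 1)
  expect_true(all(tf$TC <= tf$n_tfbs + 1e-9))
})

test_that("TC decile bins: nearest-rank, ties share a bin", {
  tf <- mk_tfcrs("chr1", (1:10) * 1000, (1:10) * 1000 + 100, TC = 1:10)
  tf <- assign_tc_bins(tf, 10)
  expect_equal(tf$tc_bin, paste0("TC", 0:9))
  tf$TC <- rep(2, 10)
  expect_equal(unique(assign_tc_bins(tf, 10)$tc_bin), "TC0")
  set.seed(1)
  tf2 <- mk_tfcrs("chr1", (1:1000) * 1000, (1:1000) * 1000 + 100,
                  TC = runif(1000))
  counts <- table(assign_tc_bins(tf2, 10)$tc_bin)
  expect_true(all(abs(counts - 100) <= 1))
  expect_error(assign_tc_bins(tf[1:5, ], 10), "smaller n_bins")
})

test_that("CAS is the mean of overlapping ATAC peak scores", {
  tf <- mk_tfcrs("chr1", 1000, 1400)
  peaks <- data.frame(chrom = "chr1", start = c(900, 1300, 5000),
                      end = c(1100, 1500, 5100), score = c(4, 8, 99))
  expect_equal(compute_cas(tf, peaks)$CAS, 6)
  one <- data.frame(chrom = "chr1", start = 1399, end = 1500, score = 7.5)
  expect_equal(compute_cas(tf, one)$CAS, 7.5)
  none <- data.frame(chrom = "chr1", start = 1400, end = 1500, score = 7.5)
  expect_true(is.na(compute_cas(tf, none)$CAS))  # half-open adjacency
})
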