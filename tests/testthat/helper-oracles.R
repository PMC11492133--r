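# Independent brute-force oracles and tiny fixture builders. These are
# deliberately written as naive loops, separate from the package's
# implementations, so the two routes can disagree.

mk_tfbs <- function(midpoints, chrom = "chr1", tf_name = NULL,
                    tf_family = NULL, width = 10L) {
  n <- length(midpoints)
  if (is.null(tf_name)) tf_name <- paste0("TF", seq_len(n))
  if (is.null(tf_family)) tf_family <- paste0("FAM", seq_len(n))
  start <- as.integer(midpoints - width %/% 2L)
  df <- data.frame(chrom = chrom, start = start, end = start + width,
                   strand = "+", tf_name = tf_name, tf_family = tf_family,
                   scan_score = 10, midpoint = as.integer(midpoints),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), ]
}

mk_tfcrs <- function(chrom, start, end, peak = NULL, TC = 1, stage = "S1") {
  n <- length(start)
  if (is.null(peak)) peak <- as.integer((start + end) %/% 2)
  df <- data.frame(
    tfcr_id = paste0(stage, "_", chrom, "_", peak), stage = stage,
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    peak_pos = as.integer(peak), TC = TC, TW = as.integer(end - start),
    stringsAsFactors = FALSE)
  df$cw <- df$TC / df$TW
  df$n_families <- 1L; df$n_tfbs <- 1L
  df$CAS <- NA_real_; df$tc_bin <- NA_character_
  df$contrib <- I(replicate(n, data.frame(), simplify = FALSE))
  df
}

# brute-force caller: 1-bp grid kernel sum, naive local-maximum scan with
# plateau collapse, contributions by direct weight evaluation
brute_call <- function(tfbs, sigma = 300, thr = 0.1, trunc_sig = 4) {
  out <- list()
  for (ch in sort(unique(tfbs$chrom))) {
    m <- tfbs$midpoint[tfbs$chrom == ch]
    ridx <- which(tfbs$chrom == ch)
    xs <- seq(min(m) - trunc_sig * sigma, max(m) + trunc_sig * sigma)
    v <- numeric(length(xs))
    edge <- exp(-trunc_sig^2 / 2)    # same continuous truncation contract
    for (mm in m) {
      sel <- abs(xs - mm) <= trunc_sig * sigma
      v[sel] <- v[sel] + (exp(-(xs[sel] - mm)^2 / (2 * sigma^2)) - edge)
    }
    i <- 1L; n <- length(v)
    while (i <= n) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1L
      left <- if (i == 1) -Inf else v[i - 1]
      right <- if (j == n) -Inf else v[j + 1]
      if (v[i] > left && v[i] > right) {
        peak <- xs[(i + j) %/% 2L]
        w <- exp(-(peak - m)^2 / (2 * sigma^2))
        contrib <- ridx[w >= thr]
        if (length(contrib))
          out[[length(out) + 1L]] <- list(chrom = ch, peak = peak,
                                          contrib = sort(contrib))
      }
      i <- j + 1L
    }
  }
  out
}

# brute-force nearest links with all ties, inside-interval clamp
brute_nearest <- function(tfcrs, genes, direction) {
  res <- list()
  dist1 <- function(peak, s, e, tss) {
    if (tss >= s && tss < e) 0L else abs(tss - peak)
  }
  if (direction == "tfcr_to_gene") {
    for (i in seq_len(nrow(tfcrs))) {
      g <- genes[genes$chrom == tfcrs$chrom[i], , drop = FALSE]
      if (!nrow(g)) next
      d <- vapply(seq_len(nrow(g)), function(j)
        dist1(tfcrs$peak_pos[i], tfcrs$start[i], tfcrs$end[i], g$tss[j]), 0L)
      k <- which(d == min(d))
      res[[length(res) + 1L]] <- data.frame(
        tfcr_id = tfcrs$tfcr_id[i], gene_id = g$gene_id[k],
        distance = d[k], stringsAsFactors = FALSE)
    }
  } else {
    for (j in seq_len(nrow(genes))) {
      t <- tfcrs[tfcrs$chrom == genes$chrom[j], , drop = FALSE]
      if (!nrow(t)) next
      d <- vapply(seq_len(nrow(t)), function(i)
        dist1(t$peak_pos[i], t$start[i], t$end[i], genes$tss[j]), 0L)
      k <- which(d == min(d))
      res[[length(res) + 1L]] <- data.frame(
        tfcr_id = t$tfcr_id[k], gene_id = genes$gene_id[j],
        distance = d[k], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# quadratic interval-overlap oracle (half-open)
brute_pairs <- function(a, b, min_ov = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_ov)
      out[[length(out) + 1L]] <- c(a$tfcr_id[i], b$tfcr_id[j])
  }
  if (!length(out)) return(data.frame(a_id = character(0), b_id = character(0)))
  m <- do.call(rbind, out)
  data.frame(a_id = m[, 1], b_id = m[, 2], stringsAsFactors = FALSE)
}

# brute-force per-bp stable-region oracle over a list of interval sets
brute_stable <- function(sets) {
  chroms <- sort(unique(unlist(lapply(sets, function(s) s$chrom))))
  frags <- list()
  for (ch in chroms) {
    subs <- lapply(sets, function(s) s[s$chrom == ch, , drop = FALSE])
    hi <- max(unlist(lapply(subs, function(s) if (nrow(s)) s$end else 0)))
    cov <- rep(TRUE, hi)
    for (s in subs) {
      c1 <- rep(FALSE, hi)
      for (i in seq_len(nrow(s))) {
        if (s$start[i] < hi) c1[(s$start[i] + 1):min(s$end[i], hi)] <- TRUE
      }
      cov <- cov & c1
    }
    r <- rle(cov)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      frags[[length(frags) + 1L]] <- data.frame(
        chrom = ch, start = starts[k] - 1L, end = ends[k],
        stringsAsFactors = FALSE)
  }
  if (!length(frags)) return(data.frame(chrom = character(0),
                                        start = integer(0), end = integer(0)))
  do.call(rbind, frags)
}

# mid-rank Spearman oracle
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# simple strict local maxima of a smooth curve (no plateaus expected)
local_maxima_of <- function(v) which(diff(sign(diff(v))) == -2) + 1L
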