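#' Significance star ladder
#'
#' \code{****} p < 0.0001, \code{***} p < 0.001, \code{**} p < 0.01,
#' \code{*} p < 0.05, else \code{ns}.
#'
#' @param p P-value(s).
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Spearman correlation with tie-aware ranks
#'
#' rho is the Pearson correlation of mid-ranks; the p-value comes from
#' \code{stats::cor.test} (exact null distribution for n <= 10 without
#' ties, t-approximation otherwise). Pairs with a missing value are
#' dropped listwise. A constant vector leaves rho undefined (NA with a
#' warning), never silently zero.
#'
#' @param x,y Numeric vectors of equal length (>= 3 usable pairs).
#' @return List: \code{rho}, \code{p_value}, \code{n}, \code{method},
#'   \code{stars}.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "spearman", stars = NA_character_))
  }
  rho <- stats::cor(rank(x), rank(y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = n <= 10))
  list(rho = rho, p_value = ct$p.value, n = n, method = "spearman",
       stars = p_stars(ct$p.value))
}

#' Fit the saturating log model y = a*log10(x + c) + b
#'
#' Ordinary least squares of \code{y} on \code{log10(x + c)} with the
#' offset \code{c} either fixed (default 0.03, the published value) or
#' estimated by a 1-D search maximising the profile R-squared over
#' \code{c} in [1e-4, 1].
#'
#' @param x Non-negative predictor (e.g. TFCR complexity).
#' @param y Response (e.g. log10(FPKM + 1)).
#' @param offset Fixed offset \code{c} (default 0.03).
#' @param estimate_offset If \code{TRUE}, profile out \code{c}.
#' @return List: \code{a}, \code{b}, \code{c}, \code{r_squared},
#'   \code{fitted}, \code{residuals}.
#' @export
fit_log_model <- function(x, y, offset = 0.03, estimate_offset = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 points", call. = FALSE)
  if (stats::sd(y) == 0) stop("zero variance in y", call. = FALSE)
  fit_at <- function(cc) stats::lm(y ~ log10(x + cc))
  r2_of <- function(fit) 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  cc <- offset
  if (estimate_offset) {
    opt <- stats::optimize(function(cc) -r2_of(fit_at(cc)),
                           interval = c(1e-4, 1), tol = 1e-6)
    cc <- opt$minimum
  }
  fit <- fit_at(cc)
  co <- stats::coef(fit)
  list(a = unname(co[2]), b = unname(co[1]), c = cc,
       r_squared = r2_of(fit), fitted = unname(stats::fitted(fit)),
       residuals = unname(stats::residuals(fit)))
}

#' Rank-binned scatter summary
#'
#' Orders points by the grouping variable, splits them into \code{n_bins}
#' equal-size rank bins and reports per-bin means of both coordinates
#' (the "100 expression groups" presentation).
#'
#' @param x,y Numeric vectors.
#' @param n_bins Number of rank bins (default 100).
#' @param by Which variable defines the ranking: \code{"y"} (default) or
#'   \code{"x"}.
#' @return \code{data.frame} with \code{bin}, \code{mean_x}, \code{mean_y},
#'   \code{n}.
#' @export
binned_scatter <- function(x, y, n_bins = 100, by = c("y", "x")) {
  by <- match.arg(by)
  stopifnot(length(x) == length(y))
  if (n_bins > length(x)) stop("more bins than points", call. = FALSE)
  ord <- order(if (by == "y") y else x)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  idx <- split(ord, bin)
  data.frame(bin = seq_along(idx),
             mean_x = vapply(idx, function(i) mean(x[i]), 0),
             mean_y = vapply(idx, function(i) mean(y[i]), 0),
             n = lengths(idx), row.names = NULL)
}

#' Label genes by TC/TW correlation strength
#'
#' Deterministic four-group rule on per-gene correlations of expression
#' with TFCR complexity (cor_TC) and width (cor_TW): \code{TC&TW} when
#' both |cor| exceed the threshold, \code{TC} or \code{TW} when only one
#' does, else \code{nTC&TW} (strict inequality at the boundary). A seeded
#' k-means on the two correlations can be recorded alongside as a
#' diagnostic.
#'
#' @param cors \code{data.frame} with \code{gene_id}, \code{cor_TC},
#'   \code{cor_TW}.
#' @param threshold Absolute correlation cutoff (default 0.5).
#' @param run_kmeans Attach a k-means cluster column.
#' @param k Number of k-means centers (default 3).
#' @param seed RNG seed for k-means.
#' @return \code{data.frame}: \code{gene_id}, \code{cor_TC}, \code{cor_TW},
#'   \code{label}, optionally \code{kmeans_cluster}. Genes with a missing
#'   correlation are excluded with a message.
#' @export
label_corr_groups <- function(cors, threshold = 0.5, run_kmeans = FALSE,
                              k = 3, seed = 1L) {
  ok <- is.finite(cors$cor_TC) & is.finite(cors$cor_TW)
  if (any(!ok)) message(sum(!ok), " gene(s) with missing correlation excluded")
  out <- cors[ok, c("gene_id", "cor_TC", "cor_TW"), drop = FALSE]
  hi_tc <- abs(out$cor_TC) > threshold
  hi_tw <- abs(out$cor_TW) > threshold
  out$label <- ifelse(hi_tc & hi_tw, "TC&TW",
               ifelse(hi_tc, "TC", ifelse(hi_tw, "TW", "nTC&TW")))
  if (run_kmeans && nrow(out) >= k) {
    set.seed(seed)
    out$kmeans_cluster <- stats::kmeans(cbind(out$cor_TC, out$cor_TW),
                                        centers = k, nstart = 10)$cluster
  }
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test with star ladder
#'
#' Two-sided unequal-variance t-test; two degenerate constant samples with
#' equal means give p = 1 ("no difference") instead of an error.
#'
#' @param a,b Numeric vectors, each length >= 2.
#' @return List: \code{t}, \code{p_value}, \code{stars}, \code{n_a},
#'   \code{n_b}, \code{mean_a}, \code{mean_b}.
#' @export
welch_ttest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    return(list(t = if (p == 1) 0 else Inf, p_value = p, stars = p_stars(p),
                n_a = length(a), n_b = length(b),
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       stars = p_stars(tt$p.value), n_a = length(a), n_b = length(b),
       mean_a = mean(a), mean_b = mean(b))
}

#' Top-n TFCRs by unit-base complexity and a seeded control draw
#'
#' The "top-200 / sampling-200" construction: the \code{n} TFCRs with the
#' largest cw (ties broken by TC, then id, deterministically) and a
#' uniform seeded sample of \code{n} from the remainder.
#'
#' @param tfcrs TFCR \code{data.frame} with at least \code{2n} rows.
#' @param n Set size (default 200).
#' @param seed RNG seed for the control draw.
#' @return List of two \code{data.frame}s: \code{top}, \code{control}.
#' @export
top_cw_and_control <- function(tfcrs, n = 200, seed = 1L) {
  if (nrow(tfcrs) < 2 * n)
    stop("need at least 2n = ", 2 * n, " TFCRs", call. = FALSE)
  ord <- order(-tfcrs$cw, -tfcrs$TC, tfcrs$tfcr_id)
  top <- tfcrs[ord[seq_len(n)], , drop = FALSE]
  rest <- tfcrs[ord[-seq_len(n)], , drop = FALSE]
  set.seed(seed)
  control <- rest[sample(nrow(rest), n), , drop = FALSE]
  rownames(top) <- rownames(control) <- NULL
  list(top = top, control = control)
}

#' Overlap of gene groups with a reference gene set
#'
#' @param genes_by_group Named list of gene-id vectors.
#' @param reference_set Character vector of reference gene ids (e.g.
#'   essential genes, ZGA genes).
#' @return \code{data.frame}: \code{group}, \code{count} (genes of the
#'   group in the reference), \code{fraction_of_reference}.
#' @export
gene_set_stats <- function(genes_by_group, reference_set) {
  reference_set <- unique(reference_set)
  if (!length(reference_set)) stop("empty reference set", call. = FALSE)
  counts <- vapply(genes_by_group,
                   function(g) length(intersect(unique(g), reference_set)), 0L)
  data.frame(group = names(genes_by_group), count = counts,
             fraction_of_reference = counts / length(reference_set),
             row.names = NULL, stringsAsFactors = FALSE)
}
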