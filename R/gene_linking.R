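#' Nearest-TSS / nearest-TFCR linking
#'
#' Pairs TFCRs and genes by minimum absolute distance between the TFCR
#' density peak and the gene TSS. Distance is clamped to 0 when the TSS
#' falls inside the TFCR interval. In direction \code{"tfcr_to_gene"} each
#' TFCR is paired with its closest gene(s); in \code{"gene_to_tfcr"} each
#' gene with its closest TFCR(s). Exact distance ties are ALL retained.
#' In gene-to-TFCR direction, genes on chromosomes without any TFCR yield
#' a \code{no_TFCR} link with missing \code{tfcr_id}; in TFCR-to-gene
#' direction TFCRs on gene-free chromosomes are dropped with a warning.
#' Strand is ignored: distances are absolute bp.
#'
#' @param tfcrs TFCR \code{data.frame}.
#' @param genes Gene \code{data.frame} from \code{\link{read_gene_tss}}.
#' @param direction \code{"tfcr_to_gene"} or \code{"gene_to_tfcr"}.
#' @return Link \code{data.frame}: \code{tfcr_id}, \code{gene_id},
#'   \code{chrom}, \code{peak_pos}, \code{tss}, \code{distance},
#'   \code{region} (NA until \code{\link{classify_regions}}),
#'   \code{direction}.
#' @export
link_nearest <- function(tfcrs, genes,
                         direction = c("tfcr_to_gene", "gene_to_tfcr")) {
  direction <- match.arg(direction)
  if (!nrow(genes)) stop("empty gene list: nearest undefined", call. = FALSE)
  out <- list()
  if (direction == "tfcr_to_gene") {
    lost <- 0L
    for (ch in unique(tfcrs$chrom)) {
      tsub <- tfcrs[tfcrs$chrom == ch, , drop = FALSE]
      gsub <- genes[genes$chrom == ch, , drop = FALSE]
      if (!nrow(gsub)) { lost <- lost + nrow(tsub); next }
      for (i in seq_len(nrow(tsub))) {
        d <- link_distance(tsub$peak_pos[i], tsub$start[i], tsub$end[i], gsub$tss)
        k <- which(d == min(d))
        out[[length(out) + 1L]] <- data.frame(
          tfcr_id = tsub$tfcr_id[i], gene_id = gsub$gene_id[k], chrom = ch,
          peak_pos = tsub$peak_pos[i], tss = gsub$tss[k],
          distance = d[k], stringsAsFactors = FALSE)
      }
    }
    if (lost) warning(lost, " TFCR(s) on gene-free chromosome(s) dropped")
  } else {
    for (ch in unique(genes$chrom)) {
      gsub <- genes[genes$chrom == ch, , drop = FALSE]
      tsub <- tfcrs[tfcrs$chrom == ch, , drop = FALSE]
      if (!nrow(tsub)) {
        out[[length(out) + 1L]] <- data.frame(
          tfcr_id = NA_character_, gene_id = gsub$gene_id, chrom = ch,
          peak_pos = NA_integer_, tss = gsub$tss,
          distance = NA_integer_, stringsAsFactors = FALSE)
        next
      }
      for (i in seq_len(nrow(gsub))) {
        d <- link_distance(tsub$peak_pos, tsub$start, tsub$end, gsub$tss[i])
        k <- which(d == min(d))
        out[[length(out) + 1L]] <- data.frame(
          tfcr_id = tsub$tfcr_id[k], gene_id = gsub$gene_id[i], chrom = ch,
          peak_pos = tsub$peak_pos[k], tss = gsub$tss[i],
          distance = d[k], stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (length(out)) do.call(rbind, out) else
    data.frame(tfcr_id = character(0), gene_id = character(0),
               chrom = character(0), peak_pos = integer(0), tss = integer(0),
               distance = integer(0), stringsAsFactors = FALSE)
  links$region <- NA_character_
  links$direction <- direction
  rownames(links) <- NULL
  links
}

# |TSS - peak|, clamped to 0 when the TSS lies inside [start, end)
#
# (helper shared by both linking directions)
link_distance <- function(peak_pos, start, end, tss) {
  d <- abs(tss - peak_pos)
  inside <- tss >= start & tss < end
  d[inside] <- 0L
  as.integer(d)
}

#' Derive R1-R4 distance thresholds from the link distance distribution
#'
#' Diagnostic re-derivation of the published distance cuts from the
#' kernel density of \code{log10(distance + 1)}. Modes are the prominent
#' local maxima of the density (height at least 5\% of the global
#' maximum, which suppresses tail ripples): \code{t1} is the distance at
#' the density minimum between the first two modes (taken on the dense
#' density grid — the inter-mode valley holds almost no data, so snapping
#' it to a data percentile would be unstable), \code{t2} the second mode
#' snapped to its nearest percentile of the 99-percentile grid, and
#' \code{t3} the smaller of the default 50 kb and the 99th percentile,
#' snapped likewise. A unimodal density (or too few links) falls back to
#' the published defaults 2 kb / 27 kb / 50 kb with provenance
#' \code{"default"}. The defaults are authoritative for classification;
#' derivation is a reproducibility aid.
#'
#' @param links Link \code{data.frame} from \code{\link{link_nearest}}.
#' @param default_thresholds Fallback cuts (bp).
#' @return List with \code{t1}, \code{t2}, \code{t3}, \code{provenance}
#'   (\code{"derived"} or \code{"default"}), and \code{diagnostics}
#'   (percentile grid, density values, extrema positions).
#' @export
derive_thresholds <- function(links, default_thresholds = c(2000, 27000, 50000)) {
  d <- links$distance[!is.na(links$distance) & links$distance > 0]
  fallback <- list(t1 = default_thresholds[1], t2 = default_thresholds[2],
                   t3 = default_thresholds[3], provenance = "default",
                   diagnostics = NULL)
  if (length(d) < 100) {
    warning("fewer than 100 positive-distance links; using default thresholds")
    return(fallback)
  }
  ld <- log10(d + 1)
  pct <- stats::quantile(ld, probs = seq_len(99) / 100, names = FALSE)
  pd <- 10^pct - 1
  dens <- stats::density(ld)
  imax <- local_maxima_idx(dens$y)
  imax <- imax[dens$y[imax] >= 0.05 * max(dens$y)]   # prominent modes only
  diag <- list(percentile_log10 = pct,
               density_at_percentiles = stats::approx(dens$x, dens$y,
                                                      xout = pct,
                                                      rule = 2)$y,
               mode_log10 = dens$x[imax])
  if (length(imax) < 2) {
    fallback$diagnostics <- diag
    return(fallback)
  }
  i1 <- imax[1]; i2 <- imax[2]
  imin <- i1 + which.min(dens$y[i1:i2]) - 1L
  diag$minimum_log10 <- dens$x[imin]
  snap <- function(lx) pd[which.min(abs(pct - lx))]
  t1 <- round(10^dens$x[imin] - 1)
  t2 <- round(snap(dens$x[i2]))
  t3 <- round(snap(log10(min(50000, pd[99]) + 1)))
  if (!(t1 > 0 && t1 < t2 && t2 < t3)) {
    fallback$diagnostics <- diag
    return(fallback)
  }
  list(t1 = t1, t2 = t2, t3 = t3, provenance = "derived", diagnostics = diag)
}

#' Classify links into distance regions R1-R4
#'
#' R1: 0 <= d <= t1 (proximal, promoter-like); R2: t1 < d <= t2;
#' R3: t2 < d <= t3; R4: d > t3 (long-range, LR-TFCR). Boundaries belong
#' to the lower region (d = t1 is R1, d = t2 is R2, d = t3 is R3). Links
#' without a TFCR (\code{no_TFCR}) keep a missing region.
#'
#' @param links Link \code{data.frame}.
#' @param thresholds List with \code{t1 < t2 < t3} (defaults 2 kb, 27 kb,
#'   50 kb) as from \code{\link{derive_thresholds}}.
#' @return \code{links} with \code{region} set.
#' @export
classify_regions <- function(links,
                             thresholds = list(t1 = 2000, t2 = 27000, t3 = 50000)) {
  stopifnot(thresholds$t1 > 0, thresholds$t1 < thresholds$t2,
            thresholds$t2 < thresholds$t3)
  has <- !is.na(links$tfcr_id)
  if (any(has & is.na(links$distance)))
    stop("link with unset distance", call. = FALSE)
  d <- links$distance
  region <- rep(NA_character_, nrow(links))
  region[has & d <= thresholds$t1] <- "R1"
  region[has & d > thresholds$t1 & d <= thresholds$t2] <- "R2"
  region[has & d > thresholds$t2 & d <= thresholds$t3] <- "R3"
  region[has & d > thresholds$t3] <- "R4"
  links$region <- region
  links
}

#' Region proportions over classified links
#'
#' @param links Classified link \code{data.frame}; \code{no_TFCR} links
#'   are excluded.
#' @return Named numeric vector over R1-R4 summing to 1.
#' @export
region_proportions <- function(links) {
  r <- links$region[!is.na(links$region)]
  if (!length(r)) stop("no classified links", call. = FALSE)
  counts <- table(factor(r, levels = c("R1", "R2", "R3", "R4")))
  setNames(as.numeric(counts) / length(r), names(counts))
}

#' Group genes by expression
#'
#' Schemes: \code{"HL"} — H iff FPKM strictly > 1, else L; \code{"E6"} —
#' six equal-size rank bins E1 (lowest) to E6; \code{"Q100"} — one hundred
#' rank bins Q1..Q100. Rank bins use nearest-rank quantile cuts so tied
#' values share the lower bin.
#'
#' @param expr Expression \code{data.frame} from
#'   \code{\link{read_expression}}.
#' @param scheme One of \code{"HL"}, \code{"E6"}, \code{"Q100"}.
#' @return Named character vector gene_id -> label.
#' @export
expression_groups <- function(expr, scheme = c("HL", "E6", "Q100")) {
  scheme <- match.arg(scheme)
  if (!nrow(expr)) stop("empty expression table", call. = FALSE)
  if (scheme == "HL")
    return(setNames(ifelse(expr$fpkm > 1, "H", "L"), expr$gene_id))
  n_bins <- if (scheme == "E6") 6L else 100L
  prefix <- if (scheme == "E6") "E" else "Q"
  cuts <- stats::quantile(expr$fpkm, probs = seq_len(n_bins - 1) / n_bins,
                          type = 1, names = FALSE)
  bin <- vapply(expr$fpkm, function(v) sum(v > cuts), 0L) + 1L
  setNames(paste0(prefix, bin), expr$gene_id)
}
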