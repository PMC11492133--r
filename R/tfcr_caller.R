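#' Gaussian kernel density track of TFBS midpoints
#'
#' Computes, per chromosome, the unnormalised Gaussian kernel sum
#' \deqn{f(x) = \sum_j \exp(-(x - m_j)^2 / (2\sigma^2))}
#' over all TFBS midpoints \eqn{m_j}, evaluated on a regular grid. The sum
#' is deliberately unnormalised — a single TFBS contributes ~1.0 at
#' zero distance — so that the downstream 0.1 contribution threshold has an
#' absolute meaning independent of the number of sites. Kernels are
#' truncated beyond \code{truncation_sigmas} standard deviations and
#' shifted down by the edge value so the track stays continuous (a hard
#' cutoff would plant spurious, grid-resolution-dependent micro-maxima at
#' truncation edges); at the default 4 sigma the per-TFBS deviation from
#' the exact Gaussian sum stays below 3.4e-4. Contribution weights used
#' for TFCR scoring are exact Gaussians, unaffected by this shift.
#'
#' @param tfbs TFBS \code{data.frame} (see \code{\link{read_fimo_tfbs}}).
#' @param bandwidth_bp Kernel standard deviation sigma in bp (default 300).
#' @param grid_step_bp Grid spacing in bp (default 10).
#' @param truncation_sigmas Truncation radius in units of sigma (default 4).
#' @return List of density tracks, one per chromosome carrying TFBSs; each
#'   a list with \code{chrom}, \code{grid_start}, \code{grid_step},
#'   \code{values}. Empty input gives an empty list.
#' @export
kde_density <- function(tfbs, bandwidth_bp = 300, grid_step_bp = 10,
                        truncation_sigmas = 4) {
  stopifnot(bandwidth_bp > 0, grid_step_bp >= 1)
  if (!nrow(tfbs)) return(list())
  sigma <- bandwidth_bp
  radius <- truncation_sigmas * sigma
  edge <- exp(-truncation_sigmas^2 / 2)   # continuity shift at the cutoff
  tracks <- lapply(split(tfbs$midpoint, tfbs$chrom), function(mids) {
    grid_start <- min(mids) - radius
    grid_end <- max(mids) + radius
    n <- as.integer((grid_end - grid_start) %/% grid_step_bp) + 1L
    values <- numeric(n)
    for (m in mids) {
      lo <- max(1L, as.integer(ceiling((m - radius - grid_start) / grid_step_bp)) + 1L)
      hi <- min(n, as.integer(floor((m + radius - grid_start) / grid_step_bp)) + 1L)
      if (lo > hi) next
      x <- grid_start + (seq.int(lo, hi) - 1) * grid_step_bp
      values[lo:hi] <- values[lo:hi] +
        (exp(-(x - m)^2 / (2 * sigma^2)) - edge)
    }
    list(grid_start = as.integer(grid_start), grid_step = as.integer(grid_step_bp),
         values = values, sigma = sigma, truncation_sigmas = truncation_sigmas)
  })
  for (ch in names(tracks)) tracks[[ch]]$chrom <- ch
  tracks[order(names(tracks))]
}

# Polish a coarse-grid density maximum to base-pair precision: evaluate
# the same continuous truncated kernel sum on the 1-bp positions within
# one grid step of the coarse peak and take the argmax (plateau ties
# collapse to their center). Keeps peak positions independent of the
# grid resolution, so contribution sets are too.
refine_peak <- function(coarse, step, mids, sigma, radius, edge) {
  cand <- (coarse - step + 1L):(coarse + step - 1L)
  near <- mids[abs(mids - coarse) <= radius + step]
  v <- vapply(cand, function(x) {
    d <- abs(x - near)
    sum((exp(-d^2 / (2 * sigma^2)) - edge)[d <= radius])
  }, 0)
  best <- which(v == max(v))
  as.integer(cand[(best[1] + best[length(best)]) %/% 2L])
}

# Local maxima of a numeric vector with plateau collapse: runs of equal
# values strictly above both flanking runs are maxima, reported at their
# center index; track boundaries count as -Inf (a monotone edge is never
# a maximum, a genuinely peaked edge is).
local_maxima_idx <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  is_max <- r$values > left & r$values > right
  as.integer((starts[is_max] + ends[is_max]) %/% 2L)
}

#' Call TFCRs from density tracks
#'
#' Each local maximum of the per-chromosome kernel density is a candidate
#' TFCR (plateaus collapse to their center grid point; two equal-height
#' maxima separated by a strict dip stay distinct). Each coarse-grid
#' maximum is then polished to base-pair precision by a local 1-bp
#' argmax of the same kernel sum, so peak positions — and with them the
#' contribution sets — do not depend on the evaluation grid step. A TFBS contributes to
#' a TFCR when its Gaussian kernel weight at the peak position,
#' \eqn{\exp(-d^2/(2\sigma^2))}, is at least \code{contribution_threshold};
#' at the defaults (sigma = 300 bp, threshold 0.1) the cutoff radius is
#' \eqn{\sigma\sqrt{2\ln 10} \approx 643.8} bp. Candidates with no
#' contributing TFBS (e.g. minute truncation artefacts) are discarded. The
#' TFCR interval is the span of its contributing TFBS intervals, so the
#' width TW reflects binding-site extent; TC is the family-deduplicated
#' kernel-weight sum (see \code{\link{tfcr_complexity}}), and cw = TC/TW.
#'
#' @param tracks Output of \code{\link{kde_density}} over the same
#'   \code{tfbs}.
#' @param tfbs TFBS \code{data.frame}.
#' @param contribution_threshold Minimum kernel weight (default 0.1).
#' @param stage Stage/sample label baked into the deterministic ids
#'   \code{"{stage}_{chrom}_{peak_pos}"}.
#' @return \code{data.frame} with one row per TFCR: \code{tfcr_id},
#'   \code{stage}, \code{chrom}, \code{start}, \code{end}, \code{peak_pos},
#'   \code{TC}, \code{TW}, \code{cw}, \code{n_families}, \code{n_tfbs},
#'   \code{CAS} (NA until \code{\link{compute_cas}}), \code{tc_bin} (unset),
#'   and a list-column \code{contrib} of per-TFCR contribution tables
#'   (\code{tf_name}, \code{tf_family}, \code{start}, \code{end},
#'   \code{midpoint}, \code{distance}, \code{weight}).
#' @export
call_tfcrs <- function(tracks, tfbs, contribution_threshold = 0.1,
                       stage = "S1") {
  track_chroms <- vapply(tracks, `[[`, "", "chrom")
  if (!setequal(track_chroms, unique(tfbs$chrom)))
    stop("tracks/tfbs chromosome mismatch", call. = FALSE)
  rows <- list()
  for (tr in tracks) {
    sub <- tfbs[tfbs$chrom == tr$chrom, , drop = FALSE]
    sigma <- tr$sigma
    cutoff <- sigma * sqrt(2 * log(1 / contribution_threshold))
    radius <- tr$truncation_sigmas * sigma
    edge <- exp(-tr$truncation_sigmas^2 / 2)
    idx <- local_maxima_idx(tr$values)
    for (i in idx) {
      coarse <- tr$grid_start + (i - 1L) * tr$grid_step
      peak <- refine_peak(coarse, tr$grid_step, sub$midpoint, sigma,
                          radius, edge)
      d <- abs(peak - sub$midpoint)
      w <- exp(-d^2 / (2 * sigma^2))
      keep <- which(w >= contribution_threshold & d <= cutoff + 1e-9)
      if (!length(keep)) next
      contrib <- data.frame(
        tf_name = sub$tf_name[keep], tf_family = sub$tf_family[keep],
        start = sub$start[keep], end = sub$end[keep],
        midpoint = sub$midpoint[keep],
        distance = as.integer(d[keep]), weight = w[keep],
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- list(
        chrom = tr$chrom, peak_pos = as.integer(peak),
        # span of contributing sites, widened minimally so the grid peak
        # always lies inside the interval (a lone narrow site can
        # otherwise leave a sub-grid-step peak just outside it)
        start = min(contrib$start, peak),
        end = max(contrib$end, peak + 1L),
        contrib = contrib
      )
    }
  }
  if (!length(rows)) return(empty_tfcr_df())
  df <- data.frame(
    tfcr_id = vapply(rows, function(r) paste(stage, r$chrom, r$peak_pos, sep = "_"), ""),
    stage = stage,
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    peak_pos = vapply(rows, `[[`, 0L, "peak_pos"),
    stringsAsFactors = FALSE
  )
  df$TC <- vapply(rows, function(r) tfcr_complexity(r$contrib), 0)
  df$TW <- df$end - df$start
  df$cw <- df$TC / df$TW
  df$n_families <- vapply(rows, function(r) length(unique(r$contrib$tf_family)), 0L)
  df$n_tfbs <- vapply(rows, function(r) nrow(r$contrib), 0L)
  df$CAS <- NA_real_
  df$tc_bin <- NA_character_
  df$contrib <- I(lapply(rows, `[[`, "contrib"))
  df <- df[order(df$chrom, df$peak_pos), ]
  # neighbouring coarse maxima can polish onto the same base: keep one
  df <- df[!duplicated(df[c("chrom", "peak_pos")]), ]
  rownames(df) <- NULL
  df
}

empty_tfcr_df <- function() {
  df <- data.frame(tfcr_id = character(0), stage = character(0),
                   chrom = character(0), start = integer(0), end = integer(0),
                   peak_pos = integer(0), TC = numeric(0), TW = integer(0),
                   cw = numeric(0), n_families = integer(0), n_tfbs = integer(0),
                   CAS = numeric(0), tc_bin = character(0),
                   stringsAsFactors = FALSE)
  df$contrib <- I(list())
  df
}

#' TFCR complexity (TC) with family-locus deduplication
#'
#' TC is the sum of Gaussian kernel weights of the contributing TFBSs,
#' after collapsing same-family sites that occupy the same locus: within a
#' TF family, TFBSs whose intervals overlap (transitively, i.e. connected
#' components of the overlap graph) count once, keeping the group's maximum
#' weight. Same-family sites at non-overlapping loci count separately;
#' different families always count separately. With every weight at most 1,
#' TC never exceeds the number of deduplicated groups.
#'
#' @param contributions Contribution table of one TFCR (columns
#'   \code{tf_family}, \code{start}, \code{end}, \code{weight}).
#' @return Non-negative real TC.
#' @export
tfcr_complexity <- function(contributions) {
  if (!nrow(contributions)) return(0)
  total <- 0
  for (fam in unique(contributions$tf_family)) {
    g <- contributions[contributions$tf_family == fam, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    # sweep: chain overlapping intervals into locus groups
    grp_max <- g$weight[1]
    reach <- g$end[1]
    if (nrow(g) > 1) for (i in 2:nrow(g)) {
      if (g$start[i] < reach) {          # half-open overlap
        grp_max <- max(grp_max, g$weight[i])
        reach <- max(reach, g$end[i])
      } else {
        total <- total + grp_max
        grp_max <- g$weight[i]
        reach <- g$end[i]
      }
    }
    total <- total + grp_max
  }
  total
}

#' Assign per-sample TC decile bins
#'
#' Bins TFCRs of one sample into \code{n_bins} quantile classes of TC
#' (nearest-rank quantiles, type 1), labelled \code{TC0} (lowest) to
#' \code{TC9} (highest) for the default 10 bins. Equal TC values always
#' share a bin, so heavy ties inflate low bins rather than being split
#' arbitrarily.
#'
#' @param tfcrs TFCR \code{data.frame}.
#' @param n_bins Number of bins (default 10).
#' @return \code{tfcrs} with \code{tc_bin} set.
#' @export
assign_tc_bins <- function(tfcrs, n_bins = 10) {
  if (nrow(tfcrs) < n_bins)
    stop("fewer TFCRs (", nrow(tfcrs), ") than bins (", n_bins,
         "); use a smaller n_bins", call. = FALSE)
  cuts <- stats::quantile(tfcrs$TC, probs = seq_len(n_bins - 1) / n_bins,
                          type = 1, names = FALSE)
  bin <- vapply(tfcrs$TC, function(tc) sum(tc > cuts), 0L)
  tfcrs$tc_bin <- paste0("TC", bin)
  tfcrs
}

#' Chromatin accessibility score (CAS) of TFCRs
#'
#' CAS is defined here as the mean score of the ATAC peaks overlapping the
#' TFCR interval by at least 1 bp; a TFCR overlapping no peak gets a
#' missing CAS. Note: the originating study cites an external CAS
#' definition without restating it; the overlapping-peak mean used here is
#' this package's own, documented reading.
#'
#' @param tfcrs TFCR \code{data.frame}.
#' @param atac_peaks Scored peak \code{data.frame} (\code{chrom},
#'   \code{start}, \code{end}, \code{score}) from
#'   \code{\link{read_bed}(scored = TRUE)}.
#' @return \code{tfcrs} with \code{CAS} filled in.
#' @export
compute_cas <- function(tfcrs, atac_peaks) {
  if (!nrow(tfcrs)) return(tfcrs)
  tfcrs$CAS <- NA_real_
  if (!nrow(atac_peaks)) return(tfcrs)
  gr_t <- as_granges0(tfcrs$chrom, tfcrs$start, tfcrs$end)
  gr_p <- as_granges0(atac_peaks$chrom, atac_peaks$start, atac_peaks$end)
  hits <- GenomicRanges::findOverlaps(gr_t, gr_p, minoverlap = 1L)
  if (length(hits)) {
    means <- tapply(atac_peaks$score[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), mean)
    tfcrs$CAS[as.integer(names(means))] <- as.numeric(means)
  }
  tfcrs
}
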