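#' Assign TFCR-gene links to TADs
#'
#' A TFCR belongs to the TAD containing its density peak, a gene to the
#' TAD containing its TSS (half-open containment, so a position exactly
#' at a TAD end belongs to the next TAD). The link status is
#' \code{same_TAD} iff both elements fall in the same TAD; an element
#' outside all TADs makes the link \code{not_same_TAD}. TADs must be
#' non-overlapping within a sample.
#'
#' @param links Link \code{data.frame} (needs \code{peak_pos},
#'   \code{tss}, \code{chrom}).
#' @param tads TAD intervals (\code{chrom}, \code{start}, \code{end}),
#'   0-based half-open.
#' @return \code{links} with \code{tfcr_tad}, \code{gene_tad} (TAD row
#'   index or NA) and \code{tad_status} columns.
#' @export
assign_tads <- function(links, tads) {
  gr_tads <- as_granges0(tads$chrom, tads$start, tads$end)
  ov <- GenomicRanges::findOverlaps(gr_tads, gr_tads)
  ov <- ov[S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)]
  if (length(ov))
    stop("overlapping TADs: rows ",
         paste(unique(pmin(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))),
               collapse = ", "), call. = FALSE)
  locate <- function(chrom, pos) {
    out <- rep(NA_integer_, length(pos))
    ok <- !is.na(pos)
    if (any(ok)) {
      gr <- as_granges0(chrom[ok], pos[ok], pos[ok] + 1L)
      hits <- GenomicRanges::findOverlaps(gr, gr_tads, type = "within")
      idx <- which(ok)
      out[idx[S4Vectors::queryHits(hits)]] <- S4Vectors::subjectHits(hits)
    }
    out
  }
  links$tfcr_tad <- locate(links$chrom, links$peak_pos)
  links$gene_tad <- locate(links$chrom, links$tss)
  links$tad_status <- ifelse(!is.na(links$tfcr_tad) & !is.na(links$gene_tad) &
                               links$tfcr_tad == links$gene_tad,
                             "same_TAD", "not_same_TAD")
  links
}

#' Annotate TFCRs with phase-separation TF content
#'
#' Counts, per TFCR, the distinct contributing TF names that appear in
#' the phase-separation TF (PSTF) list (case-insensitive name match;
#' unmatched list entries are reported once via message). The percentage
#' uses the number of distinct TFs on the TFCR as denominator.
#'
#' @param tfcrs TFCR \code{data.frame} with the \code{contrib}
#'   list-column from \code{\link{call_tfcrs}}.
#' @param pstf_list Character vector of PSTF names (non-empty).
#' @return \code{tfcrs} with \code{has_pstf}, \code{n_pstf},
#'   \code{pct_pstf} columns; group label \code{PSTF}/\code{not_PSTF} in
#'   \code{pstf_group}.
#' @export
annotate_pstf <- function(tfcrs, pstf_list) {
  if (!length(pstf_list)) stop("empty PSTF list", call. = FALSE)
  pstf <- unique(toupper(pstf_list))
  seen <- toupper(unique(unlist(lapply(tfcrs$contrib, function(x) x$tf_name))))
  unmatched <- setdiff(pstf, seen)
  if (length(unmatched))
    message(length(unmatched), " PSTF name(s) not found among motif TF names")
  stats <- lapply(tfcrs$contrib, function(x) {
    tfs <- unique(toupper(x$tf_name))
    n <- sum(tfs %in% pstf)
    c(n = n, tot = length(tfs))
  })
  tfcrs$n_pstf <- vapply(stats, `[[`, 0, "n")
  tot <- vapply(stats, `[[`, 0, "tot")
  tfcrs$has_pstf <- tfcrs$n_pstf >= 1
  tfcrs$pct_pstf <- ifelse(tot > 0, tfcrs$n_pstf / tot, 0)
  tfcrs$pstf_group <- ifelse(tfcrs$has_pstf, "PSTF", "not_PSTF")
  tfcrs
}

#' Pairwise group comparison with Welch t-tests
#'
#' All pairwise Welch tests between named groups of values, with the
#' significance star ladder and per-group summaries (n, median, IQR).
#' Groups with fewer than 2 finite values are excluded with a message.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups).
#' @return List with \code{summary} (per group) and \code{tests} (one row
#'   per pair: \code{group_a}, \code{group_b}, \code{t}, \code{p_value},
#'   \code{stars}).
#' @export
group_compare <- function(values_by_group) {
  values_by_group <- lapply(values_by_group, function(v) v[is.finite(v)])
  small <- lengths(values_by_group) < 2
  if (any(small)) {
    message("excluding group(s) with < 2 values: ",
            paste(names(values_by_group)[small], collapse = ", "))
    values_by_group <- values_by_group[!small]
  }
  if (length(values_by_group) < 2) stop("need >= 2 usable groups", call. = FALSE)
  summ <- data.frame(
    group = names(values_by_group),
    n = lengths(values_by_group),
    median = vapply(values_by_group, stats::median, 0),
    iqr = vapply(values_by_group, stats::IQR, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(names(values_by_group), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tt <- welch_ttest(values_by_group[[a]], values_by_group[[b]])
    data.frame(group_a = a, group_b = b, t = tt$t, p_value = tt$p_value,
               stars = tt$stars, stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}
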