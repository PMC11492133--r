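#' @importFrom utils read.table write.table head
#' @importFrom stats setNames
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# FIMO input (1-based inclusive) is shifted exactly once, at the read boundary.

#' Convert 0-based half-open intervals to a GRanges
#'
#' Internal helper bridging the package's 0-based half-open convention to
#' the 1-based closed convention of \pkg{GenomicRanges}.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @return A \link[GenomicRanges]{GRanges} object.
#' @keywords internal
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

validate_intervals <- function(chrom, start, end, where = "interval") {
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop(where, ": empty chromosome name", call. = FALSE)
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop(where, ": start >= end (or negative start) at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read a two-column TF-to-family map
#'
#' @param path Tab-separated file with columns \code{tf_name}, \code{tf_family}
#'   (CIS-BP style; header optional, detected by a non-data first line).
#' @return Named character vector mapping TF name to family.
#' @export
read_family_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#", quote = "")
  if (ncol(df) < 2) stop("family map needs two tab-separated columns", call. = FALSE)
  if (identical(tolower(df[1, 1]), "tf_name")) df <- df[-1, , drop = FALSE]
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read FIMO motif occurrences as TFBS records
#'
#' Parses the tab-separated FIMO output dialect (header row with columns
#' \code{motif_id}, \code{motif_alt_id}, \code{sequence_name}, \code{start},
#' \code{stop}, \code{strand}, \code{score}, \code{p-value}, \code{q-value},
#' \code{matched_sequence}). FIMO coordinates are 1-based inclusive and are
#' converted here, exactly once, to the package's 0-based half-open
#' convention. The TF name is taken from \code{motif_alt_id} when present,
#' else \code{motif_id}; the family is attached from \code{family_map}
#' (unknown TFs are bucketed as family \code{"UNKNOWN"} rather than dropped,
#' since dropping them would silently deflate complexity). Exact duplicate
#' hits (same motif, interval and strand) are removed.
#'
#' @param path FIMO TSV file.
#' @param family_map Named character vector (see \code{\link{read_family_map}}),
#'   or \code{NULL} for all-UNKNOWN families.
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{tf_name}, \code{tf_family},
#'   \code{scan_score}, \code{midpoint}, sorted by (chrom, start).
#' @export
read_fimo_tfbs <- function(path, family_map = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#", quote = "", check.names = FALSE)
  need <- c("motif_id", "sequence_name", "start", "stop", "strand", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("FIMO file missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  s <- suppressWarnings(as.integer(df$start))
  e <- suppressWarnings(as.integer(df$stop))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("non-integer coordinate at data line ", bad[1], call. = FALSE)
  tf <- if ("motif_alt_id" %in% names(df) && any(nzchar(df$motif_alt_id)))
    ifelse(nzchar(df$motif_alt_id), df$motif_alt_id, df$motif_id) else df$motif_id
  out <- data.frame(
    chrom = df$sequence_name,
    start = s - 1L,                     # 1-based inclusive -> 0-based half-open
    end = e,
    strand = df$strand,
    tf_name = tf,
    scan_score = as.numeric(df$score),
    stringsAsFactors = FALSE
  )
  validate_intervals(out$chrom, out$start, out$end, "FIMO record")
  out$tf_family <- if (is.null(family_map)) "UNKNOWN" else {
    fam <- unname(family_map[out$tf_name])
    ifelse(is.na(fam), "UNKNOWN", fam)
  }
  out$midpoint <- (out$start + out$end) %/% 2L
  out <- out[!duplicated(out[c("chrom", "start", "end", "strand", "tf_name")]), ]
  out <- out[order(out$chrom, out$start, out$end, out$tf_name), ]
  rownames(out) <- NULL
  out[c("chrom", "start", "end", "strand", "tf_name", "tf_family",
        "scan_score", "midpoint")]
}

#' Read a BED3/BED6 file
#'
#' Track and comment lines are skipped; rows are validated
#' (\code{start < end}) and returned sorted by (chrom, start).
#'
#' @param path BED file.
#' @param scored If \code{TRUE}, column 5 is kept as \code{score} (ATAC peak
#'   score convention).
#' @return \code{data.frame} with \code{chrom}, \code{start}, \code{end},
#'   plus \code{name}, \code{score}, \code{strand} where present.
#' @export
read_bed <- function(path, scored = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  empty_cols <- c("chrom", "start", "end",
                  if (scored) "score")
  if (!any(keep)) {
    out <- as.data.frame(setNames(rep(list(logical(0)), length(empty_cols)),
                                  empty_cols))
    out$chrom <- character(0)
    return(out)
  }
  df <- read.table(text = lines[keep], sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad))
    stop("BED: start >= end at line ", which(keep)[bad[1]], call. = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  if (ncol(df) >= 5) out$score <- as.numeric(df[[5]])
  if (ncol(df) >= 6) out$strand <- as.character(df[[6]])
  if (scored) {
    if (is.null(out$score)) stop("scored BED requires >= 5 columns", call. = FALSE)
    if (any(!is.finite(out$score))) stop("non-finite BED score", call. = FALSE)
  }
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Read gene TSS annotation from BED or GTF
#'
#' One transcription start site per gene: for \code{+}-strand genes the TSS
#' is the interval start, for \code{-}-strand genes the last base
#' (\code{end - 1} in 0-based coordinates). Duplicate gene ids keep the
#' first occurrence with a warning.
#'
#' @param path Annotation file.
#' @param format \code{"bed"} (gene id in column 4, strand in column 6) or
#'   \code{"gtf"} (rows of \code{feature} type, gene id from the
#'   \code{gene_id} attribute).
#' @param feature GTF feature type to use (default \code{"gene"}).
#' @return \code{data.frame} with \code{gene_id}, \code{chrom}, \code{tss}
#'   (0-based), \code{strand}.
#' @export
read_gene_tss <- function(path, format = c("bed", "gtf"), feature = "gene") {
  format <- match.arg(format)
  if (format == "bed") {
    df <- read_bed(path)
    if (is.null(df$name)) stop("BED gene file needs a name column", call. = FALSE)
    strand <- if (is.null(df$strand)) rep("+", nrow(df)) else df$strand
    tss <- ifelse(strand == "-", df$end - 1L, df$start)
    out <- data.frame(gene_id = df$name, chrom = df$chrom,
                      tss = as.integer(tss), strand = strand,
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    df <- read.table(text = lines, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, quote = "")
    df <- df[df[[3]] == feature, , drop = FALSE]
    if (!nrow(df)) stop("no '", feature, "' rows in GTF", call. = FALSE)
    if (any(!df[[7]] %in% c("+", "-")))
      stop("GTF gene without strand: TSS undefined", call. = FALSE)
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", df[[9]])
    # GTF is 1-based inclusive
    start0 <- as.integer(df[[4]]) - 1L
    end0 <- as.integer(df[[5]])
    tss <- ifelse(df[[7]] == "-", end0 - 1L, start0)
    out <- data.frame(gene_id = gid, chrom = as.character(df[[1]]),
                      tss = as.integer(tss), strand = df[[7]],
                      stringsAsFactors = FALSE)
  }
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene id(s); keeping first occurrence")
    out <- out[!dup, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$tss), ]
  rownames(out) <- NULL
  out
}

#' Read a gene expression table
#'
#' Two tab-separated columns, \code{gene_id} and FPKM-like expression
#' (header optional). The log-scale column \code{log_expr = log10(FPKM + 1)}
#' used throughout the statistics is attached. Missing genes are
#' distinguishable from zero-expression genes simply by absence from the
#' table.
#'
#' @param path Expression TSV.
#' @return \code{data.frame} with \code{gene_id}, \code{fpkm},
#'   \code{log_expr}.
#' @export
read_expression <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#", quote = "")
  if (suppressWarnings(is.na(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  fpkm <- as.numeric(df[[2]])
  if (any(is.na(fpkm) | fpkm < 0)) stop("expression must be numeric >= 0", call. = FALSE)
  data.frame(gene_id = as.character(df[[1]]), fpkm = fpkm,
             log_expr = log10(fpkm + 1), stringsAsFactors = FALSE)
}

#' Read a one-name-per-line list (gene list, PSTF list)
#'
#' @param path Plain-text file, one identifier per line; \code{#} comments
#'   and blank lines skipped.
#' @return Character vector of unique identifiers.
#' @export
read_name_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

tfcr_table_cols <- c("chrom", "start", "end", "tfcr_id", "TC", "strand",
                     "peak_pos", "TW", "cw", "CAS", "tc_bin", "n_families")

#' Write a TFCR table as BED6+ with a TSV twin
#'
#' Writes \code{path} as BED6+ (chrom, start, end, tfcr_id, TC, strand,
#' peak_pos, TW, cw, CAS, tc_bin, n_families; header line prefixed
#' \code{#}) and a plain TSV twin next to it (same stem, \code{.tsv}).
#' Numeric fields are printed with enough digits that
#' \code{\link{read_tfcr_table}} reproduces them to at least 6 decimals.
#'
#' @param tfcrs TFCR \code{data.frame} from \code{\link{call_tfcrs}} (an
#'   empty table yields a header-only file).
#' @param path Output BED path.
#' @return Invisibly, the two paths written.
#' @export
write_tfcr_table <- function(tfcrs, path) {
  df <- data.frame(
    chrom = as.character(tfcrs$chrom %||% character(0)),
    start = tfcrs$start %||% integer(0),
    end = tfcrs$end %||% integer(0),
    tfcr_id = tfcrs$tfcr_id %||% character(0),
    TC = fmt_num(tfcrs$TC %||% numeric(0)),
    strand = rep(".", nrow(tfcrs)),
    peak_pos = tfcrs$peak_pos %||% integer(0),
    TW = tfcrs$TW %||% integer(0),
    cw = fmt_num(tfcrs$cw %||% numeric(0)),
    CAS = fmt_num(tfcrs$CAS %||% numeric(0)),
    tc_bin = as.character(tfcrs$tc_bin %||% character(0)),
    n_families = tfcrs$n_families %||% integer(0),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(tfcr_table_cols, collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, na = "NA")
  tsv <- paste0(tools::file_path_sans_ext(path), ".tsv")
  write.table(setNames(df, tfcr_table_cols), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(c(bed = path, tsv = tsv))
}

#' Read back a TFCR table written by \code{\link{write_tfcr_table}}
#'
#' @param path BED6+ path written by \code{\link{write_tfcr_table}}.
#' @return TFCR \code{data.frame} (without contribution details).
#' @export
read_tfcr_table <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      tfcr_id = character(0), TC = numeric(0), strand = character(0),
                      peak_pos = integer(0), TW = integer(0), cw = numeric(0),
                      CAS = numeric(0), tc_bin = character(0), n_families = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  df <- read.table(text = body, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, na.strings = "NA", quote = "")
  names(df) <- tfcr_table_cols
  df$TC <- as.numeric(df$TC); df$cw <- as.numeric(df$cw); df$CAS <- as.numeric(df$CAS)
  df
}

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 10)
  out[is.na(x)] <- NA
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
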