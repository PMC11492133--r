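#' Build a stage collection
#'
#' Ordered container for multi-stage analyses (e.g. 2Cell, 4Cell, 8Cell,
#' ICM, primed-hESC): per stage a TFCR table, optional links and an
#' optional expression table.
#'
#' @param stages Named list, in developmental order; each element a list
#'   with \code{tfcrs} and optionally \code{links}, \code{expr}.
#' @return Object of class \code{stage_collection}.
#' @export
stage_collection <- function(stages) {
  if (is.null(names(stages)) || anyDuplicated(names(stages)))
    stop("stages must be uniquely named", call. = FALSE)
  structure(list(stage_names = names(stages), stages = stages),
            class = "stage_collection")
}

#' @export
print.stage_collection <- function(x, ...) {
  cat("<stage_collection> ", paste(x$stage_names, collapse = " -> "), "\n")
  for (s in x$stage_names)
    cat(sprintf("  %-12s %d TFCRs\n", s, nrow(x$stages[[s]]$tfcrs)))
  invisible(x)
}

#' All overlapping TFCR pairs between two stages
#'
#' Interval overlap of at least \code{min_overlap_bp} (half-open
#' convention: touching intervals do not overlap), computed with a
#' \pkg{GenomicRanges} sweep.
#'
#' @param a,b TFCR \code{data.frame}s.
#' @param min_overlap_bp Minimum overlap (default 1).
#' @return \code{data.frame} with \code{a_id}, \code{b_id}.
#' @export
overlap_pairs <- function(a, b, min_overlap_bp = 1) {
  if (!nrow(a) || !nrow(b))
    return(data.frame(a_id = character(0), b_id = character(0),
                      stringsAsFactors = FALSE))
  hits <- GenomicRanges::findOverlaps(
    as_granges0(a$chrom, a$start, a$end),
    as_granges0(b$chrom, b$start, b$end),
    minoverlap = as.integer(min_overlap_bp))
  data.frame(a_id = a$tfcr_id[S4Vectors::queryHits(hits)],
             b_id = b$tfcr_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

filter_scope <- function(stage, scope) {
  tfcrs <- stage$tfcrs
  if (scope == "LR_only") {
    if (is.null(stage$links)) stop("LR_only scope needs classified links", call. = FALSE)
    lr <- unique(stage$links$tfcr_id[stage$links$region %in% "R4"])
    tfcrs <- tfcrs[tfcrs$tfcr_id %in% lr, , drop = FALSE]
  }
  tfcrs
}

#' Gained / lost / kept TFCRs between consecutive stages
#'
#' Cross-stage TFCR identity is positional: a TFCR at stage s is
#' \emph{gained} when no TFCR of stage s-1 overlaps it by at least 1 bp,
#' \emph{lost} when no TFCR of stage s+1 does, and \emph{kept} otherwise.
#' Gained is undefined (empty) at the first stage and lost at the last.
#' Scope \code{"LR_only"} first restricts each stage to its long-range
#' (R4) TFCRs.
#'
#' @param collection \code{stage_collection} with >= 2 stages.
#' @param scope \code{"all"} or \code{"LR_only"}.
#' @param min_overlap_bp Overlap threshold (default 1).
#' @return Named list per stage: \code{gained}, \code{lost}, \code{kept}
#'   (character vectors of tfcr ids).
#' @export
gained_lost <- function(collection, scope = c("all", "LR_only"),
                        min_overlap_bp = 1) {
  scope <- match.arg(scope)
  sn <- collection$stage_names
  if (length(sn) < 2) stop("need >= 2 stages", call. = FALSE)
  sets <- lapply(collection$stages, filter_scope, scope = scope)
  out <- list()
  for (i in seq_along(sn)) {
    ids <- sets[[i]]$tfcr_id
    gained <- character(0); lost <- character(0)
    if (i > 1) {
      ov <- overlap_pairs(sets[[i]], sets[[i - 1]], min_overlap_bp)
      gained <- setdiff(ids, ov$a_id)
    }
    if (i < length(sn)) {
      ov <- overlap_pairs(sets[[i]], sets[[i + 1]], min_overlap_bp)
      lost <- setdiff(ids, ov$a_id)
    }
    out[[sn[i]]] <- list(gained = gained, lost = lost,
                         kept = setdiff(ids, union(gained, lost)))
  }
  out
}

#' Genomic regions stably occupied by TFCRs across all stages
#'
#' Sequential interval-set intersection (stage1 ∩ stage2 ∩ ...): the
#' fragments of the genome covered by at least one TFCR in \emph{every}
#' stage, each of length >= 1 bp. Intersection commutes, so the result is
#' invariant to stage order. Each fragment is annotated with the
#' contributing TFCR ids per stage.
#'
#' @param collection \code{stage_collection}; any empty stage yields an
#'   empty result with a warning.
#' @param scope \code{"all"} or \code{"LR_only"}.
#' @return \code{data.frame}: \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) plus one \code{ids_<stage>} column per stage.
#' @export
stable_regions <- function(collection, scope = c("all", "LR_only")) {
  scope <- match.arg(scope)
  sets <- lapply(collection$stages, filter_scope, scope = scope)
  if (any(vapply(sets, nrow, 0L) == 0)) {
    warning("at least one empty stage: no stable regions")
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  grs <- lapply(sets, function(s) as_granges0(s$chrom, s$start, s$end))
  inter <- Reduce(function(x, y)
    GenomicRanges::intersect(GenomicRanges::reduce(x), GenomicRanges::reduce(y)),
    grs)
  inter <- inter[IRanges::width(inter) >= 1]
  if (!length(inter))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(inter)),
                    start = GenomicRanges::start(inter) - 1L,
                    end = GenomicRanges::end(inter),
                    stringsAsFactors = FALSE)
  for (s in names(sets)) {
    hits <- GenomicRanges::findOverlaps(inter, grs[[s]], minoverlap = 1L)
    ids <- rep("", length(inter))
    if (length(hits)) {
      agg <- tapply(sets[[s]]$tfcr_id[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(v) paste(sort(unique(v)), collapse = ","))
      ids[as.integer(names(agg))] <- as.character(agg)
    }
    out[[paste0("ids_", s)]] <- ids
  }
  rownames(out) <- NULL
  out
}

#' Distance histogram of long-range links
#'
#' Bins R4 (> 50 kb) link distances into 50-100 kb, 100-150 kb,
#' 150-200 kb and > 200 kb (closed-left bins).
#'
#' @param links Classified links restricted to region R4; any non-R4 link
#'   is an error.
#' @return Named integer vector of counts summing to the number of links.
#' @export
lr_distance_bins <- function(links) {
  if (any(!links$region %in% "R4"))
    stop("lr_distance_bins expects R4 links only", call. = FALSE)
  d <- links$distance
  bins <- cut(d, breaks = c(50000, 100000, 150000, 200000, Inf),
              labels = c("50-100k", "100-150k", "150-200k", ">200k"),
              right = FALSE)
  if (any(is.na(bins))) stop("R4 link with distance <= 50k", call. = FALSE)
  tab <- table(bins)
  setNames(as.integer(tab), names(tab))
}

#' Gene-anchored TC trajectories across stages
#'
#' For each gene and stage, the TC of the gene's nearest TFCR (maximum TC
#' on exact-distance ties); genes lacking a TFCR link in any stage are
#' excluded (count messaged). Rows are z-standardised (mean 0, sd 1)
#' for trajectory clustering; zero-variance rows are excluded.
#'
#' @param collection \code{stage_collection} whose stages carry
#'   \code{links} (direction gene_to_tfcr) and \code{tfcrs}.
#' @return Numeric matrix, genes x stages, z-standardised.
#' @export
tc_trajectories <- function(collection) {
  sn <- collection$stage_names
  if (length(sn) < 2) stop("need >= 2 stages", call. = FALSE)
  per_stage <- lapply(sn, function(s) {
    st <- collection$stages[[s]]
    if (is.null(st$links)) stop("stage ", s, " has no links", call. = FALSE)
    ln <- st$links[!is.na(st$links$tfcr_id), , drop = FALSE]
    tc <- st$tfcrs$TC[match(ln$tfcr_id, st$tfcrs$tfcr_id)]
    tapply(tc, ln$gene_id, max)
  })
  genes <- Reduce(intersect, lapply(per_stage, names))
  n_all <- length(unique(unlist(lapply(per_stage, names))))
  if (n_all > length(genes))
    message(n_all - length(genes), " gene(s) missing a TFCR in some stage excluded")
  mat <- do.call(cbind, lapply(per_stage, function(v) as.numeric(v[genes])))
  dimnames(mat) <- list(genes, sn)
  sds <- apply(mat, 1, stats::sd)
  keep <- sds > 0
  mat <- mat[keep, , drop = FALSE]
  t(scale(t(mat)))[, , drop = FALSE]
}

#' Fuzzy c-means clustering of trajectories
#'
#' Standard soft c-means (the Mfuzz model): memberships
#' \eqn{u_{ij} \propto d_{ij}^{-2/(m-1)}}, centers the
#' \eqn{u^m}-weighted means, iterated until the largest center shift
#' falls below \code{tol}. The objective \eqn{\sum_{ij} u_{ij}^m d_{ij}^2}
#' is checked to be non-increasing at every iteration. A point at zero
#' distance from a center takes membership 1 there (limit rule).
#' Deterministic under a fixed seed.
#'
#' @param mat Numeric matrix (entities x stages), no missing values,
#'   >= c rows.
#' @param c Number of clusters (default 6, mirroring Cluster1-6).
#' @param m Fuzzifier > 1 (default 2).
#' @param seed RNG seed for center initialisation.
#' @param max_iter,tol Convergence controls.
#' @return List of class \code{fuzzy_cmeans}: \code{membership}
#'   (rows sum to 1), \code{centers} (c x stages), \code{cluster}
#'   (argmax hard labels), \code{m}, \code{seed}, \code{objective}
#'   (per-iteration trace), \code{iterations}.
#' @export
fuzzy_cmeans <- function(mat, c = 6, m = 2.0, seed = 1L,
                         max_iter = 300, tol = 1e-6) {
  stopifnot(is.matrix(mat), nrow(mat) >= c, m > 1, !anyNA(mat))
  set.seed(seed)
  centers <- mat[sample(nrow(mat), c), , drop = FALSE]
  obj_trace <- numeric(0)
  memb <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(mat^2), rowSums(centers^2), `+`) -
      2 * mat %*% t(centers)
    d2[d2 < 0] <- 0
    memb <- t(apply(d2, 1, function(row) {
      zero <- row < .Machine$double.eps
      if (any(zero)) { u <- as.numeric(zero); return(u / sum(u)) }
      w <- row^(-1 / (m - 1))
      w / sum(w)
    }))
    obj <- sum(memb^m * d2)
    if (length(obj_trace) && obj > obj_trace[length(obj_trace)] + 1e-8)
      stop("fuzzy c-means objective increased (internal error)", call. = FALSE)
    obj_trace <- c(obj_trace, obj)
    um <- memb^m
    new_centers <- (t(um) %*% mat) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  rownames(centers) <- paste0("Cluster", seq_len(c))
  dimnames(memb) <- list(rownames(mat), rownames(centers))
  structure(list(membership = memb, centers = centers,
                 cluster = max.col(memb, ties.method = "first"),
                 m = m, seed = seed, objective = obj_trace, iterations = it),
            class = "fuzzy_cmeans")
}
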