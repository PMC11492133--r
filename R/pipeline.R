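#' Run the TFCR pipeline on a single stage
#'
#' Reads the stage inputs, calls TFCRs by kernel density estimation,
#' scores TC/TW/cw/CAS, assigns TC decile bins, links TFCRs and genes in
#' both directions, classifies links into R1-R4, and writes the TFCR
#' table, links TSV and a JSON stats report into \code{out_dir}. Outputs
#' are deterministic given the inputs and parameters; step counts are
#' logged with \code{message()}.
#'
#' @param tfbs_path FIMO-dialect TFBS file.
#' @param genes_path Gene TSS BED.
#' @param expr_path Expression TSV (optional, enables the correlation
#'   report).
#' @param atac_path Scored ATAC peak BED (optional, enables CAS).
#' @param family_map_path TF-family map TSV (optional).
#' @param out_dir Output directory (created); \code{NULL} to skip writing.
#' @param stage Stage label.
#' @param bandwidth_bp,grid_step_bp,contribution_threshold,n_tc_bins
#'   Caller parameters (see \code{\link{kde_density}},
#'   \code{\link{call_tfcrs}}, \code{\link{assign_tc_bins}}).
#' @param thresholds Region thresholds (default published 2k/27k/50k).
#' @return List: \code{tfcrs}, \code{links_t2g}, \code{links_g2t},
#'   \code{thresholds}, \code{region_proportions}, \code{stats}
#'   (Spearman TC/TW/CAS vs expression and the log-model fit, when
#'   expression is given).
#' @export
run_single_stage <- function(tfbs_path, genes_path, expr_path = NULL,
                             atac_path = NULL, family_map_path = NULL,
                             out_dir = NULL, stage = "S1",
                             bandwidth_bp = 300, grid_step_bp = 10,
                             contribution_threshold = 0.1, n_tc_bins = 10,
                             thresholds = list(t1 = 2000, t2 = 27000,
                                               t3 = 50000)) {
  fam <- if (!is.null(family_map_path)) read_family_map(family_map_path)
  tfbs <- read_fimo_tfbs(tfbs_path, fam)
  message("[", stage, "] TFBS read: ", nrow(tfbs))
  tracks <- kde_density(tfbs, bandwidth_bp = bandwidth_bp,
                        grid_step_bp = grid_step_bp)
  tfcrs <- call_tfcrs(tracks, tfbs,
                      contribution_threshold = contribution_threshold,
                      stage = stage)
  message("[", stage, "] TFCRs called: ", nrow(tfcrs))
  if (nrow(tfcrs) >= n_tc_bins) tfcrs <- assign_tc_bins(tfcrs, n_tc_bins)
  if (!is.null(atac_path))
    tfcrs <- compute_cas(tfcrs, read_bed(atac_path, scored = TRUE))
  genes <- read_gene_tss(genes_path, "bed")
  links_t2g <- classify_regions(link_nearest(tfcrs, genes, "tfcr_to_gene"),
                                thresholds)
  links_g2t <- classify_regions(link_nearest(tfcrs, genes, "gene_to_tfcr"),
                                thresholds)
  message("[", stage, "] links (tfcr->gene): ", nrow(links_t2g),
          "; (gene->tfcr): ", nrow(links_g2t))
  props <- region_proportions(links_t2g)
  stats <- NULL
  if (!is.null(expr_path)) {
    expr <- read_expression(expr_path)
    per_gene <- merge_gene_features(tfcrs, links_g2t, expr)
    stats <- list(
      spearman_tc = spearman_cor(per_gene$TC, per_gene$log_expr),
      spearman_tw = spearman_cor(per_gene$TW, per_gene$log_expr),
      spearman_cas = if (all(is.na(per_gene$CAS))) NULL else
        spearman_cor(per_gene$CAS, per_gene$log_expr),
      log_fit = fit_log_model(per_gene$TC, per_gene$log_expr)
    )
  }
  res <- list(stage = stage, tfcrs = tfcrs, links_t2g = links_t2g,
              links_g2t = links_g2t, thresholds = thresholds,
              region_proportions = props, stats = stats)
  if (!is.null(out_dir)) write_stage_outputs(res, out_dir)
  res
}

# per-gene feature table: nearest-TFCR TC/TW/CAS (max TC on ties) + expression
merge_gene_features <- function(tfcrs, links_g2t, expr) {
  ln <- links_g2t[!is.na(links_g2t$tfcr_id), , drop = FALSE]
  idx <- match(ln$tfcr_id, tfcrs$tfcr_id)
  ln$TC <- tfcrs$TC[idx]; ln$TW <- tfcrs$TW[idx]; ln$CAS <- tfcrs$CAS[idx]
  ln <- ln[order(ln$gene_id, -ln$TC), , drop = FALSE]
  ln <- ln[!duplicated(ln$gene_id), , drop = FALSE]
  ln$log_expr <- expr$log_expr[match(ln$gene_id, expr$gene_id)]
  ln[!is.na(ln$log_expr), , drop = FALSE]
}

write_stage_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tfcr_table(res$tfcrs, file.path(out_dir,
                                        paste0(res$stage, "_tfcrs.bed")))
  for (d in c("t2g", "g2t")) {
    ln <- res[[paste0("links_", d)]]
    utils::write.table(ln, file.path(out_dir,
                                     paste0(res$stage, "_links_", d, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(stage = res$stage, n_tfcrs = nrow(res$tfcrs),
                 thresholds = res$thresholds[c("t1", "t2", "t3")],
                 region_proportions = as.list(res$region_proportions),
                 stats = strip_fit(res$stats))
  jsonlite::write_json(report,
                       file.path(out_dir, paste0(res$stage, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

strip_fit <- function(stats) {
  if (is.null(stats)) return(NULL)
  stats$log_fit <- stats$log_fit[c("a", "b", "c", "r_squared")]
  stats
}

#' Run the full multi-stage pipeline
#'
#' Runs \code{\link{run_single_stage}} for every stage of a manifest,
#' then the cross-stage analyses: gained/lost/kept TFCRs, stable regions,
#' long-range distance bins, gene-anchored TC trajectories with fuzzy
#' c-means clustering, and (when TAD/PSTF inputs are given) TAD
#' co-localisation and PSTF group comparisons. A single aggregated JSON
#' report is written when \code{out_dir} is set.
#'
#' @param manifest Named list, in stage order; each element a list with
#'   \code{tfbs}, \code{genes} and optionally \code{expr}, \code{atac},
#'   \code{family_map}, \code{tads}.
#' @param pstf_path Optional PSTF list file.
#' @param out_dir Optional output directory.
#' @param cmeans_c,cmeans_m Trajectory clustering controls.
#' @param seed Seed for the stochastic steps (fuzzy c-means init).
#' @param ... Passed to \code{\link{run_single_stage}}.
#' @return List: \code{stages} (per-stage results), \code{collection},
#'   \code{gained_lost}, \code{stable}, \code{lr_bins},
#'   \code{trajectories}, \code{cmeans}, \code{tad}, \code{pstf}.
#' @export
run_panel <- function(manifest, pstf_path = NULL, out_dir = NULL,
                      cmeans_c = 6, cmeans_m = 2.0, seed = 1L, ...) {
  if (length(manifest) < 2) stop("need >= 2 stages", call. = FALSE)
  stages <- lapply(names(manifest), function(s) {
    m <- manifest[[s]]
    run_single_stage(m$tfbs, m$genes, expr_path = m$expr,
                     atac_path = m$atac, family_map_path = m$family_map,
                     stage = s,
                     out_dir = if (is.null(out_dir)) NULL else
                       file.path(out_dir, s), ...)
  })
  names(stages) <- names(manifest)
  coll <- stage_collection(lapply(stages, function(st)
    list(tfcrs = st$tfcrs, links = st$links_g2t)))
  gl <- gained_lost(coll)
  stable <- stable_regions(coll)
  lr <- lapply(stages, function(st)
    lr_distance_bins(st$links_t2g[st$links_t2g$region %in% "R4", ,
                                  drop = FALSE]))
  traj <- tc_trajectories(coll)
  cm <- if (nrow(traj) >= cmeans_c)
    fuzzy_cmeans(traj, c = cmeans_c, m = cmeans_m, seed = seed)
  tad <- pstf <- NULL
  if (!is.null(manifest[[1]]$tads)) {
    tad <- lapply(names(manifest), function(s) {
      if (is.null(manifest[[s]]$tads)) return(NULL)
      assign_tads(stages[[s]]$links_t2g, read_bed(manifest[[s]]$tads))
    })
    names(tad) <- names(manifest)
  }
  if (!is.null(pstf_path)) {
    plist <- read_name_list(pstf_path)
    pstf <- lapply(stages, function(st) {
      ann <- annotate_pstf(st$tfcrs, plist)
      cmp <- group_compare(split(ann$TC, ann$pstf_group))
      list(annotation = ann, tc_compare = cmp)
    })
  }
  res <- list(stages = stages, collection = coll, gained_lost = gl,
              stable = stable, lr_bins = lr, trajectories = traj,
              cmeans = cm, tad = tad, pstf = pstf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
      schema_version = 1,
      stages = names(manifest),
      n_tfcrs = vapply(stages, function(s) nrow(s$tfcrs), 0L),
      n_stable_regions = nrow(stable),
      gained = vapply(gl, function(g) length(g$gained), 0L),
      lost = vapply(gl, function(g) length(g$lost), 0L),
      lr_bins = lr,
      spearman_tc = lapply(stages, function(s)
        if (is.null(s$stats)) NULL else s$stats$spearman_tc[c("rho", "p_value", "n")])
    )
    jsonlite::write_json(report, file.path(out_dir, "panel_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(stable, file.path(out_dir, "stable_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cm))
      utils::write.table(
        data.frame(gene_id = rownames(cm$membership),
                   cluster = cm$cluster, round(cm$membership, 6)),
        file.path(out_dir, "trajectory_membership.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
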