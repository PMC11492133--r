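#' Configuration for the synthetic input generator
#'
#' The generator emulates the statistical structure of TFBS clustering in
#' accessible chromatin around gene TSSs: one planted TFBS cluster per
#' gene, at a TSS distance drawn from a bimodal-plus-tail mixture
#' (promoter mode near 500 bp, mid mode near 27 kb, uniform far tail
#' beyond 50 kb); per-cluster TF-family counts Poisson-distributed; TFBSs
#' Gaussian-scattered (sd \code{site_sd}) around the cluster center; gene
#' expression following the saturating law
#' \eqn{\log_{10}FPKM = a\,\log_{10}(TC_{true}+c)+b+\epsilon}; ATAC peaks
#' spanning each cluster with score proportional to site count; tiling
#' TADs; and a phase-separation (PSTF) subset of TF families whose
#' presence boosts cluster complexity.
#'
#' Genes are laid out sparsely (spacing ~ 650-850 kb) so each planted
#' cluster is unambiguously nearest to its own gene even in the far tail.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_genes,n_chroms Problem size (default 500 genes on 5
#'   chromosomes).
#' @param gene_spacing Min/max uniform TSS spacing in bp.
#' @param mixture_weights Weights of the promoter/mid/far distance
#'   components (sum to 1).
#' @param promoter_mean,promoter_sd Half-normal promoter-distance scale
#'   (|N(500, 300)|).
#' @param mid_mean,mid_sd,mid_trunc Mid component N(27000, 8000) truncated
#'   below \code{mid_trunc}.
#' @param far_min,far_max Far component Uniform(50001, 300000).
#' @param lambda_families Poisson mean of per-cluster family count
#'   (floored at 1).
#' @param sites_extra_prob Probability a family places a second TFBS.
#' @param site_sd TFBS scatter sd around the cluster center (150 bp).
#' @param n_families,n_pstf_families,tfs_per_family TF family pool: the
#'   last \code{n_pstf_families} families are PSTF-flagged.
#' @param pstf_prob Probability a cluster is PSTF-positive.
#' @param pstf_extra_families Complexity boost of PSTF clusters.
#' @param expr_a,expr_b,expr_c,expr_sd Expression law parameters.
#' @param atac_score_sd Noise sd on the ATAC peak score.
#' @param tad_width TAD tile width in bp.
#' @return List of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 500, n_chroms = 5,
                             gene_spacing = c(650000, 850000),
                             mixture_weights = c(promoter = 0.45, mid = 0.40,
                                                 far = 0.15),
                             promoter_mean = 500, promoter_sd = 300,
                             mid_mean = 27000, mid_sd = 8000, mid_trunc = 2000,
                             far_min = 50001, far_max = 300000,
                             lambda_families = 6, sites_extra_prob = 0.3,
                             site_sd = 150,
                             n_families = 15, n_pstf_families = 4,
                             tfs_per_family = 3,
                             pstf_prob = 0.35, pstf_extra_families = 3,
                             expr_a = 2, expr_b = 1, expr_c = 0.03,
                             expr_sd = 0.15,
                             atac_score_sd = 0.5, tad_width = 1e6) {
  stopifnot(abs(sum(mixture_weights) - 1) < 1e-9, site_sd > 0,
            promoter_sd > 0, mid_sd > 0, n_pstf_families < n_families)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# family pool: FAM01..FAMnn, each with tfs_per_family named TFs; the last
# n_pstf_families families are the phase-separation (PSTF) subset
family_pool <- function(cfg) {
  fam <- sprintf("FAM%02d", seq_len(cfg$n_families))
  tf <- unlist(lapply(fam, function(f)
    paste0("TF_", f, "_", seq_len(cfg$tfs_per_family))))
  map <- setNames(rep(fam, each = cfg$tfs_per_family), tf)
  pstf_fams <- fam[(cfg$n_families - cfg$n_pstf_families + 1):cfg$n_families]
  list(families = fam, map = map, pstf_families = pstf_fams,
       pstf_tfs = names(map)[map %in% pstf_fams])
}

draw_distance <- function(cfg) {
  cat_ <- sample(names(cfg$mixture_weights), 1, prob = cfg$mixture_weights)
  d <- switch(cat_,
    promoter = abs(stats::rnorm(1, cfg$promoter_mean, cfg$promoter_sd)),
    mid = {
      repeat {
        v <- stats::rnorm(1, cfg$mid_mean, cfg$mid_sd)
        if (v > cfg$mid_trunc) break
      }
      v
    },
    far = stats::runif(1, cfg$far_min, cfg$far_max))
  list(category = cat_, distance = as.integer(round(d)))
}

# lay out genes sparsely along chromosomes and plant one cluster per gene
simulate_truth <- function(cfg, family_counts = NULL) {
  pool <- family_pool(cfg)
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  chrom <- character(cfg$n_genes); tss <- integer(cfg$n_genes)
  g <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    pos <- 400000
    for (k in seq_len(per_chrom)) {
      if (g >= cfg$n_genes) break
      g <- g + 1L
      pos <- pos + as.integer(round(stats::runif(1, cfg$gene_spacing[1],
                                                 cfg$gene_spacing[2])))
      chrom[g] <- paste0("chr", ci); tss[g] <- pos
    }
  }
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
                      chrom = chrom, tss = tss, strand = strand,
                      stringsAsFactors = FALSE)
  clusters <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    dd <- draw_distance(cfg)
    side <- sample(c(-1L, 1L), 1)
    center <- tss[i] + side * dd$distance
    retries <- 0L
    while (center < 1000 && retries < 100) {
      side <- sample(c(-1L, 1L), 1)
      center <- tss[i] + side * dd$distance
      retries <- retries + 1L
    }
    if (center < 1000) stop("cluster placement off-chromosome after retries")
    pstf <- stats::runif(1) < cfg$pstf_prob
    n_fam <- if (is.null(family_counts)) {
      nf <- max(1L, stats::rpois(1, cfg$lambda_families))
      if (pstf) nf + cfg$pstf_extra_families else nf
    } else family_counts[i]
    avail <- if (pstf) pool$families else
      setdiff(pool$families, pool$pstf_families)
    n_fam <- min(n_fam, length(avail))
    fams <- sample(avail, n_fam)
    if (pstf && !any(fams %in% pool$pstf_families))
      fams[1] <- sample(pool$pstf_families, 1)
    clusters[[i]] <- list(gene_id = genes$gene_id[i], chrom = chrom[i],
                          center = as.integer(center),
                          distance = dd$distance, category = dd$category,
                          pstf = pstf, families = fams, tc_true = n_fam)
  }
  list(genes = genes, clusters = clusters, pool = pool)
}

# scatter TFBSs for one stage's clusters; returns the FIMO-style table
scatter_tfbs <- function(cfg, clusters, pool) {
  rows <- list()
  for (cl in clusters) {
    for (fam in cl$families) {
      n_sites <- 1L + stats::rbinom(1, 1, cfg$sites_extra_prob)
      tfs <- sample(names(pool$map)[pool$map == fam], n_sites, replace = TRUE)
      for (j in seq_len(n_sites)) {
        mid <- cl$center + as.integer(round(stats::rnorm(1, 0, cfg$site_sd)))
        w <- sample(8:20, 1)
        start <- mid - w %/% 2L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cl$chrom, start = start, end = start + w,
          strand = sample(c("+", "-"), 1), tf_name = tfs[j],
          scan_score = round(stats::runif(1, 8, 25), 3),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  df$tf_family <- unname(pool$map[df$tf_name])
  df$midpoint <- (df$start + df$end) %/% 2L
  df[order(df$chrom, df$start, df$tf_name), ]
}

write_fimo <- function(tfbs, path) {
  df <- data.frame(motif_id = paste0("M_", tfbs$tf_name),
                   motif_alt_id = tfbs$tf_name,
                   sequence_name = tfbs$chrom,
                   start = tfbs$start + 1L, stop = tfbs$end,
                   strand = tfbs$strand, score = tfbs$scan_score,
                   `p.value` = 1e-5, `q.value` = 1e-3,
                   matched_sequence = "N", check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[8:9] <- c("p-value", "q-value")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_bundle_files <- function(cfg, dir, genes, clusters, tfbs, pool,
                               fpkm) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fimo(tfbs, p("tfbs_fimo.tsv"))
  # ATAC peak per cluster spanning its sites, score ~ site count + noise
  peaks <- do.call(rbind, lapply(clusters, function(cl) {
    sub <- tfbs[tfbs$chrom == cl$chrom &
                  abs(tfbs$midpoint - cl$center) <= 4 * cfg$site_sd + 200, ]
    lo <- min(cl$center - 200, sub$start); hi <- max(cl$center + 200, sub$end)
    score <- max(0.1, nrow(sub) + stats::rnorm(1, 0, cfg$atac_score_sd))
    data.frame(chrom = cl$chrom, start = lo, end = hi,
               name = paste0("peak_", cl$gene_id),
               score = round(score, 3), strand = ".",
               stringsAsFactors = FALSE)
  }))
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  utils::write.table(peaks, p("atac_peaks.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gb <- data.frame(chrom = genes$chrom, start = genes$tss,
                   end = genes$tss + 1L, name = genes$gene_id, score = 0,
                   strand = genes$strand, stringsAsFactors = FALSE)
  neg <- gb$strand == "-"        # TSS is end-1 for minus-strand BED genes
  gb$start[neg] <- genes$tss[neg]; gb$end[neg] <- genes$tss[neg] + 1L
  utils::write.table(gb[order(gb$chrom, gb$start), ], p("genes.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(genes$gene_id, round(fpkm, 4)),
                     p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # tiling TADs per chromosome
  tads <- do.call(rbind, lapply(split(genes, genes$chrom), function(gs) {
    len <- max(gs$tss) + 400000
    edges <- seq(0, len + cfg$tad_width, by = cfg$tad_width)
    data.frame(chrom = gs$chrom[1], start = as.integer(head(edges, -1)),
               end = as.integer(edges[-1]), stringsAsFactors = FALSE)
  }))
  utils::write.table(tads[order(tads$chrom, tads$start), ], p("tads.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(tf = names(pool$map), fam = unname(pool$map)),
                     p("family_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(pool$pstf_tfs, p("pstf_list.txt"))
  c(tfbs = p("tfbs_fimo.tsv"), atac = p("atac_peaks.bed"),
    genes = p("genes.bed"), expr = p("expression.tsv"),
    tads = p("tads.bed"), family_map = p("family_map.tsv"),
    pstf = p("pstf_list.txt"))
}

expr_from_tc <- function(cfg, tc_true) {
  log_fpkm <- cfg$expr_a * log10(tc_true + cfg$expr_c) + cfg$expr_b +
    stats::rnorm(length(tc_true), 0, cfg$expr_sd)
  pmax(10^log_fpkm - 1, 0)
}

cluster_truth_df <- function(clusters) {
  data.frame(
    gene_id = vapply(clusters, `[[`, "", "gene_id"),
    chrom = vapply(clusters, `[[`, "", "chrom"),
    center = vapply(clusters, `[[`, 0L, "center"),
    distance = vapply(clusters, `[[`, 0L, "distance"),
    category = vapply(clusters, `[[`, "", "category"),
    pstf = vapply(clusters, `[[`, TRUE, "pstf"),
    tc_true = vapply(clusters, function(x) as.numeric(x$tc_true), 0),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Writes, under \code{dir}: a FIMO-dialect TFBS table, scored ATAC peak
#' BED, gene TSS BED, expression TSV, tiling TAD BED, TF-family map, PSTF
#' list, and \code{truth.json} recording every planted quantity. All
#' randomness flows from \code{config$seed}; the same config reproduces a
#' byte-identical bundle.
#'
#' @param config \code{\link{synthetic_config}}.
#' @param dir Output directory (created).
#' @return List with \code{paths} (named file paths) and \code{truth}
#'   (genes, per-cluster truth table, expression parameters, seed).
#' @export
generate_bundle <- function(config, dir) {
  set.seed(config$seed)
  tr <- simulate_truth(config)
  tfbs <- scatter_tfbs(config, tr$clusters, tr$pool)
  tc_true <- vapply(tr$clusters, function(x) as.numeric(x$tc_true), 0)
  fpkm <- expr_from_tc(config, tc_true)
  paths <- write_bundle_files(config, dir, tr$genes, tr$clusters, tfbs,
                              tr$pool, fpkm)
  truth <- list(seed = config$seed, genes = tr$genes,
                clusters = cluster_truth_df(tr$clusters),
                expr_params = list(a = config$expr_a, b = config$expr_b,
                                   c = config$expr_c, sd = config$expr_sd),
                pstf_tfs = tr$pool$pstf_tfs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(paths = c(paths, truth = file.path(dir, "truth.json")), truth = truth)
}

#' Generate a multi-stage panel with a planted ZGA-like activation
#'
#' Produces \code{n_stages} bundles over a shared gene layout. A planted
#' fraction of "ZGA" genes has minimal cluster complexity (one TF family)
#' before the activation stage and elevated complexity from it onward;
#' non-ZGA genes keep a stable complexity throughout. Expression before
#' the activation stage is independent noise for every gene (emulating
#' maternal transcripts), and follows the complexity-coupled saturating
#' law from the activation stage onward — so the complexity-expression
#' correlation switches on at activation.
#'
#' @param config \code{\link{synthetic_config}}.
#' @param dir Output directory; one subdirectory per stage.
#' @param stage_names Ordered stage labels (default the five embryonic
#'   stages 2Cell..primed_hESC).
#' @param zga_stage 1-based index of the activation stage (default 3,
#'   i.e. the 8Cell position).
#' @param zga_fraction Fraction of genes planted as ZGA genes (default
#'   0.3).
#' @param zga_lambda Poisson mean of post-activation ZGA family counts
#'   (default \code{lambda_families + 4}).
#' @return List with \code{stage_names}, per-stage \code{paths}, and
#'   \code{truth} (shared layout, per-stage \code{tc_true} matrix, ZGA
#'   flags).
#' @export
generate_stage_panel <- function(config, dir,
                                 stage_names = c("2Cell", "4Cell", "8Cell",
                                                 "ICM", "primed_hESC"),
                                 zga_stage = 3, zga_fraction = 0.3,
                                 zga_lambda = NULL) {
  stopifnot(zga_stage >= 1, zga_stage <= length(stage_names),
            zga_fraction >= 0, zga_fraction <= 1)
  if (is.null(zga_lambda)) zga_lambda <- config$lambda_families + 4
  set.seed(config$seed)
  tr <- simulate_truth(config)
  n <- config$n_genes
  zga <- stats::runif(n) < zga_fraction
  base_tc <- vapply(tr$clusters, function(x) as.numeric(x$tc_true), 0)
  post_tc <- pmax(2L, stats::rpois(n, zga_lambda))
  pool <- tr$pool
  tc_mat <- matrix(0, n, length(stage_names),
                   dimnames = list(tr$genes$gene_id, stage_names))
  paths <- list()
  for (s in seq_along(stage_names)) {
    clusters <- tr$clusters
    for (i in seq_len(n)) {
      if (zga[i]) {
        nf <- if (s < zga_stage) 1L else post_tc[i]
        avail <- if (clusters[[i]]$pstf) pool$families else
          setdiff(pool$families, pool$pstf_families)
        nf <- min(nf, length(avail))
        clusters[[i]]$families <- sample(avail, nf)
        clusters[[i]]$tc_true <- nf
      }
      tc_mat[i, s] <- clusters[[i]]$tc_true
    }
    tfbs <- scatter_tfbs(config, clusters, pool)
    fpkm <- if (s < zga_stage)
      pmax(10^stats::rnorm(n, 1.5, 0.6) - 1, 0)   # maternal noise
    else expr_from_tc(config, tc_mat[, s])
    paths[[stage_names[s]]] <- write_bundle_files(
      config, file.path(dir, stage_names[s]), tr$genes, clusters, tfbs,
      pool, fpkm)
  }
  truth <- list(seed = config$seed, genes = tr$genes,
                clusters = cluster_truth_df(tr$clusters),
                zga = setNames(zga, tr$genes$gene_id),
                zga_stage = zga_stage, stage_names = stage_names,
                tc_true = tc_mat)
  jsonlite::write_json(
    list(seed = config$seed, zga_stage = zga_stage,
         stage_names = stage_names,
         zga_genes = tr$genes$gene_id[zga]),
    file.path(dir, "panel_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  list(stage_names = stage_names, paths = paths, truth = truth)
}
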