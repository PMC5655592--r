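#' Transcriptome differential analysis from a normalized probe matrix
#'
#' Runs the reference-free ANOVA, the post hoc pairwise contrasts, the
#' germ-matched q_min filter and the GF/C summary ratio, returning one record
#' per probe.
#'
#' @param pm a normalized `probe_matrix`.
#' @param alpha significance threshold on q_min.
#' @param moderate moderate residual variances (see
#'   [fit_reference_free_anova()]).
#' @return list with `records` (data frame: `gene`, `gfc`, `q_min`,
#'   `significant`), the `fit`, and the `contrasts`.
#' @export
transcriptome_analysis <- function(pm, alpha = 0.1, moderate = TRUE) {
  fit <- fit_reference_free_anova(pm, moderate = moderate)
  ctr <- pairwise_contrasts(fit)
  qm <- qmin_germ(ctr, alpha = alpha)
  records <- data.frame(gene = qm$feature_id,
                        gfc = transcriptome_gfc(fit$d),
                        q_min = qm$q_min, significant = qm$significant,
                        stringsAsFactors = FALSE)
  list(records = records, fit = fit, contrasts = ctr, qmin = qm)
}

#' Proteome differential analysis from a PSM table
#'
#' Applies the identification filter, quantifies protein groups as PSM-ratio
#' medians, performs the central-tendency normalization, the three-way ANOVA
#' and the geometric-mean GF/C ratios.
#'
#' @param psm PSM table.
#' @param mice data frame (`mouse_id`, `germ`, `sex`, `strain`).
#' @param alpha significance threshold on q_min(germ).
#' @return list with `records` (data frame: `gene`, `gfc`, `q_min`,
#'   `qmin_sex`, `qmin_strain`, `significant`), the normalized `grid`, the
#'   `normalization` summary and the `threeway` table.
#' @export
proteome_analysis <- function(psm, mice, alpha = 0.1) {
  counts <- count_identifications(psm)
  kept <- filter_identifications(counts)
  psm <- psm[psm$protein_group %in% kept$protein_group, , drop = FALSE]
  grid <- quantify_protein_groups(psm)
  norm <- central_tendency_normalize(grid, mice)
  tw <- proteome_threeway(norm$grid, mice)
  meta_cols <- mice[match(colnames(norm$grid), mice$mouse_id), ]
  gfc <- proteome_gfc(norm$grid, meta_cols$germ)
  i <- match(tw$feature_id, names(gfc))
  records <- data.frame(gene = tw$feature_id, gfc = gfc[i],
                        q_min = tw$qmin_germ, qmin_sex = tw$qmin_sex,
                        qmin_strain = tw$qmin_strain,
                        significant = !is.na(tw$qmin_germ) &
                          tw$qmin_germ < alpha,
                        row.names = NULL, stringsAsFactors = FALSE)
  list(records = records, grid = norm$grid, normalization = norm,
       threeway = tw, identification = counts)
}

#' End-to-end pipeline on synthetic data
#'
#' Generates ground-truthed inputs and runs every downstream stage:
#' simulate, preprocess, transcriptome and proteome differential calling,
#' meta-analysis, state calling, gene-set construction, pathway enrichment
#' with direction classification, intraset concordance statistics,
#' pathway-overlap networks and hierarchical clustering. Reruns with the same
#' configuration are bit-identical; the returned manifest records every seed
#' and parameter.
#'
#' @param truth_cfg a [truth_config()].
#' @param design an [array_design()].
#' @param seed master integer seed; stage seeds are derived from it.
#' @param alpha q_min significance threshold.
#' @param alpha_e enrichment threshold.
#' @param min_overlap network minimum-overlap threshold k.
#' @param include_proteome,include_meta stage toggles; disabled layers simply
#'   drop the layer-dependent gene sets.
#' @param out_dir optional directory for TSV/GMT outputs.
#' @return a list bundling every stage's results plus a `manifest`.
#' @export
run_pipeline <- function(truth_cfg = truth_config(), design = array_design(),
                         seed = 1L, alpha = 0.1, alpha_e = 0.1,
                         min_overlap = 1L,
                         include_proteome = TRUE, include_meta = TRUE,
                         out_dir = NULL) {
  seed <- as.integer(seed)
  truth_cfg$seed <- seed
  truth <- generate_truth(truth_cfg)
  spots <- simulate_microarray(truth, design, seed = seed + 1L)
  pm <- prep_microarray(spots, design$samples, floor_seed = seed + 2L)
  trans <- transcriptome_analysis(pm, alpha = alpha)

  prot <- NULL
  if (include_proteome) {
    psm <- simulate_psm_table(truth, design, seed = seed + 3L)
    prot <- proteome_analysis(psm, design$mice, alpha = alpha)
  }
  meta_res <- NULL
  if (include_meta) {
    meta_sim <- simulate_meta_groups(truth, seed = seed + 4L)
    mr <- meta_analysis(meta_sim)
    meta_res <- list(records = data.frame(gene = mr$gene, gfc = mr$gfc,
                                          q_min = mr$q_min,
                                          significant = mr$significant,
                                          stringsAsFactors = FALSE),
                     full = mr)
  }
  states <- call_states(
    transcriptome = trans$records,
    proteome = if (include_proteome) prot$records else NULL,
    meta = if (include_meta) meta_res$records else NULL,
    alpha = alpha)
  sets <- build_gene_sets(states, alpha = alpha)
  enr <- enrich_catalog(sets, truth$membership, alpha_e = alpha_e)
  tallies <- crosstab_pathways(enr$classification)

  concord <- do.call(rbind, lapply(names(sets), function(nm) {
    n_up <- length(sets[[nm]]$up)
    n_down <- length(sets[[nm]]$down)
    data.frame(gene_set = nm, n_up = n_up, n_down = n_down,
               P_c = if (n_up + n_down >= 1) binomial_pc(n_up, n_down)
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))

  t_enr <- enr$classification[enr$classification$gene_set == "T", ]
  enriched_pws <- t_enr$pathway[t_enr$label != "not-enriched" &
                                  !is.na(t_enr$label)]
  affected <- sets[["T"]]$members
  memberships <- lapply(truth$membership[enriched_pws], intersect, affected)
  labels <- stats::setNames(t_enr$label, t_enr$pathway)[enriched_pws]
  net <- build_network(memberships, labels = labels, k = min_overlap)
  comps <- network_components(net)

  sig_t <- trans$records$gene[trans$records$significant]
  hca_res <- NULL
  if (length(sig_t) >= 2) {
    d_sig <- trans$fit$d[sig_t, , drop = FALSE]
    arr_strain <- trans$fit$arrays$strain
    std <- strain_standardize(d_sig, arr_strain, mode = "sigma")
    hca_res <- hca(std, cluster_rows = TRUE, cluster_cols = TRUE)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("gfconcord")),
                   seed = seed,
                   stage_seeds = list(truth = seed, microarray = seed + 1L,
                                      floor = seed + 2L, psm = seed + 3L,
                                      meta = seed + 4L),
                   alpha = alpha, alpha_e = alpha_e,
                   min_overlap = min_overlap,
                   truth_config = unclass(truth_cfg),
                   timestamp = NA)
  out <- list(truth = truth, design = design, probe_matrix = pm,
              transcriptome = trans, proteome = prot, meta = meta_res,
              states = states, sets = sets, enrichment = enr,
              tallies = tallies, concordance = concord,
              network = net, components = comps, hca = hca_res,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(out$states, file.path(out_dir, "gene_states.tsv"))
  write_tsv(out$enrichment$analyses, file.path(out_dir, "enrichment.tsv"))
  write_tsv(out$tallies$tally, file.path(out_dir, "pathway_tally.tsv"))
  write_tsv(out$concordance, file.path(out_dir, "concordance.tsv"))
  write_tsv(out$network$edges, file.path(out_dir, "network_edges.tsv"))
  catalog_to_gmt(out$sets, file.path(out_dir, "gene_sets.gmt"))
  write_gmt(out$truth$membership, file.path(out_dir, "planted_pathways.gmt"))
  invisible(out_dir)
}
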