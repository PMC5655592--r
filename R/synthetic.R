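#' Configuration for the planted multi-omics ground truth
#'
#' Defines the study conditions the generator emulates: a gene universe in
#' which a fraction of genes respond to germ status, with the responding genes
#' split into transcript-protein concordant, transcript-only, protein-only and
#' opposite-direction categories, grouped into planted pathways, and with one
#' mouse strain responding more strongly than the other.
#'
#' @param n_genes number of genes in the universe.
#' @param n_pathways number of planted pathways.
#' @param genes_per_pathway members per pathway.
#' @param frac_affected fraction of genes affected by germ status.
#' @param mix named fractions (`concordant_TP`, `T_only`, `P_only`,
#'   `opposite`) of the affected genes falling in each concordance category;
#'   must sum to at most 1. Defaults follow the observed tallies of
#'   transcript/protein responders (88 concordant, 578 transcript-only,
#'   113 protein-only, 5 opposite).
#' @param pathway_mix named fractions (`up`, `down`, `discordant`, `none`) of
#'   pathways planted with each regulation label.
#' @param effect_log2 mean absolute log2 GF/C effect for affected genes in the
#'   less responsive strain.
#' @param strain_multiplier multiplier (>= 1) applied to effect sizes in the
#'   responsive strain, emulating the stronger germ-status response of one
#'   strain.
#' @param noise_sd_log2 spot/PSM-level noise standard deviation on the log2
#'   scale.
#' @param seed integer seed; all generator output is deterministic given the
#'   configuration.
#' @return an object of class `truth_config`.
#' @export
truth_config <- function(n_genes = 2000L,
                         n_pathways = 20L,
                         genes_per_pathway = 30L,
                         frac_affected = 0.15,
                         mix = c(concordant_TP = 0.11, T_only = 0.74,
                                 P_only = 0.14, opposite = 0.01),
                         pathway_mix = c(up = 0.4, down = 0.4,
                                         discordant = 0.1, none = 0.1),
                         effect_log2 = 0.6,
                         strain_multiplier = 3,
                         noise_sd_log2 = 0.6,
                         seed = 1L) {
  stopifnot(n_genes >= 1, n_pathways >= 0, genes_per_pathway >= 1,
            frac_affected >= 0, frac_affected <= 1,
            effect_log2 >= 0, strain_multiplier >= 1, noise_sd_log2 > 0)
  mix <- mix[c("concordant_TP", "T_only", "P_only", "opposite")]
  if (anyNA(mix) || any(mix < 0) || sum(mix) > 1 + 1e-9)
    stop("mix must have the four named components, each in [0,1], summing to <= 1")
  pathway_mix <- pathway_mix[c("up", "down", "discordant", "none")]
  if (anyNA(pathway_mix) || any(pathway_mix < 0))
    stop("pathway_mix must have components up, down, discordant, none")
  structure(list(n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 frac_affected = frac_affected,
                 mix = mix, pathway_mix = pathway_mix,
                 effect_log2 = effect_log2,
                 strain_multiplier = strain_multiplier,
                 noise_sd_log2 = noise_sd_log2,
                 seed = as.integer(seed)),
            class = "truth_config")
}

#' Generate the planted ground truth
#'
#' Draws per-gene true directions for the transcriptome (T), proteome (P) and
#' meta-analysis (M) layers and plants pathways enriched in an assigned
#' regulation direction. The meta-analysis direction mirrors the transcriptome
#' direction (the meta layer emulates transcriptomics of independent studies).
#' Up- and down-regulated pathways draw members from disjoint pools of up- and
#' down-responding genes, so that pathway-overlap networks separate into an
#' "up" and a "down" component; discordant pathways draw from both pools.
#'
#' @param config a [truth_config()].
#' @return an object of class `ground_truth`: a list with `genes` (data frame
#'   of per-gene category, per-layer true direction in \{-1, 0, 1\} and effect
#'   size), `pathways` (data frame of planted regulation labels), `membership`
#'   (named list of member gene vectors) and the `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  n_cat <- round(config$frac_affected * config$mix * config$n_genes)
  n_aff <- sum(n_cat)
  if (n_aff > config$n_genes)
    stop("infeasible configuration: more affected genes demanded than n_genes")
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  withr::with_seed(config$seed, {
    aff <- sample(genes, n_aff)
    category <- rep("none", config$n_genes)
    names(category) <- genes
    cat_names <- names(n_cat)
    category[aff] <- rep(cat_names, n_cat)
    # alternate signs within each category so planted up/down counts are equal
    # up to rounding
    sign_t <- integer(config$n_genes)
    names(sign_t) <- genes
    for (cn in cat_names) {
      members <- aff[category[aff] == cn]
      if (length(members))
        sign_t[members] <- rep_len(c(1L, -1L), length(members))
    }
    dir_t <- ifelse(category %in% c("concordant_TP", "T_only", "opposite"),
                    sign_t, 0L)
    dir_p <- ifelse(category == "concordant_TP", sign_t,
                    ifelse(category == "P_only", sign_t,
                           ifelse(category == "opposite", -sign_t, 0L)))
    dir_m <- ifelse(dir_t != 0L, dir_t, 0L)
    gene_df <- data.frame(gene = genes, category = category,
                          dir_T = as.integer(dir_t), dir_P = as.integer(dir_p),
                          dir_M = as.integer(dir_m),
                          effect_log2 = ifelse(category == "none", 0,
                                               config$effect_log2),
                          row.names = NULL, stringsAsFactors = FALSE)

    # planted pathways
    n_pw <- round(config$pathway_mix * config$n_pathways)
    slack <- config$n_pathways - sum(n_pw)
    n_pw["none"] <- max(0L, n_pw["none"] + slack)
    labels <- rep(names(n_pw), n_pw)[seq_len(config$n_pathways)]
    up_pool <- genes[dir_t == 1L]
    down_pool <- genes[dir_t == -1L]
    none_pool <- genes[category == "none"]
    membership <- vector("list", config$n_pathways)
    pw_ids <- sprintf("pw%02d", seq_len(config$n_pathways))
    names(membership) <- pw_ids
    gpp <- config$genes_per_pathway
    draw <- function(pool, k) {
      if (length(pool) < k)
        stop("infeasible configuration: gene pool smaller than genes_per_pathway")
      sample(pool, k)
    }
    for (i in seq_along(labels)) {
      membership[[i]] <- switch(labels[i],
        up = draw(up_pool, gpp),
        down = draw(down_pool, gpp),
        discordant = c(draw(up_pool, ceiling(gpp / 2)),
                       draw(down_pool, floor(gpp / 2))),
        none = draw(none_pool, gpp))
    }
    pathways <- data.frame(pathway = pw_ids, regulation = labels,
                           stringsAsFactors = FALSE)
  })
  structure(list(genes = gene_df, pathways = pathways,
                 membership = membership, config = config),
            class = "ground_truth")
}

#' Paired two-colour array design
#'
#' Builds the experimental design the two-colour analysis assumes: eight
#' experimental classes (2 germ statuses x 2 sexes x 2 strains), with each
#' array cohybridising one GF and one conventional mouse of matched sex and
#' strain. Dye assignment of the GF sample alternates within each sex/strain
#' stratum so labelling is balanced up to rounding. The default mirrors a
#' design of five mice per class with one GF class reduced to four, giving 19
#' arrays (38 arrayed samples).
#'
#' @param gf_per_class,c_per_class integer vectors of length 4 (mice per
#'   sex/strain stratum, order F-responsive, M-responsive, F-other, M-other).
#' @param strains character vector of two strain labels; the first is the
#'   responsive strain (stronger germ-status effect).
#' @param responsive which strain label carries the `strain_multiplier`.
#' @param replicate_spots replicate spots per probe on each array.
#' @return an object of class `array_design` with `mice`, `arrays` and
#'   `samples` data frames.
#' @export
array_design <- function(gf_per_class = c(4L, 5L, 5L, 5L),
                         c_per_class = c(5L, 5L, 5L, 5L),
                         strains = c("C57BL10", "BALBc"),
                         responsive = strains[1],
                         replicate_spots = 2L) {
  stopifnot(length(gf_per_class) == 4, length(c_per_class) == 4,
            all(gf_per_class >= 1), all(c_per_class >= 1),
            replicate_spots >= 1, responsive %in% strains)
  strata <- expand.grid(sex = c("F", "M"), strain = strains,
                        stringsAsFactors = FALSE)
  mice <- do.call(rbind, lapply(seq_len(4), function(i) {
    rbind(
      data.frame(germ = "GF", sex = strata$sex[i], strain = strata$strain[i],
                 idx = seq_len(gf_per_class[i])),
      data.frame(germ = "C", sex = strata$sex[i], strain = strata$strain[i],
                 idx = seq_len(c_per_class[i])))
  }))
  mice$mouse_id <- sprintf("m_%s_%s_%s_%d", mice$germ, mice$sex,
                           substr(mice$strain, 1, 4), mice$idx)
  arrays <- do.call(rbind, lapply(seq_len(4), function(i) {
    n_arr <- min(gf_per_class[i], c_per_class[i])
    gf <- mice$mouse_id[mice$germ == "GF" & mice$sex == strata$sex[i] &
                          mice$strain == strata$strain[i]][seq_len(n_arr)]
    cv <- mice$mouse_id[mice$germ == "C" & mice$sex == strata$sex[i] &
                          mice$strain == strata$strain[i]][seq_len(n_arr)]
    data.frame(sex = strata$sex[i], strain = strata$strain[i],
               gf_mouse = gf, c_mouse = cv,
               gf_channel = rep_len(c("green", "red"), n_arr),
               stringsAsFactors = FALSE)
  }))
  arrays$array_id <- sprintf("a%02d", seq_len(nrow(arrays)))
  samples <- rbind(
    data.frame(mouse_id = arrays$gf_mouse, array_id = arrays$array_id,
               channel = arrays$gf_channel, germ = "GF",
               sex = arrays$sex, strain = arrays$strain,
               stringsAsFactors = FALSE),
    data.frame(mouse_id = arrays$c_mouse, array_id = arrays$array_id,
               channel = ifelse(arrays$gf_channel == "green", "red", "green"),
               germ = "C", sex = arrays$sex, strain = arrays$strain,
               stringsAsFactors = FALSE))
  samples <- samples[order(samples$array_id, samples$channel), ]
  rownames(samples) <- NULL
  structure(list(mice = mice[, c("mouse_id", "germ", "sex", "strain")],
                 arrays = arrays[, c("array_id", "sex", "strain", "gf_mouse",
                                     "c_mouse", "gf_channel")],
                 samples = samples,
                 strains = strains, responsive = responsive,
                 replicate_spots = as.integer(replicate_spots)),
            class = "array_design")
}

#' Simulate a spot-level two-colour intensity table
#'
#' Signal is log-normal multiplicative: per-spot foreground equals background
#' plus `2^(baseline + array effect + class effect + dye offset + noise)`.
#' The GF channel of each affected gene is shifted by its true direction times
#' `effect_log2`, scaled by `strain_multiplier` on arrays of the responsive
#' strain. Backgrounds are drawn uniformly in `background_range` so the
#' median-based cap rule is exercised. Replicate spots share the same
#' expectation and differ only by noise.
#'
#' @param truth a [generate_truth()] result.
#' @param design an [array_design()].
#' @param seed integer seed.
#' @param baseline_range range of per-gene baseline log2 intensities.
#' @param array_sd standard deviation of the additive per-array effect (log2).
#' @param dye_offset additive log2 offset applied to the red channel
#'   (default 0; dye effects are mitigated by design randomisation, not
#'   modelled downstream).
#' @param background_range uniform range for spot background intensities.
#' @return a data frame with columns `array_id`, `channel`, `probe_id`,
#'   `spot_index`, `foreground`, `background` (one probe per gene).
#' @export
simulate_microarray <- function(truth, design, seed,
                                baseline_range = c(6, 12),
                                array_sd = 0.3,
                                dye_offset = 0,
                                background_range = c(20, 50)) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "array_design"))
  cfg <- truth$config
  genes <- truth$genes$gene
  n_g <- length(genes)
  smp <- design$samples
  n_s <- nrow(smp)
  reps <- design$replicate_spots
  withr::with_seed(as.integer(seed), {
    baseline <- stats::runif(n_g, baseline_range[1], baseline_range[2])
    arr_ids <- design$arrays$array_id
    arr_eff <- stats::rnorm(length(arr_ids), 0, array_sd)
    names(arr_eff) <- arr_ids
    # per-sample class shift for each gene: GF samples carry the planted effect
    mult <- ifelse(smp$strain == design$responsive, cfg$strain_multiplier, 1)
    shift <- outer(truth$genes$dir_T * truth$genes$effect_log2,
                   ifelse(smp$germ == "GF", 1, 0) * mult)  # n_g x n_s
    mu <- baseline + shift +
      rep(arr_eff[smp$array_id], each = n_g) +
      rep(ifelse(smp$channel == "red", dye_offset, 0), each = n_g)
    n_rows <- n_g * n_s * reps
    noise <- stats::rnorm(n_rows, 0, cfg$noise_sd_log2)
    background <- stats::runif(n_rows, background_range[1], background_range[2])
    out <- data.frame(
      array_id = rep(smp$array_id, each = n_g * reps),
      channel = rep(smp$channel, each = n_g * reps),
      probe_id = rep(rep(genes, times = reps), times = n_s),
      spot_index = rep(rep(seq_len(reps), each = n_g), times = n_s),
      stringsAsFactors = FALSE)
    # rows are gene-major within each replicate block, sample-major overall
    log2sig <- as.vector(mu[rep(seq_len(n_g), times = reps), , drop = FALSE])
    out$foreground <- background + 2^(log2sig + noise)
    out$background <- background
  })
  out
}

#' Simulate a PSM-level proteomics table
#'
#' Each quantified protein group (identified with its gene) receives a random
#' number of peptide groups and PSMs; PSM sample/pool ratios are log-normal
#' around the mouse's true protein-level GF/C structure, with a per-mouse
#' abundance bias that the central-tendency normalization must remove. A known
#' subset of groups (`n_filter_fail`) is planted with one peptide group and
#' fewer than 10 PSMs so the identification filter must reject them.
#'
#' @param truth a [generate_truth()] result.
#' @param design an [array_design()] (its mice are the proteomics samples).
#' @param seed integer seed.
#' @param psms_per_group integer range of PSM counts per retained group.
#' @param peptide_groups_range integer range of peptide groups per retained
#'   group.
#' @param prop_quantified probability that an unaffected gene is quantified at
#'   the protein level; all protein-affected genes are always quantified.
#' @param n_filter_fail number of planted identification-filter violators.
#' @param mouse_bias_sd standard deviation of the per-mouse log2 abundance
#'   bias.
#' @param psm_noise_sd PSM-level log2 noise standard deviation.
#' @return a data frame with columns `protein_group`, `peptide_group`,
#'   `psm_id`, `mouse_id`, `ratio` plus attribute `filter_fail` naming the
#'   planted violators.
#' @export
simulate_psm_table <- function(truth, design, seed,
                               psms_per_group = c(4L, 12L),
                               peptide_groups_range = c(2L, 6L),
                               prop_quantified = 0.6,
                               n_filter_fail = 20L,
                               mouse_bias_sd = 0.25,
                               psm_noise_sd = 0.4) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "array_design"),
            psms_per_group[1] >= 1)
  cfg <- truth$config
  mice <- design$mice
  withr::with_seed(as.integer(seed), {
    keep <- truth$genes$dir_P != 0 |
      stats::runif(nrow(truth$genes)) < prop_quantified
    quantified <- truth$genes[keep, , drop = FALSE]
    n_q <- nrow(quantified)
    n_pep <- sample(seq(peptide_groups_range[1], peptide_groups_range[2]),
                    n_q, replace = TRUE)
    n_psm <- pmax(sample(seq(psms_per_group[1], psms_per_group[2]),
                         n_q, replace = TRUE), n_pep)
    fail_idx <- sample(n_q, min(n_filter_fail, n_q))
    n_pep[fail_idx] <- 1L
    n_psm[fail_idx] <- pmin(n_psm[fail_idx], 9L)
    mouse_bias <- stats::rnorm(nrow(mice), 0, mouse_bias_sd)
    names(mouse_bias) <- mice$mouse_id
    mult <- ifelse(mice$strain == design$responsive, cfg$strain_multiplier, 1)
    half <- ifelse(mice$germ == "GF", 0.5, -0.5) * mult
    # isobaric-labelling semantics: each PSM contributes one sample/pool
    # ratio per mouse, so a group's PSM count is the number of distinct PSMs
    rows <- lapply(seq_len(n_q), function(i) {
      delta <- quantified$dir_P[i] * quantified$effect_log2[i]
      per_mouse <- half * delta + mouse_bias
      pep <- rep_len(seq_len(n_pep[i]), n_psm[i])
      data.frame(
        protein_group = quantified$gene[i],
        peptide_group = sprintf("%s_pep%02d", quantified$gene[i],
                                rep(pep, times = nrow(mice))),
        psm_id = sprintf("%s_psm%03d", quantified$gene[i],
                         rep(seq_len(n_psm[i]), times = nrow(mice))),
        mouse_id = rep(mice$mouse_id, each = n_psm[i]),
        ratio = 2^(rep(per_mouse, each = n_psm[i]) +
                     stats::rnorm(n_psm[i] * nrow(mice), 0, psm_noise_sd)),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "filter_fail") <- quantified$gene[fail_idx]
  })
  out
}

#' Simulate cross-study group-level expression matrices
#'
#' Emulates a compendium of independent GF-versus-conventional studies: each
#' study contributes intrastudy comparison group pairs (one GF group, one
#' conventional group, each with at least three replicate columns). Per-pair
#' germ-status effect magnitudes are drawn from a two-level strong/weak
#' mixture, emulating the observed clustering of strongly and weakly affected
#' comparison group pairs.
#'
#' @param truth a [generate_truth()] result.
#' @param n_studies number of studies.
#' @param pairs_per_study scalar or length-`n_studies` vector of comparison
#'   group pairs per study (default totals 31 pairs across 8 studies).
#' @param replicates replicate columns per group (must be >= 3).
#' @param seed integer seed.
#' @param strong_frac probability that a pair is strongly affected.
#' @param weak_multiplier effect multiplier for weakly affected pairs.
#' @param noise_sd residual log2 noise standard deviation.
#' @return a list with `studies` (named list of gene x column log2 matrices),
#'   `manifest` (data frame: `study_id`, `pair_id`, `gf_group`, `c_group`,
#'   `strength`) and `groups` (column-to-group map).
#' @export
simulate_meta_groups <- function(truth, n_studies = 8L,
                                 pairs_per_study = c(4L, 4L, 4L, 4L, 4L, 4L, 4L, 3L),
                                 replicates = 3L, seed = 1L,
                                 strong_frac = 0.5, weak_multiplier = 0.3,
                                 noise_sd = 0.4) {
  if (replicates < 3)
    stop("replicates must be >= 3 (minimum of three replicates per group)")
  pairs_per_study <- rep_len(as.integer(pairs_per_study), n_studies)
  genes <- truth$genes$gene
  cfg <- truth$config
  withr::with_seed(as.integer(seed), {
    baseline <- stats::runif(length(genes), 4, 10)
    studies <- list()
    manifest <- NULL
    groups <- NULL
    for (s in seq_len(n_studies)) {
      sid <- sprintf("study%02d", s)
      study_off <- stats::rnorm(1, 0, 0.5)
      cols <- list()
      for (p in seq_len(pairs_per_study[s])) {
        strength <- if (stats::runif(1) < strong_frac) 1 else weak_multiplier
        delta <- truth$genes$dir_M * truth$genes$effect_log2 * strength
        gf_group <- sprintf("%s_p%d_GF", sid, p)
        c_group <- sprintf("%s_p%d_C", sid, p)
        for (g in c(gf_group, c_group)) {
          is_gf <- grepl("_GF$", g)
          for (r in seq_len(replicates)) {
            col <- baseline + study_off + (if (is_gf) delta else 0) +
              stats::rnorm(length(genes), 0, noise_sd)
            cols[[sprintf("%s_r%d", g, r)]] <- col
            groups <- rbind(groups, data.frame(
              study_id = sid, group = g,
              column = sprintf("%s_r%d", g, r),
              germ = if (is_gf) "GF" else "C", stringsAsFactors = FALSE))
          }
        }
        manifest <- rbind(manifest, data.frame(
          study_id = sid, pair_id = sprintf("%s_p%d", sid, p),
          gf_group = gf_group, c_group = c_group,
          strength = ifelse(strength == 1, "strong", "weak"),
          stringsAsFactors = FALSE))
      }
      m <- do.call(cbind, cols)
      rownames(m) <- genes
      studies[[sid]] <- m
    }
  })
  list(studies = studies, manifest = manifest, groups = groups)
}
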