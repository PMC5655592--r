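#' Identification filter for protein groups
#'
#' Keeps a protein group iff it has at least 2 peptide groups and at least 4
#' PSMs, or else at least 10 PSMs.
#'
#' @param counts data frame with columns `protein_group`, `peptide_groups`,
#'   `psms`.
#' @return the retained rows.
#' @export
filter_identifications <- function(counts) {
  stopifnot(all(c("protein_group", "peptide_groups", "psms") %in% names(counts)),
            all(counts$peptide_groups >= 0), all(counts$psms >= 0))
  keep <- (counts$peptide_groups >= 2 & counts$psms >= 4) | counts$psms >= 10
  counts[keep, , drop = FALSE]
}

#' Count peptide groups and PSMs per protein group
#'
#' @param psm PSM table (`protein_group`, `peptide_group`, `psm_id`,
#'   `mouse_id`, `ratio`).
#' @return data frame with `protein_group`, `peptide_groups`, `psms`.
#' @export
count_identifications <- function(psm) {
  pep <- tapply(psm$peptide_group, psm$protein_group,
                function(x) length(unique(x)))
  n <- tapply(psm$psm_id, psm$protein_group, function(x) length(unique(x)))
  data.frame(protein_group = names(pep),
             peptide_groups = as.integer(pep), psms = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantify protein groups as the median of PSM ratios
#'
#' Each protein group abundance equals the median of the corresponding PSM
#' sample/pool ratios, pooled per (protein group, mouse).
#'
#' @param psm PSM table, already identification-filtered.
#' @return protein group x mouse abundance matrix (`NA` for missing cells).
#' @export
quantify_protein_groups <- function(psm) {
  stopifnot(all(psm$ratio > 0))
  groups <- sort(unique(psm$protein_group))
  mice <- sort(unique(psm$mouse_id))
  med <- tapply(psm$ratio,
                list(factor(psm$protein_group, groups),
                     factor(psm$mouse_id, mice)),
                stats::median)
  grid <- matrix(as.numeric(med), length(groups), length(mice),
                 dimnames = list(groups, mice))
  if (anyNA(grid))
    message(sum(is.na(grid)), " protein group/mouse cells missing")
  grid
}

#' Central-tendency (median) normalization with bias summary
#'
#' Divides each mouse's abundances by that mouse's median abundance, so the
#' post-normalization per-mouse median equals 1 exactly. The per-mouse
#' normalization values are summarised as log-absolute values (the value if
#' >1, else its reciprocal); the overall bias is
#' `(geometric mean of log-absolute values - 1) x 100` percent, and subset
#' geometric means are reported for each experimental parameter value when
#' mouse metadata are supplied.
#'
#' @param grid protein group x mouse abundance matrix.
#' @param mice optional data frame (`mouse_id`, `germ`, `sex`, `strain`) for
#'   the per-parameter subset geometric means.
#' @return list with `grid` (normalized), `normalization` (per-mouse values),
#'   `log_absolute`, `bias_percent`, and `subset_geomeans`.
#' @export
central_tendency_normalize <- function(grid, mice = NULL) {
  n_per_mouse <- colSums(!is.na(grid))
  if (any(n_per_mouse < 2)) stop("at least 2 protein groups per mouse required")
  norm <- apply(grid, 2, stats::median, na.rm = TRUE)
  normalized <- sweep(grid, 2, norm, "/")
  log_abs <- ifelse(norm > 1, norm, 1 / norm)
  geomean <- function(x) exp(mean(log(x)))
  subset_geomeans <- NULL
  if (!is.null(mice)) {
    meta <- mice[match(colnames(grid), mice$mouse_id), ]
    vals <- c(germ = list(meta$germ), sex = list(meta$sex),
              strain = list(meta$strain))
    subset_geomeans <- unlist(lapply(vals, function(v)
      tapply(norm, v, geomean)))
  }
  list(grid = normalized, normalization = norm, log_absolute = log_abs,
       bias_percent = (geomean(log_abs) - 1) * 100,
       subset_geomeans = subset_geomeans)
}

#' Proteome GF/C ratio per protein group
#'
#' Ratio of the geometric mean abundance across GF samples to the geometric
#' mean across conventional samples.
#'
#' @param grid normalized protein group x mouse abundance matrix.
#' @param germ character vector ("GF"/"C") aligned with the columns.
#' @return named vector of GF/C ratios.
#' @export
proteome_gfc <- function(grid, germ) {
  stopifnot(length(germ) == ncol(grid), all(germ %in% c("GF", "C")))
  gm <- function(M) {
    lg <- log(M)
    exp(rowMeans(lg, na.rm = TRUE))
  }
  gf <- grid[, germ == "GF", drop = FALSE]
  cv <- grid[, germ == "C", drop = FALSE]
  if (!ncol(gf) || !ncol(cv)) stop("need at least one GF and one C sample")
  gm(gf) / gm(cv)
}

#' Three-way ANOVA on the proteome grid
#'
#' Log2-transforms the normalized abundances and delegates to
#' [fit_threeway_anova()]. Protein groups quantified in fewer than half of the
#' mice are excluded (and reported via a message).
#'
#' @param grid normalized abundance matrix.
#' @param mice data frame (`mouse_id`, `germ`, `sex`, `strain`).
#' @param min_frac_quantified minimum fraction of non-missing cells.
#' @return the [fit_threeway_anova()] result for the retained groups.
#' @export
proteome_threeway <- function(grid, mice, min_frac_quantified = 0.5) {
  meta <- mice[match(colnames(grid), mice$mouse_id), ]
  frac <- rowMeans(!is.na(grid))
  drop <- frac < min_frac_quantified
  if (any(drop))
    message(sum(drop), " protein groups excluded (>",
            round((1 - min_frac_quantified) * 100), "% missing)")
  fit_threeway_anova(log2(grid[!drop, , drop = FALSE]),
                     meta[, c("germ", "sex", "strain")])
}
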