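#' Reference-free two-colour ANOVA with array effects
#'
#' Fits, per feature, the model value = intercept + array effect + class
#' effect + residual for the eight experimental classes (2 germ statuses x 2
#' sexes x 2 strains), where each array contributes the two channels of one
#' GF/conventional pair. Because arrays only connect the GF and conventional
#' classes of one sex/strain stratum, the fit uses the split-plot
#' decomposition: within-array differences (GF - C) carry the germ contrasts
#' exactly, and between-array sums carry the cross-stratum information with
#' the array effect treated as random. Residual variances are pooled within
#' each stratum and may be moderated by empirical-Bayes shrinkage toward a
#' common value across features.
#'
#' @param pm a `probe_matrix` from [prep_microarray()].
#' @param moderate logical; moderate the residual variances with
#'   [limma::squeezeVar()] (a documented moderated-variance option).
#' @return an object of class `rf_anova_fit` holding per-array log2 GF/C
#'   differences (`d`), channel sums (`s`), per-stratum means, pooled
#'   variances with their degrees of freedom, and the class table.
#' @export
fit_reference_free_anova <- function(pm, moderate = TRUE) {
  stopifnot(inherits(pm, "probe_matrix"))
  smp <- pm$samples
  arrays <- unique(smp$array_id)
  if (length(arrays) < 2) stop("at least two arrays required")
  gf_col <- c_col <- integer(length(arrays))
  for (i in seq_along(arrays)) {
    gf_col[i] <- which(smp$array_id == arrays[i] & smp$germ == "GF")
    c_col[i] <- which(smp$array_id == arrays[i] & smp$germ == "C")
  }
  arr_meta <- smp[match(arrays, smp$array_id), c("array_id", "sex", "strain")]
  stratum <- factor(paste(arr_meta$sex, arr_meta$strain, sep = "."))
  if (nlevels(stratum) == 1 && length(arrays) == 1)
    stop("rank-deficient design: all samples on one array")
  V <- pm$values
  d <- V[, gf_col, drop = FALSE] - V[, c_col, drop = FALSE]
  s <- V[, gf_col, drop = FALSE] + V[, c_col, drop = FALSE]
  colnames(d) <- colnames(s) <- arrays

  Z <- stats::model.matrix(~ 0 + stratum)
  colnames(Z) <- levels(stratum)
  stratum_stats <- function(M) {
    obs <- !is.na(M)
    n_st <- obs %*% Z
    sum_st <- ifelse(obs, M, 0) %*% Z
    mean_st <- sum_st / n_st
    mean_st[n_st == 0] <- NA_real_
    resid <- M - mean_st[, as.integer(stratum), drop = FALSE]
    ss <- rowSums(resid^2, na.rm = TRUE)
    df <- rowSums(pmax(n_st - 1L, 0L))
    list(n = n_st, mean = mean_st, var = ifelse(df > 0, ss / df, NA_real_),
         df = df)
  }
  sd_ <- stratum_stats(d)
  ss_ <- stratum_stats(s)
  if (all(sd_$df == 0))
    stop("rank-deficient design: no replicate arrays within any stratum")

  moderate_var <- function(v, df) {
    ok <- df > 0 & !is.na(v)
    out <- list(var = v, df = df)
    if (moderate && sum(ok) > 1) {
      sq <- limma::squeezeVar(v[ok], df[ok])
      out$var[ok] <- sq$var.post
      prior <- if (is.finite(sq$df.prior)) sq$df.prior else 1e6
      out$df[ok] <- df[ok] + prior
    }
    out
  }
  vd <- moderate_var(sd_$var, sd_$df)
  vs <- moderate_var(ss_$var, ss_$df)

  classes <- expand.grid(germ = c("GF", "C"), sex = unique(arr_meta$sex),
                         strain = unique(arr_meta$strain),
                         stringsAsFactors = FALSE)
  classes$stratum <- paste(classes$sex, classes$strain, sep = ".")
  classes <- classes[classes$stratum %in% levels(stratum), ]
  classes$class <- paste(classes$germ, classes$stratum, sep = ".")
  rownames(classes) <- NULL

  structure(list(d = d, s = s, stratum = stratum, arrays = arr_meta,
                 mean_d = sd_$mean, mean_s = ss_$mean,
                 n_d = sd_$n, n_s = ss_$n,
                 var_d = vd$var, df_d = vd$df, var_d_raw = sd_$var,
                 var_s = vs$var, df_s = vs$df,
                 classes = classes, samples = smp, moderated = moderate),
            class = "rf_anova_fit")
}

#' Post hoc pairwise contrasts between experimental classes
#'
#' Computes t-statistics for every pair of experimental classes (28 pairs for
#' 8 classes) from the fitted class effects, with Satterthwaite degrees of
#' freedom for contrasts mixing the within-array and between-array strata,
#' two-sided p values, and Benjamini-Hochberg q values adjusted within each
#' class pair across features. Features with zero residual variance get p = 1.
#'
#' @param fit an `rf_anova_fit`.
#' @param pairs optional data frame with columns `class1`, `class2`; defaults
#'   to all pairs.
#' @return a list with `estimate`, `p` and `q` matrices (features x pairs) and
#'   the `pairs` table.
#' @export
pairwise_contrasts <- function(fit, pairs = NULL) {
  stopifnot(inherits(fit, "rf_anova_fit"))
  cls <- fit$classes
  if (is.null(pairs)) {
    idx <- utils::combn(nrow(cls), 2)
    pairs <- data.frame(class1 = cls$class[idx[1, ]],
                        class2 = cls$class[idx[2, ]],
                        stringsAsFactors = FALSE)
  }
  strata <- colnames(fit$mean_d)
  n_feat <- nrow(fit$d)
  est <- p <- matrix(NA_real_, n_feat, nrow(pairs),
                     dimnames = list(rownames(fit$d),
                                     paste(pairs$class1, pairs$class2, sep = "-")))
  for (k in seq_len(nrow(pairs))) {
    w <- stats::setNames(numeric(length(strata)), strata)  # coef on mean_s
    v <- w                                                 # coef on mean_d
    for (sgn_class in list(c(1, pairs$class1[k]), c(-1, pairs$class2[k]))) {
      sgn <- as.numeric(sgn_class[1])
      ci <- cls[cls$class == sgn_class[2], ]
      if (nrow(ci) != 1) stop("unknown class ", sgn_class[2])
      w[ci$stratum] <- w[ci$stratum] + sgn / 2
      v[ci$stratum] <- v[ci$stratum] + sgn * (if (ci$germ == "GF") 1 else -1) / 2
    }
    active <- abs(w) > 1e-12 | abs(v) > 1e-12
    e_k <- rowSums(sweep(fit$mean_s[, active, drop = FALSE], 2, w[active], "*") +
                   sweep(fit$mean_d[, active, drop = FALSE], 2, v[active], "*"))
    a <- rowSums(sweep(1 / fit$n_s[, active, drop = FALSE], 2,
                       (w[active])^2, "*"))
    b <- rowSums(sweep(1 / fit$n_d[, active, drop = FALSE], 2,
                       (v[active])^2, "*"))
    var_c <- a * fit$var_s + b * fit$var_d
    # Satterthwaite df; collapses to the single stratum df when one
    # component has zero weight
    num <- (a * fit$var_s + b * fit$var_d)^2
    den <- ifelse(a > 0, (a * fit$var_s)^2 / fit$df_s, 0) +
      ifelse(b > 0, (b * fit$var_d)^2 / fit$df_d, 0)
    df_c <- ifelse(den > 0, num / den, NA_real_)
    t_k <- e_k / sqrt(var_c)
    p_k <- 2 * stats::pt(abs(t_k), df_c, lower.tail = FALSE)
    p_k[!is.finite(t_k) | is.na(df_c) | var_c <= 0] <- 1
    est[, k] <- e_k
    p[, k] <- p_k
  }
  q <- apply(p, 2, stats::p.adjust, method = "BH")
  if (is.null(dim(q))) q <- matrix(q, nrow = n_feat, dimnames = dimnames(p))
  list(estimate = est, p = p, q = q, pairs = pairs)
}

#' Minimum q over the germ-matched contrasts
#'
#' For each feature, takes the minimum Benjamini-Hochberg q value across the
#' four matched GF-versus-conventional class pairs (sex and strain matched).
#' A feature is called significantly affected by germ status when
#' `q_min < alpha` (strict).
#'
#' @param contrasts result of [pairwise_contrasts()].
#' @param alpha significance threshold (default 0.1).
#' @return data frame with `feature_id`, `q_min`, `significant`, and one
#'   column of q values per germ-matched pair.
#' @export
qmin_germ <- function(contrasts, alpha = 0.1) {
  pr <- contrasts$pairs
  g1 <- sub("\\..*", "", pr$class1)
  g2 <- sub("\\..*", "", pr$class2)
  st1 <- sub("^[^.]*\\.", "", pr$class1)
  st2 <- sub("^[^.]*\\.", "", pr$class2)
  germ_pairs <- which(st1 == st2 & g1 != g2)
  if (!length(germ_pairs)) stop("no germ-matched class pairs found")
  qg <- contrasts$q[, germ_pairs, drop = FALSE]
  n_avail <- rowSums(!is.na(qg))
  if (any(n_avail < ncol(qg) & n_avail > 0))
    message("q_min computed over available contrasts for ",
            sum(n_avail < ncol(qg) & n_avail > 0), " features")
  q_min <- apply(qg, 1, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  data.frame(feature_id = rownames(contrasts$q), q_min = q_min,
             significant = !is.na(q_min) & q_min < alpha,
             qg, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' GF/C summary ratio from per-array log ratios
#'
#' The arithmetic mean of the log2 GF/C ratios across arrays, anti-logged.
#'
#' @param ratios numeric vector, or matrix with one row per feature and one
#'   column per array.
#' @param log2_scale logical; if `FALSE` the input is on the natural ratio
#'   scale and is log2-transformed first (so the result is the geometric
#'   mean).
#' @return GF/C ratio (vector for matrix input).
#' @export
transcriptome_gfc <- function(ratios, log2_scale = TRUE) {
  if (!log2_scale) ratios <- log2(ratios)
  if (is.matrix(ratios)) 2^rowMeans(ratios, na.rm = TRUE)
  else 2^mean(ratios, na.rm = TRUE)
}

#' Collapse probe-level results to gene level
#'
#' A gene's q_min is the minimum over its probes; its GF/C ratio is taken from
#' the probe achieving that minimum; the gene is significant iff any probe is.
#' Probes significant in conflicting directions are flagged. Unmapped probes
#' are excluded.
#'
#' @param records data frame with `feature_id`, `q_min`, `gfc` columns.
#' @param map data frame with `probe_id`, `gene` columns.
#' @param alpha significance threshold.
#' @return gene-level data frame (`gene`, `q_min`, `gfc`, `significant`,
#'   `direction_conflict`).
#' @export
collapse_probes_to_genes <- function(records, map, alpha = 0.1) {
  m <- merge(records, map, by.x = "feature_id", by.y = "probe_id")
  if (!nrow(m)) stop("no probes could be mapped to genes")
  out <- do.call(rbind, lapply(split(m, m$gene), function(g) {
    i <- which.min(g$q_min)
    sig <- !is.na(g$q_min) & g$q_min < alpha
    dirs <- sign(log(g$gfc[sig]))
    data.frame(gene = g$gene[1], q_min = g$q_min[i], gfc = g$gfc[i],
               significant = any(sig),
               direction_conflict = length(unique(dirs[dirs != 0])) > 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Three-way factorial ANOVA with per-parameter minimum q values
#'
#' For each feature, fits the full germ x sex x strain model and computes
#' Type-II sums-of-squares p values for the three main effects and four
#' interactions (appropriate for the unbalanced design). Each term's p vector
#' is Benjamini-Hochberg adjusted across features, and a per-parameter
#' minimum q is taken over the four terms involving that parameter, e.g.
#' q_min(sex) = min of q(sex), q(germ:sex), q(sex:strain),
#' q(germ:sex:strain).
#'
#' @param values numeric matrix, features x samples (log2 scale). `NA` cells
#'   are dropped per feature.
#' @param design data frame with one row per column of `values` and columns
#'   `germ`, `sex`, `strain`.
#' @return data frame with per-term p and q columns and `qmin_germ`,
#'   `qmin_sex`, `qmin_strain`.
#' @export
fit_threeway_anova <- function(values, design) {
  stopifnot(is.matrix(values), nrow(design) == ncol(values),
            all(c("germ", "sex", "strain") %in% names(design)))
  design <- data.frame(germ = factor(design$germ), sex = factor(design$sex),
                       strain = factor(design$strain))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%05d", seq_len(nrow(values)))
  if (any(vapply(design, nlevels, 0L) < 2))
    stop("full 2x2x2 design required (each factor needs two levels)")
  terms7 <- c("germ", "sex", "strain", "germ:sex", "germ:strain",
              "sex:strain", "germ:sex:strain")
  pattern <- apply(!is.na(values), 1, paste, collapse = "")
  p_mat <- matrix(NA_real_, nrow(values), 7,
                  dimnames = list(rownames(values), terms7))
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    keep <- !is.na(values[rows[1], ])
    sub_design <- design[keep, , drop = FALSE]
    Y <- t(values[rows, keep, drop = FALSE])
    p_mat[rows, ] <- typeII_anova_block(Y, sub_design, terms7)
  }
  q_mat <- apply(p_mat, 2, stats::p.adjust, method = "BH")
  if (is.null(dim(q_mat)))
    q_mat <- matrix(q_mat, nrow = nrow(p_mat), dimnames = dimnames(p_mat))
  colnames(q_mat) <- paste0("q.", terms7)
  colnames(p_mat) <- paste0("p.", terms7)
  qmin_for <- function(par) {
    cols <- paste0("q.", terms7[grepl(par, terms7)])
    apply(q_mat[, cols, drop = FALSE], 1, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  }
  data.frame(feature_id = rownames(values), p_mat, q_mat,
             qmin_germ = qmin_for("germ"), qmin_sex = qmin_for("sex"),
             qmin_strain = qmin_for("strain"),
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}

# Type-II sums of squares for the 2x2x2 factorial, vectorised across the
# columns of Y (samples x features). For each term: SS = RSS(model with all
# terms not containing the term) - RSS(same + term); F against the full-model
# residual mean square.
typeII_anova_block <- function(Y, design, terms7) {
  X_full <- stats::model.matrix(~ germ * sex * strain, design)
  asn <- attr(X_full, "assign")
  term_labels <- attr(stats::terms(~ germ * sex * strain), "term.labels")
  factors_of <- strsplit(term_labels, ":")
  contains <- function(t_small, t_big)
    all(factors_of[[t_small]] %in% factors_of[[t_big]])
  qr_full <- qr(X_full)
  rss_full <- colSums(qr.resid(qr_full, Y)^2)
  df_res <- nrow(Y) - qr_full$rank
  p_out <- matrix(NA_real_, ncol(Y), length(terms7))
  s2 <- if (df_res > 0) rss_full / df_res else rep(NA_real_, ncol(Y))
  for (ti in seq_along(terms7)) {
    others <- which(vapply(seq_along(term_labels), function(u)
      u != ti && !contains(ti, u), TRUE))
    cols_red <- asn %in% c(0L, others)
    cols_aug <- asn %in% c(0L, others, ti)
    qr_red <- qr(X_full[, cols_red, drop = FALSE])
    qr_aug <- qr(X_full[, cols_aug, drop = FALSE])
    df_t <- qr_aug$rank - qr_red$rank
    if (df_t <= 0 || df_res <= 0) next
    ss_t <- colSums(qr.resid(qr_red, Y)^2) - colSums(qr.resid(qr_aug, Y)^2)
    f <- (ss_t / df_t) / s2
    p <- stats::pf(f, df_t, df_res, lower.tail = FALSE)
    p[!is.finite(f) | s2 <= 0] <- 1   # zero residual variance: p := 1
    p_out[, ti] <- p
  }
  p_out
}
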