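#' Per-pair differential expression for one comparison group pair
#'
#' Two-sample t statistics (pooled variance) per gene for one intrastudy
#' GF-versus-conventional comparison group pair, with one-sided p values in
#' both directions. The direction convention is GF/C > 1 = up, so
#' p(up) = P(T >= t) and p(down) = P(T <= t).
#'
#' @param gf,cv numeric matrices (genes x replicate columns), log2 scale.
#' @return data frame with `gene`, `log2_ratio`, `ratio`, `p_up`, `p_down`.
#' @export
pair_differential <- function(gf, cv) {
  stopifnot(is.matrix(gf), is.matrix(cv), nrow(gf) == nrow(cv),
            ncol(gf) >= 3, ncol(cv) >= 3)
  n1 <- ncol(gf); n2 <- ncol(cv)
  m1 <- rowMeans(gf); m2 <- rowMeans(cv)
  v1 <- apply(gf, 1, stats::var); v2 <- apply(cv, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  df <- n1 + n2 - 2
  data.frame(gene = rownames(gf), log2_ratio = m1 - m2, ratio = 2^(m1 - m2),
             p_up = stats::pt(t, df, lower.tail = FALSE),
             p_down = stats::pt(t, df, lower.tail = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine comparison group pairs into a per-gene meta-analysis record
#'
#' Per direction, combines the per-pair one-sided p values (Fisher's method,
#' or Stouffer's as an alternative), then Benjamini-Hochberg adjusts each
#' direction across genes to produce q(up) and q(down); q_min is the minimum
#' of the two. The combined GF/C ratio is the geometric mean of the per-pair
#' ratios. Genes present in fewer than `min_pairs` pairs are dropped.
#'
#' @param pair_results list of [pair_differential()] data frames.
#' @param combiner "fisher" or "stouffer".
#' @param min_pairs minimum number of pairs per gene.
#' @param alpha significance threshold on q_min (strict).
#' @return data frame with `gene`, `n_pairs`, `gfc`, `q_up`, `q_down`,
#'   `q_min`, `significant`.
#' @export
combine_meta <- function(pair_results, combiner = c("fisher", "stouffer"),
                         min_pairs = 2L, alpha = 0.1) {
  combiner <- match.arg(combiner)
  stopifnot(length(pair_results) >= 2)
  genes <- sort(unique(unlist(lapply(pair_results, `[[`, "gene"))))
  get <- function(col) vapply(pair_results, function(pr)
    pr[[col]][match(genes, pr$gene)], numeric(length(genes)))
  p_up <- get("p_up"); p_down <- get("p_down"); lr <- get("log2_ratio")
  n_pairs <- rowSums(!is.na(p_up))
  combine <- function(P) {
    apply(P, 1, function(p) {
      p <- p[!is.na(p)]
      if (length(p) < 1) return(NA_real_)
      if (combiner == "fisher") {
        p <- pmax(p, .Machine$double.xmin)
        stats::pchisq(-2 * sum(log(p)), df = 2 * length(p),
                      lower.tail = FALSE)
      } else {
        z <- sum(stats::qnorm(p, lower.tail = FALSE)) / sqrt(length(p))
        stats::pnorm(z, lower.tail = FALSE)
      }
    })
  }
  keep <- n_pairs >= min_pairs
  cp_up <- combine(p_up[keep, , drop = FALSE])
  cp_down <- combine(p_down[keep, , drop = FALSE])
  q_up <- stats::p.adjust(cp_up, method = "BH")
  q_down <- stats::p.adjust(cp_down, method = "BH")
  q_min <- pmin(q_up, q_down)
  data.frame(gene = genes[keep], n_pairs = n_pairs[keep],
             gfc = 2^rowMeans(lr[keep, , drop = FALSE], na.rm = TRUE),
             q_up = q_up, q_down = q_down, q_min = q_min,
             significant = !is.na(q_min) & q_min < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the meta-analysis from simulated or user-supplied study matrices
#'
#' @param meta a list as returned by [simulate_meta_groups()]: `studies`,
#'   `manifest`, `groups`.
#' @param ... passed to [combine_meta()].
#' @return the [combine_meta()] result.
#' @export
meta_analysis <- function(meta, ...) {
  pair_results <- lapply(seq_len(nrow(meta$manifest)), function(i) {
    row <- meta$manifest[i, ]
    m <- meta$studies[[row$study_id]]
    gf_cols <- meta$groups$column[meta$groups$group == row$gf_group]
    c_cols <- meta$groups$column[meta$groups$group == row$c_group]
    pair_differential(m[, gf_cols, drop = FALSE], m[, c_cols, drop = FALSE])
  })
  combine_meta(pair_results, ...)
}
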