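#' Per-strain standardization of a heat-map matrix
#'
#' Scales each feature row within each strain's columns: `sigma` mode divides
#' by the strain-wise sample standard deviation of the (log2) values; `zscore`
#' mode additionally centres on the strain-wise mean first. Rows with zero
#' strain-wise variance become missing in that strain's columns and are
#' flagged.
#'
#' @param x numeric matrix (features x columns), log2 scale.
#' @param strain character vector of strain labels, one per column.
#' @param mode "sigma" or "zscore".
#' @return the standardized matrix, with attribute `n_degenerate` counting
#'   zero-variance row/strain combinations.
#' @export
strain_standardize <- function(x, strain, mode = c("sigma", "zscore")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), length(strain) == ncol(x))
  if (any(table(strain) < 2)) stop("at least 2 columns per strain required")
  n_degenerate <- 0L
  for (st in unique(strain)) {
    cols <- strain == st
    m <- rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
    sd_st <- apply(x[, cols, drop = FALSE], 1, stats::sd, na.rm = TRUE)
    bad <- is.na(sd_st) | sd_st == 0
    n_degenerate <- n_degenerate + sum(bad)
    centre <- if (mode == "zscore") m else 0
    x[, cols] <- (x[, cols, drop = FALSE] - centre) / sd_st
    x[bad, cols] <- NA_real_
  }
  attr(x, "n_degenerate") <- n_degenerate
  x
}

#' Hierarchical cluster analysis (complete linkage, Euclidean distance)
#'
#' Complete-linkage agglomeration on Euclidean distances. Missing cells are
#' handled pairwise-complete: the squared distance over observed pairs is
#' rescaled by total/observed before the square root (the behaviour of
#' [stats::dist()]).
#'
#' @param x numeric matrix.
#' @param cluster_rows,cluster_cols logical flags; an unclustered dimension
#'   keeps its input order.
#' @return list with `rows` and `cols`, each either `NULL` or a list holding
#'   the `hclust` object, the leaf `order`, and merge `heights`.
#' @export
hca <- function(x, cluster_rows = TRUE, cluster_cols = FALSE) {
  stopifnot(is.matrix(x))
  one <- function(m) {
    if (nrow(m) < 2) stop("at least 2 rows required for clustering")
    h <- stats::hclust(stats::dist(m, method = "euclidean"),
                       method = "complete")
    list(hclust = h, order = h$order, heights = h$height)
  }
  list(rows = if (cluster_rows) one(x) else NULL,
       cols = if (cluster_cols) one(t(x)) else NULL)
}
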