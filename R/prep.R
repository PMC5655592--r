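#' Cap spot background intensities
#'
#' Within each (array, channel) partition, background values above four times
#' the partition's median background are replaced by exactly four times that
#' median.
#'
#' @param spots spot table with columns `array_id`, `channel`, `probe_id`,
#'   `spot_index`, `foreground`, `background`.
#' @return the spot table with capped backgrounds; attribute `n_capped` holds
#'   the replacement count.
#' @export
cap_background <- function(spots) {
  check_spot_table(spots)
  key <- interaction(spots$array_id, spots$channel, drop = TRUE)
  if (any(tabulate(key) == 0L)) stop("empty array/channel partition")
  med <- tapply(spots$background, key, stats::median)
  cap <- 4 * med[as.character(key)]
  hit <- spots$background > cap
  spots$background[hit] <- cap[hit]
  attr(spots, "n_capped") <- sum(hit)
  spots
}

#' Floor net intensities
#'
#' Computes net intensity (foreground minus background) and replaces every
#' value strictly below 10 with a seeded uniform draw in \[10, 20\]. Draws are
#' consumed in stable (array, channel, probe, spot) order so the result does
#' not depend on input row order.
#'
#' @param spots spot table with capped backgrounds.
#' @param seed integer seed for the replacement draws.
#' @return the spot table with a `net` column; attribute `n_floored` holds the
#'   replacement count.
#' @export
floor_net_intensity <- function(spots, seed) {
  check_spot_table(spots)
  ord <- order(spots$array_id, spots$channel, spots$probe_id, spots$spot_index)
  spots <- spots[ord, , drop = FALSE]
  net <- spots$foreground - spots$background
  low <- net < 10
  withr::with_seed(as.integer(seed), {
    net[low] <- stats::runif(sum(low), 10, 20)
  })
  spots$net <- net
  rownames(spots) <- NULL
  attr(spots, "n_floored") <- sum(low)
  spots
}

#' Collapse replicate spots to a per-probe log2 matrix
#'
#' Averages net intensities across replicate spots per (array, channel,
#' probe), log2-transforms, and arranges one column per mouse using the
#' sample sheet's array/channel-to-mouse map.
#'
#' @param spots floored spot table (with `net` column).
#' @param samples sample sheet data frame (`mouse_id`, `array_id`, `channel`,
#'   `germ`, `sex`, `strain`).
#' @return a `probe_matrix`: list with `values` (probe x mouse matrix of log2
#'   net intensities, `NA` where a probe is missing on an array) and
#'   `samples`.
#' @export
collapse_replicates <- function(spots, samples) {
  stopifnot(!is.null(spots$net))
  probes <- sort(unique(spots$probe_id))
  key_s <- paste(spots$array_id, spots$channel, sep = "\r")
  key_col <- paste(samples$array_id, samples$channel, sep = "\r")
  if (anyDuplicated(key_col)) stop("duplicate array/channel in sample sheet")
  col_idx <- match(key_s, key_col)
  if (anyNA(col_idx)) stop("spots reference array/channel absent from sample sheet")
  row_idx <- match(spots$probe_id, probes)
  sums <- matrix(0, length(probes), nrow(samples))
  counts <- matrix(0L, length(probes), nrow(samples))
  ij <- cbind(row_idx, col_idx)
  sums <- rowsum_matrix(spots$net, ij, dim(sums))
  counts <- rowsum_matrix(rep(1, nrow(spots)), ij, dim(counts))
  values <- log2(sums / counts)
  values[counts == 0L] <- NA_real_
  dimnames(values) <- list(probes, samples$mouse_id)
  if (anyNA(values))
    message(sum(is.na(values)), " probe/sample cells missing after collapsing")
  structure(list(values = values, samples = samples), class = "probe_matrix")
}

# accumulate x into a matrix by (row, col) index pairs
rowsum_matrix <- function(x, ij, dims) {
  flat <- (ij[, 2] - 1L) * dims[1] + ij[, 1]
  acc <- rowsum(x, flat)
  out <- matrix(0, dims[1], dims[2])
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Intra-array LOWESS normalization
#'
#' For each array, estimates the trend of M = log2(channel 1 / channel 2)
#' against A = mean log2 intensity by locally weighted regression (classic
#' LOWESS, degree 1, 3 robustifying iterations) with the given span, subtracts
#' it from M, and reconstructs the per-channel values from the corrected M and
#' the unchanged A.
#'
#' @param pm a `probe_matrix`.
#' @param span LOWESS span (fraction of probes in each local window).
#' @return the normalized `probe_matrix`.
#' @export
lowess_intra_array <- function(pm, span = 0.4) {
  stopifnot(inherits(pm, "probe_matrix"))
  smp <- pm$samples
  values <- pm$values
  for (arr in unique(smp$array_id)) {
    i1 <- which(smp$array_id == arr & smp$channel == "green")
    i2 <- which(smp$array_id == arr & smp$channel == "red")
    if (length(i1) != 1L || length(i2) != 1L)
      stop("both channels of each array must be present")
    ok <- !is.na(values[, i1]) & !is.na(values[, i2])
    if (sum(ok) < 10) stop("fewer than 10 probes on array ", arr)
    m <- values[ok, i1] - values[ok, i2]
    a <- (values[ok, i1] + values[ok, i2]) / 2
    m_corr <- m - lowess_fit(a, m, span)
    values[ok, i1] <- a + m_corr / 2
    values[ok, i2] <- a - m_corr / 2
  }
  pm$values <- values
  pm
}

# classic lowess trend evaluated at every x (lowess returns sorted unique x)
lowess_fit <- function(x, y, span) {
  fit <- stats::lowess(x, y, f = span, iter = 3)
  stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
}

#' Inter-array LOESS normalization against the per-probe median
#'
#' Normalizes each sample column against a per-probe median pseudo-sample:
#' the trend of (sample - reference) against the mean of sample and reference
#' is estimated by locally weighted regression and subtracted.
#'
#' @param pm a `probe_matrix` (or plain matrix of log2 values).
#' @param span LOWESS span.
#' @return the normalized object of the same shape.
#' @export
loess_inter_array <- function(pm, span = 0.4) {
  values <- if (inherits(pm, "probe_matrix")) pm$values else pm
  if (ncol(values) < 2) stop("at least two samples required for a reference")
  ref <- apply(values, 1, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(values))) {
    ok <- !is.na(values[, j]) & !is.na(ref)
    m <- values[ok, j] - ref[ok]
    a <- (values[ok, j] + ref[ok]) / 2
    values[ok, j] <- values[ok, j] - lowess_fit(a, m, span)
  }
  if (inherits(pm, "probe_matrix")) {
    pm$values <- values
    pm
  } else values
}

check_spot_table <- function(spots) {
  need <- c("array_id", "channel", "probe_id", "spot_index",
            "foreground", "background")
  miss <- setdiff(need, names(spots))
  if (length(miss)) stop("spot table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(spots) == 0L) stop("empty spot table")
  invisible(TRUE)
}

#' Run the full spot-level preprocessing chain
#'
#' Fixed order: cap backgrounds, floor net intensities, collapse replicates to
#' log2, intra-array LOWESS normalization.
#'
#' @inheritParams cap_background
#' @inheritParams collapse_replicates
#' @param floor_seed seed for the flooring draws.
#' @param span LOWESS span.
#' @return a normalized `probe_matrix`.
#' @export
prep_microarray <- function(spots, samples, floor_seed = 1L, span = 0.4) {
  spots <- cap_background(spots)
  spots <- floor_net_intensity(spots, floor_seed)
  pm <- collapse_replicates(spots, samples)
  lowess_intra_array(pm, span = span)
}
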