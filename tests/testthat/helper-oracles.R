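# Independent oracles used to cross-check the package's statistics.
# These deliberately avoid the implementation path they validate.

# Benjamini-Hochberg by the definition: q_i = min_{j: p_j >= p_i} p_j * n / rank_j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# right-tail hypergeometric P(X >= k) by explicit log-binomial summation
hyper_tail_oracle <- function(k, K, N, n) {
  if (k == 0) return(1)
  js <- k:min(K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# exact two-tailed binomial p at p = 0.5 by enumerating the 2^n outcomes,
# grouped by success count with Pascal-triangle multiplicities
binom_two_tail_oracle <- function(k, n) {
  row <- 1
  for (i in seq_len(n)) row <- c(0, row) + c(row, 0)  # Pascal's triangle
  probs <- row / 2^n
  lower <- sum(probs[seq_len(k + 1)])
  upper <- sum(probs[(k + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

# two-tailed Mann-Whitney by full enumeration of group assignments
mw_perm_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  min(1, 2 * min(lower, upper))
}

# naive complete-linkage agglomeration: returns sorted merge heights
complete_linkage_heights_oracle <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# small spot table for preprocessing tests: one array, two channels,
# user-supplied backgrounds/foregrounds recycled over probes
toy_spot_table <- function(foreground, background,
                           array_id = "a1", channel = "green") {
  n <- max(length(foreground), length(background))
  data.frame(array_id = array_id, channel = channel,
             probe_id = sprintf("p%03d", seq_len(n)), spot_index = 1L,
             foreground = rep_len(foreground, n),
             background = rep_len(background, n),
             stringsAsFactors = FALSE)
}

# minimal probe_matrix wrapper for direct matrix input
toy_probe_matrix <- function(values, samples) {
  structure(list(values = values, samples = samples), class = "probe_matrix")
}

# gene state table built directly from per-layer (state, gfc, qmin) triples
toy_states <- function(genes, t_state = NULL, p_state = NULL, m_state = NULL,
                       gfc_from_state = TRUE) {
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  fill <- function(state) {
    gfc <- ifelse(state == "up", 2, ifelse(state == "down", 0.5,
                  ifelse(state == "unaffected", 1.2, NA)))
    qmin <- ifelse(state %in% c("up", "down"), 0.05,
                   ifelse(state == "unaffected", 0.5, NA))
    list(state = state, gfc = gfc, qmin = qmin)
  }
  for (nm in c("T", "P", "M")) {
    st <- switch(nm, T = t_state, P = p_state, M = m_state)
    if (is.null(st)) next
    f <- fill(st)
    out[[paste0("state_", nm)]] <- f$state
    out[[paste0("gfc_", nm)]] <- f$gfc
    out[[paste0("qmin_", nm)]] <- f$qmin
  }
  class(out) <- c("gene_state_table", "data.frame")
  out
}
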