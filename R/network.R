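#' Pathway-overlap network
#'
#' Builds an undirected network whose nodes are enriched pathways and whose
#' edges link pathways sharing at least `k` significantly affected genes; the
#' edge weight is the shared count. `k` is the minimum-overlap threshold
#' (1 to 5).
#'
#' @param memberships named list: per pathway, the member genes restricted to
#'   the analysis's significantly affected genes.
#' @param labels optional named character vector of pathway classification
#'   labels (attached as a node attribute).
#' @param k minimum overlap (1..5).
#' @return a `pathway_network`: list with `graph` (igraph object), `edges`
#'   (data frame: `source`, `target`, `weight`) and `k`.
#' @export
build_network <- function(memberships, labels = NULL, k = 1L) {
  stopifnot(k >= 1, k <= 5)
  pws <- names(memberships)
  edges <- NULL
  if (length(pws) >= 2) {
    idx <- utils::combn(length(pws), 2)
    w <- vapply(seq_len(ncol(idx)), function(j)
      length(intersect(memberships[[idx[1, j]]], memberships[[idx[2, j]]])),
      integer(1))
    keep <- w >= k
    edges <- data.frame(source = pws[idx[1, keep]],
                        target = pws[idx[2, keep]],
                        weight = w[keep], stringsAsFactors = FALSE)
  }
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  g <- if (length(pws))
    igraph::graph_from_data_frame(edges, directed = FALSE,
                                  vertices = data.frame(name = pws,
                                                        stringsAsFactors = FALSE))
  else igraph::make_empty_graph(0, directed = FALSE)
  if (!is.null(labels))
    igraph::V(g)$label_class <- unname(labels[pws])
  structure(list(graph = g, edges = edges, k = as.integer(k)),
            class = "pathway_network")
}

#' Connected components of a pathway network
#'
#' The paper-style "clusters": connected components, each summarised by its
#' node count and the histogram of classification labels.
#'
#' @param network a `pathway_network`.
#' @return data frame with one row per component: `component`, `n_nodes`,
#'   `members`, and per-label counts when labels are present.
#' @export
network_components <- function(network) {
  stopifnot(inherits(network, "pathway_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0)
    return(data.frame(component = integer(), n_nodes = integer(),
                      members = character(), stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  labels <- igraph::vertex_attr(g, "label_class")
  out <- do.call(rbind, lapply(seq_len(comp$no), function(i) {
    nodes <- igraph::V(g)$name[comp$membership == i]
    row <- data.frame(component = i, n_nodes = length(nodes),
                      members = paste(nodes, collapse = ","),
                      stringsAsFactors = FALSE)
    if (!is.null(labels)) {
      lab <- labels[comp$membership == i]
      for (lv in c("upregulated", "downregulated", "intraset-discordant",
                   "not-enriched"))
        row[[gsub("-", "_", lv)]] <- sum(lab == lv, na.rm = TRUE)
    }
    row
  }))
  out[order(-out$n_nodes), , drop = FALSE]
}
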