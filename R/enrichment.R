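#' Right-tailed Fisher exact pathway enrichment
#'
#' For each pathway, tests over-representation of the gene set among the
#' pathway's members within the reference universe: a right-tailed
#' hypergeometric test on the 2 x 2 table (in set and in pathway, versus the
#' reference), followed by Benjamini-Hochberg adjustment across pathways
#' within the analysis. Pathways with no reference members are excluded.
#'
#' @param gene_set character vector (must be a subset of `reference`).
#' @param reference character vector: the quantified universe.
#' @param catalog named list of pathway member vectors (e.g. from
#'   [read_gmt()]).
#' @param alpha_e enrichment significance threshold.
#' @return data frame with `pathway`, `pathway_size`, `overlap`, `p`, `q_e`,
#'   `enriched`, plus an `overlap_genes` list column.
#' @export
fisher_enrichment <- function(gene_set, reference, catalog, alpha_e = 0.1) {
  if (!length(catalog)) stop("empty pathway catalog")
  reference <- unique(reference)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% reference))
    stop("gene set must be a subset of the reference set")
  N <- length(reference)
  n <- length(gene_set)
  res <- lapply(names(catalog), function(pw) {
    members <- intersect(unique(catalog[[pw]]), reference)
    if (!length(members)) return(NULL)
    hits <- intersect(members, gene_set)
    k <- length(hits)
    K <- length(members)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, pathway_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  dropped <- vapply(res, is.null, TRUE)
  if (any(dropped))
    message(sum(dropped), " pathways with no reference members excluded")
  out <- do.call(rbind, res[!dropped])
  if (is.null(out)) stop("no pathway has members in the reference set")
  out$q_e <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q_e < alpha_e
  out$overlap_genes <- lapply(out$pathway, function(pw)
    intersect(intersect(unique(catalog[[pw]]), reference), gene_set))
  out
}

#' Classify a pathway's regulation direction from its three enrichment q values
#'
#' `upregulated` iff q_e(up) < q_e(up+down), q_e(up) < q_e(down) and
#' q_e(up) < alpha; `downregulated` mirrors it; `intraset-discordant` iff
#' q_e(up+down) <= q_e(up), q_e(up+down) <= q_e(down) and
#' q_e(up+down) < alpha. If no rule fires the pathway is `not-enriched`
#' (including the tie q_up = q_down < q_updown, on which the rules are
#' silent).
#'
#' @param q_up,q_down,q_updown enrichment q values (vectorised).
#' @param alpha_e enrichment threshold.
#' @return character vector of labels.
#' @export
classify_pathway <- function(q_up, q_down, q_updown, alpha_e = 0.1) {
  stopifnot(length(q_up) == length(q_down), length(q_up) == length(q_updown))
  up <- q_up < q_updown & q_up < q_down & q_up < alpha_e
  down <- q_down < q_updown & q_down < q_up & q_down < alpha_e
  disc <- q_updown <= q_up & q_updown <= q_down & q_updown < alpha_e
  label <- rep("not-enriched", length(q_up))
  label[disc] <- "intraset-discordant"
  label[down & !disc] <- "downregulated"
  label[up & !disc] <- "upregulated"
  label[is.na(q_up) | is.na(q_down) | is.na(q_updown)] <- NA_character_
  label
}

#' Run the full battery of enrichment analyses over a gene set catalog
#'
#' For every gene set in the catalog, runs three analyses (up, down, up+down
#' subsets against the set's reference universe) and classifies every pathway
#' from the resulting q_e triple.
#'
#' @param sets a `gene_set_catalog` from [build_gene_sets()].
#' @param catalog named list of pathway member vectors.
#' @param alpha_e enrichment threshold.
#' @return a list with `analyses` (long data frame: one row per pathway per
#'   gene set per subset) and `classification` (one row per pathway per gene
#'   set with the q_e triple and label).
#' @export
enrich_catalog <- function(sets, catalog, alpha_e = 0.1) {
  stopifnot(inherits(sets, "gene_set_catalog"))
  analyses <- NULL
  classification <- NULL
  for (nm in names(sets)) {
    entry <- sets[[nm]]
    subsets <- list(`up` = entry$up, `down` = entry$down,
                    `up+down` = entry$members)
    qs <- list()
    for (sub in names(subsets)) {
      fe <- fisher_enrichment(subsets[[sub]], entry$reference, catalog,
                              alpha_e = alpha_e)
      fe$gene_set <- nm
      fe$subset <- sub
      analyses <- rbind(analyses,
                        fe[, c("gene_set", "subset", "pathway",
                               "pathway_size", "overlap", "p", "q_e",
                               "enriched")])
      qs[[sub]] <- stats::setNames(fe$q_e, fe$pathway)
    }
    pws <- names(qs[["up+down"]])
    cl <- data.frame(gene_set = nm, pathway = pws,
                     q_up = qs[["up"]][pws], q_down = qs[["down"]][pws],
                     q_updown = qs[["up+down"]][pws],
                     row.names = NULL, stringsAsFactors = FALSE)
    cl$label <- classify_pathway(cl$q_up, cl$q_down, cl$q_updown, alpha_e)
    classification <- rbind(classification, cl)
  }
  list(analyses = analyses, classification = classification)
}

#' Tally pathway classifications per gene set
#'
#' One row per gene set with the counts of upregulated, downregulated and
#' intraset-discordant pathways, plus a wide pathway-by-gene-set label table.
#'
#' @param classification the `classification` component of
#'   [enrich_catalog()].
#' @return list with `tally` and `wide`.
#' @export
crosstab_pathways <- function(classification) {
  lv <- c("upregulated", "downregulated", "intraset-discordant")
  tally <- do.call(rbind, lapply(split(classification, classification$gene_set),
    function(d) data.frame(gene_set = d$gene_set[1],
                           upregulated = sum(d$label == lv[1], na.rm = TRUE),
                           downregulated = sum(d$label == lv[2], na.rm = TRUE),
                           intraset_discordant = sum(d$label == lv[3],
                                                     na.rm = TRUE),
                           stringsAsFactors = FALSE)))
  rownames(tally) <- NULL
  wide <- stats::reshape(
    classification[, c("gene_set", "pathway", "label")],
    idvar = "pathway", timevar = "gene_set", direction = "wide")
  names(wide) <- sub("^label\\.", "", names(wide))
  list(tally = tally, wide = wide)
}
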