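#' Call per-gene, per-layer regulation states
#'
#' Assigns each gene a state per data layer: `up` (GF/C > 1, q_min < alpha),
#' `down` (GF/C < 1, q_min < alpha), `unaffected` (quantified, q_min >=
#' alpha), or `unquantified` (absent from the layer). A significant gene with
#' GF/C exactly 1 is flagged indeterminate and treated as unaffected.
#'
#' @param transcriptome,proteome,meta per-layer data frames with columns
#'   `gene`, `gfc`, `q_min`; the proteome may additionally carry `qmin_sex`
#'   and `qmin_strain` (used by the invariant set). Any layer may be `NULL`.
#' @param alpha significance threshold (strict `<`).
#' @return a `gene_state_table` data frame: one row per gene in the union of
#'   the layers, columns `state_X`, `gfc_X`, `qmin_X` for each supplied layer
#'   X in T, P, M (plus `qmin_P_sex`/`qmin_P_strain` when available).
#' @export
call_states <- function(transcriptome = NULL, proteome = NULL, meta = NULL,
                        alpha = 0.1) {
  layers <- list(T = transcriptome, P = proteome, M = meta)
  layers <- layers[!vapply(layers, is.null, TRUE)]
  if (!length(layers)) stop("at least one layer required")
  genes <- sort(unique(unlist(lapply(layers, `[[`, "gene"))))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(layers)) {
    lr <- layers[[nm]]
    stopifnot(all(c("gene", "gfc", "q_min") %in% names(lr)))
    i <- match(genes, lr$gene)
    gfc <- lr$gfc[i]
    qm <- lr$q_min[i]
    sig <- !is.na(qm) & qm < alpha
    state <- rep("unquantified", length(genes))
    state[!is.na(i)] <- "unaffected"
    state[sig & !is.na(gfc) & gfc > 1] <- "up"
    state[sig & !is.na(gfc) & gfc < 1] <- "down"
    indeterminate <- sig & !is.na(gfc) & gfc == 1
    if (any(indeterminate))
      message(sum(indeterminate), " significant genes with GF/C exactly 1 in ",
              nm, " treated as unaffected")
    out[[paste0("state_", nm)]] <- state
    out[[paste0("gfc_", nm)]] <- gfc
    out[[paste0("qmin_", nm)]] <- qm
    if (nm == "P" && all(c("qmin_sex", "qmin_strain") %in% names(lr))) {
      out$qmin_P_sex <- lr$qmin_sex[i]
      out$qmin_P_strain <- lr$qmin_strain[i]
    }
  }
  class(out) <- c("gene_state_table", "data.frame")
  out
}

#' Build the ten concordance/discordance gene sets
#'
#' Constructs the named gene sets from a gene state table: the three
#' single-layer sets (T, P, M), the concordant sets (significant in the named
#' layers with all GF/C ratios on the same side of 1), the discordant sets
#' (significant in one layer, quantified in the other, and either not
#' significant there or regulated in the opposite direction; `T!=P` is the
#' union), and the invariant proteome set (significant for germ status,
#' unaffected by sex and strain). Each set carries `up` and `down` subsets
#' (split by the defining layer's direction; opposite-direction genes in the
#' union set follow the transcriptome) and a reference set: the quantified
#' universe of the layer(s) defining the set.
#'
#' @param states a `gene_state_table` from [call_states()].
#' @param meta_universe optional character vector used as the reference set
#'   for the meta-analysis layer (defaults to the genes quantified in M).
#' @param alpha threshold used for the invariant set's sex/strain filter.
#' @return a `gene_set_catalog`: named list of entries with `members`, `up`,
#'   `down`, `reference`.
#' @export
build_gene_sets <- function(states, meta_universe = NULL, alpha = 0.1) {
  stopifnot(inherits(states, "gene_state_table"))
  has <- function(nm) paste0("state_", nm) %in% names(states)
  st <- function(nm) states[[paste0("state_", nm)]]
  gfc <- function(nm) states[[paste0("gfc_", nm)]]
  for (nm in c("T", "P", "M")[c(has("T"), has("P"), has("M"))]) {
    bad <- (st(nm) == "up" & !is.na(gfc(nm)) & gfc(nm) < 1) |
      (st(nm) == "down" & !is.na(gfc(nm)) & gfc(nm) > 1)
    if (any(bad))
      stop("conflicting state table: state disagrees with GF/C in layer ", nm)
  }
  g <- states$gene
  sig <- function(nm) st(nm) %in% c("up", "down")
  quant <- function(nm) st(nm) != "unquantified"
  side <- function(nm) ifelse(is.na(gfc(nm)), 0, sign(log(gfc(nm))))

  catalog <- list()
  add <- function(name, members, up, down, reference) {
    catalog[[name]] <<- list(members = g[members], up = g[up], down = g[down],
                             reference = g[reference])
  }
  single <- function(nm, name) {
    add(name, sig(nm), st(nm) == "up", st(nm) == "down", quant(nm))
  }
  if (has("T")) single("T", "T")
  if (has("P")) single("P", "P")
  if (has("M")) single("M", "M")

  if (has("T") && has("P")) {
    both <- sig("T") & sig("P")
    conc <- both & side("T") == side("P")
    add("concordant[T,P]", conc, conc & st("T") == "up",
        conc & st("T") == "down", quant("T") & quant("P"))
    opp <- both & side("T") != side("P")
    tp <- sig("T") & quant("P") & (!sig("P") | opp)
    pt <- sig("P") & quant("T") & (!sig("T") | opp)
    add("discordant[T\\P]", tp, tp & st("T") == "up", tp & st("T") == "down",
        quant("T") & quant("P"))
    add("discordant[P\\T]", pt, pt & st("P") == "up", pt & st("P") == "down",
        quant("T") & quant("P"))
    un <- tp | pt
    # direction from the significant layer; opposite-direction genes follow
    # the transcriptome
    dir_layer <- ifelse(opp, side("T"), ifelse(tp, side("T"), side("P")))
    add("discordant[T!=P]", un, un & dir_layer > 0, un & dir_layer < 0,
        quant("T") & quant("P"))
  }
  if (has("T") && has("M")) {
    conc <- sig("T") & sig("M") & side("T") == side("M")
    add("concordant[T,M]", conc, conc & st("T") == "up",
        conc & st("T") == "down", quant("T") & quant("M"))
  }
  if (has("T") && has("P") && has("M")) {
    conc <- sig("T") & sig("P") & sig("M") &
      side("T") == side("P") & side("T") == side("M")
    add("concordant[T,P,M]", conc, conc & st("T") == "up",
        conc & st("T") == "down", quant("T") & quant("P") & quant("M"))
  }
  if (has("P") && all(c("qmin_P_sex", "qmin_P_strain") %in% names(states))) {
    inv <- sig("P") & !is.na(states$qmin_P_sex) & states$qmin_P_sex >= alpha &
      !is.na(states$qmin_P_strain) & states$qmin_P_strain >= alpha
    add("invariant[P]", inv, inv & st("P") == "up", inv & st("P") == "down",
        quant("P"))
  }
  if (has("M") && !is.null(meta_universe)) {
    for (nm in names(catalog)) {
      if (nm == "M") catalog[[nm]]$reference <- meta_universe
    }
  }
  structure(catalog, class = "gene_set_catalog")
}

#' Cross-tabulate per-gene states between two layers
#'
#' Counts genes over the 4 x 4 grid of states for a pair of layers and
#' reports the concordant total (up/up + down/down), the opposite-direction
#' total (up/down + down/up), and the significant-versus-unaffected cells.
#'
#' @param states a `gene_state_table`.
#' @param layers character vector of two layer codes among "T", "P", "M".
#' @return list with `table` (4 x 4), `concordant`, `opposite`,
#'   `sig_vs_unaffected`.
#' @export
tally_concordance <- function(states, layers = c("T", "P")) {
  stopifnot(length(layers) == 2)
  lv <- c("up", "down", "unaffected", "unquantified")
  s1 <- factor(states[[paste0("state_", layers[1])]], lv)
  s2 <- factor(states[[paste0("state_", layers[2])]], lv)
  tab <- table(s1, s2, dnn = layers)
  list(table = tab,
       concordant = tab["up", "up"] + tab["down", "down"],
       opposite = tab["up", "down"] + tab["down", "up"],
       sig_vs_unaffected = tab["up", "unaffected"] + tab["down", "unaffected"] +
         tab["unaffected", "up"] + tab["unaffected", "down"])
}
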