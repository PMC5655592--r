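test_that("state calling applies the GF/C and q_min rules with strict thresholds", {
  t_layer <- data.frame(gene = c("g1", "g2", "g3"),
                        gfc = c(2.0, 0.5, 1.0),
                        q_min = c(0.05, 0.10, 0.02),
                        stringsAsFactors = FALSE)
  p_layer <- data.frame(gene = "g1", gfc = 0.4, q_min = 0.01,
                        stringsAsFactors = FALSE)
  expect_message(states <- call_states(t_layer, p_layer), "GF/C exactly 1")
  expect_equal(states$state_T[states$gene == "g1"], "up")
  expect_equal(states$state_T[states$gene == "g2"], "unaffected")  # q = 0.10
  expect_equal(states$state_T[states$gene == "g3"], "unaffected")  # GF/C = 1
  expect_equal(states$state_P[states$gene == "g2"], "unquantified")
  expect_equal(states$state_P[states$gene == "g1"], "down")
})

test_that("the toy catalogue reproduces the set definitions by brute force", {
  # T: A up, B up, C down; P: A up, C up, D down; all quantified in both
  states <- toy_states(c("A", "B", "C", "D"),
                       t_state = c("up", "up", "down", "unaffected"),
                       p_state = c("up", "unaffected", "up", "down"))
  sets <- build_gene_sets(states)
  expect_setequal(sets[["concordant[T,P]"]]$members, "A")
  expect_setequal(sets[["discordant[T\\P]"]]$members, c("B", "C"))
  expect_setequal(sets[["discordant[P\\T]"]]$members, c("C", "D"))
  expect_setequal(sets[["discordant[T!=P]"]]$members, c("B", "C", "D"))
  # opposite-direction gene C sits in BOTH one-sided discordant sets
  expect_true("C" %in% sets[["discordant[T\\P]"]]$members &&
                "C" %in% sets[["discordant[P\\T]"]]$members)
  # up/down subsets follow the defining layer
  expect_setequal(sets[["discordant[T\\P]"]]$up, "B")
  expect_setequal(sets[["discordant[T\\P]"]]$down, "C")
  expect_setequal(sets[["discordant[P\\T]"]]$up, "C")
  expect_setequal(sets[["discordant[P\\T]"]]$down, "D")
  # union subsets: opposite genes follow the transcriptome
  expect_setequal(sets[["discordant[T!=P]"]]$up, "B")
  expect_setequal(sets[["discordant[T!=P]"]]$down, c("C", "D"))
})

test_that("genes unquantified in the other layer never enter discordant sets", {
  states <- toy_states(c("A", "B"),
                       t_state = c("up", "up"),
                       p_state = c("unquantified", "unaffected"))
  sets <- build_gene_sets(states)
  expect_setequal(sets[["T"]]$members, c("A", "B"))
  expect_setequal(sets[["discordant[T\\P]"]]$members, "B")
  expect_false("A" %in% sets[["discordant[T!=P]"]]$members)
})

test_that("set algebra |A u B| = |A| + |B| - |A n B| holds on random tables", {
  set.seed(6)
  for (i in 1:5) {
    n <- 200
    states <- toy_states(sprintf("g%d", 1:n),
                         t_state = sample(c("up", "down", "unaffected",
                                            "unquantified"), n, TRUE),
                         p_state = sample(c("up", "down", "unaffected",
                                            "unquantified"), n, TRUE))
    sets <- build_gene_sets(states)
    a <- sets[["discordant[T\\P]"]]$members
    b <- sets[["discordant[P\\T]"]]$members
    u <- sets[["discordant[T!=P]"]]$members
    expect_setequal(u, union(a, b))
    expect_equal(length(u), length(a) + length(b) - length(intersect(a, b)))
    # up and down subsets partition every directional set
    for (nm in c("T", "P", "concordant[T,P]", "discordant[T!=P]"))
      expect_setequal(c(sets[[nm]]$up, sets[[nm]]$down), sets[[nm]]$members)
  }
})

test_that("three-layer concordant sets nest correctly", {
  n <- 300
  set.seed(7)
  states <- toy_states(sprintf("g%d", 1:n),
                       t_state = sample(c("up", "down", "unaffected"), n, TRUE),
                       p_state = sample(c("up", "down", "unaffected"), n, TRUE),
                       m_state = sample(c("up", "down", "unaffected"), n, TRUE))
  sets <- build_gene_sets(states)
  tpm <- sets[["concordant[T,P,M]"]]$members
  expect_true(all(tpm %in% sets[["concordant[T,P]"]]$members))
  expect_true(all(tpm %in% sets[["concordant[T,M]"]]$members))
})

test_that("invariant[P] requires sex and strain q_min at or above the threshold", {
  p_layer <- data.frame(gene = c("g1", "g2", "g3"),
                        gfc = c(2, 2, 0.5), q_min = c(0.05, 0.05, 0.05),
                        qmin_sex = c(0.5, 0.05, 0.2),
                        qmin_strain = c(0.3, 0.4, 0.1),
                        stringsAsFactors = FALSE)
  states <- call_states(proteome = p_layer)
  sets <- build_gene_sets(states)
  expect_setequal(sets[["invariant[P]"]]$members, c("g1", "g3"))
  expect_setequal(sets[["invariant[P]"]]$up, "g1")
  expect_setequal(sets[["invariant[P]"]]$down, "g3")
})

test_that("a conflicting state table is rejected", {
  states <- toy_states("g1", t_state = "up")
  states$gfc_T <- 0.5
  expect_error(build_gene_sets(states), "conflicting")
})

test_that("concordance tallies count the cross-tab and conserve the total", {
  states <- toy_states(c("A", "B", "C", "D"),
                       t_state = c("up", "up", "down", "unaffected"),
                       p_state = c("up", "unaffected", "up", "down"))
  tly <- tally_concordance(states, c("T", "P"))
  expect_equal(sum(tly$table), 4)
  expect_equal(unname(tly$table["down", "up"]), 1)  # gene C
  expect_equal(unname(tly$concordant), 1)           # gene A
  expect_equal(unname(tly$opposite), 1)
  # all genes unquantified in P: everything lands in that column
  states2 <- toy_states(c("A", "B"), t_state = c("up", "down"),
                        p_state = c("unquantified", "unquantified"))
  tly2 <- tally_concordance(states2, c("T", "P"))
  expect_equal(sum(tly2$table[, "unquantified"]), 2)
})

test_that("planted mix structure is recovered by the end-to-end gene sets", {
  cfg <- truth_config(n_genes = 2000, frac_affected = 0.15,
                      effect_log2 = 2.4, noise_sd_log2 = 0.6,
                      mix = c(concordant_TP = 0.3, T_only = 0.4,
                              P_only = 0.28, opposite = 0.02),
                      n_pathways = 4, genes_per_pathway = 10, seed = 21)
  res <- run_pipeline(cfg, seed = 21, include_meta = FALSE)
  truth <- res$truth$genes
  sets <- res$sets
  states <- res$states
  # the concordant set requires significance in BOTH layers, so its size is
  # robust to single-layer false calls: within +-20% of the planted count
  expected_conc <- sum(truth$category == "concordant_TP")
  got_conc <- length(sets[["concordant[T,P]"]]$members)
  expect_lt(abs(got_conc - expected_conc) / expected_conc, 0.20)
  # planted one-sided discordant genes are recalled when quantified in the
  # other layer (single-layer set SIZES are inflated by the defining layer's
  # BH false calls, so recall, not size, is the planted signal here)
  quant_p <- states$gene[states$state_P != "unquantified"]
  unaff_p <- states$gene[states$state_P == "unaffected"]
  planted_tp <- truth$gene[truth$category == "T_only"]
  planted_tp <- planted_tp[planted_tp %in% unaff_p]
  expect_gte(mean(planted_tp %in% sets[["discordant[T\\P]"]]$members), 0.9)
  planted_opp <- truth$gene[truth$category == "opposite"]
  in_both <- planted_opp %in% sets[["discordant[T\\P]"]]$members &
    planted_opp %in% sets[["discordant[P\\T]"]]$members
  expect_gte(mean(in_both), 0.5)
})
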