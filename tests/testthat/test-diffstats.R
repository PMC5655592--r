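# small balanced design shared by several tests: 2 arrays per stratum
small_design <- function(n_per_stratum = 2L) {
  array_design(gf_per_class = rep(n_per_stratum, 4),
               c_per_class = rep(n_per_stratum, 4))
}

# probe matrix with directly specified per-sample values
pm_from_matrix <- function(values, design) {
  colnames(values) <- design$samples$mouse_id
  rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  structure(list(values = values, samples = design$samples),
            class = "probe_matrix")
}

test_that("eight classes yield exactly 28 pairwise contrasts", {
  des <- small_design()
  set.seed(1)
  pm <- pm_from_matrix(matrix(rnorm(20 * nrow(des$samples)), 20), des)
  fit <- fit_reference_free_anova(pm)
  ctr <- pairwise_contrasts(fit)
  expect_equal(ncol(ctr$p), choose(8, 2))
  expect_equal(nrow(fit$classes), 8)
})

test_that("array effects are absorbed: germ contrasts are shift-invariant", {
  des <- small_design()
  set.seed(2)
  v <- matrix(rnorm(30 * nrow(des$samples)), 30)
  pm1 <- pm_from_matrix(v, des)
  v2 <- v
  arr1 <- des$samples$array_id == des$arrays$array_id[1]
  v2[, arr1] <- v2[, arr1] + 5  # constant added to every value of one array
  pm2 <- pm_from_matrix(v2, des)
  c1 <- pairwise_contrasts(fit_reference_free_anova(pm1))
  c2 <- pairwise_contrasts(fit_reference_free_anova(pm2))
  germ <- grepl("^GF\\.(.*)-C\\.\\1$", colnames(c1$estimate))
  expect_true(any(germ))
  expect_equal(c1$estimate[, germ], c2$estimate[, germ], tolerance = 1e-12)
  expect_equal(c1$p[, germ], c2$p[, germ], tolerance = 1e-12)
})

test_that("zero-variance features get p = 1, never NaN", {
  des <- small_design()
  v <- matrix(rnorm(5 * nrow(des$samples)), 5)
  v[3, ] <- 7  # identical everywhere
  pm <- pm_from_matrix(v, des)
  ctr <- pairwise_contrasts(fit_reference_free_anova(pm, moderate = FALSE))
  expect_true(all(ctr$p[3, ] == 1))
  expect_false(anyNA(ctr$p))
})

test_that("planted class shifts agree with a paired t-test oracle", {
  # only the tested stratum is replicated, so the split-plot fit and the
  # paired t-test see the same within-array information
  des <- array_design(gf_per_class = c(5L, 1L, 1L, 1L),
                      c_per_class = c(5L, 1L, 1L, 1L))
  set.seed(3)
  n_feat <- 50
  v <- matrix(rnorm(n_feat * nrow(des$samples), 0, 0.2), n_feat)
  # plant a 2-unit GF shift in stratum F x first strain for features 1:10
  target <- des$samples$germ == "GF" & des$samples$sex == "F" &
    des$samples$strain == des$strains[1]
  v[1:10, target] <- v[1:10, target] + 2
  pm <- pm_from_matrix(v, des)
  fit <- fit_reference_free_anova(pm, moderate = FALSE)
  ctr <- pairwise_contrasts(fit)
  pair_name <- sprintf("GF.F.%s-C.F.%s", des$strains[1], des$strains[1])
  p_pkg <- ctr$p[1:10, pair_name]
  expect_true(all(p_pkg < 1e-3))
  expect_gte(mean(p_pkg < 1e-4), 0.5)
  # oracle: per-feature paired t-test on the per-array GF - C differences
  arr5 <- des$arrays$array_id[des$arrays$sex == "F" &
                                des$arrays$strain == des$strains[1]]
  for (f in 1:10) {
    d <- fit$d[f, arr5]
    p_oracle <- t.test(d)$p.value
    expect_lt(abs(log10(p_pkg[f]) - log10(p_oracle)), 1)
  }
})

test_that("pairwise q values equal the Benjamini-Hochberg oracle", {
  des <- small_design()
  set.seed(4)
  pm <- pm_from_matrix(matrix(rnorm(200 * nrow(des$samples)), 200), des)
  ctr <- pairwise_contrasts(fit_reference_free_anova(pm))
  for (j in c(1, 10, 28))
    expect_equal(ctr$q[, j], bh_oracle(ctr$p[, j]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  # the hand example: p = (0.01, 0.02, 0.03, 1.0) -> q = (0.04, 0.04, 0.04, 1.0)
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 1.0)), c(0.04, 0.04, 0.04, 1.0))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 1.0), "BH"),
               c(0.04, 0.04, 0.04, 1.0))
})

test_that("BH q is monotone in p rank and matches the oracle on random vectors", {
  set.seed(5)
  for (n in c(10, 1000, 10000)) {
    p <- runif(n)^2
    q <- p.adjust(p, "BH")
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("under the null the pairwise contrast calls stay within the BH band", {
  frac <- vapply(1:10, function(seed) {
    set.seed(seed)
    des <- small_design()
    pm <- pm_from_matrix(matrix(rnorm(400 * nrow(des$samples)), 400), des)
    ctr <- pairwise_contrasts(fit_reference_free_anova(pm))
    mean(apply(ctr$q, 1, min) < 0.1)
  }, numeric(1))
  expect_gte(sum(frac <= 0.15), 9)
})

test_that("q_min takes the minimum over the four germ-matched pairs", {
  q <- matrix(c(0.5, 0.09, 0.2, 0.8), 1)
  pairs <- data.frame(class1 = c("GF.F.A", "GF.M.A", "GF.F.B", "GF.M.B"),
                      class2 = c("C.F.A", "C.M.A", "C.F.B", "C.M.B"),
                      stringsAsFactors = FALSE)
  colnames(q) <- paste(pairs$class1, pairs$class2, sep = "-")
  rownames(q) <- "f1"
  res <- qmin_germ(list(q = q, pairs = pairs))
  expect_equal(res$q_min, 0.09)
  expect_true(res$significant)
  # boundary: all four equal to 0.1 is NOT significant (strict <)
  q2 <- q; q2[] <- 0.1
  res2 <- qmin_germ(list(q = q2, pairs = pairs))
  expect_equal(res2$q_min, 0.1)
  expect_false(res2$significant)
  # missing contrasts: minimum over the available ones, with a message
  q3 <- q; q3[1, 2] <- NA
  expect_message(res3 <- qmin_germ(list(q = q3, pairs = pairs)), "available")
  expect_equal(res3$q_min, 0.2)
})

test_that("GF/C summary ratio is the anti-logged mean of log2 ratios", {
  expect_equal(transcriptome_gfc(c(1, -1)), 1.0)
  expect_equal(transcriptome_gfc(2), 4.0)
  expect_equal(transcriptome_gfc(c(2, 2, 2), log2_scale = FALSE), 2.0)
  m <- rbind(a = c(1, 1), b = c(0, 2))
  expect_equal(unname(transcriptome_gfc(m)), c(2, 2))
})

test_that("probe-to-gene collapsing follows the min-q rule", {
  records <- data.frame(feature_id = c("pr1", "pr2", "pr3", "pr4", "pr5"),
                        q_min = c(0.05, 0.5, 0.02, 0.03, 0.2),
                        gfc = c(2.0, 0.7, 0.5, 3.0, 1.5),
                        stringsAsFactors = FALSE)
  map <- data.frame(probe_id = c("pr1", "pr2", "pr3", "pr4"),
                    gene = c("gA", "gA", "gB", "gB"),
                    stringsAsFactors = FALSE)
  out <- collapse_probes_to_genes(records, map)
  gA <- out[out$gene == "gA", ]
  expect_equal(gA$q_min, 0.05)
  expect_equal(gA$gfc, 2.0)
  expect_true(gA$significant)
  expect_false(gA$direction_conflict)
  gB <- out[out$gene == "gB", ]  # both probes significant, opposite directions
  expect_equal(gB$q_min, 0.02)
  expect_equal(gB$gfc, 0.5)
  expect_true(gB$direction_conflict)
  expect_false("pr5" %in% out$gene)  # unmapped probes stay out of the gene table
})

test_that("three-way ANOVA p values match the car Type-II oracle", {
  skip_if_not_installed("car")
  set.seed(6)
  design <- expand.grid(germ = c("GF", "C"), sex = c("F", "M"),
                        strain = c("A", "B"),
                        stringsAsFactors = FALSE)[rep(1:8, c(3, 3, 3, 3, 3, 3, 2, 3)), ]
  v <- matrix(rnorm(8 * nrow(design)), 8)
  v[1, design$germ == "GF"] <- v[1, design$germ == "GF"] + 2
  v[2, design$sex == "F" & design$strain == "A"] <-
    v[2, design$sex == "F" & design$strain == "A"] + 1.5
  res <- fit_threeway_anova(v, design)
  for (f in 1:4) {
    lmfit <- lm(y ~ germ * sex * strain,
                data = cbind(design, y = v[f, ]))
    oracle <- car::Anova(lmfit, type = 2)
    terms7 <- c("germ", "sex", "strain", "germ:sex", "germ:strain",
                "sex:strain", "germ:sex:strain")
    expect_equal(unname(unlist(res[f, paste0("p.", terms7)])),
                 oracle[terms7, "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("per-parameter q_min picks the minimum over the involved terms", {
  # assemble a record by hand through the public interface: use a design
  # where q values are known, then check the q_min(sex) definition directly
  q <- c(`q.sex` = 0.5, `q.germ:sex` = 0.05, `q.sex:strain` = 0.6,
         `q.germ:sex:strain` = 0.2)
  expect_equal(min(q), 0.05)  # definitional anchor for the checks below
  set.seed(7)
  design <- expand.grid(germ = c("GF", "C"), sex = c("F", "M"),
                        strain = c("A", "B"), rep = 1:3,
                        stringsAsFactors = FALSE)
  v <- matrix(rnorm(300 * nrow(design), 0, 0.3), 300)
  v[1:60, design$germ == "GF"] <- v[1:60, design$germ == "GF"] + 2
  res <- fit_threeway_anova(v, design)
  expect_equal(res$qmin_sex,
               pmin(res$`q.sex`, res$`q.germ:sex`, res$`q.sex:strain`,
                    res$`q.germ:sex:strain`))
  expect_equal(res$qmin_germ,
               pmin(res$`q.germ`, res$`q.germ:sex`, res$`q.germ:strain`,
                    res$`q.germ:sex:strain`))
  # planted pure germ effect: q(germ) is the smallest of the seven terms
  planted <- res[1:60, paste0("q.", c("germ", "sex", "strain", "germ:sex",
                                      "germ:strain", "sex:strain",
                                      "germ:sex:strain"))]
  frac_min <- mean(apply(planted, 1, which.min) == 1)
  expect_gte(frac_min, 0.95)
})

test_that("balanced null data give approximately uniform term p values", {
  set.seed(8)
  design <- expand.grid(germ = c("GF", "C"), sex = c("F", "M"),
                        strain = c("A", "B"), rep = 1:3,
                        stringsAsFactors = FALSE)
  v <- matrix(rnorm(2000 * nrow(design)), 2000)
  res <- fit_threeway_anova(v, design)
  for (term in c("p.germ", "p.sex:strain", "p.germ:sex:strain")) {
    ks <- suppressWarnings(ks.test(res[[term]], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})
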