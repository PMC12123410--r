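test_that("predictor eligibility requires completeness and a shared pathway", {
  m <- matrix(c(1, 2, 0.5, NA, 3, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("protA_S1", "protA_S2", "protB_S9"),
                              c("p1", "p2")))
  ph <- phospho_table(m)
  pw <- list(P1 = c("TFX", "protA"), P2 = c("protB", "other"))
  expect_identical(eligible_predictors("TFX", ph, pw), "protA_S1")
  # TF in no pathway -> empty
  expect_identical(eligible_predictors("TFQ", ph, pw), character(0))
})

test_that("an empty eligible set yields a no-predictors model", {
  prob <- noise_lasso_problem(n = 30, p = 5, seed = 1)
  m <- fit_tf_model("TF_UNKNOWN", prob$y, prob$phospho, prob$pathways, seed = 1)
  expect_identical(m$status, "no_predictors")
  expect_length(m$selected, 0)
  expect_error(phospho_scores(m, prob$phospho), "no_predictors")
})

test_that("a strongly informative site is selected among decoys", {
  set.seed(7)
  n <- 100
  fc_a <- rnorm(n)
  x <- cbind(fc_a, matrix(rnorm(n * 50), n))
  colnames(x) <- c("SITEA_S1", sprintf("DC%02d_S%d", 1:50, 101:150))
  ph <- make_phospho(t(x))
  y <- setNames(3 * fc_a + rnorm(n, sd = 0.3), colnames(ph$log2fc))
  pw <- list(P1 = c("TFX", site_proteins(colnames(x))))
  m <- fit_tf_model("TFX", y, ph, pw, seed = 7)
  expect_identical(m$status, "fitted")
  expect_true("SITEA_S1" %in% names(m$selected))
  expect_gt(m$selected[["SITEA_S1"]], 0)
  expect_lte(sum(names(m$selected) != "SITEA_S1"), 2)
})

test_that("selection is invariant to predictor column order", {
  prob <- planted_lasso_problem(n = 80, n_true = 3, n_decoy = 30, seed = 5)
  m1 <- fit_tf_model("TFX", prob$y, prob$phospho, prob$pathways, seed = 3)
  perm <- sample(nrow(prob$phospho$log2fc))
  ph2 <- phospho_table(prob$phospho$log2fc[perm, , drop = FALSE])
  m2 <- fit_tf_model("TFX", prob$y, ph2, prob$pathways, seed = 3)
  expect_setequal(names(m1$selected), names(m2$selected))
})

test_that("doubling the response doubles the coefficients", {
  prob <- planted_lasso_problem(n = 80, n_true = 3, n_decoy = 20, seed = 6)
  m1 <- fit_tf_model("TFX", prob$y, prob$phospho, prob$pathways, seed = 4)
  m2 <- fit_tf_model("TFX", 2 * prob$y, prob$phospho, prob$pathways, seed = 4)
  expect_setequal(names(m1$selected), names(m2$selected))
  common <- intersect(names(m1$selected), names(m2$selected))
  expect_equal(m2$selected[common], 2 * m1$selected[common], tolerance = 1e-6)
})

test_that("the lambda path is (near) monotone in model size", {
  prob <- planted_lasso_problem(n = 100, n_true = 5, n_decoy = 60, seed = 8)
  m <- fit_tf_model("TFX", prob$y, prob$phospho, prob$pathways, seed = 8)
  nz <- m$path_nonzero      # lambda descending -> sizes non-decreasing
  ok <- diff(nz) >= 0
  expect_gte(mean(ok), 0.95)
  # the path starts empty at lambda_max
  expect_equal(nz[1], 0)
})

test_that("too few usable patients is an error", {
  prob <- noise_lasso_problem(n = 10, p = 4, seed = 2)
  expect_error(fit_tf_model("TFX", prob$y, prob$phospho, prob$pathways,
                            seed = 1),
               ">= 20 usable patients")
})

test_that("sign-partitioned scores reproduce the reference coefficient set", {
  tbl <- erg_coefficient_table()
  expect_equal(nrow(tbl), 13)
  model <- coefficient_model("ERG", setNames(tbl$coefficient, tbl$site_id))

  pos_expected <- c("MYH9_S1943", "MYH11_S1954", "ALB_S82", "NEXN_S16",
                    "PRKCE_T710", "MYH11_S23", "FGA_S609", "ALB_T551",
                    "SSR3_S105", "PRKCD_S683", "FHOD1_S549")
  neg_expected <- c("CTNND1_S847", "IQGAP1_S330")
  expect_setequal(names(model$selected[model$selected > 0]), pos_expected)
  expect_setequal(names(model$selected[model$selected < 0]), neg_expected)

  set.seed(9)
  fc <- matrix(rnorm(13 * 10), 13,
               dimnames = list(tbl$site_id, sprintf("p%02d", 1:10)))
  ph <- phospho_table(fc)
  sc <- phospho_scores(model, ph)
  manual_plus <- sapply(colnames(fc), function(p) {
    acc <- 0
    for (s in pos_expected) acc <- acc + fc[s, p]
    acc
  })
  manual_minus <- sapply(colnames(fc), function(p) {
    acc <- 0
    for (s in neg_expected) acc <- acc + fc[s, p]
    acc
  })
  expect_equal(sc$p_plus, unname(manual_plus), tolerance = 1e-12)
  expect_equal(sc$p_minus, unname(manual_minus), tolerance = 1e-12)

  # all-zero patient scores zero
  fc0 <- fc
  fc0[, 1] <- 0
  sc0 <- phospho_scores(model, phospho_table(fc0))
  expect_equal(sc0$p_plus[1], 0)
  expect_equal(sc0$p_minus[1], 0)
})

test_that("tidy and glance summarize fitted models", {
  prob <- planted_lasso_problem(n = 80, n_true = 2, n_decoy = 10, seed = 10)
  m <- fit_tf_model("TFX", prob$y, prob$phospho, prob$pathways, seed = 2)
  td <- tidy(m)
  expect_true(all(c("site", "coefficient", "sign") %in% names(td)))
  gl <- glance(m)
  expect_identical(gl$status, m$status)
  expect_equal(gl$n_selected, length(m$selected))
})
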