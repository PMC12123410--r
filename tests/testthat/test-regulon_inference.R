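test_that("edge p-values match the exact correlation test", {
  expect_equal(edge_pvalue(0, 10), 1)
  expect_equal(edge_pvalue(1, 10), 0)
  expect_equal(edge_pvalue(-1, 7), 0)
  expect_error(edge_pvalue(0.5, 3), "n >= 4")

  # independent oracle: cor.test on data realizing a given r
  set.seed(1)
  x <- rnorm(50)
  y <- 0.6 * x + rnorm(50)
  ct <- stats::cor.test(x, y)
  expect_equal(edge_pvalue(unname(ct$estimate), 50), ct$p.value,
               tolerance = 1e-9)

  # matrix input keeps its shape
  m <- matrix(c(0, 0.5, -0.5, 1), 2)
  expect_identical(dim(edge_pvalue(m, 10)), dim(m))
})

test_that("perfect (anti)correlation yields the expected signed regulon", {
  set.seed(2)
  base <- rnorm(10)
  em <- rbind(
    TFX = base,
    g1 = base + rnorm(10, sd = 1e-3), g2 = base + rnorm(10, sd = 1e-3),
    g3 = base + rnorm(10, sd = 1e-3),
    g4 = -base + rnorm(10, sd = 1e-3), g5 = -base + rnorm(10, sd = 1e-3),
    n1 = rnorm(10), n2 = rnorm(10))
  reg <- infer_regulons(em, "TFX",
                        inference_params(n_bootstraps = 50, min_targets = 2),
                        seed = 1)
  expect_setequal(reg$target, c("g1", "g2", "g3", "g4", "g5"))
  expect_identical(setNames(reg$mode, reg$target)[c("g1", "g2", "g3", "g4", "g5")],
                   setNames(c(1L, 1L, 1L, -1L, -1L),
                            c("g1", "g2", "g3", "g4", "g5")))
})

test_that("independent noise yields no regulon at a stringent threshold", {
  set.seed(3)
  em <- matrix(rnorm(31 * 20), nrow = 31,
               dimnames = list(c("TFX", sprintf("n%02d", 1:30)), NULL))
  colnames(em) <- sprintf("s%02d", 1:20)
  reg <- infer_regulons(em, "TFX",
                        inference_params(n_bootstraps = 20, min_targets = 1),
                        seed = 1)
  expect_false("TFX" %in% reg$tf)
})

test_that("negating a target's expression flips its mode and preserves r, p, support", {
  set.seed(4)
  base <- rnorm(30)
  em <- rbind(TFX = base,
              gA = base + rnorm(30, sd = 0.2),
              gB = base + rnorm(30, sd = 0.2),
              pad1 = rnorm(30), pad2 = rnorm(30))
  colnames(em) <- sprintf("s%02d", 1:30)
  p <- inference_params(p_threshold = 1e-6, n_bootstraps = 40, min_targets = 1)
  r1 <- infer_regulons(em, "TFX", p, seed = 9)
  em2 <- em
  em2["gA", ] <- -em2["gA", ]
  r2 <- infer_regulons(em2, "TFX", p, seed = 9)
  a1 <- r1[r1$target == "gA", ]
  a2 <- r2[r2$target == "gA", ]
  expect_identical(a2$mode, -a1$mode)
  expect_equal(abs(a2$r), abs(a1$r))
  expect_equal(a2$p, a1$p)
  expect_equal(a2$support, a1$support)
})

test_that("lowering the p threshold never adds edges", {
  ch <- small_cohort()
  v <- vst(ch$bundle$counts_nat)$mat
  tfs <- names(ch$truth$targets)
  loose <- infer_regulons(v, tfs,
                          inference_params(p_threshold = 1e-4,
                                           n_bootstraps = 20, min_targets = 1),
                          seed = 5)
  strict <- infer_regulons(v, tfs,
                           inference_params(p_threshold = 1e-8,
                                            n_bootstraps = 20, min_targets = 1),
                           seed = 5)
  loose_keys <- paste(loose$tf, loose$target)
  strict_keys <- paste(strict$tf, strict$target)
  expect_true(all(strict_keys %in% loose_keys))
})

test_that("degenerate inputs are rejected or skipped with reasons", {
  em <- matrix(rnorm(9), 3, dimnames = list(c("TFX", "a", "b"), NULL))
  expect_error(infer_regulons(em, "TFX"), "4 samples")

  set.seed(6)
  em2 <- rbind(TFX = rep(1, 10), g1 = rnorm(10), g2 = rnorm(10))
  colnames(em2) <- sprintf("s%d", 1:10)
  expect_warning(
    reg <- infer_regulons(em2, "TFX", inference_params(n_bootstraps = 5),
                          seed = 1),
    "constant")
  expect_equal(nrow(reg), 0)
  expect_true("constant" %in% attr(reg, "skipped")$reason)

  expect_warning(
    reg2 <- infer_regulons(em2[-1, , drop = FALSE], "TFX",
                           inference_params(n_bootstraps = 5), seed = 1),
    "absent")
  expect_true("absent" %in% attr(reg2, "skipped")$reason)
})

test_that("the minimum-target exclusion drops small regulons", {
  set.seed(7)
  base <- rnorm(20)
  em <- rbind(TFX = base,
              g1 = base + rnorm(20, sd = 0.05),
              g2 = base + rnorm(20, sd = 0.05),
              n1 = rnorm(20), n2 = rnorm(20))
  colnames(em) <- sprintf("s%d", 1:20)
  p_small <- inference_params(p_threshold = 1e-6, n_bootstraps = 30,
                              min_targets = 10)
  reg <- infer_regulons(em, "TFX", p_small, seed = 2)
  expect_equal(nrow(reg), 0)
  sk <- attr(reg, "skipped")
  expect_true(any(sk$tf == "TFX" & sk$reason == "min_targets"))
})

test_that("planted regulons are recovered on the reduced cohort", {
  ch <- small_cohort()
  v <- vst(ch$bundle$counts_nat)$mat
  reg <- infer_regulons(v, names(ch$truth$targets),
                        inference_params(n_bootstraps = 100, min_targets = 10),
                        seed = 7)
  ev <- truth_eval(lapply(regulon_list(reg), function(x) x$target),
                   lapply(ch$truth$targets, function(t) t$gene))
  expect_true(all(ev$precision >= 0.9))
  expect_true(all(ev$recall >= 0.8))
})
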