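test_that("vst size factors and transform behave on simple cases", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  v <- vst(m)
  expect_equal(unname(v$size_factors), c(1, 1))
  expect_equal(v$mat[, 1], v$mat[, 2])

  # all-zero gene: excluded from size factors, transformed row is zero
  m2 <- rbind(m, z = c(0, 0))
  v2 <- vst(m2)
  expect_equal(unname(v2$mat["z", ]), c(0, 0))
  expect_equal(v2$size_factors, v$size_factors)

  expect_error(vst(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))),
               "all-zero")
})

test_that("doubling a library doubles its size factor, leaving large counts stable", {
  set.seed(1)
  n <- 100
  counts <- matrix(rpois(200 * n, lambda = 300), nrow = 200,
                   dimnames = list(sprintf("g%03d", 1:200), sprintf("s%03d", 1:n)))
  v1 <- vst(counts)
  doubled <- counts
  doubled[, 1] <- 2 * counts[, 1]
  v2 <- vst(doubled)
  expect_equal(unname(v2$size_factors[1] / v1$size_factors[1]), 2,
               tolerance = 0.05)
  big <- counts[, 1] >= 100
  expect_lt(max(abs(v2$mat[big, 1] - v1$mat[big, 1])), 0.02)
})

test_that("activity scores equal signed sums of target expression", {
  x <- matrix(c(3, 4, 5), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  reg <- tibble::tibble(tf = "T", target = c("g1", "g2", "g3"),
                        mode = c(1L, 1L, -1L))
  expect_equal(unname(activity_score(x, reg)), 3 + 4 - 5)
  reg_pos <- reg[reg$mode == 1, ]
  expect_equal(unname(activity_score(x, reg_pos)), 7)

  # brute-force oracle on a random matrix
  set.seed(2)
  xm <- matrix(rnorm(200), 20,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  regm <- tibble::tibble(tf = "T", target = rownames(xm),
                         mode = sample(c(-1L, 1L), 20, replace = TRUE))
  manual <- sapply(1:10, function(j) {
    acc <- 0
    for (i in 1:20) acc <- acc + regm$mode[i] * xm[regm$target[i], j]
    acc
  })
  expect_equal(unname(activity_score(xm, regm)), manual, tolerance = 1e-12)

  # linearity and mode-flip antisymmetry
  expect_equal(activity_score(3 * xm, regm), 3 * activity_score(xm, regm))
  flipped <- regm
  flipped$mode <- -flipped$mode
  expect_equal(activity_score(xm, flipped), -activity_score(xm, regm))

  # absent targets dropped with warning; nothing present -> no score
  expect_warning(activity_score(xm, tibble::tibble(tf = "T", target = c("g01", "zz"),
                                                   mode = c(1L, 1L))),
                 "absent")
  expect_null(suppressWarnings(
    activity_score(xm, tibble::tibble(tf = "T", target = "zz", mode = 1L))))
})

test_that("activity matrices label conditions and commute with sample order", {
  set.seed(3)
  tum <- matrix(rnorm(8), 4, dimnames = list(sprintf("g%d", 1:4), c("p1", "p2")))
  nat <- matrix(rnorm(8), 4, dimnames = dimnames(tum))
  reg <- tibble::tibble(tf = "T", target = rownames(tum), mode = 1L)
  am <- activity_matrix(tum, nat, reg)
  expect_equal(dim(am$scores), c(1L, 4L))
  expect_equal(as.character(am$condition), c("tumor", "tumor", "nat", "nat"))

  perm <- c("p2", "p1")
  am2 <- activity_matrix(tum[, perm], nat[, perm], reg)
  expect_equal(am2$scores[1, c("p1_T", "p2_T")], am$scores[1, c("p1_T", "p2_T")])

  long <- tidy(am)
  expect_setequal(names(long), c("tf", "sample", "score", "patient", "condition"))
  expect_equal(nrow(long), 4)
})

test_that("score structure reproduces an independent eigendecomposition", {
  set.seed(4)
  scores <- matrix(rnorm(5 * 30), 5,
                   dimnames = list(sprintf("T%d", 1:5), sprintf("s%02d", 1:30)))
  scores[2, ] <- 2 * scores[1, ] + 3   # perfectly correlated pair
  am <- structure(list(scores = scores,
                       condition = factor(rep(c("tumor", "nat"), each = 15),
                                          levels = c("tumor", "nat")),
                       patient = rep(sprintf("p%02d", 1:15), 2),
                       dropped = character(0)),
                  class = "tfa_activity")
  st <- score_structure(am, standardize = TRUE)
  expect_equal(st$cor_tumor["T1", "T2"], 1.0)
  expect_equal(sum(st$explained), 1)

  # eigen oracle on the standardized sample matrix
  x <- scale(t(scores))
  ev <- eigen(stats::cov(x))
  coords <- unname(x %*% ev$vectors)
  for (k in 1:3) {
    got <- st$pca[[paste0("PC", k)]]
    expect_true(isTRUE(all.equal(got, coords[, k], tolerance = 1e-8)) ||
                isTRUE(all.equal(got, -coords[, k], tolerance = 1e-8)))
  }

  # correlation invariant under per-TF affine rescaling
  scaled <- scores
  scaled[3, ] <- 5 * scaled[3, ] - 2
  am2 <- am
  am2$scores <- scaled
  st2 <- score_structure(am2, standardize = TRUE)
  expect_equal(st2$cor_tumor, st$cor_tumor)

  # constant TF row excluded from correlation with warning
  am3 <- am
  am3$scores[4, ] <- 1
  expect_warning(st3 <- score_structure(am3), "constant")
  expect_false("T4" %in% rownames(st3$cor_tumor))
})

test_that("planted perturbation separates tumor from NAT activity", {
  ch <- small_cohort()
  nm <- vst_bundle(ch$bundle)
  direct <- filter_regulon(truth_edges(ch), ch$se_table)
  am <- activity_matrix(nm$tumor, nm$nat, direct)
  auroc <- sapply(rownames(am$scores), function(tf)
    rank_auroc(am$scores[tf, ], am$condition == "tumor"))
  expect_true(all(auroc > 0.75))
})
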