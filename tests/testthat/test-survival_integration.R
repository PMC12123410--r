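test_that("median split follows the stated tie and midpoint conventions", {
  s <- setNames(c(1, 2, 3, 4), sprintf("p%d", 1:4))
  sp <- median_split(s)
  expect_identical(as.character(sp), c("low", "low", "high", "high"))

  s2 <- setNames(c(1, 2, 2, 4), sprintf("p%d", 1:4))
  sp2 <- median_split(s2)
  expect_identical(as.character(sp2), c("low", "low", "low", "high"))

  expect_error(median_split(setNames(rep(1, 5), 1:5)), "degenerate")
  expect_error(median_split(setNames(1:3, 1:3)), ">= 4")
})

test_that("median split group sizes differ at most by the median ties", {
  set.seed(1)
  for (i in 1:30) {
    n <- sample(c(15, 20), 1)
    s <- setNames(rnorm(n), sprintf("p%02d", 1:n))
    sp <- median_split(s)
    n_tied <- sum(s == median(s))
    expect_lte(abs(sum(sp == "low") - sum(sp == "high")), max(n_tied, 1))
  }
  # duplicated middle values land in "low" and stay within the tie bound
  s2 <- setNames(c(1, 2, 2, 4), sprintf("q%d", 1:4))
  sp2 <- median_split(s2)
  expect_lte(abs(sum(sp2 == "low") - sum(sp2 == "high")), sum(s2 == median(s2)))
})

test_that("median split is equivariant under increasing transforms", {
  set.seed(2)
  for (i in 1:20) {
    s <- setNames(rnorm(15), sprintf("p%02d", 1:15))
    expect_identical(median_split(s), median_split(exp(s)))
  }
})

test_that("log-rank is null on identical groups and invariant to time scale", {
  time <- c(2, 4, 6, 8, 10)
  ev <- c(1, 0, 1, 1, 0)
  surv <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:10),
    time = rep(time, 2), event = rep(ev, 2))
  labels <- setNames(factor(rep(c("A", "B"), each = 5)), surv$patient_id)
  km <- km_logrank(labels, surv)
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)

  # monotone relabeling of time preserves the statistic
  set.seed(3)
  surv2 <- tibble::tibble(patient_id = sprintf("p%02d", 1:20),
                          time = rexp(20, 0.2) + 0.01,
                          event = rbinom(20, 1, 0.7))
  lab2 <- setNames(factor(rep(c("A", "B"), 10)), surv2$patient_id)
  km_a <- km_logrank(lab2, surv2)
  surv3 <- surv2
  surv3$time <- surv3$time^3
  km_b <- km_logrank(lab2, surv3)
  expect_equal(km_a$chisq, km_b$chisq)
  expect_equal(km_a$p, km_b$p)
})

test_that("KM curves start at 1 and never increase", {
  set.seed(4)
  surv <- tibble::tibble(patient_id = sprintf("p%02d", 1:30),
                         time = rexp(30, 0.1) + 0.01,
                         event = rbinom(30, 1, 0.6))
  labels <- setNames(factor(rep(c("A", "B"), 15)), surv$patient_id)
  km <- km_logrank(labels, surv)
  expect_true(all(km$fit$surv <= 1 + 1e-12))
  for (g in seq_along(km$fit$strata)) {
    idx <- cumsum(c(0, km$fit$strata))[g] + seq_len(km$fit$strata[g])
    expect_true(all(diff(km$fit$surv[idx]) <= 1e-12))
  }
})

test_that("patients missing survival data are dropped with a warning", {
  surv <- tibble::tibble(patient_id = c("p1", "p2", "p3", "p4"),
                         time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  labels <- setNames(factor(c("A", "A", "B", "B", "A")),
                     c("p1", "p2", "p3", "p4", "ghost"))
  expect_warning(km <- km_logrank(labels, surv), "1 patient")
  expect_equal(km$n_dropped, 1)
})

test_that("combined strata count worst-side memberships", {
  p <- sprintf("p%d", 1:4)
  la <- setNames(factor(c("high", "high", "low", "low"),
                        levels = c("low", "high")), p)
  lb <- setNames(factor(c("high", "low", "low", "high"),
                        levels = c("low", "high")), p)
  worst <- c(TFA = "high", TFB = "high")
  cs <- combined_strata(list(TFA = la, TFB = lb), worst)
  expect_identical(unname(cs), c(2L, 1L, 0L, 1L))
  expect_equal(sum(table(cs)), 4)

  lb_bad <- lb[1:3]
  expect_error(combined_strata(list(TFA = la, TFB = lb_bad), worst), "lacks labels")

  # histogram sums to n on random inputs
  set.seed(5)
  for (i in 1:10) {
    n <- 12
    pats <- sprintf("q%02d", 1:n)
    ls <- lapply(1:3, function(k)
      setNames(factor(sample(c("low", "high"), n, replace = TRUE),
                      levels = c("low", "high")), pats))
    names(ls) <- paste0("T", 1:3)
    w <- setNames(sample(c("low", "high"), 3, replace = TRUE), names(ls))
    cs2 <- combined_strata(ls, w)
    expect_equal(sum(table(cs2)), n)
    # brute-force counting oracle
    manual <- sapply(pats, function(pp)
      sum(sapply(names(ls), function(tf)
        as.character(ls[[tf]][pp]) == w[[tf]])))
    expect_identical(unname(cs2), unname(as.integer(manual)))
  }
})

test_that("quadrants follow the double median split reading", {
  p <- sprintf("p%d", 1:4)
  act <- setNames(c(1, 1, -1, -1), p)
  php <- setNames(c(1, -1, 1, -1), p)
  q <- quadrant_groups(act, php)
  expect_identical(as.character(q), c("Q2", "Q3", "Q1", "Q4"))

  # sizes sum to n and match the brute-force double split
  set.seed(6)
  for (i in 1:10) {
    n <- 20
    pats <- sprintf("r%02d", 1:n)
    a <- setNames(rnorm(n), pats)
    b <- setNames(rnorm(n), pats)
    q2 <- quadrant_groups(a, b)
    expect_equal(sum(table(q2)), n)
    ax <- a > median(a)
    ay <- b > median(b)
    manual <- ifelse(ax & ay, "Q2", ifelse(!ax & !ay, "Q4",
                     ifelse(!ax & ay, "Q1", "Q3")))
    expect_identical(as.character(q2), unname(manual))
  }

  expect_error(quadrant_groups(setNames(rep(1, 4), p), php), "degenerate")
  expect_error(quadrant_groups(act, php[1:3]), "same patients")
})

test_that("worst direction is read off the survival data", {
  set.seed(7)
  n <- 40
  pats <- sprintf("p%02d", 1:n)
  score <- setNames(c(rnorm(n / 2, 0), rnorm(n / 2, 5)), pats)
  # high scores die fast
  time <- ifelse(score > median(score), rexp(n, 1), rexp(n, 0.05)) + 0.01
  surv <- tibble::tibble(patient_id = pats, time = time,
                         event = rep(1, n))
  labels <- median_split(score)
  expect_identical(worst_direction(labels, surv), "high")
})
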