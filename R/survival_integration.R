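#' Median split of a molecular score
#'
#' Patients at or below the median (even n: midpoint of the middle two) are
#' labeled `"low"`, the rest `"high"`. Ties at the median go to `"low"`,
#' keeping the split deterministic.
#'
#' @param score named numeric vector patient -> score (>= 4 patients, not
#'   all equal).
#' @return named factor patient -> `low`/`high`.
#' @export
median_split <- function(score) {
  if (length(score) < 4) abort("median_split: need >= 4 patients")
  if (length(unique(score)) == 1) abort("median_split: all scores equal (degenerate split)")
  m <- median(score)
  factor(ifelse(score <= m, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank test for labeled strata
#'
#' @param labels named factor/character patient -> group label (>= 2
#'   non-empty groups, each with >= 2 patients having survival data).
#' @param survival_df survival tibble (`patient_id`, `time`, `event`).
#' @return An object of class `tfa_km`: `fit` (a [survival::survfit()]
#'   object), `chisq`, `df`, `p`, `n_dropped` (patients without survival
#'   data), `groups`.
#' @export
km_logrank <- function(labels, survival_df) {
  surv <- validate_survival(survival_df)
  known <- names(labels) %in% surv$patient_id
  if (!all(known)) {
    warn(sprintf("dropping %d patient(s) missing from the survival table",
                 sum(!known)))
  }
  labels <- labels[known]
  df <- tibble(patient_id = names(labels), group = as.character(labels)) %>%
    left_join(surv, by = "patient_id")
  sizes <- table(df$group)
  if (length(sizes) < 2) abort("km_logrank: need >= 2 non-empty groups")
  if (any(sizes < 2)) abort("km_logrank: each group needs >= 2 patients")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  test <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sizes)
  p <- stats::pchisq(test$chisq, df = k - 1, lower.tail = FALSE)
  structure(list(fit = fit, chisq = unname(test$chisq), df = k - 1, p = p,
                 n_dropped = sum(!known), groups = names(sizes), data = df),
            class = "tfa_km")
}

#' @export
print.tfa_km <- function(x, ...) {
  cat(sprintf("<tfa_km> %d groups, log-rank chisq = %.3f (df %d), p = %.3g\n",
              length(x$groups), x$chisq, x$df, x$p))
  invisible(x)
}

#' @export
#' @rdname km_logrank
#' @param x a `tfa_km` result.
#' @param ... unused.
glance.tfa_km <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, p = x$p,
         n_groups = length(x$groups), n_dropped = x$n_dropped)
}

#' @export
#' @rdname km_logrank
tidy.tfa_km <- function(x, ...) {
  s <- summary(x$fit)
  tibble(group = sub("^group=", "", as.character(s$strata)),
         time = s$time, n_risk = s$n.risk, n_event = s$n.event,
         estimate = s$surv, std_error = s$std.err)
}

#' Which side of a median split carries the worse prognosis
#'
#' Compares restricted-mean survival between the two groups; the group with
#' the smaller restricted mean is the worst-prognosis side. Derived from the
#' data, not hardcoded.
#'
#' @param labels named factor `low`/`high` from [median_split()].
#' @param survival_df survival tibble.
#' @return `"low"` or `"high"`.
#' @export
worst_direction <- function(labels, survival_df) {
  km <- km_logrank(labels, survival_df)
  s <- summary(km$fit, rmean = "common")$table
  rmean <- s[, grep("^\\*?rmean$", colnames(s))]
  names(rmean) <- sub("^group=", "", rownames(s))
  names(which.min(rmean))
}

#' Combined strata over several TFs
#'
#' Each patient's label is the number of TFs for which they sit on the
#' declared worst-prognosis side (0 = best combined prognosis).
#'
#' @param labels_by_tf named list TF -> named `low`/`high` labels.
#' @param worst named character TF -> worst side (`"low"`/`"high"`), e.g.
#'   from [worst_direction()].
#' @return named integer vector patient -> count of worst-side memberships.
#' @export
combined_strata <- function(labels_by_tf, worst) {
  stopifnot(length(labels_by_tf) > 0, all(names(labels_by_tf) %in% names(worst)))
  patients <- names(labels_by_tf[[1]])
  for (tf in names(labels_by_tf)) {
    miss <- setdiff(patients, names(labels_by_tf[[tf]]))
    extra <- setdiff(names(labels_by_tf[[tf]]), patients)
    if (length(miss) > 0 || length(extra) > 0) {
      abort(sprintf("combined_strata: %s lacks labels for some patients", tf))
    }
  }
  counts <- rep(0L, length(patients))
  for (tf in names(labels_by_tf)) {
    counts <- counts +
      as.integer(as.character(labels_by_tf[[tf]][patients]) == worst[[tf]])
  }
  setNames(counts, patients)
}

#' Quadrant groups from a double median split
#'
#' Splits the transcriptomic activity score (x-axis) and the positive-sign
#' phosphorylation score (y-axis) at their medians (ties to low, as in
#' [median_split()]). Concordant patients fall in Q2 (both high) and Q4
#' (both low); discordant patients in Q1 (low activity, high phospho) and
#' Q3 (high activity, low phospho).
#'
#' @param activity named numeric patient -> activity score.
#' @param p_plus named numeric patient -> positive-coefficient phospho
#'   score; must cover the same patients.
#' @return named factor patient -> `Q1`/`Q2`/`Q3`/`Q4`.
#' @export
quadrant_groups <- function(activity, p_plus) {
  patients <- names(activity)
  if (!setequal(patients, names(p_plus))) {
    abort("quadrant_groups: the two scores must cover the same patients")
  }
  p_plus <- p_plus[patients]
  ax <- median_split(activity)
  ay <- median_split(p_plus)
  lab <- ifelse(ax == "high" & ay == "high", "Q2",
         ifelse(ax == "low" & ay == "low", "Q4",
         ifelse(ax == "low" & ay == "high", "Q1", "Q3")))
  setNames(factor(lab, levels = c("Q1", "Q2", "Q3", "Q4")), patients)
}
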