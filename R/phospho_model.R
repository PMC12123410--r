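#' Phosphosites eligible as predictors of a TF's activity
#'
#' A site is eligible when it was detected in every patient
#' (`complete_sites`) and its protein shares at least one pathway with the
#' TF. A TF found in no pathway has an empty eligible set.
#'
#' @param tf TF id.
#' @param phospho a [phospho_table()].
#' @param pathways named list pathway -> member ids (see [read_gmt()]).
#' @return character vector of eligible site ids.
#' @export
eligible_predictors <- function(tf, phospho, pathways) {
  tf_pw <- names(pathways)[vapply(pathways, function(m) tf %in% m, logical(1))]
  if (length(tf_pw) == 0) return(character(0))
  shared_prots <- unique(unlist(pathways[tf_pw], use.names = FALSE))
  keep <- phospho$complete_sites &
    phospho$protein_of_site %in% shared_prots
  phospho$site_ids[keep]
}

#' Sparse regression of TF activity on phosphosite fold changes
#'
#' LASSO feature selection: the tumor-sample activity score of one TF is
#' regressed on the log2 fold changes of its eligible phosphosites. The
#' data are split 80/20 (stratified by response quantile); on the training
#' set an L1 path over 100 log-spaced lambdas (from the smallest lambda
#' zeroing all coefficients down to 1e-3 of it) is fit and lambda chosen by
#' 5-fold cross-validated mean-squared error. Nonzero coefficients at the
#' chosen lambda are the selected sites. The 20% holdout R-squared is
#' recorded but nothing downstream depends on it.
#'
#' The default lambda rule is `"1se"` (largest lambda within one standard
#' error of the CV-MSE minimum): as a feature-selection device the model
#' should prefer parsimony, and under a pure-noise response the CV-MSE
#' minimizer admits spurious predictors roughly half the time while the
#' 1-SE rule mostly returns the empty model. The plain CV minimum is
#' available via `lambda_rule = "min"`.
#'
#' @param tf TF id.
#' @param activity_tumor named numeric vector patient -> tumor activity
#'   score of `tf`.
#' @param phospho a [phospho_table()].
#' @param pathways named list pathway -> member ids.
#' @param seed integer seed controlling split and fold assignment.
#' @param lambda_rule `"1se"` (default) or `"min"` (CV-MSE minimum).
#' @param standardize standardize predictors inside the fit (default FALSE:
#'   fold changes share a common log2 scale).
#' @return An object of class `tfa_phospho_model` with `tf`,
#'   `status` (`fitted`, `no_predictors`, or `all_zero`), `selected`
#'   (named nonzero coefficients), `lambda_chosen`, `eligible_sites`,
#'   `split` (train/test patient ids), `r2_test`, `seed`.
#' @export
fit_tf_model <- function(tf, activity_tumor, phospho, pathways, seed,
                         lambda_rule = c("1se", "min"), standardize = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  eligible <- eligible_predictors(tf, phospho, pathways)
  base <- structure(
    list(tf = tf, status = "no_predictors", selected = setNames(numeric(0), character(0)),
         lambda_chosen = NA_real_, eligible_sites = eligible,
         split = NULL, r2_test = NA_real_, seed = as.integer(seed),
         lambda_rule = lambda_rule, standardize = standardize),
    class = "tfa_phospho_model")
  if (length(eligible) == 0) return(base)

  patients <- intersect(names(activity_tumor)[is.finite(activity_tumor)],
                        colnames(phospho$log2fc))
  if (length(patients) < 20) {
    abort(sprintf("fit_tf_model(%s): need >= 20 usable patients, have %d",
                  tf, length(patients)))
  }
  x <- t(phospho$log2fc[eligible, patients, drop = FALSE])
  y <- activity_tumor[patients]

  set.seed(as.integer(seed))
  train <- stratified_split(y, frac_train = 0.8, n_strata = 4)
  xtr <- x[train, , drop = FALSE]
  ytr <- y[train]

  # lambda grid anchored at the smallest lambda with an all-zero solution
  xs <- scale(xtr, center = TRUE, scale = standardize)
  yc <- ytr - mean(ytr)
  lambda_max <- max(abs(crossprod(xs, yc))) / nrow(xtr)
  if (lambda_max <= 0) {
    base$status <- "all_zero"
    base$split <- list(train = patients[train], test = patients[!train])
    return(base)
  }
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-3), length.out = 100))
  foldid <- sample(rep_len(1:5, length(ytr)))

  xfit <- xtr
  pad <- ncol(xfit) == 1
  if (pad) xfit <- cbind(xfit, `.pad` = 0)   # glmnet needs >= 2 columns
  cv <- glmnet::cv.glmnet(xfit, ytr, alpha = 1, lambda = grid,
                          foldid = foldid, standardize = standardize)
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.matrix(stats::coef(cv, s = lam))[-1, 1]
  if (pad) beta <- beta[colnames(x)]
  selected <- beta[beta != 0]

  test_idx <- which(!train)
  r2 <- NA_real_
  if (length(test_idx) >= 2 && length(selected) > 0) {
    xte <- x[test_idx, , drop = FALSE]
    if (pad) xte <- cbind(xte, `.pad` = 0)
    pred <- as.numeric(stats::predict(cv, newx = xte, s = lam))
    yte <- y[test_idx]
    sst <- sum((yte - mean(yte))^2)
    if (sst > 0) r2 <- 1 - sum((yte - pred)^2) / sst
  }

  base$status <- if (length(selected) == 0) "all_zero" else "fitted"
  base$selected <- selected
  base$lambda_chosen <- lam
  base$split <- list(train = patients[train], test = patients[test_idx])
  base$r2_test <- r2
  # nonzero count along the descending lambda path (for path diagnostics)
  base$path_lambda <- cv$lambda
  base$path_nonzero <- unname(cv$nzero)
  base
}

# 80/20 split stratified by response quantile; returns logical train mask
stratified_split <- function(y, frac_train = 0.8, n_strata = 4) {
  qs <- quantile(y, probs = seq(0, 1, length.out = n_strata + 1))
  bins <- cut(y, breaks = unique(qs), include.lowest = TRUE)
  train <- logical(length(y))
  for (lev in levels(bins)) {
    idx <- which(bins == lev)
    n_tr <- max(1L, round(frac_train * length(idx)))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' @export
print.tfa_phospho_model <- function(x, ...) {
  cat(sprintf("<tfa_phospho_model> %s: %s (%d selected of %d eligible)\n",
              x$tf, x$status, length(x$selected), length(x$eligible_sites)))
  invisible(x)
}

#' @export
#' @rdname fit_tf_model
#' @param x a `tfa_phospho_model`.
#' @param ... unused.
tidy.tfa_phospho_model <- function(x, ...) {
  tibble(tf = x$tf, site = names(x$selected),
         coefficient = unname(x$selected),
         sign = ifelse(x$selected > 0, "positive", "negative"))
}

#' @export
#' @rdname fit_tf_model
glance.tfa_phospho_model <- function(x, ...) {
  tibble(tf = x$tf, status = x$status, n_eligible = length(x$eligible_sites),
         n_selected = length(x$selected), lambda = x$lambda_chosen,
         r2_test = x$r2_test)
}

#' Sign-partitioned phosphorylation scores
#'
#' Sites selected by the model are split by coefficient sign; for each
#' patient, `p_plus` is the sum of log2 fold changes over positive-sign
#' sites and `p_minus` the sum over negative-sign sites. Coefficients are
#' used only for their sign, never as weights.
#'
#' @param model a fitted `tfa_phospho_model`.
#' @param phospho a [phospho_table()] carrying the sites.
#' @return tibble `patient`, `p_plus`, `p_minus`.
#' @export
phospho_scores <- function(model, phospho) {
  stopifnot(inherits(model, "tfa_phospho_model"))
  if (model$status != "fitted") {
    abort(sprintf("phospho_scores: model for %s has status '%s'",
                  model$tf, model$status))
  }
  sites <- names(model$selected)
  missing <- setdiff(sites, phospho$site_ids)
  if (length(missing) > 0) {
    abort(sprintf("phospho_scores: site(s) absent from table: %s",
                  paste(missing, collapse = ", ")))
  }
  pos <- sites[model$selected > 0]
  neg <- sites[model$selected < 0]
  sum_rows <- function(ss) {
    if (length(ss) == 0) return(rep(0, ncol(phospho$log2fc)))
    unname(colSums(phospho$log2fc[ss, , drop = FALSE]))
  }
  tibble(patient = colnames(phospho$log2fc),
         p_plus = sum_rows(pos), p_minus = sum_rows(neg))
}

#' Fit phospho models for every TF of an activity matrix
#'
#' @param activity a `tfa_activity` (tumor columns are the responses).
#' @param phospho a [phospho_table()].
#' @param pathways named list pathway -> member ids.
#' @param seed integer seed (each TF's fit is seeded deterministically from
#'   it).
#' @param ... passed to [fit_tf_model()].
#' @return named list TF -> `tfa_phospho_model`.
#' @export
fit_all_models <- function(activity, phospho, pathways, seed, ...) {
  tfs <- rownames(activity$scores)
  models <- lapply(seq_along(tfs), function(i) {
    fit_tf_model(tfs[i], tumor_activity(activity, tfs[i]), phospho, pathways,
                 seed = as.integer(seed) + i, ...)
  })
  setNames(models, tfs)
}
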