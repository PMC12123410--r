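#' Simplified variance-stabilizing transform of RNA-seq counts
#'
#' A median-of-ratios size factor per sample (median over genes with a
#' nonzero geometric mean of `count / geomean(gene)`), followed by
#' `log2(count / size_factor + 1)`. Named "vst-simple" in outputs: it
#' removes library-size differences and compresses variance, the two
#' properties downstream stages rely on.
#'
#' @param counts non-negative integer matrix (genes x samples).
#' @return list with `mat` (transformed matrix) and `size_factors`.
#' @export
vst <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) abort("vst: counts must be non-negative")
  if (all(counts == 0)) abort("vst: all-zero count matrix")
  log_geo <- rowMeans(log(counts))     # -Inf where any zero
  usable <- is.finite(log_geo)
  if (!any(usable)) abort("vst: no gene with all-nonzero counts for size factors")
  sf <- apply(counts[usable, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - log_geo[usable]))
  })
  if (any(sf <= 0)) abort("vst: non-positive size factor")
  mat <- log2(sweep(counts, 2, sf, "/") + 1)
  list(mat = mat, size_factors = sf, method = "vst-simple")
}

#' Normalize both conditions of an expression bundle
#'
#' Applies [vst()] jointly across all 2N samples (tumor and NAT share size
#' factor estimation) and returns the per-condition matrices.
#'
#' @param bundle a [expression_bundle()].
#' @return list `tumor`, `nat` (genes x patients), `size_factors`.
#' @export
vst_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "tfa_bundle"))
  joint <- cbind(bundle$counts_tumor, bundle$counts_nat)
  colnames(joint) <- c(paste0(bundle$patient_ids, "_T"),
                       paste0(bundle$patient_ids, "_N"))
  v <- vst(joint)
  np <- length(bundle$patient_ids)
  tum <- v$mat[, seq_len(np), drop = FALSE]
  nat <- v$mat[, np + seq_len(np), drop = FALSE]
  colnames(tum) <- colnames(nat) <- bundle$patient_ids
  list(tumor = tum, nat = nat, size_factors = v$size_factors)
}

#' Per-sample TF activity score from direct targets
#'
#' The score of a sample is the sum of the variance-stabilized expression of
#' the TF's positive-mode direct targets minus the sum over its
#' negative-mode targets.
#'
#' @param expr_vst normalized expression matrix (genes x samples).
#' @param direct_regulon tibble of one TF's direct edges (`target`, `mode`).
#' @return named numeric vector sample -> score, or `NULL` (no-score) if no
#'   target is present in the matrix; absent targets are dropped with a
#'   warning.
#' @export
activity_score <- function(expr_vst, direct_regulon) {
  present <- direct_regulon$target %in% rownames(expr_vst)
  if (!all(present)) {
    warn(sprintf("dropping %d target(s) absent from the expression matrix",
                 sum(!present)))
  }
  reg <- direct_regulon[present, , drop = FALSE]
  if (nrow(reg) == 0) return(NULL)
  drop(as.numeric(reg$mode) %*% expr_vst[reg$target, , drop = FALSE])
}

#' TF activity matrix over tumor and NAT samples
#'
#' @param expr_vst_tumor,expr_vst_nat normalized matrices (genes x
#'   patients), e.g. from [vst_bundle()].
#' @param direct_regulons regulon tibble (typically SE-filtered).
#' @return An object of class `tfa_activity`: list with `scores`
#'   (TF x sample matrix over the 2N samples), `condition` (per-sample
#'   tumor/nat factor), `patient` (per-sample patient id) and `dropped`
#'   (TFs with no scorable target).
#' @export
activity_matrix <- function(expr_vst_tumor, expr_vst_nat, direct_regulons) {
  stopifnot(identical(colnames(expr_vst_tumor), colnames(expr_vst_nat)))
  patients <- colnames(expr_vst_tumor)
  tfs <- unique(direct_regulons$tf)
  rows <- list()
  dropped <- character(0)
  for (tf in tfs) {
    reg <- direct_regulons[direct_regulons$tf == tf, , drop = FALSE]
    st <- suppressWarnings(activity_score(expr_vst_tumor, reg))
    sn <- suppressWarnings(activity_score(expr_vst_nat, reg))
    if (is.null(st) || is.null(sn)) {
      dropped <- c(dropped, tf)
      inform(sprintf("activity_matrix: no scorable target for %s", tf))
      next
    }
    rows[[tf]] <- c(st, sn)
  }
  if (length(rows) == 0) abort("activity_matrix: no TF could be scored")
  scores <- do.call(rbind, rows)
  colnames(scores) <- c(paste0(patients, "_T"), paste0(patients, "_N"))
  structure(
    list(scores = scores,
         condition = factor(rep(c("tumor", "nat"), each = length(patients)),
                            levels = c("tumor", "nat")),
         patient = rep(patients, 2), dropped = dropped),
    class = "tfa_activity"
  )
}

#' @export
print.tfa_activity <- function(x, ...) {
  cat(sprintf("<tfa_activity> %d TFs x %d samples (%d tumor / %d NAT)\n",
              nrow(x$scores), ncol(x$scores), sum(x$condition == "tumor"),
              sum(x$condition == "nat")))
  invisible(x)
}

#' @export
#' @rdname activity_matrix
#' @param x a `tfa_activity` object.
#' @param ... unused.
tidy.tfa_activity <- function(x, ...) {
  as_tibble(x$scores, rownames = "tf") %>%
    tidyr::pivot_longer(-"tf", names_to = "sample", values_to = "score") %>%
    left_join(tibble(sample = colnames(x$scores),
                     patient = x$patient,
                     condition = as.character(x$condition)),
              by = "sample")
}

#' Tumor-side activity scores by patient
#'
#' @param activity a `tfa_activity`.
#' @param tf TF id.
#' @return named numeric vector patient -> tumor activity score.
#' @export
tumor_activity <- function(activity, tf) {
  stopifnot(inherits(activity, "tfa_activity"), tf %in% rownames(activity$scores))
  sel <- activity$condition == "tumor"
  setNames(activity$scores[tf, sel], activity$patient[sel])
}

#' Descriptive structure over TF activity scores
#'
#' PCA with samples as observations on centered, unit-variance TF rows
#' (standardization can be disabled), plus the TF x TF Pearson correlation
#' matrix computed on tumor samples only.
#'
#' @param activity a `tfa_activity` from [activity_matrix()].
#' @param standardize standardize TF rows before PCA (default TRUE).
#' @return An object of class `tfa_structure`: `pca` (tibble of sample
#'   coordinates with condition), `explained` (variance fractions, summing
#'   to 1), `cor_tumor` (correlation matrix), `excluded` (constant TFs
#'   dropped from the correlation).
#' @export
score_structure <- function(activity, standardize = TRUE) {
  stopifnot(inherits(activity, "tfa_activity"))
  scores <- activity$scores
  if (nrow(scores) < 2 || ncol(scores) < 3) {
    abort("score_structure: need >= 2 TFs and >= 3 samples")
  }
  tf_sd <- apply(scores, 1, sd)
  excluded <- rownames(scores)[tf_sd == 0]
  if (length(excluded) > 0) {
    warn(sprintf("excluding constant TF row(s): %s",
                 paste(excluded, collapse = ", ")))
  }
  usable <- scores[tf_sd > 0, , drop = FALSE]
  x <- t(usable)                       # samples x TFs
  pc <- prcomp(x, center = TRUE, scale. = standardize)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  pca <- as_tibble(pc$x, rownames = "sample") %>%
    mutate(condition = as.character(activity$condition),
           patient = activity$patient)
  tum <- usable[, activity$condition == "tumor", drop = FALSE]
  cor_tumor <- cor(t(tum))
  structure(list(pca = pca, explained = explained, cor_tumor = cor_tumor,
                 excluded = excluded, rotation = pc$rotation),
            class = "tfa_structure")
}
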