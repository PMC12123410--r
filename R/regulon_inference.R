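#' Parameters for coexpression regulon inference
#'
#' @param p_threshold two-sided Pearson p-value threshold for a candidate
#'   TF-target edge (default 1e-8).
#' @param n_bootstraps bootstrap resamples used to assess edge support
#'   (default 1000).
#' @param min_targets minimum surviving targets for a TF to be retained
#'   (default 20; smaller regulons are excluded).
#' @param min_support minimum fraction of bootstraps in which an edge must
#'   reach `p_threshold` (default 0.5).
#' @return a `tfa_inference_params` list.
#' @export
inference_params <- function(p_threshold = 1e-8, n_bootstraps = 1000,
                             min_targets = 20, min_support = 0.5) {
  if (p_threshold <= 0 || p_threshold >= 1) abort("p_threshold must be in (0,1)")
  if (n_bootstraps < 1) abort("n_bootstraps must be >= 1")
  if (min_support < 0 || min_support > 1) abort("min_support must be in [0,1]")
  structure(list(p_threshold = p_threshold, n_bootstraps = as.integer(n_bootstraps),
                 min_targets = as.integer(min_targets), min_support = min_support),
            class = "tfa_inference_params")
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution `t = r * sqrt(n-2) / sqrt(1-r^2)` on
#' `n-2` degrees of freedom; `r = +/-1` yields `p = 0`.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @param n number of paired observations, `n >= 4`.
#' @return two-sided p-value(s).
#' @export
edge_pvalue <- function(r, n) {
  if (any(n < 4)) abort("edge_pvalue: need n >= 4")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) abort("edge_pvalue: |r| must be <= 1")
  r[] <- pmin(1, pmax(-1, as.numeric(r)))
  p <- r
  deg <- abs(r) >= 1
  p[deg] <- 0
  tt <- r[!deg] * sqrt(n - 2) / sqrt(1 - r[!deg]^2)
  p[!deg] <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p
}

#' Infer signed TF regulons from coexpression with bootstrap support
#'
#' For each TF, a candidate edge to a gene is kept if its two-sided Pearson
#' p-value on the full data is at most `p_threshold` and the edge reaches
#' that threshold in at least `min_support` of `n_bootstraps` resamples of
#' the samples (drawn with replacement). Target mode is the sign of the
#' full-data correlation. TFs with fewer than `min_targets` surviving
#' targets are dropped from the result.
#'
#' @param expr_nat normalized (variance-stabilized) expression matrix,
#'   genes x samples. Inference is intended to run on normal-tissue samples.
#' @param tf_ids character vector of TF gene ids; TFs absent from the matrix
#'   are skipped with a warning.
#' @param params an [inference_params()].
#' @param seed integer seed for the bootstrap resamples.
#' @return A regulon tibble with columns `tf`, `target`, `mode`, `r`, `p`,
#'   `support`, and an attribute `skipped` naming TFs skipped (absent or
#'   constant) or dropped (`< min_targets`).
#' @export
infer_regulons <- function(expr_nat, tf_ids, params = inference_params(),
                           seed = 1L) {
  stopifnot(is.matrix(expr_nat))
  n <- ncol(expr_nat)
  if (n < 4) abort("infer_regulons: need at least 4 samples")
  set.seed(as.integer(seed))

  skipped <- tibble(tf = character(0), reason = character(0))
  absent <- setdiff(tf_ids, rownames(expr_nat))
  if (length(absent) > 0) {
    warn(sprintf("skipping %d TF(s) absent from the expression matrix: %s",
                 length(absent), paste(head(absent, 5), collapse = ", ")))
    skipped <- bind_rows(skipped, tibble(tf = absent, reason = "absent"))
  }
  tf_ids <- intersect(tf_ids, rownames(expr_nat))

  gene_sd <- apply(expr_nat, 1, sd)
  constant_tfs <- tf_ids[gene_sd[tf_ids] == 0]
  if (length(constant_tfs) > 0) {
    warn(sprintf("skipping constant-expression TF(s): %s",
                 paste(constant_tfs, collapse = ", ")))
    skipped <- bind_rows(skipped, tibble(tf = constant_tfs, reason = "constant"))
    tf_ids <- setdiff(tf_ids, constant_tfs)
  }
  if (length(tf_ids) == 0) {
    out <- tibble(tf = character(0), target = character(0), mode = integer(0),
                  r = double(0), p = double(0), support = double(0))
    attr(out, "skipped") <- skipped
    return(out)
  }

  # zero-variance genes cannot carry a correlation; exclude from candidates
  cand_genes <- rownames(expr_nat)[gene_sd > 0]
  x_tf <- t(expr_nat[tf_ids, , drop = FALSE])
  x_all <- t(expr_nat[cand_genes, , drop = FALSE])
  r_full <- cor(x_tf, x_all)
  p_full <- edge_pvalue(r_full, n)

  # candidate edges on the full data (self-edges removed)
  edges <- map_dfr(tf_ids, function(tf) {
    hit <- which(p_full[tf, ] <= params$p_threshold)
    tg <- setdiff(cand_genes[hit], tf)
    if (length(tg) == 0) return(NULL)
    r_tg <- unname(r_full[tf, tg])
    p_tg <- unname(p_full[tf, tg])
    tibble(tf = tf, target = tg, mode = as.integer(sign(r_tg)),
           r = r_tg, p = p_tg)
  })
  if (nrow(edges) == 0) {
    out <- tibble(tf = character(0), target = character(0), mode = integer(0),
                  r = double(0), p = double(0), support = double(0))
    attr(out, "skipped") <- bind_rows(skipped, tibble(tf = tf_ids, reason = "min_targets"))
    return(out)
  }

  # bootstrap support, restricted to the candidate target set
  boot_genes <- unique(edges$target)
  x_boot <- x_all[, boot_genes, drop = FALSE]
  hits <- matrix(0L, nrow = length(tf_ids), ncol = length(boot_genes),
                 dimnames = list(tf_ids, boot_genes))
  for (b in seq_len(params$n_bootstraps)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb_tf <- x_tf[idx, , drop = FALSE]
    xb_tg <- x_boot[idx, , drop = FALSE]
    ok_tf <- matrixStats_sd(xb_tf) > 0
    ok_tg <- matrixStats_sd(xb_tg) > 0
    if (!any(ok_tf) || !any(ok_tg)) next
    rb <- suppressWarnings(cor(xb_tf[, ok_tf, drop = FALSE],
                               xb_tg[, ok_tg, drop = FALSE]))
    pb <- edge_pvalue(ifelse(is.na(rb), 0, rb), n)
    hits[ok_tf, ok_tg] <- hits[ok_tf, ok_tg] + (pb <= params$p_threshold)
  }
  edges$support <- hits[cbind(edges$tf, edges$target)] / params$n_bootstraps
  edges <- edges %>% filter(.data$support >= params$min_support)

  # the "< min_targets" exclusion applies to the inferred regulon
  sizes <- edges %>% count(.data$tf)
  small <- c(setdiff(tf_ids, sizes$tf),
             sizes$tf[sizes$n < params$min_targets])
  if (length(small) > 0) {
    skipped <- bind_rows(skipped, tibble(tf = sort(small), reason = "min_targets"))
    edges <- edges %>% filter(!.data$tf %in% small)
  }
  out <- edges %>% arrange(.data$tf, .data$target)
  attr(out, "skipped") <- skipped
  out
}

# column sds without extra dependencies
matrixStats_sd <- function(m) {
  mu <- colMeans(m)
  sqrt(pmax(0, colMeans(m^2) - mu^2))
}

#' Split a regulon tibble into a per-TF list
#'
#' @param regulons regulon tibble (`tf`, `target`, `mode`, ...).
#' @return named list TF -> tibble of its edges.
#' @export
regulon_list <- function(regulons) {
  split(regulons, regulons$tf)
}
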