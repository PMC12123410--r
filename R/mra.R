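#' Paired tumor-vs-NAT differential signature
#'
#' Per gene, the paired t-statistic of the tumor minus NAT differences
#' across patients, mapped to a standard-normal z-score through the t CDF
#' with `n - 1` degrees of freedom. Genes whose differences have zero
#' variance but nonzero mean get `z = +/- z_cap`; genes with all-zero
#' differences get `z = 0`.
#'
#' @param bundle_vst list with matrices `tumor` and `nat` (genes x patients,
#'   same dimnames), e.g. variance-stabilized counts from [vst()] applied to
#'   both conditions, or a [expression_bundle()] whose counts are passed
#'   through [vst()] first by the caller.
#' @param z_cap cap for degenerate zero-variance genes (default 8).
#' @return named numeric vector gene -> z.
#' @export
paired_signature <- function(bundle_vst, z_cap = 8) {
  tum <- bundle_vst$tumor
  nat <- bundle_vst$nat
  stopifnot(is.matrix(tum), is.matrix(nat), identical(dimnames(tum), dimnames(nat)))
  n <- ncol(tum)
  if (n < 3) abort("paired_signature: need at least 3 patients")
  d <- tum - nat
  mu <- rowMeans(d)
  s <- apply(d, 1, sd)
  z <- numeric(nrow(d))
  # zero-variance up to floating-point jitter relative to the mean shift
  deg <- s <= 1e-10 * pmax(abs(mu), .Machine$double.xmin)
  z[deg & mu != 0] <- sign(mu[deg & mu != 0]) * z_cap
  z[deg & mu == 0] <- 0
  if (any(!deg)) {
    tt <- mu[!deg] / (s[!deg] / sqrt(n))
    # quantile-quantile map t -> z in log space to keep extreme tails exact
    lp <- pt(-abs(tt), df = n - 1, log.p = TRUE)
    z[!deg] <- sign(tt) * -qnorm(lp, log.p = TRUE)
  }
  setNames(z, rownames(d))
}

#' Normalized enrichment score of a regulon against a signature
#'
#' `NES = sum(mode_t * z_t) / sqrt(m)` over the `m` regulon targets present
#' in the signature; positive when positive-mode targets are up and
#' negative-mode targets are down. The p-value is the two-sided standard
#' normal tail of the NES.
#'
#' @param regulon tibble of one TF's edges (`target`, `mode`).
#' @param signature named numeric vector gene -> z from [paired_signature()].
#' @return list `nes`, `p`, `n_targets_used`, `n_dropped`; `NULL` fields
#'   (a no-score outcome) if no target is present in the signature.
#' @export
nes <- function(regulon, signature) {
  present <- regulon$target %in% names(signature)
  m <- sum(present)
  if (m == 0) {
    return(list(nes = NA_real_, p = NA_real_, n_targets_used = 0L,
                n_dropped = nrow(regulon)))
  }
  z <- signature[regulon$target[present]]
  score <- sum(regulon$mode[present] * z) / sqrt(m)
  list(nes = score, p = 2 * pnorm(-abs(score)), n_targets_used = m,
       n_dropped = as.integer(nrow(regulon) - m))
}

#' Master regulator analysis over all regulons
#'
#' @param regulons regulon tibble (all TFs).
#' @param signature named z vector from [paired_signature()].
#' @param alpha significance level for the NES screen (default 0.05,
#'   two-sided, uncorrected).
#' @return An object of class `tfa_mra`: tibble `tf`, `nes`, `p`,
#'   `n_targets_used`, `significant`. TFs with no usable target carry `NA`
#'   scores and are never significant.
#' @export
mra_all <- function(regulons, signature, alpha = 0.05) {
  tfs <- unique(regulons$tf)
  if (length(tfs) == 0) abort("mra_all: no regulons supplied")
  out <- map_dfr(tfs, function(tf) {
    res <- nes(regulons[regulons$tf == tf, , drop = FALSE], signature)
    tibble(tf = tf, nes = res$nes, p = res$p,
           n_targets_used = res$n_targets_used)
  })
  out$significant <- !is.na(out$p) & out$p <= alpha
  class(out) <- c("tfa_mra", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' @export
#' @rdname mra_all
#' @param x a `tfa_mra` result.
#' @param ... unused.
glance.tfa_mra <- function(x, ...) {
  tibble(n_tfs = nrow(x), n_significant = sum(x$significant),
         alpha = attr(x, "alpha"))
}
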