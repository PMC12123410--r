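#' Substrate-level kinase activity z-score for one patient
#'
#' The "ksea-z" statistic: for a kinase with `m` observed substrate sites,
#' `z = (mean(substrates) - mean(all sites)) * sqrt(m) / sd(all sites)`,
#' comparing the kinase's substrate fold changes against the global site
#' background of that patient.
#'
#' @param phospho_fc named numeric vector site -> log2 fold change for one
#'   patient (NA = not observed); needs >= 10 observed sites for a stable
#'   background.
#' @param ksmap named list kinase -> substrate site ids.
#' @return named numeric vector kinase -> z (NA where a kinase has no
#'   observed substrate), with attribute `n_substrates`.
#' @export
kinase_z <- function(phospho_fc, ksmap) {
  obs <- phospho_fc[is.finite(phospho_fc)]
  if (length(obs) < 10) abort("kinase_z: need >= 10 observed sites for the background")
  bg_mean <- mean(obs)
  bg_sd <- sd(obs)
  if (bg_sd == 0) abort("kinase_z: zero background standard deviation")
  z <- vapply(ksmap, function(sites) {
    sub <- obs[intersect(sites, names(obs))]
    if (length(sub) == 0) return(NA_real_)
    (mean(sub) - bg_mean) * sqrt(length(sub)) / bg_sd
  }, numeric(1))
  m <- vapply(ksmap, function(sites) length(intersect(sites, names(obs))),
              integer(1))
  attr(z, "n_substrates") <- m
  z
}

#' Patient-wise kinase activity matrix
#'
#' @param phospho a [phospho_table()].
#' @param ksmap named list kinase -> substrate site ids.
#' @return An object of class `tfa_kinase`: `z` (kinase x patient matrix),
#'   `n_substrates` (kinase x patient matrix of observed substrate counts).
#' @export
kinase_activity_matrix <- function(phospho, ksmap) {
  stopifnot(inherits(phospho, "tfa_phospho"))
  patients <- colnames(phospho$log2fc)
  cols <- lapply(patients, function(p) kinase_z(phospho$log2fc[, p], ksmap))
  z <- do.call(cbind, cols)
  m <- do.call(cbind, lapply(cols, attr, "n_substrates"))
  dimnames(z) <- dimnames(m) <- list(names(ksmap), patients)
  structure(list(z = z, n_substrates = m), class = "tfa_kinase")
}

#' @export
print.tfa_kinase <- function(x, ...) {
  cat(sprintf("<tfa_kinase> %d kinases x %d patients\n", nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' @export
#' @rdname kinase_activity_matrix
#' @param x a `tfa_kinase`.
#' @param ... unused.
tidy.tfa_kinase <- function(x, ...) {
  as_tibble(x$z, rownames = "kinase") %>%
    tidyr::pivot_longer(-"kinase", names_to = "patient", values_to = "z")
}

#' FDR control of kinase activity z-scores
#'
#' Two-sided normal p-values per entry with Benjamini-Hochberg adjustment
#' across kinases within each patient (`scope = "patient"`) or across the
#' whole matrix (`scope = "global"`). Entries with `q <= alpha` are kept.
#'
#' @param kinase a `tfa_kinase` from [kinase_activity_matrix()].
#' @param alpha FDR level (default 0.05).
#' @param scope BH scope, `"patient"` (default) or `"global"`.
#' @return list `p`, `q` (matrices), `kept` (logical matrix), `alpha`.
#' @export
kinase_significance <- function(kinase, alpha = 0.05, scope = c("patient", "global")) {
  scope <- match.arg(scope)
  z <- kinase$z
  p <- 2 * pnorm(-abs(z))
  q <- p
  if (scope == "patient") {
    for (j in seq_len(ncol(p))) q[, j] <- p.adjust(p[, j], method = "BH")
  } else {
    q[] <- p.adjust(p, method = "BH")
  }
  kept <- !is.na(q) & q <= alpha
  list(p = p, q = q, kept = kept, alpha = alpha, scope = scope)
}

#' Kinase-substrate concordance across patients
#'
#' Pearson correlation, across patients, between each kinase's activity
#' z-score and the fold change of each of its mapped substrate sites.
#'
#' @param kinase a `tfa_kinase`.
#' @param phospho a [phospho_table()].
#' @param ksmap named list kinase -> substrate site ids.
#' @return tibble `kinase`, `site`, `n`, `r`, `p` (NA with a warning when a
#'   vector is constant; pairs with < 4 complete patients are skipped).
#' @export
kinase_substrate_concordance <- function(kinase, phospho, ksmap) {
  patients <- intersect(colnames(kinase$z), colnames(phospho$log2fc))
  map_dfr(names(ksmap), function(k) {
    if (!k %in% rownames(kinase$z)) return(NULL)
    zk <- kinase$z[k, patients]
    map_dfr(intersect(ksmap[[k]], phospho$site_ids), function(s) {
      fc <- phospho$log2fc[s, patients]
      ok <- is.finite(zk) & is.finite(fc)
      if (sum(ok) < 4) return(NULL)
      if (sd(zk[ok]) == 0 || sd(fc[ok]) == 0) {
        warn(sprintf("constant vector for pair (%s, %s)", k, s))
        return(tibble(kinase = k, site = s, n = sum(ok),
                      r = NA_real_, p = NA_real_))
      }
      ct <- stats::cor.test(zk[ok], fc[ok])
      tibble(kinase = k, site = s, n = sum(ok),
             r = unname(ct$estimate), p = ct$p.value)
    })
  })
}

#' Group-wise kinase activity profile
#'
#' Mean kinase activity (with a t-based 95% confidence interval) per patient
#' group, e.g. the quadrant groups from [quadrant_groups()].
#'
#' @param kinase a `tfa_kinase`.
#' @param patient_groups named factor patient -> group label.
#' @return tibble `kinase`, `group`, `n`, `mean`, `ci_lo`, `ci_hi` (NA
#'   entries for empty groups or single observations).
#' @export
group_kinase_profile <- function(kinase, patient_groups) {
  patients <- intersect(colnames(kinase$z), names(patient_groups))
  groups <- levels(factor(patient_groups[patients]))
  map_dfr(rownames(kinase$z), function(k) {
    map_dfr(groups, function(g) {
      v <- kinase$z[k, patients[patient_groups[patients] == g]]
      v <- v[is.finite(v)]
      if (length(v) == 0) {
        return(tibble(kinase = k, group = g, n = 0L, mean = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_))
      }
      m <- mean(v)
      half <- if (length(v) > 1) qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v)) else NA_real_
      tibble(kinase = k, group = g, n = length(v), mean = m,
             ci_lo = m - half, ci_hi = m + half)
    })
  })
}
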