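#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the scale of a paired tumor/NAT lung-adenocarcinoma
#' cohort: 100 patients sampled in both conditions, 20 TFs with 50 signed
#' targets each, a super-enhancer-supported direct subset, phosphosite fold
#' changes linear in latent TF activity plus decoys, and exponential
#' survival with hazard tied to TF activity.
#'
#' @param n_patients number of patients (each with one tumor and one NAT
#'   sample).
#' @param n_genes total genes in the expression matrices.
#' @param n_tfs number of TFs with planted regulons.
#' @param targets_per_tf planted targets per TF.
#' @param frac_negative_targets fraction of targets with repressive mode (-1).
#' @param frac_direct fraction of each TF's targets given super-enhancer
#'   support (the planted direct subset).
#' @param effect_beta expression-scale effect (natural-log units per activity
#'   unit) of latent TF activity on its targets.
#' @param tumor_activity_shift mean shift of latent activity in tumor
#'   samples for perturbed TFs.
#' @param nb_dispersion negative-binomial dispersion of counts
#'   (`size = 1/nb_dispersion`).
#' @param n_true_sites_per_tf phosphosites truly linear in each TF's
#'   activity change.
#' @param n_decoy_sites phosphosites of pure noise.
#' @param phospho_noise_sd noise standard deviation of phosphosite log2 fold
#'   changes.
#' @param hazard_log_hr_per_activity log hazard ratio per unit of the
#'   survival-driving TF's tumor activity.
#' @param censor_rate fraction of patients censored.
#' @param phospho_abundance_mode also emit tumor/NAT phospho abundance
#'   matrices whose difference reproduces the fold changes.
#' @param seed mandatory integer seed.
#' @return a `tfa_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 100, n_genes = 2000, n_tfs = 20,
                          targets_per_tf = 50, frac_negative_targets = 0.3,
                          frac_direct = 0.4, effect_beta = 1.0,
                          tumor_activity_shift = 1.5, nb_dispersion = 0.1,
                          n_true_sites_per_tf = 5, n_decoy_sites = 200,
                          phospho_noise_sd = 0.5,
                          hazard_log_hr_per_activity = 0.7,
                          censor_rate = 0.4,
                          phospho_abundance_mode = FALSE,
                          seed) {
  if (missing(seed) || is.null(seed)) abort("cohort_config: seed is mandatory")
  cfg <- list(
    n_patients = n_patients, n_genes = n_genes, n_tfs = n_tfs,
    targets_per_tf = targets_per_tf,
    frac_negative_targets = frac_negative_targets, frac_direct = frac_direct,
    effect_beta = effect_beta, tumor_activity_shift = tumor_activity_shift,
    nb_dispersion = nb_dispersion,
    n_true_sites_per_tf = n_true_sites_per_tf, n_decoy_sites = n_decoy_sites,
    phospho_noise_sd = phospho_noise_sd,
    hazard_log_hr_per_activity = hazard_log_hr_per_activity,
    censor_rate = censor_rate,
    phospho_abundance_mode = isTRUE(phospho_abundance_mode),
    seed = as.integer(seed)
  )
  counts <- c("n_patients", "n_genes", "n_tfs", "targets_per_tf",
              "n_true_sites_per_tf")
  for (nm in counts) {
    if (cfg[[nm]] < 1) abort(sprintf("cohort_config: %s must be positive", nm))
  }
  for (nm in c("frac_negative_targets", "frac_direct", "censor_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(sprintf("cohort_config: %s must be in [0,1]", nm))
    }
  }
  if (cfg$n_tfs * cfg$targets_per_tf > cfg$n_genes) {
    abort("cohort_config: targets_per_tf * n_tfs exceeds n_genes")
  }
  structure(cfg, class = "tfa_cohort_config")
}

#' Generate a synthetic paired tumor/NAT cohort with planted ground truth
#'
#' Latent per-TF activity is drawn `N(0,1)` in NAT and
#' `N(tumor_activity_shift, 1)` in tumor samples. Each target gene's
#' log-mean expression is `baseline + mode * effect_beta * activity` of its
#' TF, with negative-binomial counts around the exponentiated mean; a TF's
#' own gene tracks its activity with the same effect. True phosphosite fold
#' changes are `w * (a_tumor - a_nat) + noise` with the signed weight `w`
#' recorded; decoy sites are pure noise. The SE table marks the planted
#' direct subset in tissue `"lung"`; the pathway collection places each TF
#' with its true-site proteins (decoy proteins are spread over the same
#' pathways so they are eligible — but uninformative — LASSO predictors).
#' Survival time is exponential with log hazard proportional to the first
#' TF's tumor activity.
#'
#' @param config a [cohort_config()].
#' @return A `tfa_cohort` list with elements `bundle`
#'   ([expression_bundle()]), `phospho` ([phospho_table()]), `se_table`,
#'   `pathways`, `ksmap`, `survival`, `truth` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "tfa_cohort_config"))
  cfg <- config
  set.seed(cfg$seed)

  patients <- sprintf("PT%03d", seq_len(cfg$n_patients))
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  # TF genes live alongside the target/background genes
  gene_ids <- c(tfs, genes)

  # planted regulons: disjoint target blocks, signed modes, direct subsets
  target_pool <- matrix(genes[seq_len(cfg$n_tfs * cfg$targets_per_tf)],
                        nrow = cfg$targets_per_tf)
  truth_targets <- list()
  truth_direct <- list()
  for (k in seq_len(cfg$n_tfs)) {
    tg <- target_pool[, k]
    n_neg <- round(cfg$frac_negative_targets * length(tg))
    mode <- rep(1L, length(tg))
    if (n_neg > 0) mode[sample(length(tg), n_neg)] <- -1L
    truth_targets[[tfs[k]]] <- tibble(gene = tg, mode = mode)
    n_dir <- max(1L, round(cfg$frac_direct * length(tg)))
    truth_direct[[tfs[k]]] <- sort(sample(tg, n_dir))
  }

  # latent activity, NAT ~ N(0,1), tumor ~ N(shift,1)
  a_nat <- matrix(rnorm(cfg$n_tfs * cfg$n_patients), nrow = cfg$n_tfs,
                  dimnames = list(tfs, patients))
  a_tum <- matrix(rnorm(cfg$n_tfs * cfg$n_patients, mean = cfg$tumor_activity_shift),
                  nrow = cfg$n_tfs, dimnames = list(tfs, patients))

  baseline <- setNames(runif(length(gene_ids), log(50), log(500)), gene_ids)

  draw_counts <- function(a) {
    logmu <- matrix(baseline, nrow = length(gene_ids), ncol = cfg$n_patients,
                    dimnames = list(gene_ids, patients))
    for (k in seq_len(cfg$n_tfs)) {
      tt <- truth_targets[[tfs[k]]]
      logmu[tt$gene, ] <- logmu[tt$gene, ] +
        tt$mode %o% (cfg$effect_beta * a[k, ])
      logmu[tfs[k], ] <- logmu[tfs[k], ] + cfg$effect_beta * a[k, ]
    }
    cnt <- matrix(rnbinom(length(logmu), mu = exp(logmu),
                          size = 1 / cfg$nb_dispersion),
                  nrow = nrow(logmu), dimnames = dimnames(logmu))
    cnt
  }
  counts_nat <- draw_counts(a_nat)
  counts_tum <- draw_counts(a_tum)
  bundle <- expression_bundle(counts_tum, counts_nat)

  # phospho: true sites linear in activity change, decoys pure noise
  delta <- a_tum - a_nat
  site_rows <- list()
  truth_sites <- list()
  for (k in seq_len(cfg$n_tfs)) {
    prot <- sprintf("PP%02d_%d", k, seq_len(cfg$n_true_sites_per_tf))
    site <- sprintf("%s_S%d", prot, 100 + seq_len(cfg$n_true_sites_per_tf))
    sgn <- sample(c(-1, 1), cfg$n_true_sites_per_tf, replace = TRUE,
                  prob = c(0.4, 0.6))
    sgn[sample.int(cfg$n_true_sites_per_tf, min(2L, cfg$n_true_sites_per_tf))] <- 1
    w <- sgn * runif(cfg$n_true_sites_per_tf, 0.8, 1.5)
    fc <- w %o% delta[k, ] +
      matrix(rnorm(cfg$n_true_sites_per_tf * cfg$n_patients,
                   sd = cfg$phospho_noise_sd),
             nrow = cfg$n_true_sites_per_tf)
    rownames(fc) <- site
    site_rows[[length(site_rows) + 1]] <- fc
    truth_sites[[tfs[k]]] <- tibble(site = site, protein = prot, w = w)
  }
  decoy_prot <- sprintf("DP%03d", seq_len(cfg$n_decoy_sites))
  decoy_site <- sprintf("%s_S%d", decoy_prot,
                        200 + seq_len(cfg$n_decoy_sites))
  decoy_fc <- matrix(rnorm(cfg$n_decoy_sites * cfg$n_patients,
                           sd = cfg$phospho_noise_sd),
                     nrow = cfg$n_decoy_sites,
                     dimnames = list(decoy_site, patients))
  log2fc <- rbind(do.call(rbind, site_rows), decoy_fc)
  colnames(log2fc) <- patients
  phospho <- phospho_table(log2fc)

  # SE table: one lung SE per TF marking its planted direct subset
  se_table <- tibble(
    se_id = sprintf("SE_%s", tfs), tissue = rep("lung", cfg$n_tfs),
    tf_ids = lapply(tfs, identity),
    gene_ids = unname(truth_direct)
  )
  class(se_table) <- c("tfa_se_table", class(se_table))

  # pathways: TF + its true-site proteins share one pathway; decoy proteins
  # are spread round-robin over the TF pathways (eligible, uninformative)
  decoy_assign <- split(decoy_prot,
                        rep_len(seq_len(cfg$n_tfs), cfg$n_decoy_sites))
  pathways <- lapply(seq_len(cfg$n_tfs), function(k) {
    unique(c(tfs[k], truth_sites[[tfs[k]]]$protein,
             decoy_assign[[as.character(k)]] %||% character(0)))
  })
  names(pathways) <- sprintf("PW_%s", tfs)

  # kinase map: one planted kinase per TF phosphorylating the true sites
  # that track activity positively (a kinase's own substrates move with its
  # activity), plus noise kinases over decoy sites
  ksmap <- lapply(truth_sites, function(ts) ts$site[ts$w > 0])
  names(ksmap) <- sprintf("KIN_%s", tfs)
  n_decoy_kin <- 2L
  if (cfg$n_decoy_sites >= 4) {
    for (j in seq_len(n_decoy_kin)) {
      ksmap[[sprintf("KIN_DECOY%d", j)]] <-
        sort(sample(decoy_site, min(5L, cfg$n_decoy_sites)))
    }
  }

  # survival: exponential, hazard tied to the first TF's tumor activity
  survival_tf <- tfs[1]
  log_hazard <- cfg$hazard_log_hr_per_activity * a_tum[survival_tf, ]
  rate <- 0.1 * exp(log_hazard)
  t_event <- rexp(cfg$n_patients, rate = rate)
  event <- rbinom(cfg$n_patients, 1, 1 - cfg$censor_rate)
  time <- ifelse(event == 1, t_event, runif(cfg$n_patients, 0, 1) * t_event)
  survival <- tibble(patient_id = patients, time = time, event = event)

  truth <- list(
    targets = truth_targets, direct = truth_direct, sites = truth_sites,
    activity_tumor = a_tum, activity_nat = a_nat,
    hazard = setNames(rate, patients), survival_tf = survival_tf,
    perturbed = if (cfg$tumor_activity_shift != 0) tfs else character(0)
  )

  out <- list(bundle = bundle, phospho = phospho, se_table = se_table,
              pathways = pathways, ksmap = ksmap, survival = survival,
              truth = truth, config = cfg)
  if (cfg$phospho_abundance_mode) {
    ab_nat <- matrix(rnorm(length(log2fc), sd = 1), nrow = nrow(log2fc),
                     dimnames = dimnames(log2fc))
    out$phospho_abundance <- list(tumor = ab_nat + log2fc, nat = ab_nat)
  }
  class(out) <- "tfa_cohort"
  out
}

#' @export
print.tfa_cohort <- function(x, ...) {
  cat(sprintf(
    "<tfa_cohort> %d patients, %d genes, %d TFs, %d phosphosites (seed %d)\n",
    x$config$n_patients, length(x$bundle$gene_ids), x$config$n_tfs,
    nrow(x$phospho$log2fc), x$config$seed))
  invisible(x)
}

#' Compute log2 fold changes from paired phospho abundance matrices
#'
#' @param tumor,nat abundance matrices (sites x patients) with identical
#'   dimnames.
#' @return a [phospho_table()] of `tumor - nat` values.
#' @export
phospho_log2fc <- function(tumor, nat) {
  stopifnot(identical(dimnames(tumor), dimnames(nat)))
  phospho_table(tumor - nat)
}

#' Score predicted sets against the planted ground truth
#'
#' @param predicted named list TF -> character vector of predicted ids.
#' @param truth_sets named list TF -> character vector of true ids (e.g.
#'   `truth$direct`, or target/site ids pulled from the truth tibbles).
#' @return tibble with per-TF `precision` (NA for an empty prediction) and
#'   `recall`.
#' @export
truth_eval <- function(predicted, truth_sets) {
  unknown <- setdiff(names(predicted), names(truth_sets))
  if (length(unknown) > 0) {
    abort(sprintf("unknown TF id(s) in prediction: %s",
                  paste(unknown, collapse = ", ")))
  }
  map_dfr(names(predicted), function(tf) {
    pred <- unique(predicted[[tf]])
    tru <- unique(truth_sets[[tf]])
    hits <- length(intersect(pred, tru))
    tibble(
      tf = tf, n_pred = length(pred), n_true = length(tru),
      precision = if (length(pred) == 0) NA_real_ else hits / length(pred),
      recall = if (length(tru) == 0) NA_real_ else hits / length(tru)
    )
  })
}

#' Write every cohort artifact to a directory
#'
#' Emits the seven pipeline inputs in the package's file dialects plus a
#' `truth.json` with the planted ground truth.
#'
#' @param cohort a `tfa_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tfa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tumor = file.path(dir, "counts_tumor.tsv"),
    nat = file.path(dir, "counts_nat.tsv"),
    pairing = file.path(dir, "pairing.tsv"),
    phospho = file.path(dir, "phospho_log2fc.tsv"),
    se = file.path(dir, "se_table.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    ksmap = file.path(dir, "kinase_substrates.tsv"),
    survival = file.path(dir, "survival.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(cohort$bundle, paths["tumor"], paths["nat"], paths["pairing"])
  write_phospho(cohort$phospho, paths["phospho"])
  write_se_table(cohort$se_table, paths["se"])
  write_gmt(cohort$pathways, paths["gmt"])
  write_ksmap(cohort$ksmap, paths["ksmap"])
  write_survival(cohort$survival, paths["survival"])
  truth_json <- list(
    targets = lapply(cohort$truth$targets, function(t)
      list(gene = t$gene, mode = t$mode)),
    direct = cohort$truth$direct,
    sites = lapply(cohort$truth$sites, function(s)
      list(site = s$site, w = s$w)),
    survival_tf = cohort$truth$survival_tf,
    perturbed = cohort$truth$perturbed,
    seed = cohort$config$seed
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
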