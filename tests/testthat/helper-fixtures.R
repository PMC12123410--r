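# Shared fixtures, all generated in code. Heavier objects are cached per
# test run so several files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

# reduced cohort for cross-module tests (fast, still structured)
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_cohort(cohort_config(
      n_patients = 60, n_genes = 300, n_tfs = 4, targets_per_tf = 25,
      n_true_sites_per_tf = 5, n_decoy_sites = 40, seed = 42))
  }
  .fixture_env$small
}

# the standard synthetic study cohort (defaults, seed 7)
study_cohort <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- generate_cohort(cohort_config(seed = 7))
  }
  .fixture_env$study
}

study_vst <- function() {
  if (is.null(.fixture_env$study_vst)) {
    .fixture_env$study_vst <- vst_bundle(study_cohort()$bundle)
  }
  .fixture_env$study_vst
}

# regulon inference on the study cohort at the default (full) parameters
study_regulons <- function() {
  if (is.null(.fixture_env$study_reg)) {
    ch <- study_cohort()
    .fixture_env$study_reg <- infer_regulons(
      study_vst()$nat, names(ch$truth$targets), inference_params(), seed = 7)
  }
  .fixture_env$study_reg
}

# truth regulons in the package's edge-table shape
truth_edges <- function(cohort) {
  dplyr::bind_rows(lapply(names(cohort$truth$targets), function(tf) {
    tt <- cohort$truth$targets[[tf]]
    tibble::tibble(tf = tf, target = tt$gene, mode = tt$mode,
                   r = NA_real_, p = NA_real_, support = 1)
  }))
}

# phospho table from a patients-in-columns matrix
make_phospho <- function(mat_sites_by_patients) {
  if (is.null(colnames(mat_sites_by_patients))) {
    colnames(mat_sites_by_patients) <-
      sprintf("PT%03d", seq_len(ncol(mat_sites_by_patients)))
  }
  phospho_table(mat_sites_by_patients)
}

# planted single-TF phospho regression problem: n_true informative sites
# among n_decoy noise sites, response linear in the shared latent factor
planted_lasso_problem <- function(n = 100, n_true = 5, n_decoy = 200,
                                  noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  w <- sample(c(-1, 1), n_true, replace = TRUE) * runif(n_true, 0.8, 1.5)
  a <- rnorm(n)
  x_true <- sapply(w, function(wi) wi * a + rnorm(n, sd = noise_sd))
  x_decoy <- matrix(rnorm(n * n_decoy, sd = noise_sd), n)
  true_sites <- sprintf("TP%d_S%d", seq_len(n_true), 100 + seq_len(n_true))
  decoy_sites <- sprintf("DX%03d_S%d", seq_len(n_decoy), 200 + seq_len(n_decoy))
  x <- cbind(x_true, x_decoy)
  colnames(x) <- c(true_sites, decoy_sites)
  phospho <- make_phospho(t(x))
  y <- setNames(2 * a + rnorm(n, sd = noise_sd), colnames(phospho$log2fc))
  pathways <- list(PW1 = c("TFX", unique(site_proteins(colnames(x)))))
  list(phospho = phospho, y = y, pathways = pathways,
       true_sites = true_sites, decoy_sites = decoy_sites, w = w)
}

site_proteins <- function(sites) sub("_[STY][0-9]+$", "", sites)

# pure-noise phospho regression problem (no signal anywhere)
noise_lasso_problem <- function(n = 100, p = 30, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n)
  colnames(x) <- sprintf("NP%03d_S%d", seq_len(p), 100 + seq_len(p))
  phospho <- make_phospho(t(x))
  y <- setNames(rnorm(n), colnames(phospho$log2fc))
  pathways <- list(PW1 = c("TFX", site_proteins(colnames(x))))
  list(phospho = phospho, y = y, pathways = pathways)
}

# survival data with hazard tied to a score, mirroring the generator's model
simulate_survival <- function(score, log_hr, censor_rate, base_rate = 0.1) {
  n <- length(score)
  rate <- base_rate * exp(log_hr * score)
  t_event <- rexp(n, rate = rate)
  event <- rbinom(n, 1, 1 - censor_rate)
  time <- ifelse(event == 1, t_event, runif(n) * t_event)
  tibble::tibble(patient_id = names(score), time = time, event = event)
}

rank_auroc <- function(score, is_pos) {
  r <- rank(score)
  (sum(r[is_pos]) - sum(is_pos) * (sum(is_pos) + 1) / 2) /
    (sum(is_pos) * sum(!is_pos))
}
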