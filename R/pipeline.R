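#' Run the full TF-activity pipeline on in-memory inputs
#'
#' Stage order: VST normalization, regulon inference on NAT expression,
#' super-enhancer direct-target filtering, master regulator analysis
#' (NES screen), sample-specific activity scores, per-TF LASSO phospho
#' models with sign-partitioned scores, survival stratification (median
#' splits, combined strata, quadrants) and substrate-level kinase activity.
#' Any stage failure aborts with the stage name.
#'
#' @param bundle a [expression_bundle()].
#' @param phospho a [phospho_table()].
#' @param se_table a tissue-filtered SE table.
#' @param pathways named list pathway -> member ids.
#' @param ksmap named list kinase -> substrate sites.
#' @param survival_df survival tibble (`patient_id`, `time`, `event`).
#' @param tf_ids character vector of candidate TF gene ids.
#' @param params an [inference_params()].
#' @param alpha_nes,alpha_km,alpha_fdr significance levels for the NES
#'   screen, the Kaplan-Meier log-rank tests, and the kinase FDR.
#' @param seed_regulon,seed_lasso seeds for the two stochastic stages.
#' @param out_dir optional directory; when given, every stage artifact plus
#'   a `manifest.json` is written there.
#' @return An object of class `tfa_pipeline`: stage outputs plus a
#'   `manifest` list (per-stage entity counts, drops, seeds, version).
#' @export
run_pipeline <- function(bundle, phospho, se_table, pathways, ksmap,
                         survival_df, tf_ids, params = inference_params(),
                         alpha_nes = 0.05, alpha_km = 0.05, alpha_fdr = 0.05,
                         seed_regulon = 1L, seed_lasso = 2L, out_dir = NULL) {
  for (a in c(alpha_nes, alpha_km, alpha_fdr)) {
    if (a <= 0 || a >= 1) abort("alpha levels must be in (0,1)")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  norm <- stage("vst", vst_bundle(bundle))

  regulons <- stage("regulon_inference",
                    infer_regulons(norm$nat, tf_ids, params, seed = seed_regulon))
  if (nrow(regulons) == 0) abort("pipeline stage 'regulon_inference' failed: no regulon survived")

  direct <- stage("direct_targets", filter_regulon(regulons, se_table))
  direct_summary <- attr(direct, "summary")
  if (nrow(direct) == 0) abort("pipeline stage 'direct_targets' failed: no direct target survived")

  signature <- stage("mra", paired_signature(norm))
  mra <- stage("mra", mra_all(direct, signature, alpha = alpha_nes))
  sig_tfs <- mra$tf[mra$significant]
  if (length(sig_tfs) == 0) abort("pipeline stage 'mra' failed: no significant TF")

  direct_sig <- direct[direct$tf %in% sig_tfs, , drop = FALSE]
  activity <- stage("activity_scores",
                    activity_matrix(norm$tumor, norm$nat, direct_sig))

  models <- stage("phospho_model",
                  fit_all_models(activity, phospho, pathways, seed = seed_lasso))
  fitted_tfs <- names(models)[vapply(models, function(m) m$status == "fitted", logical(1))]
  scores <- lapply(models[fitted_tfs], phospho_scores, phospho = phospho)

  surv <- stage("survival_integration", {
    splits <- list(); kms <- list(); worst <- character(0)
    for (tf in rownames(activity$scores)) {
      act <- tumor_activity(activity, tf)
      act <- act[names(act) %in% survival_df$patient_id]
      sp <- median_split(act)
      splits[[tf]] <- sp
      kms[[tf]] <- km_logrank(sp, survival_df)
      worst[tf] <- worst_direction(sp, survival_df)
    }
    km_p <- vapply(kms, function(k) k$p, numeric(1))
    km_sig <- names(km_p)[km_p <= alpha_km]
    combo_tfs <- if (length(km_sig) >= 2) km_sig else names(sort(km_p))[1:min(2, length(km_p))]
    combined <- combined_strata(splits[combo_tfs], worst[combo_tfs])
    km_combined <- if (length(unique(combined)) >= 2 && all(table(combined) >= 2)) {
      km_logrank(setNames(factor(combined), names(combined)), survival_df)
    } else NULL
    # quadrants: the KM-best TF that also has a fitted phospho model
    quad <- NULL; quad_tf <- NA_character_; km_quad <- NULL
    for (cand in intersect(names(sort(km_p)), fitted_tfs)) {
      p_plus <- deframe(scores[[cand]][, c("patient", "p_plus")])
      act <- tumor_activity(activity, cand)
      common <- intersect(names(act), names(p_plus))
      ok <- tryCatch({
        quad <- quadrant_groups(act[common], p_plus[common])
        TRUE
      }, error = function(e) FALSE)
      if (!ok) next              # degenerate axis (e.g. no positive sites)
      quad_tf <- cand
      if (length(unique(quad)) >= 2 && all(table(droplevels(quad)) >= 2)) {
        km_quad <- km_logrank(droplevels(quad), survival_df)
      }
      break
    }
    if (is.na(quad_tf)) quad <- NULL
    list(splits = splits, km = kms, km_p = km_p, km_significant = km_sig,
         worst = worst, combined_tfs = combo_tfs, combined = combined,
         km_combined = km_combined, quadrant_tf = quad_tf, quadrants = quad,
         km_quadrant = km_quad)
  })

  kin <- stage("kinase_activity", {
    act_mat <- kinase_activity_matrix(phospho, ksmap)
    sig <- kinase_significance(act_mat, alpha = alpha_fdr)
    conc <- kinase_substrate_concordance(act_mat, phospho, ksmap)
    profile <- if (!is.null(surv$quadrants)) {
      group_kinase_profile(act_mat, surv$quadrants)
    } else NULL
    list(activity = act_mat, significance = sig, concordance = conc,
         profile = profile)
  })

  skipped <- attr(regulons, "skipped") %||% tibble(tf = character(0), reason = character(0))
  manifest <- list(
    version = as.character(utils::packageVersion("tfacts")),
    seeds = list(regulon = seed_regulon, lasso = seed_lasso),
    alphas = list(nes = alpha_nes, km = alpha_km, kinase_fdr = alpha_fdr),
    stages = list(
      io = list(n_genes = length(bundle$gene_ids),
                n_patients = length(bundle$patient_ids),
                n_sites = nrow(phospho$log2fc), n_se = nrow(se_table),
                n_pathways = length(pathways), n_kinases = length(ksmap)),
      regulon_inference = list(
        n_tf_input = length(tf_ids),
        n_tf_kept = length(unique(regulons$tf)),
        n_edges = nrow(regulons),
        dropped = as.list(table(skipped$reason))),
      direct_targets = list(
        n_tf_kept = length(unique(direct$tf)),
        n_edges = nrow(direct),
        dropped = sum(direct_summary$status == "filtered_out")),
      mra = list(n_tf_scored = nrow(mra), n_significant = length(sig_tfs)),
      activity_scores = list(n_tf = nrow(activity$scores),
                             dropped = length(activity$dropped)),
      phospho_model = list(
        n_models = length(models), n_fitted = length(fitted_tfs),
        n_no_predictors = sum(vapply(models, function(m) m$status == "no_predictors", logical(1))),
        n_all_zero = sum(vapply(models, function(m) m$status == "all_zero", logical(1)))),
      survival_integration = list(
        n_median_splits = length(surv$splits),
        n_km_significant = length(surv$km_significant),
        combined_tfs = surv$combined_tfs,
        quadrant_tf = surv$quadrant_tf),
      kinase_activity = list(
        n_kinases = nrow(kin$activity$z),
        n_kept = sum(kin$significance$kept),
        n_concordance_pairs = nrow(kin$concordance))
    )
  )

  res <- structure(
    list(norm_size_factors = norm$size_factors, regulons = regulons,
         regulons_skipped = skipped, direct = direct,
         direct_summary = direct_summary, signature = signature, mra = mra,
         activity = activity, models = models, phospho_scores = scores,
         survival = surv, kinase = kin, manifest = manifest),
    class = "tfa_pipeline")

  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.tfa_pipeline <- function(x, ...) {
  cat("<tfa_pipeline>\n")
  print(tf_funnel(x))
  invisible(x)
}

#' Write pipeline artifacts and the manifest to a directory
#'
#' @param result a `tfa_pipeline`.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_regulons(result$regulons, file.path(dir, "regulons.tsv"))
  write_regulons(result$direct, file.path(dir, "direct_regulons.tsv"))
  readr::write_tsv(result$direct_summary, file.path(dir, "direct_summary.tsv"))
  readr::write_tsv(as_tibble(result$mra), file.path(dir, "mra.tsv"))
  readr::write_tsv(tidy(result$activity), file.path(dir, "activity.tsv"))
  jsonlite::write_json(
    lapply(result$models, function(m) list(
      tf = m$tf, status = m$status, lambda = m$lambda_chosen,
      coefficients = as.list(m$selected), r2_test = m$r2_test)),
    file.path(dir, "phospho_models.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  if (length(result$phospho_scores) > 0) {
    readr::write_tsv(
      bind_rows(lapply(names(result$phospho_scores), function(tf)
        mutate(result$phospho_scores[[tf]], tf = tf))),
      file.path(dir, "phospho_scores.tsv"))
  }
  readr::write_tsv(
    tibble(tf = names(result$survival$km_p), p = unname(result$survival$km_p),
           worst = unname(result$survival$worst[names(result$survival$km_p)])),
    file.path(dir, "survival_median_splits.tsv"))
  readr::write_tsv(tidy(result$kinase$activity), file.path(dir, "kinase_z.tsv"))
  readr::write_tsv(result$kinase$concordance, file.path(dir, "kinase_concordance.tsv"))
  readr::write_tsv(tf_funnel(result), file.path(dir, "tf_funnel.tsv"))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(manifest_path)
}

#' Per-stage TF funnel report
#'
#' Counts of TFs entering and surviving each filter of the pipeline, with
#' the number dropped at each step. Counts are monotonically non-increasing
#' and every drop is accounted for.
#'
#' @param result a `tfa_pipeline`.
#' @return tibble `stage`, `n_tfs`, `n_dropped`.
#' @export
tf_funnel <- function(result) {
  st <- result$manifest$stages
  n_input <- st$regulon_inference$n_tf_input
  n_reg <- st$regulon_inference$n_tf_kept
  n_se <- st$direct_targets$n_tf_kept
  n_sig <- st$mra$n_significant
  n_fit <- st$phospho_model$n_fitted
  tibble(
    stage = c("input_tf_list", "regulon_inferred", "se_supported",
              "nes_significant", "phospho_modeled"),
    n_tfs = c(n_input, n_reg, n_se, n_sig, n_fit),
    n_dropped = c(0L, n_input - n_reg, n_reg - n_se, n_se - n_sig,
                  n_sig - n_fit)
  )
}

#' One-command synthetic demo
#'
#' Generates a synthetic cohort and runs the full pipeline on it with seeds
#' derived from `seed`.
#'
#' @param seed integer seed.
#' @param out_dir optional output directory for all artifacts.
#' @param config a [cohort_config()]; defaults to the standard synthetic
#'   cohort built with `seed`.
#' @param params an [inference_params()].
#' @return the `tfa_pipeline` result, with the cohort attached as
#'   `$cohort`.
#' @export
run_demo <- function(seed, out_dir = NULL, config = cohort_config(seed = seed),
                     params = inference_params()) {
  cohort <- generate_cohort(config)
  res <- run_pipeline(
    bundle = cohort$bundle, phospho = cohort$phospho,
    se_table = cohort$se_table, pathways = cohort$pathways,
    ksmap = cohort$ksmap, survival_df = cohort$survival,
    tf_ids = names(cohort$truth$targets), params = params,
    seed_regulon = as.integer(seed) + 100L,
    seed_lasso = as.integer(seed) + 200L,
    out_dir = out_dir)
  res$cohort <- cohort
  res
}
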