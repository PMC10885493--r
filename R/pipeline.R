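# End-to-end orchestration: development (extract -> select -> score -> fit
# -> evaluate) and frozen external validation with zero refitting.

#' Run the full development pipeline on a cohort
#'
#' Extracts features for every subject (reader 1) and for the re-segmented
#' subset (reader 2, perturbed masks), runs the three-stage selection
#' cascade, builds the fitted radiomics score, fits the clinical (C) and
#' clinical-radiomics (CR) Cox models, and evaluates them on the development
#' cohort. All randomness is controlled by the seeds in the configs.
#'
#' @param cohort a cohort as returned by [generate_cohort()] (elements
#'   `subjects`, `clinical`, `survival`).
#' @param registry a [feature_registry()].
#' @param sel_config a [selection_config()].
#' @param ev_config an [eval_config()].
#' @param n_reader2 number of subjects re-segmented by the simulated second
#'   reader (default 30).
#' @param jitter_mm boundary jitter of the second reader's masks (mm).
#' @param target_spacing,n_bins preprocessing parameters.
#' @return A `dev_artifacts` list: `selection` (report etc.),
#'   `rscore_def`, `standardization`, `models`, `evaluation`, `features`,
#'   `rscores`.
#' @export
run_development <- function(cohort, registry = feature_registry(),
                            sel_config = selection_config(),
                            ev_config = eval_config(),
                            n_reader2 = 30L, jitter_mm = 1.0,
                            target_spacing = c(1, 1, 3), n_bins = 32L) {
  ids <- cohort$clinical$subject_id
  feats <- extract_cohort_features(cohort$subjects, ids, registry,
                                   target_spacing, n_bins)
  n2 <- min(n_reader2, length(ids))
  idx2 <- with_seed(sel_config$seed, sample(seq_along(ids), n2))
  subjects2 <- lapply(cohort$subjects[idx2], function(s) {
    list(ap = s$ap, pvp = s$pvp,
         mask = perturb_mask(s$mask, jitter_mm,
                             seed = sel_config$seed + 7L))
  })
  feats2 <- extract_cohort_features(subjects2, ids[idx2], registry,
                                    target_spacing, n_bins)
  sel <- run_selection(feats, feats2, cohort$survival, sel_config)
  cf <- sel$lasso$coefficients
  if (!length(cf))
    stop("LASSO-Cox selected no features; no radiomics score can be built")
  def <- rscore_definition(names(cf), unname(cf), "fitted")
  std_tab <- apply_standardization(feats, sel$standardization$means,
                                   sel$standardization$sds)
  rsc <- compute_rscore(std_tab, def)
  models <- build_models(cohort$clinical, rsc, cohort$survival)
  lps <- list(C = cox_lp(models$c_model, cohort$clinical),
              CR = cox_lp(models$cr_model,
                          transform(cohort$clinical, rscore = rsc)))
  t <- ev_config$horizon_months
  probs <- list(
    C = 1 - cox_survprob(models$c_model, cohort$clinical, t),
    CR = 1 - cox_survprob(models$cr_model,
                          transform(cohort$clinical, rscore = rsc), t))
  ev <- evaluate_models(lps, probs, cohort$survival, ev_config)
  structure(list(selection = sel, rscore_def = def,
                 standardization = sel$standardization, models = models,
                 evaluation = ev, features = feats, rscores = rsc,
                 registry = registry, target_spacing = target_spacing,
                 n_bins = n_bins),
            class = "dev_artifacts")
}

#' Externally validate frozen development artifacts on a test cohort
#'
#' No refitting: test-set features are standardized with the development
#' means/SDs, scored with the frozen radiomics-score definition, and pushed
#' through the frozen C and CR Cox models; performance is evaluated on the
#' test outcomes.
#'
#' @param artifacts a `dev_artifacts` from [run_development()].
#' @param cohort the test cohort (as from [generate_cohort()]).
#' @param ev_config an [eval_config()].
#' @return List with `evaluation` (an `eval_report`), `rscores`, `lps`.
#' @export
run_external_validation <- function(artifacts, cohort,
                                    ev_config = eval_config()) {
  stopifnot(inherits(artifacts, "dev_artifacts"))
  ids <- cohort$clinical$subject_id
  feats <- extract_cohort_features(cohort$subjects, ids,
                                   artifacts$registry,
                                   artifacts$target_spacing,
                                   artifacts$n_bins)
  need <- names(artifacts$standardization$means)
  if (!all(need %in% names(feats)))
    stop("test features lack frozen signature ids: ",
         paste(setdiff(need, names(feats)), collapse = ", "))
  std_tab <- apply_standardization(feats, artifacts$standardization$means,
                                   artifacts$standardization$sds)
  rsc <- compute_rscore(std_tab, artifacts$rscore_def)
  newdat <- transform(cohort$clinical, rscore = rsc)
  lps <- list(C = cox_lp(artifacts$models$c_model, cohort$clinical),
              CR = cox_lp(artifacts$models$cr_model, newdat))
  t <- ev_config$horizon_months
  probs <- list(
    C = 1 - cox_survprob(artifacts$models$c_model, cohort$clinical, t),
    CR = 1 - cox_survprob(artifacts$models$cr_model, newdat, t))
  ev <- evaluate_models(lps, probs, cohort$survival, ev_config)
  list(evaluation = ev, rscores = rsc, lps = lps, features = feats)
}
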