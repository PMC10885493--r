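# Radiomics score construction and the clinical (C) / clinical-radiomics
# (CR) Cox proportional-hazards models.

#' Radiomics score definition
#'
#' An ordered list of (feature id, coefficient) terms defining the linear
#' radiomics risk score: the score of a standardized feature vector is the
#' sum of each feature value multiplied by its coefficient.
#'
#' @param feature_ids character vector of unique canonical feature ids.
#' @param coefficients numeric vector of the same length, finite.
#' @param provenance `"fitted"` (from [fit_lasso_cox()]) or `"published"`.
#' @return An `rscore_definition`.
#' @export
rscore_definition <- function(feature_ids, coefficients,
                              provenance = c("fitted", "published")) {
  provenance <- match.arg(provenance)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (length(feature_ids) != length(coefficients))
    stop("feature_ids and coefficients differ in length")
  if (!all(is.finite(coefficients))) stop("coefficients must be finite")
  structure(list(terms = data.frame(feature_id = as.character(feature_ids),
                                    coefficient = as.numeric(coefficients),
                                    stringsAsFactors = FALSE),
                 provenance = provenance),
            class = "rscore_definition")
}

#' The published 15-term radiomics signature
#'
#' Loads the published radiomics score definition: 15 standardized
#' arterial-phase features (2 morphologic, 4 first-order, 4 texture and 5
#' filtered higher-order features) with their fixed coefficients. The score
#' is the sum of each feature multiplied by its coefficient.
#'
#' @return An `rscore_definition` with provenance `"published"`.
#' @export
published_rscore <- function() {
  path <- system.file("extdata", "rscore_published.csv", package = "radsurv",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  rscore_definition(tab$feature_id, tab$coefficient, "published")
}

#' Compute the radiomics score
#'
#' Linear combination `sum(coefficient * value)` of standardized feature
#' values. Accepts a single named vector or a feature data.frame (one score
#' per row).
#'
#' @param fv named numeric vector, or data.frame with `subject_id` and
#'   feature columns, containing every feature id of the definition.
#' @param def an [rscore_definition()].
#' @return A numeric score, or named vector of scores for a table.
#' @export
compute_rscore <- function(fv, def) {
  stopifnot(inherits(def, "rscore_definition"))
  ids <- def$terms$feature_id
  if (is.data.frame(fv)) {
    m <- feature_matrix(fv)
    missing <- setdiff(ids, colnames(m))
    if (length(missing))
      stop("feature vector lacks signature features: ",
           paste(missing, collapse = ", "))
    return(stats::setNames(as.vector(m[, ids, drop = FALSE] %*%
                                       def$terms$coefficient),
                           fv$subject_id))
  }
  missing <- setdiff(ids, names(fv))
  if (length(missing))
    stop("feature vector lacks signature features: ",
         paste(missing, collapse = ", "))
  sum(fv[ids] * def$terms$coefficient)
}

#' Fit a Cox proportional-hazards model
#'
#' Multivariable Cox regression with Breslow tie handling. AJCC stage (when
#' present as a factor) is encoded as indicator contrasts against stage I.
#' The fit stores the Breslow baseline cumulative hazard so absolute
#' survival probabilities can be predicted for new subjects.
#'
#' @param covariates data.frame with `subject_id` and covariate columns.
#' @param outcomes data.frame with `subject_id`, `time_months`, `event`.
#' @return A `cox_fit`: list with the `survival::coxph` fit, coefficient
#'   table (HRs, CIs, p), baseline cumulative hazard steps, `n`, `n_events`.
#' @export
fit_cox <- function(covariates, outcomes) {
  stopifnot(identical(covariates$subject_id, outcomes$subject_id))
  if (sum(outcomes$event) < 2L) stop("need at least 2 events")
  vars <- setdiff(names(covariates), "subject_id")
  dat <- covariates
  for (v in vars) {
    if (is.factor(dat[[v]])) {
      dat[[v]] <- droplevels(dat[[v]])
      if (nlevels(dat[[v]]) < 2L) {
        warning("dropping single-level covariate: ", v)
        dat[[v]] <- NULL
        vars <- setdiff(vars, v)
      }
    } else if (stats::sd(dat[[v]]) == 0) {
      stop("constant covariate: ", v)
    }
  }
  if (!length(vars)) stop("no usable covariates")
  dat$time_months <- outcomes$time_months
  dat$event <- outcomes$event
  fml <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                                 paste(sprintf("`%s`", vars),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow", x = TRUE)
  if (any(!is.finite(stats::coef(fit))) ||
      any(sqrt(diag(stats::vcov(fit))) > 1e3))
    stop("Cox fit did not converge (possible separation); coefficients: ",
         paste(signif(stats::coef(fit), 3), collapse = ", "))
  s <- summary(fit)
  coef_tab <- data.frame(term = rownames(s$coefficients),
                         coef = s$coefficients[, "coef"],
                         se = s$coefficients[, "se(coef)"],
                         hr = s$conf.int[, "exp(coef)"],
                         hr_lower = s$conf.int[, "lower .95"],
                         hr_upper = s$conf.int[, "upper .95"],
                         p = s$coefficients[, "Pr(>|z|)"],
                         row.names = NULL, stringsAsFactors = FALSE)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(fit = fit, coefficients = coef_tab,
                 baseline = data.frame(time = bh$time, cumhaz = bh$hazard),
                 variables = vars, n = nrow(dat),
                 n_events = sum(outcomes$event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit:", x$n, "subjects,", x$n_events, "events\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Linear predictor and survival probability for new subjects
#'
#' `cox_lp()` evaluates the linear predictor (log relative hazard, centered
#' as in the fit); `cox_survprob()` converts it to an absolute survival
#' probability at a horizon via the Breslow baseline,
#' `S(t | x) = exp(-H0(t) exp(lp))`.
#'
#' @param fit a `cox_fit`.
#' @param newdata data.frame with the model's covariate columns.
#' @param t horizon (months) for `cox_survprob`.
#' @return Numeric vector.
#' @export
cox_lp <- function(fit, newdata) {
  stopifnot(inherits(fit, "cox_fit"))
  as.numeric(stats::predict(fit$fit, newdata = newdata, type = "lp",
                            reference = "zero"))
}

#' @rdname cox_lp
#' @export
cox_survprob <- function(fit, newdata, t) {
  lp <- cox_lp(fit, newdata)
  bh <- fit$baseline
  h0 <- if (t < bh$time[1]) 0 else bh$cumhaz[max(which(bh$time <= t))]
  exp(-h0 * exp(lp))
}

#' Build the clinical (C) and clinical-radiomics (CR) models
#'
#' The C-model regresses outcome on age and AJCC stage (indicators vs stage
#' I); the CR-model adds the radiomics score as one further covariate.
#'
#' @param clinical data.frame with `subject_id`, `age`, `stage` (factor
#'   I-IV).
#' @param rscores named numeric vector of radiomics scores (names =
#'   subject ids) or `NULL` to fit only the C-model.
#' @param outcomes survival data.frame.
#' @return List with `c_model` and (if scores given) `cr_model`.
#' @export
build_models <- function(clinical, rscores, outcomes) {
  stopifnot(all(c("age", "stage") %in% names(clinical)))
  c_model <- fit_cox(clinical[c("subject_id", "age", "stage")], outcomes)
  out <- list(c_model = c_model)
  if (!is.null(rscores)) {
    cr <- clinical[c("subject_id", "age", "stage")]
    cr$rscore <- as.numeric(rscores[match(clinical$subject_id,
                                          names(rscores))])
    if (any(is.na(cr$rscore))) stop("missing R-score for some subjects")
    out$cr_model <- fit_cox(cr, outcomes)
  }
  out
}

#' Optimal risk cutoff at a horizon
#'
#' Scans midpoints of sorted unique scores as candidate cutoffs; event
#' status at the horizon is defined on subjects whose status is known
#' (event before the horizon, or follow-up beyond it) and subjects censored
#' earlier are excluded. Among cutoffs with both sensitivity and specificity
#' strictly above `min_sens_spec`, returns the one maximizing their sum,
#' breaking ties toward the lower cutoff value.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param outcomes survival data.frame.
#' @param horizon months, default 36 (3 years).
#' @param min_sens_spec constraint on both sensitivity and specificity,
#'   default 0.6.
#' @return List with `cutoff`, `sensitivity`, `specificity`.
#' @export
select_cutoff <- function(scores, outcomes, horizon = 36,
                          min_sens_spec = 0.6) {
  known_event <- outcomes$time_months <= horizon & outcomes$event == 1
  known_ctrl <- outcomes$time_months > horizon
  keep <- known_event | known_ctrl
  if (!any(known_event[keep]) || !any(known_ctrl[keep]))
    stop("need both events and non-events observable at the horizon")
  s <- scores[keep]
  y <- known_event[keep]
  u <- sort(unique(s))
  cuts <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  sens <- vapply(cuts, function(cc) mean(s[y] > cc), 0.0)
  spec <- vapply(cuts, function(cc) mean(s[!y] <= cc), 0.0)
  ok <- sens > min_sens_spec & spec > min_sens_spec
  if (!any(ok)) {
    best <- which.max(sens + spec)
    stop(sprintf(paste0("no cutoff reaches sensitivity and specificity > ",
                        "%.0f%%; best unconstrained cutoff %.4g ",
                        "(sens %.3f, spec %.3f)"),
                 100 * min_sens_spec, cuts[best], sens[best], spec[best]))
  }
  tot <- ifelse(ok, sens + spec, -Inf)
  best <- which(tot == max(tot))[1]  # ties -> lower cutoff
  list(cutoff = cuts[best], sensitivity = sens[best],
       specificity = spec[best])
}
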