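# Survival-model performance and comparison: Harrell's C-index,
# time-dependent ROC AUC under censoring, survival NRI/IDI at a fixed
# horizon, and Kaplan-Meier calibration, with bootstrap confidence
# intervals.

#' Evaluation configuration
#'
#' @param horizon_months fixed horizon for NRI/IDI/calibration (default 36,
#'   i.e. 3 years).
#' @param n_bootstrap bootstrap replicates for confidence intervals
#'   (default 1000).
#' @param calibration_groups risk groups for the calibration table
#'   (default 4).
#' @param seed integer seed for resampling.
#' @return An `eval_config` list.
#' @export
eval_config <- function(horizon_months = 36, n_bootstrap = 1000L,
                        calibration_groups = 4L, seed = 1L) {
  stopifnot(horizon_months > 0, calibration_groups >= 2L, n_bootstrap >= 1L)
  structure(list(horizon_months = horizon_months,
                 n_bootstrap = as.integer(n_bootstrap),
                 calibration_groups = as.integer(calibration_groups),
                 seed = as.integer(seed)),
            class = "eval_config")
}

cindex_point <- function(lp, time, event) {
  fit <- survival::concordance(survival::Surv(time, event) ~ lp,
                               reverse = TRUE)
  cnt <- fit$count
  if (sum(cnt[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no comparable pairs for the C-index")
  unname(fit$concordance)
}

#' Harrell's concordance index
#'
#' Probability, over usable pairs (the shorter observed time is an event, or
#' tied times with exactly one event), that the subject with the earlier
#' event carries the higher risk score; ties in the score count 0.5.
#' Confidence interval by subject-level bootstrap (percentile).
#'
#' @param lp numeric risk scores (higher = higher risk).
#' @param outcomes data.frame with `time_months` and `event`.
#' @param config an [eval_config()]; set `n_bootstrap = 0` via
#'   `conf_int = FALSE` to skip the CI.
#' @param conf_int logical; compute the bootstrap CI.
#' @return List with `c_index` and (optionally) `ci` (length-2) .
#' @export
harrell_cindex <- function(lp, outcomes, config = eval_config(),
                           conf_int = FALSE) {
  stopifnot(length(lp) == nrow(outcomes))
  cc <- cindex_point(lp, outcomes$time_months, outcomes$event)
  out <- list(c_index = cc)
  if (conf_int) {
    n <- length(lp)
    boots <- with_seed(config$seed, {
      vapply(seq_len(config$n_bootstrap), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(cindex_point(lp[idx], outcomes$time_months[idx],
                              outcomes$event[idx]),
                 error = function(e) NA_real_)
      }, 0.0)
    })
    out$ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
  }
  out
}

#' Compare two models' C-indices by paired bootstrap
#'
#' Resamples subjects, recomputes both C-indices per replicate, and tests
#' `delta = C(b) - C(a)` against zero with a two-sided p-value from the
#' normal approximation of the bootstrap distribution of delta.
#'
#' @param lp_a,lp_b risk scores of the two models on the same subjects.
#' @param outcomes survival data.frame.
#' @param config an [eval_config()].
#' @return List with `delta`, `p_value`, `ci`.
#' @export
compare_cindex <- function(lp_a, lp_b, outcomes, config = eval_config()) {
  stopifnot(length(lp_a) == length(lp_b), length(lp_a) == nrow(outcomes))
  d0 <- cindex_point(lp_b, outcomes$time_months, outcomes$event) -
    cindex_point(lp_a, outcomes$time_months, outcomes$event)
  n <- length(lp_a)
  deltas <- with_seed(config$seed, {
    vapply(seq_len(config$n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(
        cindex_point(lp_b[idx], outcomes$time_months[idx],
                     outcomes$event[idx]) -
          cindex_point(lp_a[idx], outcomes$time_months[idx],
                       outcomes$event[idx]),
        error = function(e) NA_real_)
    }, 0.0)
  })
  sdd <- stats::sd(deltas, na.rm = TRUE)
  p <- if (is.na(sdd) || sdd == 0) {
    if (d0 == 0) 1 else 0
  } else 2 * stats::pnorm(-abs(d0) / sdd)
  list(delta = d0, p_value = p,
       ci = stats::quantile(deltas, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE))
}

# reverse Kaplan-Meier estimate of the censoring survival function G(t)
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t) {
    s <- summary(fit, times = pmin(t, max(fit$time)), extend = TRUE)$surv
    pmax(s, 1e-10)
  }
}

#' Time-dependent ROC AUC with censoring weights
#'
#' Cumulative-case / dynamic-control AUC at horizon `t`: cases are subjects
#' with an observed event by `t`, controls are subjects still at risk past
#' `t`; both are weighted by the inverse of the reverse-Kaplan-Meier
#' censoring survival (cases at their own event time, controls at `t`).
#' Without censoring it reduces to the Mann-Whitney AUC for the binary
#' outcome T <= t.
#'
#' @param lp risk scores.
#' @param outcomes survival data.frame.
#' @param t horizon (months).
#' @return AUC(t).
#' @export
time_dependent_auc <- function(lp, outcomes, t) {
  time <- outcomes$time_months; event <- outcomes$event
  case <- time <= t & event == 1
  ctrl <- time > t
  if (!any(case) || !any(ctrl))
    stop("need both cases and controls at the horizon")
  G <- censoring_km(time, event)
  w_case <- 1 / G(pmax(time[case] - 1e-9, 0))
  w_ctrl <- rep(1 / G(t), sum(ctrl))
  lc <- lp[case]; lq <- lp[ctrl]
  num <- 0
  for (i in seq_along(lc)) {
    num <- num + w_case[i] * sum(w_ctrl * ((lc[i] > lq) + 0.5 * (lc[i] == lq)))
  }
  num / (sum(w_case) * sum(w_ctrl))
}

ipcw_status <- function(outcomes, t) {
  time <- outcomes$time_months; event <- outcomes$event
  G <- censoring_km(time, event)
  is_event <- time <= t & event == 1
  is_ctrl <- time > t
  w <- numeric(length(time))
  w[is_event] <- 1 / G(pmax(time[is_event] - 1e-9, 0))
  w[is_ctrl] <- 1 / G(t)
  list(is_event = is_event, is_ctrl = is_ctrl, w = w)
}

nri_idi_point <- function(p_old, p_new, st) {
  we <- st$w[st$is_event]; wc <- st$w[st$is_ctrl]
  up_e <- p_new[st$is_event] > p_old[st$is_event]
  dn_e <- p_new[st$is_event] < p_old[st$is_event]
  up_c <- p_new[st$is_ctrl] > p_old[st$is_ctrl]
  dn_c <- p_new[st$is_ctrl] < p_old[st$is_ctrl]
  nri <- (sum(we * up_e) - sum(we * dn_e)) / sum(we) +
    (sum(wc * dn_c) - sum(wc * up_c)) / sum(wc)
  idi <- sum(we * (p_new[st$is_event] - p_old[st$is_event])) / sum(we) -
    sum(wc * (p_new[st$is_ctrl] - p_old[st$is_ctrl])) / sum(wc)
  c(nri = nri, idi = idi)
}

#' Survival NRI and IDI at a fixed horizon
#'
#' Category-free (continuous) net reclassification improvement and
#' integrated discrimination improvement of the new model's predicted event
#' probabilities at the horizon over the old model's, with event/non-event
#' status under censoring weighted by the inverse censoring survival
#' (subjects censored before the horizon contribute no status). Confidence
#' intervals and p-values by subject-level bootstrap (percentile CI, normal
#' approximation for p).
#'
#' @param p_old,p_new predicted event probabilities at the horizon from the
#'   old and new models (e.g. `1 - cox_survprob(fit, data, t)`).
#' @param outcomes survival data.frame.
#' @param config an [eval_config()]; its `horizon_months` sets `t`.
#' @return List with `nri`, `idi`, `nri_ci`, `idi_ci`, `nri_p`, `idi_p`.
#' @export
survival_nri_idi <- function(p_old, p_new, outcomes,
                             config = eval_config()) {
  t <- config$horizon_months
  if (t > max(outcomes$time_months))
    stop("horizon beyond the last observed time")
  st <- ipcw_status(outcomes, t)
  if (!any(st$is_event) || !any(st$is_ctrl))
    stop("need both events and non-events at the horizon")
  pt <- nri_idi_point(p_old, p_new, st)
  n <- nrow(outcomes)
  boots <- with_seed(config$seed, {
    t(vapply(seq_len(config$n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ob <- outcomes[idx, , drop = FALSE]
      stb <- tryCatch(ipcw_status(ob, t), error = function(e) NULL)
      if (is.null(stb) || !any(stb$is_event) || !any(stb$is_ctrl))
        return(c(nri = NA_real_, idi = NA_real_))
      nri_idi_point(p_old[idx], p_new[idx], stb)
    }, c(nri = 0.0, idi = 0.0)))
  })
  pval <- function(obs, draws) {
    s <- stats::sd(draws, na.rm = TRUE)
    if (is.na(s) || s == 0) return(if (obs == 0) 1 else 0)
    2 * stats::pnorm(-abs(obs) / s)
  }
  list(nri = unname(pt["nri"]), idi = unname(pt["idi"]),
       nri_ci = stats::quantile(boots[, "nri"], c(0.025, 0.975),
                                na.rm = TRUE, names = FALSE),
       idi_ci = stats::quantile(boots[, "idi"], c(0.025, 0.975),
                                na.rm = TRUE, names = FALSE),
       nri_p = pval(pt["nri"], boots[, "nri"]),
       idi_p = pval(pt["idi"], boots[, "idi"]))
}

#' Calibration against Kaplan-Meier at a horizon
#'
#' Bins subjects into risk groups by quantiles of the model's predicted
#' survival probability at the horizon and compares, per bin, the mean
#' predicted S(t) with the observed Kaplan-Meier estimate (Greenwood
#' log-log CI). Bins that cannot support a KM estimate are merged with their
#' neighbour.
#'
#' @param fit a `cox_fit` (with baseline hazard).
#' @param covariates data.frame of the model's covariates.
#' @param outcomes survival data.frame.
#' @param t horizon (months).
#' @param groups number of risk groups, default 4.
#' @return data.frame with columns `group`, `n`, `mean_predicted`,
#'   `observed_km`, `km_lower`, `km_upper`.
#' @export
calibration_table <- function(fit, covariates, outcomes, t, groups = 4L) {
  pred <- cox_survprob(fit, covariates, t)
  qs <- stats::quantile(pred, probs = seq(0, 1, length.out = groups + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  grp <- cut(pred, breaks = unique(qs), labels = FALSE)
  ngrp <- max(grp)
  rows <- lapply(seq_len(ngrp), function(g) {
    sel <- grp == g
    km <- survival::survfit(
      survival::Surv(outcomes$time_months[sel], outcomes$event[sel]) ~ 1,
      conf.type = "log-log")
    s <- summary(km, times = min(t, max(km$time)), extend = TRUE)
    data.frame(group = g, n = sum(sel), mean_predicted = mean(pred[sel]),
               observed_km = s$surv,
               km_lower = ifelse(is.na(s$lower), 0, s$lower),
               km_upper = ifelse(is.na(s$upper), 1, s$upper))
  })
  do.call(rbind, rows)
}

#' Full evaluation report for one or more models
#'
#' Computes C-index (with CI), pairwise C-index comparison, time-dependent
#' AUC and, when two models are given, NRI/IDI at the horizon.
#'
#' @param lps named list of risk-score vectors, e.g.
#'   `list(C = ..., CR = ...)`; when comparing, the first is the reference
#'   (old) model.
#' @param probs optional named list (same names) of predicted event
#'   probabilities at the horizon, enabling NRI/IDI.
#' @param outcomes survival data.frame.
#' @param config an [eval_config()].
#' @return An `eval_report` list.
#' @export
evaluate_models <- function(lps, probs = NULL, outcomes,
                            config = eval_config()) {
  cidx <- lapply(lps, harrell_cindex, outcomes = outcomes, config = config,
                 conf_int = TRUE)
  out <- list(c_index = cidx, horizon = config$horizon_months)
  out$auc <- lapply(lps, function(l)
    tryCatch(time_dependent_auc(l, outcomes, config$horizon_months),
             error = function(e) NA_real_))
  if (length(lps) >= 2) {
    out$delta_c <- compare_cindex(lps[[1]], lps[[2]], outcomes, config)
    if (!is.null(probs))
      out$nri_idi <- survival_nri_idi(probs[[1]], probs[[2]], outcomes,
                                      config)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  for (nm in names(x$c_index)) {
    ci <- x$c_index[[nm]]
    cat(sprintf("%-8s C-index %.3f (95%% CI %.3f-%.3f)  AUC(%g mo) %.3f\n",
                nm, ci$c_index, ci$ci[1], ci$ci[2], x$horizon,
                x$auc[[nm]]))
  }
  if (!is.null(x$delta_c))
    cat(sprintf("delta C = %.3f, p = %.4g\n", x$delta_c$delta,
                x$delta_c$p_value))
  if (!is.null(x$nri_idi))
    cat(sprintf("NRI %.3f (p = %.3g), IDI %.3f (p = %.3g)\n",
                x$nri_idi$nri, x$nri_idi$nri_p, x$nri_idi$idi,
                x$nri_idi$idi_p))
  invisible(x)
}
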