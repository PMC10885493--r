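test_that("Harrell's C-index matches exhaustive pair enumeration on censored toys", {
  # perfect anti-monotone ranking, no censoring
  time <- c(1, 3, 5, 8, 13, 21)
  lp <- -time
  out <- toy_surv(time, rep(1, 6))
  expect_equal(harrell_cindex(lp, out)$c_index, 1)
  expect_equal(harrell_cindex(rep(0, 6), out)$c_index, 0.5)

  set.seed(44)
  for (rep_i in 1:5) {
    n <- 12
    t2 <- round(rexp(n, 0.1), 1)
    e2 <- rbinom(n, 1, 0.6)
    if (sum(e2) < 2) e2[1:2] <- 1
    lp2 <- rnorm(n)
    out2 <- toy_surv(t2, e2)
    expect_equal(harrell_cindex(lp2, out2)$c_index,
                 oracle_cindex(lp2, t2, e2), tolerance = 1e-12)
    # complement symmetry on tie-free data
    expect_equal(harrell_cindex(lp2, out2)$c_index +
                   harrell_cindex(-lp2, out2)$c_index, 1, tolerance = 1e-12)
  }
})

test_that("bootstrap CI of the C-index covers the large-sample value at ~95%", {
  truth_data <- generate_cohort(
    cohort_spec(n_subjects = 20000, true_beta = c(amplitude = 0.8),
                baseline = list(shape = 1.2, scale = 300),
                censor_time_months = 120, seed = 123), images = FALSE)
  c_true <- harrell_cindex(truth_data$latents$z_amplitude,
                           truth_data$survival)$c_index
  hits <- 0; runs <- 120
  for (i in seq_len(runs)) {
    d <- generate_cohort(
      cohort_spec(n_subjects = 100, true_beta = c(amplitude = 0.8),
                  baseline = list(shape = 1.2, scale = 300),
                  censor_time_months = 120, seed = 1000 + i),
      images = FALSE)
    ci <- harrell_cindex(d$latents$z_amplitude, d$survival,
                         eval_config(n_bootstrap = 200, seed = i),
                         conf_int = TRUE)$ci
    if (ci[1] <= c_true && c_true <= ci[2]) hits <- hits + 1
  }
  expect_gt(hits / runs, 0.88)
  expect_lte(hits / runs, 1.0)
})

test_that("paired C-index comparison is null for identical models and antisymmetric", {
  set.seed(3)
  n <- 80
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.5)
  if (sum(event) < 2) event[1:2] <- 1
  out <- toy_surv(time, event)
  lp <- rnorm(n)
  same <- compare_cindex(lp, lp, out, eval_config(n_bootstrap = 100, seed = 2))
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)

  lp2 <- rnorm(n)
  ab <- compare_cindex(lp, lp2, out, eval_config(n_bootstrap = 100, seed = 2))
  ba <- compare_cindex(lp2, lp, out, eval_config(n_bootstrap = 100, seed = 2))
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
})

test_that("a strong model beats noise in the paired comparison most of the time", {
  wins <- 0
  for (i in 1:12) {
    d <- generate_cohort(
      cohort_spec(n_subjects = 300, true_beta = c(amplitude = 1),
                  baseline = list(shape = 1.2, scale = 200),
                  censor_time_months = 120, seed = 400 + i), images = FALSE)
    set.seed(5000 + i)
    noise <- rnorm(300)
    cmp <- compare_cindex(noise, d$latents$z_amplitude, d$survival,
                          eval_config(n_bootstrap = 150, seed = i))
    if (cmp$p_value < 0.05 && cmp$delta > 0) wins <- wins + 1
  }
  expect_gte(wins, 10)
})

test_that("time-dependent AUC reduces to the rank-sum AUC without censoring", {
  set.seed(7)
  n <- 40
  time <- rexp(n, 0.04)
  out <- toy_surv(time, rep(1, n))
  lp <- -time + rnorm(n, sd = 5)
  t0 <- median(time)
  y <- time <= t0
  auc_rank <- (mean(rank(lp)[y]) - (sum(y) + 1) / 2) * sum(y) /
    (sum(y) * sum(!y))
  expect_equal(time_dependent_auc(lp, out, t0), auc_rank, tolerance = 1e-12)
})

test_that("IPCW AUC matches a direct weighted-sum evaluation on a censored toy", {
  time <- c(2, 4, 6, 7, 9, 12, 15, 20, 25, 30)
  event <- c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0)
  lp <- c(2.0, 1.5, 1.8, 0.2, 0.0, 0.9, -0.5, -1.0, 0.4, -2.0)
  out <- toy_surv(time, event)
  t0 <- 10
  # direct evaluation of the weighted formula with a hand reverse-KM
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stepfun(cens_fit$time, c(1, cens_fit$surv))
  case <- which(time <= t0 & event == 1)
  ctrl <- which(time > t0)
  wc <- 1 / sapply(time[case], function(u) max(G(u - 1e-9), 1e-10))
  wq <- rep(1 / max(G(t0), 1e-10), length(ctrl))
  num <- 0
  for (a in seq_along(case)) for (b in seq_along(ctrl)) {
    cmp <- (lp[case[a]] > lp[ctrl[b]]) + 0.5 * (lp[case[a]] == lp[ctrl[b]])
    num <- num + wc[a] * wq[b] * cmp
  }
  expected <- num / (sum(wc) * sum(wq))
  expect_equal(time_dependent_auc(lp, out, t0), expected, tolerance = 1e-12)

  expect_error(time_dependent_auc(lp, out, 100), "controls")
})

test_that("random scores give AUC(t) near 0.5", {
  d <- generate_cohort(cohort_spec(n_subjects = 800, seed = 77),
                       images = FALSE)
  set.seed(1)
  auc <- time_dependent_auc(rnorm(800), d$survival, 36)
  expect_lt(abs(auc - 0.5), 0.07)
})

test_that("NRI and IDI vanish for identical models, negate under swap, and match uncensored closed forms", {
  set.seed(10)
  n <- 10
  time <- c(5, 8, 12, 20, 28, 40, 50, 60, 70, 90)
  event <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)  # no censoring before 36 months
  out <- toy_surv(time, event)
  p_old <- runif(n, 0.05, 0.6)
  p_new <- pmin(p_old + rnorm(n, 0, 0.15), 0.95)
  cfg <- eval_config(horizon_months = 36, n_bootstrap = 50, seed = 4)

  same <- survival_nri_idi(p_old, p_old, out, cfg)
  expect_equal(same$nri, 0)
  expect_equal(same$idi, 0)

  res <- survival_nri_idi(p_old, p_new, out, cfg)
  swp <- survival_nri_idi(p_new, p_old, out, cfg)
  expect_equal(res$nri, -swp$nri, tolerance = 1e-12)
  expect_equal(res$idi, -swp$idi, tolerance = 1e-12)

  # no censoring before the horizon: IPCW weights are constant within
  # groups, so the closed-form uncensored NRI/IDI applies
  ev <- time <= 36 & event == 1
  ctrl <- time > 36
  up <- p_new > p_old; dn <- p_new < p_old
  nri_cf <- mean(up[ev]) - mean(dn[ev]) + mean(dn[ctrl]) - mean(up[ctrl])
  idi_cf <- mean(p_new[ev] - p_old[ev]) - mean(p_new[ctrl] - p_old[ctrl])
  expect_equal(res$nri, nri_cf, tolerance = 1e-12)
  expect_equal(res$idi, idi_cf, tolerance = 1e-12)

  # NRI is invariant to a common strictly monotone probability transform
  tr <- function(p) p^2
  res_tr <- survival_nri_idi(tr(p_old), tr(p_new), out, cfg)
  expect_equal(res_tr$nri, res$nri, tolerance = 1e-12)

  expect_error(survival_nri_idi(p_old, p_new, out,
                                eval_config(horizon_months = 1000)),
               "horizon")
})

test_that("calibration bins are monotone and constant-risk models recover the pooled KM", {
  d <- generate_cohort(cohort_spec(n_subjects = 400, seed = 15),
                       images = FALSE)
  cov <- data.frame(subject_id = d$survival$subject_id,
                    z = d$latents$z_amplitude)
  fit <- fit_cox(cov, d$survival)
  cal <- calibration_table(fit, cov, d$survival, 36, groups = 4)
  expect_true(all(diff(cal$mean_predicted) >= -1e-12))
  expect_true(all(cal$observed_km >= 0 & cal$observed_km <= 1))
  expect_equal(sum(cal$n), 400)

  # constant linear predictor: a single pooled bin equal to the overall KM
  cov0 <- data.frame(subject_id = d$survival$subject_id,
                     z = cov$z, z0 = 0)
  pred0 <- cox_survprob(fit, transform(cov, z = 0), 36)
  expect_equal(length(unique(round(pred0, 12))), 1)
  km <- survival::survfit(survival::Surv(d$survival$time_months,
                                         d$survival$event) ~ 1)
  cal0 <- calibration_table(fit, transform(cov, z = 0), d$survival, 36,
                            groups = 4)
  expect_equal(nrow(cal0), 1)
  expect_equal(cal0$observed_km,
               summary(km, times = 36)$surv, tolerance = 1e-12)
})

test_that("evaluate_models assembles a coherent report", {
  d <- generate_cohort(cohort_spec(n_subjects = 250, seed = 19),
                       images = FALSE)
  lps <- list(C = rnorm(250), CR = d$latents$z_amplitude)
  set.seed(2)
  probs <- list(C = runif(250), CR = plogis(d$latents$z_amplitude))
  rep <- evaluate_models(lps, probs, d$survival,
                         eval_config(n_bootstrap = 100, seed = 3))
  expect_true(all(vapply(rep$c_index, function(z)
    z$c_index >= 0 && z$c_index <= 1, TRUE)))
  expect_true(rep$c_index$CR$c_index > rep$c_index$C$c_index)
  expect_true(!is.null(rep$delta_c$p_value))
  expect_true(abs(rep$nri_idi$nri) <= 2)
  expect_true(abs(rep$nri_idi$idi) <= 1)
  expect_output(print(rep), "C-index")
})
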