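test_that("Lin's CCC matches its formula and penalizes location shift", {
  x <- c(1, 2, 3, 4)
  expect_equal(lin_ccc(x, x), 1)
  expect_lt(lin_ccc(x, x + 2), 1)
  expect_gt(lin_ccc(x, x + 2), 0)

  y <- c(1.1, 2.1, 2.9, 4.2)
  # independent evaluation through r * sx * sy form
  n <- 4
  sx <- sqrt(mean((x - mean(x))^2)); sy <- sqrt(mean((y - mean(y))^2))
  r <- cor(x, y)
  expected <- 2 * r * sx * sy / (sx^2 + sy^2 + (mean(x) - mean(y))^2)
  expect_equal(lin_ccc(x, y), expected, tolerance = 1e-12)

  expect_error(lin_ccc(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_error(lin_ccc(1:3, 1:4), "equal length")
})

test_that("reliability filter removes noise features and keeps the threshold boundary", {
  set.seed(8)
  n <- 30
  base <- matrix(rnorm(n * 4), n, 4)
  t1 <- data.frame(subject_id = sprintf("S%02d", 1:n), base,
                   check.names = FALSE)
  names(t1)[-1] <- paste0("f", 1:4)
  t2 <- t1
  t2$f3 <- rnorm(n)  # second reader's f3 is pure noise
  res <- reliability_filter(t1, t2, 0.8)
  expect_identical(res$removed_ids, "f3")
  expect_setequal(res$retained_ids, c("f1", "f2", "f4"))

  # feature with CCC exactly at the threshold is retained (strict <)
  t3 <- t1
  t3$f1 <- t1$f1 + rnorm(n, sd = 0.4)
  c1 <- lin_ccc(t1$f1, t3$f1)
  res2 <- reliability_filter(t1, t3, threshold = c1)
  expect_true("f1" %in% res2$retained_ids)

  expect_error(reliability_filter(t1, t2[c(1:10), ], 0.8), "subjects")
})

test_that("redundancy filter prunes to max |r| <= threshold with minimal removals on small instances", {
  set.seed(3)
  n <- 200
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 2] <- x[, 1]  # exact duplicate
  tab <- data.frame(subject_id = sprintf("S%03d", 1:n), x,
                    check.names = FALSE)
  names(tab)[-1] <- paste0("f", 1:5)
  res <- redundancy_filter(tab, 0.9)
  expect_equal(length(res$removed_ids), 1)
  expect_true(res$removed_ids %in% c("f1", "f2"))

  # nothing removed when all |r| <= threshold
  tab2 <- tab[c("subject_id", "f1", "f3", "f4", "f5")]
  res2 <- redundancy_filter(tab2, 0.9)
  expect_length(res2$removed_ids, 0)

  # planted 3-feature block at r ~ 0.95: brute-force search over subsets
  # confirms the greedy result is a minimal removal set
  ft <- generate_feature_table(400, 6, block_correlations = list(
    list(cols = 1:3, rho = 0.95)), seed = 5)
  res3 <- redundancy_filter(ft$features, 0.9)
  r <- abs(cor(as.matrix(ft$features[paste0("f", 1:6)])))
  ok_subset <- function(keep) {
    rr <- r[keep, keep, drop = FALSE]; diag(rr) <- 0; max(rr) <= 0.9
  }
  sizes <- integer(0)
  for (k in 0:6) {
    combs <- combn(6, 6 - k)
    found <- any(apply(combs, 2, ok_subset))
    if (found) { sizes <- k; break }
  }
  expect_equal(length(res3$removed_ids), sizes)
  expect_true(ok_subset(match(res3$retained_ids, paste0("f", 1:6))))

  # constant features are removed first, with a warning
  tabc <- tab2; tabc$f3 <- 1
  expect_warning(res4 <- redundancy_filter(tabc, 0.9), "zero-variance")
  expect_true("f3" %in% res4$removed_ids)
})

test_that("standardization hits exact moments and transfers to test data", {
  ft <- generate_feature_table(80, 4, seed = 2)
  std <- standardize(ft$features)
  m <- as.matrix(std$table[paste0("f", 1:4)])
  expect_true(all(abs(colMeans(m)) < 1e-12))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-12))

  again <- apply_standardization(ft$features, std$means, std$sds)
  expect_equal(as.matrix(again[paste0("f", 1:4)]), m, tolerance = 1e-12)

  ft2 <- generate_feature_table(40, 4, seed = 99)
  test_std <- apply_standardization(ft2$features, std$means, std$sds)
  mt <- as.matrix(test_std[paste0("f", 1:4)])
  expect_false(all(abs(colMeans(mt)) < 1e-6))  # train params, not refit

  ftc <- ft$features; ftc$f2 <- 3
  expect_error(standardize(ftc), "f2")
})

test_that("LASSO-Cox shrinks fully at large lambda and matches a Newton oracle at lambda 0", {
  ft <- generate_feature_table(100, 3, planted = c(f1 = 0.8, f2 = -0.5),
                               seed = 6)
  std <- standardize(ft$features)

  big <- fit_lasso_cox(std$table, ft$survival, lambda = 5)
  expect_length(big$coefficients, 0)

  unpen <- fit_lasso_cox(std$table, ft$survival, lambda = 0)
  x <- as.matrix(std$table[paste0("f", 1:3)])
  beta_oracle <- oracle_cox_newton(x, ft$survival$time_months,
                                   ft$survival$event)
  expect_equal(unname(unpen$all_coefficients), as.vector(beta_oracle),
               tolerance = 1e-4)

  expect_error(fit_lasso_cox(std$table,
                             transform(ft$survival, event = 0)),
               "events")
  raw <- ft$features
  raw$f1 <- raw$f1 * 50 + 100  # HU-scale column, clearly unstandardized
  expect_warning(fit_lasso_cox(raw, ft$survival, lambda = 1),
                 "standardized")
})

test_that("cross-validated LASSO-Cox recovers a planted prognostic feature", {
  ft <- generate_feature_table(400, 21, planted = c(f1 = 1), seed = 17)
  std <- standardize(ft$features)
  fit <- fit_lasso_cox(std$table, ft$survival,
                       selection_config(seed = 17))
  expect_true("f1" %in% names(fit$coefficients))
  expect_equal(names(which.max(abs(fit$all_coefficients))), "f1")
  # same seed, same answer
  fit2 <- fit_lasso_cox(std$table, ft$survival, selection_config(seed = 17))
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$chosen_lambda, fit2$chosen_lambda)
})

test_that("coefficient paths grow sparser toward large lambda", {
  ft <- generate_feature_table(150, 8, planted = c(f1 = 1, f2 = 0.5),
                               seed = 4)
  std <- standardize(ft$features)
  fit <- fit_lasso_cox(std$table, ft$survival, selection_config(seed = 4))
  path <- fit$fit$glmnet.fit
  nz <- path$df
  expect_equal(nz[1], 0)                 # largest lambda: all zero
  expect_gte(nz[length(nz)], nz[1])
})

test_that("selection report enforces the accounting identity", {
  rep <- selection_report(692, 347, 274, paste0("f", 1:71))
  expect_equal(rep$n_retained, 71)
  expect_output(print(rep), "692")
  expect_error(selection_report(692, 347, 274, paste0("f", 1:70)),
               "accounting")
})

test_that("the full selection cascade runs end to end on tabular data", {
  ft <- generate_feature_table(200, 10,
                               block_correlations = list(
                                 list(cols = c(2, 3), rho = 0.97)),
                               planted = c(f1 = 1), seed = 8)
  # reader 2: subset of subjects, one feature made unreliable
  idx <- 1:30
  t2 <- ft$features[idx, ]
  t2$f5 <- rnorm(30)
  sel <- run_selection(ft$features, t2, ft$survival,
                       selection_config(seed = 8))
  rep <- sel$report
  expect_equal(rep$n_total, 10)
  expect_true("f5" %in% setdiff(paste0("f", 1:10), rep$retained_ids))
  expect_equal(rep$n_retained,
               rep$n_total - rep$n_removed_ccc - rep$n_removed_corr)
  expect_true("f1" %in% names(sel$lasso$coefficients))
})
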