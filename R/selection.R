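# Three-stage feature selection: inter-reader reliability (Lin's CCC),
# redundancy pruning (pairwise Pearson correlation), and LASSO-Cox with a
# cross-validated penalty; plus train/test feature standardization.

feature_matrix <- function(table) {
  stopifnot(is.data.frame(table), "subject_id" %in% names(table))
  m <- as.matrix(table[setdiff(names(table), "subject_id")])
  rownames(m) <- table$subject_id
  storage.mode(m) <- "double"
  m
}

#' Lin's concordance correlation coefficient
#'
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with population
#' (1/n) moments: agreement of two measurements, penalizing both scale and
#' location shifts.
#'
#' @param x,y equal-length numeric vectors (n >= 3, finite).
#' @return CCC in [-1, 1].
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("CCC needs at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) stop("CCC undefined: zero variance and equal means")
  2 * cxy / den
}

#' Inter-reader reliability filter
#'
#' Removes features whose Lin's CCC between the two readers' extractions is
#' below the threshold (strictly `CCC < threshold` is removed, so a feature
#' exactly at the threshold is retained).
#'
#' @param table_reader1,table_reader2 feature data.frames (subject_id +
#'   features) on the same subjects and feature ids.
#' @param threshold CCC retention threshold, default 0.8.
#' @return List with `retained_ids`, `removed_ids` and the per-feature
#'   `ccc` values.
#' @export
reliability_filter <- function(table_reader1, table_reader2,
                               threshold = 0.8) {
  m1 <- feature_matrix(table_reader1)
  m2 <- feature_matrix(table_reader2)
  if (!identical(colnames(m1), colnames(m2)))
    stop("readers' tables have different feature ids")
  if (!identical(rownames(m1), rownames(m2)))
    stop("readers' tables have different subjects")
  ccc <- vapply(seq_len(ncol(m1)), function(j) {
    tryCatch(lin_ccc(m1[, j], m2[, j]), error = function(e) NA_real_)
  }, 0.0)
  names(ccc) <- colnames(m1)
  removed <- is.na(ccc) | ccc < threshold
  list(retained_ids = colnames(m1)[!removed],
       removed_ids = colnames(m1)[removed], ccc = ccc)
}

#' Redundancy filter on pairwise Pearson correlation
#'
#' Iterative greedy pruning: while any absolute pairwise correlation exceeds
#' the threshold, take the worst offending pair and drop the member with the
#' larger mean absolute correlation to all other remaining features. The
#' retained set therefore has max |r| <= threshold. Zero-variance features
#' are removed first with a warning.
#'
#' @param table feature data.frame (subject_id + >= 2 features).
#' @param threshold absolute correlation above which a pair is redundant
#'   (strictly `|r| > threshold` triggers removal), default 0.9.
#' @return List with `retained_ids` and `removed_ids`.
#' @export
redundancy_filter <- function(table, threshold = 0.9) {
  m <- feature_matrix(table)
  if (ncol(m) < 2L) stop("redundancy filter needs >= 2 features")
  sds <- apply(m, 2, stats::sd)
  removed <- character(0)
  if (any(sds == 0)) {
    warning("removing zero-variance features: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    removed <- colnames(m)[sds == 0]
    m <- m[, sds > 0, drop = FALSE]
  }
  r <- abs(stats::cor(m))
  diag(r) <- 0
  while (ncol(r) > 1L && max(r) > threshold) {
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(r)
    drop_j <- if (mean_abs[worst[1]] >= mean_abs[worst[2]]) worst[1]
              else worst[2]
    removed <- c(removed, colnames(r)[drop_j])
    r <- r[-drop_j, -drop_j, drop = FALSE]
  }
  list(retained_ids = colnames(r), removed_ids = removed)
}

#' Standardize a feature table (and apply stored parameters to new data)
#'
#' Centers and scales every feature column to mean 0 and SD 1 and records
#' the transform so a test set can be standardized with the training
#' parameters.
#'
#' @param table feature data.frame (subject_id + features).
#' @return List with `table` (standardized data.frame), `means` and `sds`.
#' @export
standardize <- function(table) {
  m <- feature_matrix(table)
  means <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance columns cannot be standardized: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  out <- sweep(sweep(m, 2, means), 2, sds, "/")
  list(table = data.frame(subject_id = table$subject_id, out,
                          check.names = FALSE, stringsAsFactors = FALSE),
       means = means, sds = sds)
}

#' @rdname standardize
#' @param means,sds stored training parameters (named as the feature
#'   columns).
#' @export
apply_standardization <- function(table, means, sds) {
  m <- feature_matrix(table)
  if (!all(names(means) %in% colnames(m)))
    stop("table lacks features: ",
         paste(setdiff(names(means), colnames(m)), collapse = ", "))
  m <- m[, names(means), drop = FALSE]
  out <- sweep(sweep(m, 2, means), 2, sds, "/")
  data.frame(subject_id = table$subject_id, out, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Selection configuration
#'
#' @param ccc_threshold inter-reader CCC retention threshold (default 0.8).
#' @param pearson_threshold redundancy correlation threshold (default 0.9).
#' @param n_folds cross-validation folds for the LASSO penalty (default 10).
#' @param lambda_rule `"min"` (deviance-minimizing) or `"1se"`.
#' @param seed integer seed controlling fold assignment.
#' @return A `selection_config` list.
#' @export
selection_config <- function(ccc_threshold = 0.8, pearson_threshold = 0.9,
                             n_folds = 10L, lambda_rule = c("min", "1se"),
                             seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(ccc_threshold > 0, ccc_threshold < 1,
            pearson_threshold > 0, pearson_threshold < 1, n_folds >= 2L)
  structure(list(ccc_threshold = ccc_threshold,
                 pearson_threshold = pearson_threshold,
                 n_folds = as.integer(n_folds), lambda_rule = lambda_rule,
                 seed = as.integer(seed)),
            class = "selection_config")
}

stratified_folds <- function(event, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(event))
    for (g in unique(event)) {
      idx <- which(event == g)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    fold
  })
}

#' LASSO-Cox regression with cross-validated penalty
#'
#' L1-penalized Cox partial-likelihood maximization (Breslow ties) over a
#' log-spaced lambda grid, with the penalty chosen by k-fold cross-validated
#' partial-likelihood deviance. Folds are stratified by event status and
#' seeded, so results are deterministic given the seed.
#'
#' @param table standardized feature data.frame (subject_id + features).
#' @param outcomes data.frame with `subject_id`, `time_months`, `event`.
#' @param config a [selection_config()].
#' @param lambda optional fixed penalty; skips cross-validation (0 gives the
#'   unpenalized Cox fit).
#' @return List with `coefficients` (named, nonzero only), `chosen_lambda`,
#'   `cv_curve` (data.frame lambda/deviance/se, `NULL` for fixed lambda) and
#'   the underlying `glmnet` fit.
#' @export
fit_lasso_cox <- function(table, outcomes, config = selection_config(),
                          lambda = NULL) {
  x <- feature_matrix(table)
  stopifnot(identical(table$subject_id, outcomes$subject_id))
  if (sum(outcomes$event) < 2L) stop("need at least 2 events")
  mx <- colMeans(x); sx <- apply(x, 2, stats::sd)
  if (max(abs(mx)) > 0.1 || max(abs(sx - 1)) > 0.1)
    warning("features do not look standardized (means near 0, SDs near 1)")
  y <- survival::Surv(outcomes$time_months, outcomes$event)
  if (!is.null(lambda)) {
    grid <- sort(unique(c(exp(seq(log(1), log(1e-4), length.out = 30)),
                          lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "cox", standardize = FALSE,
                          lambda = grid, thresh = 1e-12, maxit = 1e6)
    cf <- as.numeric(stats::coef(fit, s = lambda))
    names(cf) <- colnames(x)
    return(list(coefficients = cf[cf != 0], all_coefficients = cf,
                chosen_lambda = lambda, cv_curve = NULL, fit = fit))
  }
  foldid <- stratified_folds(outcomes$event, config$n_folds, config$seed)
  # path floored at 5% of lambda_max: with the low event counts typical of
  # these cohorts the partial likelihood degenerates (quasi-separation) at
  # very small penalties, and such solutions are never competitive in CV
  cv <- glmnet::cv.glmnet(x, y, family = "cox", standardize = FALSE,
                          foldid = foldid, lambda.min.ratio = 0.05)
  lam <- if (config$lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.numeric(stats::coef(cv, s = lam))
  names(cf) <- colnames(x)
  list(coefficients = cf[cf != 0], all_coefficients = cf,
       chosen_lambda = lam,
       cv_curve = data.frame(lambda = cv$lambda, deviance = cv$cvm,
                             se = cv$cvsd),
       fit = cv)
}

#' Selection report
#'
#' Bookkeeping of the three-stage cascade. The accounting identity
#' `n_retained == n_total - n_removed_ccc - n_removed_corr` is enforced at
#' construction.
#'
#' @param n_total features entering the cascade.
#' @param n_removed_ccc removed by the reliability filter.
#' @param n_removed_corr removed by the redundancy filter.
#' @param retained_ids ids surviving both filters.
#' @param ccc per-feature CCC values (optional).
#' @param lasso lasso summary list (optional).
#' @return A `selection_report`.
#' @export
selection_report <- function(n_total, n_removed_ccc, n_removed_corr,
                             retained_ids, ccc = NULL, lasso = NULL) {
  n_retained <- length(retained_ids)
  if (n_retained != n_total - n_removed_ccc - n_removed_corr)
    stop("selection accounting violated: ", n_total, " - ", n_removed_ccc,
         " - ", n_removed_corr, " != ", n_retained)
  structure(list(n_total = n_total, n_removed_ccc = n_removed_ccc,
                 n_removed_corr = n_removed_corr, n_retained = n_retained,
                 retained_ids = retained_ids, ccc = ccc, lasso = lasso),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Feature selection:", x$n_total, "total -", x$n_removed_ccc,
      "unreliable (CCC) -", x$n_removed_corr, "redundant (|r|) =",
      x$n_retained, "retained\n")
  if (!is.null(x$lasso))
    cat("  LASSO-Cox kept", length(x$lasso$coefficients),
        "features at lambda =", signif(x$lasso$chosen_lambda, 4), "\n")
  invisible(x)
}

#' Run the full selection cascade
#'
#' Reliability filter on the two readers' tables, redundancy filter and
#' LASSO-Cox on the reader-1 table restricted to reliable features. The
#' reader-2 table may cover a subset of subjects (re-segmented cases); the
#' CCC is computed on that subset.
#'
#' @param table feature data.frame for all subjects (reader 1).
#' @param table_reader2 feature data.frame for the re-segmented subset
#'   (reader 2); its subjects must be a subset of `table`'s.
#' @param outcomes survival data.frame aligned with `table`.
#' @param config a [selection_config()].
#' @return List with `report` ([selection_report()]), `standardization`
#'   (means/sds) and `lasso` (the [fit_lasso_cox()] result).
#' @export
run_selection <- function(table, table_reader2, outcomes,
                          config = selection_config()) {
  ids2 <- table_reader2$subject_id
  if (!all(ids2 %in% table$subject_id))
    stop("reader-2 subjects not all present in the main table")
  sub1 <- table[match(ids2, table$subject_id), , drop = FALSE]
  rel <- reliability_filter(sub1, table_reader2, config$ccc_threshold)
  n_total <- length(rel$ccc)
  tab_rel <- table[c("subject_id", rel$retained_ids)]
  red <- redundancy_filter(tab_rel, config$pearson_threshold)
  tab_sel <- table[c("subject_id", red$retained_ids)]
  std <- standardize(tab_sel)
  lasso <- fit_lasso_cox(std$table, outcomes, config)
  rep <- selection_report(n_total, length(rel$removed_ids),
                          length(red$removed_ids), red$retained_ids,
                          ccc = rel$ccc,
                          lasso = list(coefficients = lasso$coefficients,
                                       chosen_lambda = lasso$chosen_lambda))
  list(report = rep, standardization = list(means = std$means,
                                            sds = std$sds),
       lasso = lasso, standardized_table = std$table)
}
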