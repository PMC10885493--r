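# Small fixture builders used across test files.

make_vol <- function(arr, spacing = c(1, 1, 1)) image_volume(arr, spacing)

full_mask <- function(dm, spacing = c(1, 1, 1)) {
  voi_mask(array(1L, dm), spacing)
}

# random small VOI: irregular mask inside a small grid plus random levels
random_voi <- function(seed, dm = c(6, 6, 4), ng = 4) {
  set.seed(seed)
  m <- array(rbinom(prod(dm), 1, 0.7), dm)
  if (sum(m) < 10) m[1:3, 1:3, 1] <- 1L
  lev <- array(0L, dm)
  lev[m == 1] <- sample.int(ng, sum(m), replace = TRUE)
  structure(list(levels = lev, n_levels = ng,
                 binning = list(method = "fixed_bin_count", n_bins = ng)),
            class = "discretized_voi")
}

as_dvoi <- function(lev, ng) {
  structure(list(levels = array(as.integer(lev), dim(lev)), n_levels = ng,
                 binning = list(method = "fixed_bin_count", n_bins = ng)),
            class = "discretized_voi")
}

sphere_mask <- function(r_mm, spacing = c(1, 1, 1), pad = 2) {
  dm <- as.integer(ceiling(2 * r_mm / spacing) + 2 * pad + 1)
  co <- lapply(1:3, function(k) (seq_len(dm[k]) - 1) * spacing[k])
  center <- (dm - 1) * spacing / 2
  r2 <- outer(outer((co[[1]] - center[1])^2, (co[[2]] - center[2])^2, "+"),
              (co[[3]] - center[3])^2, "+")
  voi_mask(array(as.integer(r2 <= r_mm^2), dm), spacing)
}

ellipsoid_mask <- function(semi_mm, spacing = c(1, 1, 1), pad = 2) {
  dm <- as.integer(ceiling(2 * semi_mm / spacing) + 2 * pad + 1)
  co <- lapply(1:3, function(k) (seq_len(dm[k]) - 1) * spacing[k])
  center <- (dm - 1) * spacing / 2
  u <- lapply(1:3, function(k) ((co[[k]] - center[k]) / semi_mm[k])^2)
  r2 <- outer(outer(u[[1]], u[[2]], "+"), u[[3]], "+")
  voi_mask(array(as.integer(r2 <= 1), dm), spacing)
}

toy_surv <- function(time, event) {
  data.frame(subject_id = sprintf("S%02d", seq_along(time)),
             time_months = time, event = event, stringsAsFactors = FALSE)
}
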