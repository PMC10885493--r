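# Synthetic tumor phantoms, reader-perturbed masks, clinical covariates and
# Cox-linked censored outcomes with known ground truth. The generators are
# first-class, seeded and deterministic so every downstream stage of the
# pipeline can be tested without patient data.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Tumor phantom specification
#'
#' Describes an ellipsoidal tumor embedded in a uniform background: grid and
#' voxel spacing, ellipsoid semi-axes, mean tumor enhancement, and a smoothed
#' Gaussian random field that modulates intra-tumoral texture. The field is
#' white noise convolved with a Gaussian kernel of the stated correlation
#' length, then scaled to the stated amplitude (its standard deviation in HU),
#' so its smoothness directly controls texture entropy and contrast.
#'
#' @param grid_shape integer length-3: voxels per axis.
#' @param spacing_mm numeric length-3 voxel size (mm).
#' @param semi_axes_mm ellipsoid semi-axes (mm); each must exceed one voxel
#'   and the ellipsoid must fit inside the grid.
#' @param base_intensity_hu mean tumor intensity (HU).
#' @param heterogeneity list with `corr_length_mm` (> 0) and `amplitude_hu`
#'   (>= 0): correlation length and SD of the random texture field.
#' @param background_hu intensity outside the tumor.
#' @param noise_sd_hu SD of additive white noise (HU).
#' @param seed integer RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32),
                         spacing_mm = c(1, 1, 3),
                         semi_axes_mm = c(15, 12, 10),
                         base_intensity_hu = 110,
                         heterogeneity = list(corr_length_mm = 3,
                                              amplitude_hu = 20),
                         background_hu = 60,
                         noise_sd_hu = 5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  semi_axes_mm <- as.numeric(semi_axes_mm)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(semi_axes_mm) == 3L)
  if (any(semi_axes_mm <= spacing_mm))
    stop("semi_axes_mm must each exceed one voxel")
  if (heterogeneity$amplitude_hu < 0)
    stop("heterogeneity amplitude must be >= 0")
  if (heterogeneity$corr_length_mm <= 0)
    stop("heterogeneity correlation length must be > 0")
  if (noise_sd_hu < 0) stop("noise_sd_hu must be >= 0")
  extent <- (grid_shape - 1) * spacing_mm
  if (any(2 * semi_axes_mm >= extent))
    stop("ellipsoid exceeds the image grid")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 semi_axes_mm = semi_axes_mm,
                 base_intensity_hu = base_intensity_hu,
                 heterogeneity = heterogeneity,
                 background_hu = background_hu, noise_sd_hu = noise_sd_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phys_coords <- function(grid_shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  lapply(1:3, function(k)
    origin_mm[k] + (seq_len(grid_shape[k]) - 1) * spacing_mm[k])
}

smooth_random_field <- function(grid_shape, spacing_mm, corr_length_mm,
                                amplitude) {
  w <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  f <- image_volume(w, spacing_mm)
  f <- gaussian_filter(f, corr_length_mm)$values
  s <- stats::sd(as.vector(f))
  if (s == 0 || amplitude == 0) return(array(0, grid_shape))
  f / s * amplitude
}

#' Generate a tumor phantom image and mask
#'
#' Voxelizes the ellipsoid of the spec as the VOI mask and fills the image
#' with `background_hu` outside and `base_intensity_hu` plus the smoothed
#' random texture field plus white noise inside. Deterministic given the
#' spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` ([image_volume()]) and `mask` ([voi_mask()]).
#' @export
generate_tumor_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    gs <- spec$grid_shape; sp <- spec$spacing_mm
    co <- phys_coords(gs, sp)
    center <- (gs - 1) * sp / 2
    u <- lapply(1:3, function(k) (co[[k]] - center[k]) / spec$semi_axes_mm[k])
    r2 <- outer(outer(u[[1]]^2, u[[2]]^2, "+"), u[[3]]^2, "+")
    mvals <- array(as.integer(r2 <= 1), gs)
    if (sum(mvals) == 0) stop("ellipsoid produced an empty mask")
    field <- smooth_random_field(gs, sp, spec$heterogeneity$corr_length_mm,
                                 spec$heterogeneity$amplitude_hu)
    noise <- if (spec$noise_sd_hu > 0)
      array(stats::rnorm(prod(gs), sd = spec$noise_sd_hu), gs)
    else array(0, gs)
    img <- array(spec$background_hu, gs) + noise
    inside <- mvals == 1L
    img[inside] <- spec$base_intensity_hu + field[inside] + noise[inside]
    list(volume = image_volume(img, sp), mask = voi_mask(mvals, sp))
  })
}

#' Perturb a mask to emulate a second reader's segmentation
#'
#' Displaces the mask boundary by a smooth zero-mean random field scaled by
#' `jitter_mm`: a voxel within `u * jitter_mm` of the boundary is added
#' (positive field outside) or removed (negative field inside), emulating the
#' boundary variability of an independent reader re-segmenting the tumor.
#' `jitter_mm = 0` returns the input unchanged; deterministic given the seed.
#'
#' @param mask a non-empty [voi_mask()].
#' @param jitter_mm boundary displacement scale (mm, >= 0).
#' @param seed integer RNG seed.
#' @return A perturbed [voi_mask()] on the same grid.
#' @export
perturb_mask <- function(mask, jitter_mm, seed = 1L) {
  stopifnot(inherits(mask, "voi_mask"))
  if (n_voxels_in_mask(mask) == 0L) stop("mask is empty")
  if (jitter_mm < 0) stop("jitter_mm must be >= 0")
  if (jitter_mm == 0) return(mask)
  with_seed(seed, {
    gs <- dim(mask$values); sp <- mask$spacing_mm
    m <- mask$values
    field <- smooth_random_field(gs, sp, max(jitter_mm, min(sp)), 1)
    field <- pmin(pmax(field, -3), 3)

    din <- .cpp_border_distance(array(as.integer(m), gs))
    dout <- .cpp_border_distance(array(as.integer(1L - m), gs))
    kmax <- as.integer(ceiling(3 * jitter_mm / min(sp))) + 1L
    cand_in <- which(m == 1L & din <= kmax)
    cand_out <- which(m == 0L & dout <= kmax)
    ref_out <- which(m == 0L & dout == 1L)  # outside voxels touching mask
    ref_in <- which(m == 1L & din == 1L)    # in-mask border voxels

    coords <- function(idx) {
      i0 <- idx - 1L
      x <- i0 %% gs[1]; y <- (i0 %/% gs[1]) %% gs[2]; z <- i0 %/% (gs[1] * gs[2])
      cbind(x * sp[1], y * sp[2], z * sp[3])
    }
    min_dist <- function(a_idx, b_idx) {
      a <- coords(a_idx); b <- coords(b_idx)
      out <- numeric(nrow(a))
      step <- 2000L
      for (s in seq(1L, nrow(a), by = step)) {
        e <- min(s + step - 1L, nrow(a))
        d2 <- outer(a[s:e, 1], b[, 1], "-")^2 +
          outer(a[s:e, 2], b[, 2], "-")^2 +
          outer(a[s:e, 3], b[, 3], "-")^2
        out[s:e] <- sqrt(apply(d2, 1, min))
      }
      out
    }
    disp <- field * jitter_mm
    new_m <- m
    if (length(cand_in) && length(ref_out)) {
      d_in <- min_dist(cand_in, ref_out)  # distance to outside region
      new_m[cand_in[d_in <= -disp[cand_in]]] <- 0L
    }
    if (length(cand_out) && length(ref_in)) {
      d_out <- min_dist(cand_out, ref_in)  # distance to mask
      new_m[cand_out[d_out <= disp[cand_out]]] <- 1L
    }
    if (sum(new_m) == 0L) stop("perturbation emptied the mask")
    voi_mask(new_m, sp, mask$origin_mm)
  })
}

#' Cohort specification for synthetic survival studies
#'
#' Defines cohort size, the true log-hazard coefficients wired into outcome
#' generation, a Weibull baseline hazard, an administrative censoring horizon,
#' and covariate distributions. The defaults emulate a resected G1-2 PanNET
#' cohort: mean age 53 (SD 12), AJCC stage mix dominated by stages I-II, and
#' a ~13% event rate over a 120-month horizon.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param true_beta named log-hazard coefficients; recognized names are
#'   `amplitude` (per-SD effect of the latent texture-field amplitude), `age`
#'   (per year, centered at `age_dist$mean`), and `stageII`, `stageIII`,
#'   `stageIV` (contrasts vs stage I).
#' @param baseline list with Weibull `shape` and `scale` (months) of the
#'   baseline event-time distribution.
#' @param censor_time_months administrative censoring horizon (months).
#' @param age_dist list with `mean` and `sd` of the age distribution (years).
#' @param stage_probs probabilities of stages I-IV (sum to 1).
#' @param amplitude_dist list with `meanlog`/`sdlog` of the log-normal
#'   distribution of the per-subject texture-field amplitude (HU).
#' @param seed integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 100L,
                        true_beta = c(amplitude = 0.8, age = 0.02,
                                      stageII = 0.7, stageIII = 1.4,
                                      stageIV = 2.0),
                        baseline = list(shape = 1.2, scale = 1300),
                        censor_time_months = 120,
                        age_dist = list(mean = 53, sd = 12),
                        stage_probs = c(I = 0.40, II = 0.48, III = 0.09,
                                        IV = 0.03),
                        amplitude_dist = list(meanlog = log(15), sdlog = 0.5),
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (abs(sum(stage_probs) - 1) > 1e-8)
    stop("stage_probs must sum to 1 over stages I-IV")
  if (length(stage_probs) != 4L) stop("stage_probs must have 4 entries")
  if (censor_time_months < 0) stop("censor_time_months must be >= 0")
  stopifnot(baseline$shape > 0, baseline$scale > 0)
  structure(list(n_subjects = n_subjects, true_beta = true_beta,
                 baseline = baseline,
                 censor_time_months = censor_time_months,
                 age_dist = age_dist, stage_probs = stage_probs,
                 amplitude_dist = amplitude_dist, seed = as.integer(seed)),
            class = "cohort_spec")
}

weibull_ph_times <- function(n, lp, shape, scale) {
  u <- stats::runif(n)
  scale * (-log(u) / exp(lp))^(1 / shape)
}

#' Generate a synthetic cohort of tumor images and censored outcomes
#'
#' Per subject, draws a texture-field amplitude (log-normal), tumor size,
#' age and AJCC stage; renders arterial-phase (AP) and portal-venous-phase
#' (PVP) phantom images sharing one tumor mask (the PVP field is attenuated,
#' emulating washout of arterial heterogeneity); and draws an event time
#' from a Weibull proportional-hazards model whose linear predictor combines
#' the standardized amplitude, centered age and stage through `true_beta`.
#' Times beyond the censoring horizon are administratively censored.
#'
#' @param cohort a [cohort_spec()].
#' @param phantom_base a [phantom_spec()] providing grid, spacing, intensity
#'   and correlation-length defaults shared by all subjects.
#' @param images logical; set `FALSE` to skip image rendering and return
#'   only covariates, outcomes and latents (fast path for survival-only
#'   tests).
#' @return List with `subjects` (each `list(ap, pvp, mask)`), `clinical`
#'   (data.frame: subject_id, age, stage), `survival` (data.frame:
#'   subject_id, time_months, event) and `latents` (data.frame with the
#'   per-subject amplitude, its standardized value and the true linear
#'   predictor).
#' @export
generate_cohort <- function(cohort, phantom_base = phantom_spec(),
                            images = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(phantom_base, "phantom_spec"))
  with_seed(cohort$seed, {
    n <- cohort$n_subjects
    amp <- stats::rlnorm(n, cohort$amplitude_dist$meanlog,
                         cohort$amplitude_dist$sdlog)
    # standardization uses the distribution's own moments so the latent scale
    # does not depend on the realized sample
    mu_a <- exp(cohort$amplitude_dist$meanlog +
                  cohort$amplitude_dist$sdlog^2 / 2)
    sd_a <- mu_a * sqrt(exp(cohort$amplitude_dist$sdlog^2) - 1)
    z_amp <- (amp - mu_a) / sd_a
    age <- round(pmax(18, stats::rnorm(n, cohort$age_dist$mean,
                                       cohort$age_dist$sd)))
    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                    prob = cohort$stage_probs)
    b <- function(nm) if (nm %in% names(cohort$true_beta))
      cohort$true_beta[[nm]] else 0
    lp <- b("amplitude") * z_amp +
      b("age") * (age - cohort$age_dist$mean) +
      ifelse(stage == "II", b("stageII"),
             ifelse(stage == "III", b("stageIII"),
                    ifelse(stage == "IV", b("stageIV"), 0)))
    t_event <- weibull_ph_times(n, lp, cohort$baseline$shape,
                                cohort$baseline$scale)
    event <- as.integer(t_event <= cohort$censor_time_months)
    time <- pmin(t_event, cohort$censor_time_months)
    # tumor size loosely tied to stage (stage is partly size-based)
    size_scale <- stats::runif(n, 0.55, 1.15) *
      c(I = 0.8, II = 1.0, III = 1.15, IV = 1.2)[stage]
    subj_seed <- sample.int(2^30, n)

    subjects <- vector("list", n)
    if (images) {
      for (i in seq_len(n)) {
        sp_i <- phantom_base
        sp_i$semi_axes_mm <- pmax(phantom_base$spacing_mm * 1.5,
                                  phantom_base$semi_axes_mm * size_scale[i])
        sp_i$heterogeneity$amplitude_hu <- amp[i]
        sp_i$seed <- subj_seed[i]
        ap <- generate_tumor_volume(sp_i)
        sp_p <- sp_i
        sp_p$heterogeneity$amplitude_hu <- amp[i] * 0.4
        sp_p$base_intensity_hu <- phantom_base$base_intensity_hu * 0.85
        sp_p$seed <- subj_seed[i] + 1L
        pvp <- generate_tumor_volume(sp_p)
        subjects[[i]] <- list(ap = ap$volume, pvp = pvp$volume,
                              mask = ap$mask)
      }
    }
    ids <- sprintf("S%04d", seq_len(n))
    list(subjects = subjects,
         clinical = data.frame(subject_id = ids, age = age,
                               stage = factor(stage,
                                              levels = c("I", "II", "III",
                                                         "IV")),
                               stringsAsFactors = FALSE),
         survival = data.frame(subject_id = ids,
                               time_months = time, event = event,
                               stringsAsFactors = FALSE),
         latents = data.frame(subject_id = ids, amplitude = amp,
                              z_amplitude = z_amp, lp_true = lp,
                              stringsAsFactors = FALSE))
  })
}

#' Generate a correlated Gaussian feature table with Cox-linked outcomes
#'
#' Direct input for testing the feature-selection cascade without images:
#' multivariate Gaussian features (unit variance) with user-specified
#' correlation blocks, and outcomes drawn from a Weibull proportional-hazards
#' model on a planted set of prognostic features.
#'
#' @param n subjects; @param p features (named `f1..fp`).
#' @param block_correlations list of blocks, each `list(cols =, rho =)`,
#'   giving equicorrelation `rho` within the column set; columns not listed
#'   are independent. The implied correlation matrix must be positive
#'   definite.
#' @param planted named numeric of true log-hazard coefficients on feature
#'   names (subset of `f1..fp`).
#' @param seed integer RNG seed.
#' @param baseline,censor_time_months Weibull baseline and censoring horizon
#'   as in [cohort_spec()].
#' @return List with `features` (data.frame, subject_id + f1..fp),
#'   `survival` (data.frame) and `lp_true`.
#' @export
generate_feature_table <- function(n, p, block_correlations = list(),
                                   planted = c(), seed = 1L,
                                   baseline = list(shape = 1.2, scale = 120),
                                   censor_time_months = 120) {
  if (p < 1L) stop("p must be >= 1")
  if (length(planted) > p) stop("p must be >= number of planted features")
  nm <- paste0("f", seq_len(p))
  if (length(planted) && !all(names(planted) %in% nm))
    stop("planted names must be among ", nm[1], "..", nm[p])
  sigma <- diag(p)
  for (bl in block_correlations) {
    cols <- bl$cols
    sigma[cols, cols] <- bl$rho
    diag(sigma)[cols] <- 1
  }
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("correlation spec is not positive definite"))
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * p), n, p) %*% ch
    colnames(x) <- nm
    beta <- stats::setNames(numeric(p), nm)
    beta[names(planted)] <- planted
    lp <- as.vector(x %*% beta)
    t_event <- weibull_ph_times(n, lp, baseline$shape, baseline$scale)
    event <- as.integer(t_event <= censor_time_months)
    time <- pmin(t_event, censor_time_months)
    ids <- sprintf("S%04d", seq_len(n))
    list(features = data.frame(subject_id = ids, x, stringsAsFactors = FALSE),
         survival = data.frame(subject_id = ids, time_months = time,
                               event = event, stringsAsFactors = FALSE),
         lp_true = lp)
  })
}
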