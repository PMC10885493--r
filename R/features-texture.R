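# Texture feature families on a discretized VOI: gray-level co-occurrence
# (GLCM), size-zone (GLSZM), distance-zone (GLDZM) and neighbouring
# gray-level dependence (NGLDM) matrices. Conventions: GLCM uses the 13
# unique Chebyshev-distance-1 directions, symmetric pairs, per-direction
# normalized matrices averaged; zones are 26-connected; NGLDM counts
# equal-level 26-neighbours (alpha = 0); entropies use log base 2.

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Gray-level co-occurrence matrix features
#'
#' Computes the direction-averaged symmetric GLCM at Chebyshev distance 1
#' over the 13 unique 3D directions (in-mask voxel pairs only) and derives
#' the standard scalar features: entropies on the joint, difference and sum
#' distributions, contrast/dissimilarity, cluster statistics, and marginal
#' correlation.
#'
#' @param d a `discretized_voi` from [discretize()].
#' @return Named numeric vector of GLCM features.
#' @export
glcm_features <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  ng <- d$n_levels
  p <- .cpp_glcm(d$levels, ng)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)                      # equals mu_i by symmetry
  var_i <- sum((i - mu_i)^2 * p)
  diff_k <- abs(row(p) - col(p))
  p_diff <- tapply(p, diff_k, sum)        # indexed by |i-j| = 0..ng-1
  kd <- as.numeric(names(p_diff))
  sum_k <- row(p) + col(p)
  p_sum <- tapply(p, sum_k, sum)
  ks <- as.numeric(names(p_sum))
  corr <- if (var_i > 0) (sum(i * j * p) - mu_i * mu_j) / var_i else 1
  c(joint_maximum = max(p),
    joint_average = mu_i,
    joint_variance = var_i,
    joint_entropy = -sum(xlog2(p)),
    joint_energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    inverse_difference = sum(p / (1 + abs(i - j))),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    correlation = corr,
    autocorrelation = sum(i * j * p),
    cluster_tendency = sum((i + j - mu_i - mu_j)^2 * p),
    cluster_shade = sum((i + j - mu_i - mu_j)^3 * p),
    cluster_prominence = sum((i + j - mu_i - mu_j)^4 * p),
    difference_average = sum(kd * p_diff),
    difference_variance = sum((kd - sum(kd * p_diff))^2 * p_diff),
    difference_entropy = -sum(xlog2(p_diff)),
    sum_average = sum(ks * p_sum),
    sum_entropy = -sum(xlog2(p_sum)))
}

zone_table <- function(d) {
  lab <- .cpp_label_zones(d$levels)
  nz <- max(lab)
  if (nz == 0L) stop("mask is empty")
  first <- match(seq_len(nz), lab)
  data.frame(level = d$levels[first], size = tabulate(lab, nz))
}

#' Gray-level size-zone matrix features
#'
#' Zones are maximal 26-connected regions of equal gray level within the
#' mask; the GLSZM tabulates (gray level, zone size). Features follow the
#' standard size/level emphasis, non-uniformity, variance and entropy
#' definitions, e.g. large zone high gray level emphasis =
#' sum s^2 g^2 p(g, s).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of GLSZM features.
#' @export
glszm_features <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  zt <- zone_table(d)
  nv <- sum(d$levels > 0)
  nz <- nrow(zt)
  g <- zt$level; s <- zt$size
  p <- rep(1 / nz, nz)
  mu_g <- sum(p * g); mu_s <- sum(p * s)
  # per-(g,s) cell probabilities for the entropy
  cell <- table(paste(g, s)) / nz
  c(small_zone_emphasis = sum(p / s^2),
    large_zone_emphasis = sum(p * s^2),
    low_gray_level_zone_emphasis = sum(p / g^2),
    high_gray_level_zone_emphasis = sum(p * g^2),
    small_zone_low_gray_level_emphasis = sum(p / (s^2 * g^2)),
    small_zone_high_gray_level_emphasis = sum(p * g^2 / s^2),
    large_zone_low_gray_level_emphasis = sum(p * s^2 / g^2),
    large_zone_high_gray_level_emphasis = sum(p * s^2 * g^2),
    gray_level_nonuniformity = sum(tapply(rep(1, nz), g, sum)^2) / nz,
    zone_size_nonuniformity = sum(tapply(rep(1, nz), s, sum)^2) / nz,
    zone_percentage = nz / nv,
    gray_level_variance = sum(p * (g - mu_g)^2),
    zone_size_variance = sum(p * (s - mu_s)^2),
    zone_size_entropy = -sum(xlog2(as.numeric(cell))))
}

#' Gray-level distance-zone matrix features
#'
#' Zones as in the GLSZM; each zone's distance is the minimum in-mask
#' Chebyshev distance from any of its voxels to the mask border (border
#' voxels have distance 1). Features mirror the size-zone set with distance
#' in place of size, e.g. large distance high gray level emphasis =
#' sum d^2 g^2 p(g, d).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of GLDZM features.
#' @export
gldzm_features <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  lab <- .cpp_label_zones(d$levels)
  nz <- max(lab)
  if (nz == 0L) stop("mask is empty")
  dist <- .cpp_border_distance(d$levels)
  first <- match(seq_len(nz), lab)
  g <- d$levels[first]
  dd <- as.integer(tapply(dist[lab > 0], lab[lab > 0], min))
  p <- rep(1 / nz, nz)
  mu_g <- sum(p * g); mu_d <- sum(p * dd)
  cell <- table(paste(g, dd)) / nz
  c(small_distance_emphasis = sum(p / dd^2),
    large_distance_emphasis = sum(p * dd^2),
    low_gray_level_zone_emphasis = sum(p / g^2),
    high_gray_level_zone_emphasis = sum(p * g^2),
    small_distance_low_gray_level_emphasis = sum(p / (dd^2 * g^2)),
    small_distance_high_gray_level_emphasis = sum(p * g^2 / dd^2),
    large_distance_low_gray_level_emphasis = sum(p * dd^2 / g^2),
    large_distance_high_gray_level_emphasis = sum(p * dd^2 * g^2),
    gray_level_nonuniformity = sum(tapply(rep(1, nz), g, sum)^2) / nz,
    zone_distance_nonuniformity = sum(tapply(rep(1, nz), dd, sum)^2) / nz,
    gray_level_variance = sum(p * (g - mu_g)^2),
    zone_distance_variance = sum(p * (dd - mu_d)^2),
    zone_distance_entropy = -sum(xlog2(as.numeric(cell))))
}

#' Neighbouring gray-level dependence matrix features
#'
#' The dependence count of an in-mask voxel is the number of its in-mask
#' 26-neighbours sharing its gray level (coarseness threshold alpha = 0,
#' counts 0..26). The NGLDM tabulates (gray level, dependence count) over
#' voxels. Emphasis features dividing by the count use (k + 1) so a count of
#' zero is defined; high dependence high gray level emphasis =
#' sum k^2 g^2 p(g, k).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of NGLDM features.
#' @export
ngldm_features <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  dep <- .cpp_dependence_counts(d$levels)
  inm <- d$levels > 0
  if (!any(inm)) stop("mask is empty")
  g <- d$levels[inm]
  k <- dep[inm]
  n <- length(g)
  p <- rep(1 / n, n)
  mu_g <- sum(p * g); mu_k <- sum(p * k)
  cell <- table(paste(g, k)) / n
  c(low_dependence_emphasis = sum(p / (k + 1)^2),
    high_dependence_emphasis = sum(p * k^2),
    low_gray_level_count_emphasis = sum(p / g^2),
    high_gray_level_count_emphasis = sum(p * g^2),
    low_dependence_low_gray_level_emphasis = sum(p / ((k + 1)^2 * g^2)),
    low_dependence_high_gray_level_emphasis = sum(p * g^2 / (k + 1)^2),
    high_dependence_low_gray_level_emphasis = sum(p * k^2 / g^2),
    high_dependence_high_gray_level_emphasis = sum(p * k^2 * g^2),
    gray_level_nonuniformity = sum(tapply(rep(1, n), g, sum)^2) / n,
    dependence_count_nonuniformity = sum(tapply(rep(1, n), k, sum)^2) / n,
    gray_level_variance = sum(p * (g - mu_g)^2),
    dependence_count_variance = sum(p * (k - mu_k)^2),
    dependence_count_entropy = -sum(xlog2(as.numeric(cell))))
}
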