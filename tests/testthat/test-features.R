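test_that("morphologic volume is voxel count times voxel volume", {
  m1 <- voi_mask(array(c(1L, rep(0L, 7)), c(2, 2, 2)), c(1, 1, 3))
  expect_equal(morph_volume(m1), 3)

  m100 <- array(0L, c(10, 10, 4)); m100[1:5, 1:5, 1:4] <- 1L
  expect_equal(morph_volume(voi_mask(m100, c(1, 1, 3))), 100 * 3)

  sp <- sphere_mask(10, c(1, 1, 1))
  expect_lt(abs(morph_volume(sp) - 4188.79) / 4188.79, 0.05)
  expect_error(morph_volume(voi_mask(array(0L, c(2, 2, 2)), c(1, 1, 1))),
               "empty")
})

test_that("flatness is ~1 for balls, matches axis ratio for ellipsoids, and is permutation-invariant", {
  expect_lt(abs(morph_flatness(sphere_mask(20, c(1, 1, 1))) - 1), 0.05)
  # anisotropic voxels must not distort the physical shape
  expect_lt(abs(morph_flatness(sphere_mask(20, c(1, 1, 2.5))) - 1), 0.05)

  el <- ellipsoid_mask(c(40, 20, 10), c(1, 1, 1))
  expect_equal(morph_flatness(el), 0.25, tolerance = 0.02)

  perm <- voi_mask(aperm(el$values, c(3, 1, 2)), c(1, 1, 1))
  expect_equal(morph_flatness(perm), morph_flatness(el), tolerance = 1e-10)

  flat <- array(0L, c(5, 5, 3)); flat[, , 2] <- 1L
  expect_error(morph_flatness(voi_mask(flat, c(1, 1, 1))), "coplanar")
})

test_that("first-order statistics match hand values and a two-pass oracle", {
  arr <- array(0, c(5, 1, 2)); arr[, 1, 1] <- 1:5; arr[, 1, 2] <- 1:5
  v <- image_volume(arr, c(1, 1, 1))
  f <- firstorder_features(v, full_mask(c(5, 1, 2)))
  expect_equal(unname(f["maximum"]), 5)
  expect_equal(unname(f["median"]), 3)
  expect_equal(unname(f["percentile25"]), 2)

  const <- firstorder_features(image_volume(array(4, c(3, 3, 3)), c(1, 1, 1)),
                               full_mask(c(3, 3, 3)))
  expect_equal(unname(const["robust_mad"]), 0)
  expect_equal(unname(const["sd"]), 0)

  set.seed(5)
  x <- runif(1000)
  vv <- image_volume(array(x, c(10, 10, 10)), c(1, 1, 1))
  fo <- firstorder_features(vv, full_mask(c(10, 10, 10)))
  # independent two-pass recomputation of the robust MAD
  q <- quantile(x, c(0.1, 0.9), names = FALSE)
  sub <- x[x >= q[1] & x <= q[2]]
  expect_equal(unname(fo["robust_mad"]), sum(abs(sub - sum(sub) / length(sub))) /
                 length(sub), tolerance = 1e-12)
})

test_that("GLCM features match the brute-force pair-enumeration oracle", {
  for (seed in 1:4) {
    d <- random_voi(seed, dm = c(6, 5, 4), ng = 4)
    p_oracle <- oracle_glcm_matrix(d$levels, 4)
    f <- glcm_features(d)
    i <- matrix(1:4, 4, 4); j <- t(i)
    expect_equal(unname(f["joint_entropy"]),
                 -sum(ifelse(p_oracle > 0, p_oracle * log2(p_oracle), 0)),
                 tolerance = 1e-9)
    expect_equal(unname(f["contrast"]), sum((i - j)^2 * p_oracle),
                 tolerance = 1e-9)
    mu <- sum(i * p_oracle)
    expect_equal(unname(f["cluster_shade"]),
                 sum((i + j - 2 * mu)^3 * p_oracle), tolerance = 1e-9)
    pd <- tapply(p_oracle, abs(i - j), sum)
    expect_equal(unname(f["difference_entropy"]),
                 -sum(ifelse(pd > 0, pd * log2(pd), 0)), tolerance = 1e-9)
  }
})

test_that("GLCM is zero-entropy on a single gray level and symmetric under level reversal", {
  lev <- array(0L, c(4, 4, 3)); lev[2:3, 2:3, 1:2] <- 1L
  d <- as_dvoi(lev, 4)
  f <- glcm_features(d)
  expect_equal(unname(f["joint_entropy"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["cluster_shade"]), 0)

  d2 <- random_voi(7, ng = 5)
  rev <- d2
  rev$levels[rev$levels > 0] <- 5L + 1L - rev$levels[rev$levels > 0]
  f1 <- glcm_features(d2); f2 <- glcm_features(rev)
  expect_equal(f1["joint_entropy"], f2["joint_entropy"], tolerance = 1e-12)
  expect_equal(f1["contrast"], f2["contrast"], tolerance = 1e-12)
  expect_equal(unname(f1["cluster_shade"]), -unname(f2["cluster_shade"]),
               tolerance = 1e-9)
})

test_that("GLSZM zones match flood-fill oracle and single-zone closed form", {
  lev <- array(0L, c(4, 4, 2)); lev[1:3, 1:3, 1:2] <- 2L
  f <- glszm_features(as_dvoi(lev, 2))
  n <- sum(lev > 0)
  expect_equal(unname(f["large_zone_high_gray_level_emphasis"]), n^2 * 2^2)
  expect_equal(unname(f["zone_percentage"]), 1 / n)

  for (seed in c(3, 8)) {
    d <- random_voi(seed, dm = c(5, 5, 4), ng = 3)
    lab_o <- oracle_zones(d$levels)
    nz <- max(lab_o)
    sizes <- tabulate(lab_o[lab_o > 0], nz)
    glev <- vapply(seq_len(nz), function(k) d$levels[which(lab_o == k)[1]], 0L)
    f <- glszm_features(d)
    expect_equal(unname(f["large_zone_high_gray_level_emphasis"]),
                 mean(sizes^2 * as.numeric(glev)^2), tolerance = 1e-9)
    mu_s <- mean(sizes)
    expect_equal(unname(f["zone_size_variance"]), mean((sizes - mu_s)^2),
                 tolerance = 1e-9)
  }
})

test_that("GLSZM normalized features are invariant to duplicating the VOI disjointly", {
  base <- random_voi(12, dm = c(5, 5, 3), ng = 3)
  dup <- array(0L, c(12, 5, 3))
  dup[1:5, , ] <- base$levels
  dup[8:12, , ] <- base$levels
  d2 <- as_dvoi(dup, 3)
  f1 <- glszm_features(base); f2 <- glszm_features(d2)
  for (nm in c("small_zone_emphasis", "large_zone_high_gray_level_emphasis",
               "zone_size_variance", "zone_percentage"))
    expect_equal(f1[nm], f2[nm], tolerance = 1e-9)
})

test_that("GLDZM distances match the erosion oracle and closed forms", {
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 3L
  f <- gldzm_features(as_dvoi(one, 3))
  expect_equal(unname(f["large_distance_high_gray_level_emphasis"]), 3^2)

  cube <- array(1L, c(4, 4, 4))
  fc <- gldzm_features(as_dvoi(cube, 1))
  expect_equal(unname(fc["large_distance_emphasis"]), 1)
  expect_equal(unname(fc["zone_distance_variance"]), 0)

  for (seed in c(2, 9)) {
    d <- random_voi(seed, dm = c(6, 5, 4), ng = 3)
    dist_o <- oracle_border_distance(d$levels)
    dist_p <- radsurv:::.cpp_border_distance(d$levels)
    expect_identical(as.vector(dist_p), as.vector(dist_o))
  }
})

test_that("NGLDM dependence counts match the exhaustive neighbour oracle", {
  uni <- array(1L, c(3, 3, 3))
  dep <- radsurv:::.cpp_dependence_counts(uni)
  expect_equal(dep[2, 2, 2], 26L)

  iso <- array(1L, c(3, 3, 3)); iso[2, 2, 2] <- 2L
  dep2 <- radsurv:::.cpp_dependence_counts(iso)
  expect_equal(dep2[2, 2, 2], 0L)

  for (seed in c(1, 6)) {
    d <- random_voi(seed, dm = c(5, 5, 3), ng = 4)
    expect_identical(as.vector(radsurv:::.cpp_dependence_counts(d$levels)),
                     as.vector(oracle_dependence(d$levels)))
    # feature value from the oracle's counts
    dep_o <- oracle_dependence(d$levels)
    k <- dep_o[d$levels > 0]; g <- d$levels[d$levels > 0]
    f <- ngldm_features(d)
    expect_equal(unname(f["high_dependence_high_gray_level_emphasis"]),
                 mean(k^2 * as.numeric(g)^2), tolerance = 1e-9)
  }
})

test_that("texture probability matrices are normalized and nonnegative", {
  d <- random_voi(21, dm = c(6, 6, 4), ng = 5)
  p <- radsurv:::.cpp_glcm(d$levels, 5)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("texture features are invariant to affine intensity rescaling", {
  set.seed(31)
  arr <- array(rnorm(6 * 6 * 4, 100, 15), c(6, 6, 4))
  m <- full_mask(c(6, 6, 4))
  v1 <- image_volume(arr, c(1, 1, 1))
  v2 <- image_volume(2.7 * arr + 300, c(1, 1, 1))
  f1 <- glcm_features(discretize(v1, m, 8))
  f2 <- glcm_features(discretize(v2, m, 8))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("extract_all produces exactly the published signature ids and handles degenerate phases", {
  ph <- phantom_spec(grid_shape = c(32, 32, 16), semi_axes_mm = c(9, 8, 7),
                     seed = 13)
  tv <- generate_tumor_volume(ph)
  fv <- extract_all(tv$volume, NULL, tv$mask, signature_registry())
  def <- published_rscore()
  expect_identical(names(fv), def$terms$feature_id)
  expect_true(all(is.finite(fv)))

  # identical phases give identical non-morph features
  reg2 <- feature_registry(phases = c("AP", "PVP"),
                           families = c("firstorder", "glcm"))
  fb <- extract_all(tv$volume, tv$volume, tv$mask, reg2)
  ap <- fb[grep("^AP", names(fb))]
  pvp <- fb[grep("^PVP", names(fb))]
  expect_equal(unname(ap), unname(pvp), tolerance = 1e-12)
})

test_that("a homogeneous phantom yields zero texture on the raw image", {
  ph <- phantom_spec(grid_shape = c(24, 24, 12), semi_axes_mm = c(8, 7, 6),
                     heterogeneity = list(corr_length_mm = 3,
                                          amplitude_hu = 0),
                     noise_sd_hu = 0, base_intensity_hu = 100, seed = 2)
  tv <- generate_tumor_volume(ph)
  d <- discretize(tv$volume, tv$mask, 32)
  f <- glcm_features(d)
  expect_equal(unname(f["joint_entropy"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["cluster_shade"]), 0)
})
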