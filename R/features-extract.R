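# Feature registry and whole-VOI extraction across phases and transforms.

#' Canonical feature identifiers
#'
#' Feature ids are `phase|transform|family|name`, e.g.
#' `AP|LOG|glcm|joint_entropy`. Morphologic features depend only on the mask
#' and use the phase token `MASK` with transform `N`.
#'
#' @param phase `"AP"`, `"PVP"` or `"MASK"`.
#' @param transform transform token (`"N"`, `"G"`, `"LOG"`, possibly
#'   suffixed with a scale when a registry holds several scales per filter).
#' @param family feature family.
#' @param name feature name within the family.
#' @return Character id.
#' @export
feature_id <- function(phase, transform, family, name) {
  paste(phase, transform, family, name, sep = "|")
}

#' Feature registry
#'
#' Declares which transforms and feature families are extracted per phase.
#' The default registry covers the raw image plus one Gaussian (1 mm) and one
#' Laplacian-of-Gaussian (2 mm) filtered variant of both contrast phases,
#' with all first-order and texture families, plus the mask-only morphologic
#' features.
#'
#' @param transforms list of [transform_tag()]s.
#' @param families character vector among `firstorder`, `glcm`, `glszm`,
#'   `gldzm`, `ngldm`.
#' @param phases character vector among `AP`, `PVP`.
#' @param include_morph logical; include mask-only morphologic features.
#' @param features optional named list restricting each family (and `morph`)
#'   to the given feature names.
#' @return A `feature_registry` list.
#' @export
feature_registry <- function(transforms = list(transform_tag("N"),
                                               transform_tag("G", 1.0),
                                               transform_tag("LOG", 2.0)),
                             families = c("firstorder", "glcm", "glszm",
                                          "gldzm", "ngldm"),
                             phases = c("AP", "PVP"),
                             include_morph = TRUE,
                             features = NULL) {
  families <- match.arg(families, several.ok = TRUE)
  phases <- match.arg(phases, c("AP", "PVP"), several.ok = TRUE)
  kinds <- vapply(transforms, function(t) t$kind, "")
  tokens <- kinds
  for (k in unique(kinds)) {
    w <- which(kinds == k)
    if (length(w) > 1L)
      tokens[w] <- paste0(k, vapply(transforms[w],
                                    function(t) format(t$sigma_mm), ""))
  }
  structure(list(transforms = transforms, tokens = tokens,
                 families = families, phases = phases,
                 include_morph = include_morph, features = features),
            class = "feature_registry")
}

#' Registry restricted to the published 15-feature signature
#'
#' The published radiomics signature uses arterial-phase features on the raw
#' (`N`), Gaussian (`G`) and Laplacian-of-Gaussian (`LOG`) images plus the
#' two mask-only morphologic features; this registry extracts exactly those
#' 15 features.
#'
#' @param sigma_g,sigma_log filter scales in mm for the Gaussian and
#'   Laplacian-of-Gaussian transforms.
#' @return A `feature_registry`.
#' @export
signature_registry <- function(sigma_g = 1.0, sigma_log = 2.0) {
  reg <- feature_registry(
    transforms = list(transform_tag("N"), transform_tag("G", sigma_g),
                      transform_tag("LOG", sigma_log)),
    families = c("firstorder", "glcm", "glszm", "gldzm", "ngldm"),
    phases = "AP", include_morph = TRUE)
  reg$signature_only <- TRUE
  reg
}

signature_feature_ids <- function() {
  c("MASK|N|morph|volume", "MASK|N|morph|flatness",
    "AP|N|firstorder|maximum", "AP|N|firstorder|percentile25",
    "AP|LOG|firstorder|median", "AP|LOG|firstorder|robust_mad",
    "AP|N|glcm|cluster_shade", "AP|N|glcm|difference_entropy",
    "AP|N|glcm|joint_entropy",
    "AP|N|glszm|large_zone_high_gray_level_emphasis",
    "AP|LOG|glcm|cluster_shade", "AP|LOG|glcm|contrast",
    "AP|LOG|glszm|zone_size_variance",
    "AP|G|gldzm|large_distance_high_gray_level_emphasis",
    "AP|LOG|ngldm|high_dependence_high_gray_level_emphasis")
}

family_fun <- function(family) {
  switch(family,
         glcm = glcm_features, glszm = glszm_features,
         gldzm = gldzm_features, ngldm = ngldm_features,
         stop("unknown family: ", family))
}

#' Extract all registered features for one subject
#'
#' Resamples the image/mask pair to the uniform grid, applies each registered
#' transform, discretizes the filtered intensities over the VOI, and computes
#' every registered feature family per phase. Ordering and naming are
#' deterministic; the result is a named numeric vector keyed by canonical
#' feature ids.
#'
#' @param volume_ap,volume_pvp arterial- and portal-venous-phase
#'   [image_volume()]s (pass `NULL` for a phase absent from the registry).
#' @param mask the shared [voi_mask()].
#' @param registry a [feature_registry()].
#' @param target_spacing uniform voxel size for resampling (mm); `NULL`
#'   skips resampling.
#' @param n_bins gray levels for discretization.
#' @return Named numeric feature vector.
#' @export
extract_all <- function(volume_ap, volume_pvp = NULL, mask,
                        registry = feature_registry(),
                        target_spacing = c(1, 1, 3), n_bins = 32L) {
  stopifnot(inherits(registry, "feature_registry"))
  vols <- list(AP = volume_ap, PVP = volume_pvp)
  out <- c()
  keep <- if (isTRUE(registry$signature_only)) signature_feature_ids()
          else NULL
  if (registry$include_morph) {
    m <- mask
    v0 <- vols[[registry$phases[1]]]
    if (!is.null(target_spacing)) {
      rs <- resample(v0, mask, target_spacing)
      m <- rs$mask
    }
    mf <- morph_features(m)
    if (!is.null(registry$features$morph))
      mf <- mf[names(mf) %in% registry$features$morph]
    names(mf) <- feature_id("MASK", "N", "morph", names(mf))
    out <- c(out, mf)
  }
  for (ph in registry$phases) {
    v <- vols[[ph]]
    if (is.null(v)) stop("registry requires phase ", ph,
                         " but no volume was given")
    msk <- mask
    if (!is.null(target_spacing)) {
      rs <- resample(v, mask, target_spacing)
      v <- rs$volume; msk <- rs$mask
    }
    for (ti in seq_along(registry$transforms)) {
      tag <- registry$transforms[[ti]]
      tok <- registry$tokens[ti]
      fv <- apply_transform(v, tag)
      dvoi <- NULL
      if ("firstorder" %in% registry$families) {
        fo <- firstorder_features(fv, msk)
        if (!is.null(registry$features$firstorder))
          fo <- fo[names(fo) %in% registry$features$firstorder]
        names(fo) <- feature_id(ph, tok, "firstorder", names(fo))
        out <- c(out, fo)
      }
      for (fam in setdiff(registry$families, "firstorder")) {
        if (is.null(dvoi)) dvoi <- discretize(fv, msk, n_bins)
        ff <- tryCatch(family_fun(fam)(dvoi), error = function(e)
          stop("feature family ", fam, " failed for ",
               feature_id(ph, tok, fam, "*"), ": ", conditionMessage(e)))
        if (!is.null(registry$features[[fam]]))
          ff <- ff[names(ff) %in% registry$features[[fam]]]
        names(ff) <- feature_id(ph, tok, fam, names(ff))
        out <- c(out, ff)
      }
    }
  }
  if (!is.null(keep)) out <- out[keep]
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Extract features for a list of subjects into a feature table
#'
#' @param subjects list of `list(ap =, pvp =, mask =)` per subject (as
#'   produced by [generate_cohort()]).
#' @param subject_ids character vector of ids.
#' @inheritParams extract_all
#' @return data.frame with `subject_id` and one column per feature id.
#' @export
extract_cohort_features <- function(subjects, subject_ids = NULL,
                                    registry = feature_registry(),
                                    target_spacing = c(1, 1, 3),
                                    n_bins = 32L) {
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d",
                                                   seq_along(subjects))
  rows <- lapply(subjects, function(s)
    extract_all(s$ap, s$pvp, s$mask, registry, target_spacing, n_bins))
  tab <- do.call(rbind, rows)
  df <- data.frame(subject_id = subject_ids, tab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
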