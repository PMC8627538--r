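#' Simulate a synthetic multi-lesion cohort
#'
#' Draws a cohort of patients, each carrying one or more lesions, directly in
#' radiomic feature space. Per patient a latent phenotype archetype is drawn;
#' each lesion's feature vector is the archetype mean, plus an additive
#' site-class shift, plus spherical Gaussian within-patient noise of sd
#' `sigma_within` (optionally growing with the patient's lesion count).
#' SUVmax is drawn from the per-site lognormal law, optionally coupled to the
#' archetype. Clinical covariates (age, Gleason score, PSA, ADT status,
#' primary treatment) are drawn with realistic marginals so the clinical
#' splits downstream are exercised.
#'
#' @param config a [cohort_config()] object.
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{cohort_table}{per-patient clinical data.frame
#'       (`patient_id`, `age`, `gleason`, `psa_ng_ml`, `adt_status`,
#'       `primary_treatment`, `n_lesions`).}
#'     \item{lesion_table}{per-lesion data.frame (`lesion_id`, `patient_id`,
#'       `site_class`, `suv_max`).}
#'     \item{feature_table}{lesion metadata plus one numeric column per
#'       feature axis — the pipeline's central exchange object.}
#'     \item{truth}{latent ground truth: per-patient archetype id, archetype
#'       means, site effects, and per-lesion noise-free phenotype vectors.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 10, seed = 7))
#' nrow(cohort$feature_table)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  with_seed(config$seed, {
    n <- as.integer(config$n_patients)
    d <- length(config$feature_names)
    counts_support <- as.integer(names(config$lesion_count_law))
    n_lesions <- counts_support[sample.int(length(counts_support), n,
                                           replace = TRUE,
                                           prob = config$lesion_count_law)]

    # archetype assignment: distinct phenotypes when there are enough of them
    if (config$n_archetypes >= n) {
      archetype <- sample.int(config$n_archetypes, n, replace = FALSE)
    } else {
      archetype <- sample.int(config$n_archetypes, n, replace = TRUE)
    }
    arch_means <- matrix(stats::rnorm(config$n_archetypes * d,
                                      sd = config$sigma_between),
                         nrow = config$n_archetypes,
                         dimnames = list(NULL, config$feature_names))
    site_eff <- matrix(stats::rnorm(3 * d) * config$site_effect_scale,
                       nrow = 3, dimnames = list(SITE_CLASSES,
                                                 config$feature_names))

    patient_id <- sprintf("P%03d", seq_len(n))
    age <- round(pmin(pmax(stats::rnorm(n, 72, 7), 50), 90), 1)
    gleason <- sample(5:9, n, replace = TRUE,
                      prob = c(0.05, 0.15, 0.43, 0.22, 0.15))
    psa <- round(stats::rlnorm(n, meanlog = log(1.5) +
                                 config$psa_count_coupling * n_lesions,
                               sdlog = 1.1), 2)
    adt <- sample(c("ON", "OFF"), n, replace = TRUE, prob = c(0.36, 0.64))
    trt <- sample(c("RP", "RP+RT", "RT", "other"), n, replace = TRUE,
                  prob = c(0.25, 0.565, 0.098, 0.087))

    cohort_table <- data.frame(patient_id = patient_id, age = age,
                               gleason = gleason, psa_ng_ml = psa,
                               adt_status = adt, primary_treatment = trt,
                               n_lesions = n_lesions,
                               stringsAsFactors = FALSE)

    total <- sum(n_lesions)
    les_patient <- rep(patient_id, n_lesions)
    les_arch <- rep(archetype, n_lesions)
    les_count <- rep(n_lesions, n_lesions)
    site <- sample(SITE_CLASSES, total, replace = TRUE,
                   prob = config$site_probs[SITE_CLASSES])
    # dispersion grows with burden but saturates above ~4 lesions, so the
    # low-burden/high-burden contrast concentrates at small lesion counts
    sigma_w <- config$sigma_within *
      (1 + config$within_count_slope * pmin(les_count - 1, 3))

    phenotype <- arch_means[les_arch, , drop = FALSE] +
      site_eff[site, , drop = FALSE]
    noise <- matrix(stats::rnorm(total * d), nrow = total) * sigma_w
    feats <- phenotype + noise

    # patient-level metabolic trait: part of the latent phenotype, shared by
    # a patient's lesions, so SUVmax tertiles group whole patients when
    # suv_coupling > 0 (metabolically homogeneous slicings then compare each
    # patient against fewer, metabolically comparable competitors)
    metab <- stats::rnorm(n)
    score <- rep(metab, n_lesions)
    ml <- vapply(site, function(s) config$suv_law[[s]][1], numeric(1))
    sl <- vapply(site, function(s) config$suv_law[[s]][2], numeric(1))
    suv <- stats::rlnorm(total, meanlog = ml + config$suv_coupling * score,
                         sdlog = sl)

    lesion_id <- sprintf("%s_L%02d", les_patient,
                         unlist(lapply(n_lesions, seq_len), use.names = FALSE))
    lesion_table <- data.frame(lesion_id = lesion_id,
                               patient_id = les_patient,
                               site_class = site, suv_max = suv,
                               stringsAsFactors = FALSE)
    feature_table <- cbind(lesion_table,
                           as.data.frame(feats,
                                         col.names = config$feature_names))
    names(feature_table)[-(1:4)] <- config$feature_names

    out <- list(cohort_table = cohort_table, lesion_table = lesion_table,
                feature_table = feature_table,
                truth = list(archetype = stats::setNames(archetype, patient_id),
                             metabolic_trait = stats::setNames(metab,
                                                               patient_id),
                             archetype_means = arch_means,
                             site_effects = site_eff,
                             phenotype = phenotype),
                config = config)
    class(out) <- "synthetic_cohort"
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic lesion cohort\n")
  cat(sprintf("  patients: %d   lesions: %d   feature axes: %d\n",
              nrow(x$cohort_table), nrow(x$lesion_table),
              length(x$config$feature_names)))
  cat("  sites:",
      paste(sprintf("%s=%d", names(table(x$lesion_table$site_class)),
                    table(x$lesion_table$site_class)), collapse = "  "), "\n")
  invisible(x)
}

#' Generate one synthetic PET-like lesion volume and mask
#'
#' Builds an ellipsoidal binary VOI on an isotropic-by-axis grid and fills it
#' with a correlated Gaussian random field: white noise smoothed with a
#' Gaussian kernel of the requested correlation length, rescaled to the
#' archetype's intensity sd, shifted to the mean SUV and clipped at zero.
#' Background voxels are zero. This gives non-trivial grey-level texture with
#' two interpretable knobs (variance and correlation length).
#'
#' @param texture list with `mean_suv`, `sd_suv`, `corr_length_mm`.
#' @param radius_mm ellipsoid semi-axes in mm (length 1 or 3).
#' @param spacing_mm voxel spacing in mm (length 1 or 3).
#' @param seed RNG seed.
#' @param margin_vox background margin around the ellipsoid, in voxels.
#' @return list with `volume` (3-D array, SUV-like), `mask` (0/1 array of the
#'   same dimensions) and `spacing_mm`.
#' @export
generate_lesion_volume <- function(texture, radius_mm, spacing_mm = c(2, 2, 2),
                                   seed = NULL, margin_vox = 2) {
  radius_mm <- rep_len(radius_mm, 3L)
  spacing_mm <- rep_len(spacing_mm, 3L)
  span_vox <- floor(2 * radius_mm / spacing_mm) + 1
  if (any(span_vox < 3))
    rh_stop("degenerate_voi",
            "VOI spans fewer than 3 voxels along axis %d (span %d)",
            which.min(span_vox), min(span_vox))
  dims <- as.integer(span_vox + 2 * margin_vox)
  centre <- (dims + 1) / 2
  ax <- lapply(1:3, function(k) ((seq_len(dims[k]) - centre[k]) *
                                   spacing_mm[k] / radius_mm[k])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  mask <- array(as.integer(r2 <= 1), dim = dims)
  with_seed(seed, {
    field <- array(stats::rnorm(prod(dims)), dim = dims)
    sigma_vox <- texture$corr_length_mm / spacing_mm
    field <- gaussian_smooth3d(field, sigma_vox)
    s <- stats::sd(as.vector(field))
    if (s > 0 && texture$sd_suv > 0) {
      field <- field / s * texture$sd_suv
    } else field <- array(0, dim = dims)
    vol <- pmax(field + texture$mean_suv, 0) * mask
    list(volume = array(vol, dim = dims), mask = mask, spacing_mm = spacing_mm)
  })
}

# separable Gaussian smoothing of a 3-D array (reflecting edges)
gaussian_smooth3d <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    arr <- apply_along(arr, axis, function(v) conv_reflect(v, k))
  }
  arr
}

conv_reflect <- function(v, k) {
  half <- (length(k) - 1L) / 2L
  n <- length(v)
  idx <- c(rev(seq_len(min(half, n))), seq_len(n),
           n + 1 - rev(seq_len(min(half, n))))
  # if half > n the reflection above is short; pad by clamping
  pad <- c(pmin(pmax(idx, 1L), n))
  vp <- v[pad]
  out <- stats::filter(vp, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# apply a vector function along one axis of a 3-D array, preserving dims
apply_along <- function(arr, axis, f) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- apply(m, 2, f)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

#' Attach synthetic volumes to a cohort
#'
#' Generates one PET-like volume+mask pair per lesion of `cohort`, deriving
#' the texture law from the lesion's latent phenotype: mean SUV from the
#' drawn SUVmax and texture variance/correlation length modulated by the
#' patient archetype. Used to exercise the extraction pipeline end to end.
#'
#' @param cohort a `synthetic_cohort`.
#' @param spacing_mm voxel spacing for all volumes.
#' @param radius_range_mm range of ellipsoid semi-axes to draw from.
#' @return the cohort with a `volumes` element (named list per lesion_id).
#' @export
simulate_cohort_volumes <- function(cohort, spacing_mm = c(2, 2, 2),
                                    radius_range_mm = c(6, 14)) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  lt <- cohort$lesion_table
  arch <- cohort$truth$archetype[lt$patient_id]
  with_seed(cohort$config$seed + 1L, {
    vols <- vector("list", nrow(lt))
    names(vols) <- lt$lesion_id
    for (i in seq_len(nrow(lt))) {
      tex <- list(mean_suv = lt$suv_max[i] * 0.7,
                  sd_suv = 0.15 * lt$suv_max[i] * (1 + 0.3 * (arch[i] %% 3)),
                  corr_length_mm = 2 + 1.5 * (arch[i] %% 2))
      r <- stats::runif(3, radius_range_mm[1], radius_range_mm[2])
      vols[[i]] <- generate_lesion_volume(tex, r, spacing_mm,
                                          seed = NULL)
    }
    cohort$volumes <- vols
  })
  cohort
}
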