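#' Synthetic cohort configuration
#'
#' Builds and validates the parameter set controlling [simulate_cohort()].
#' The defaults emulate the shape of a recurrent prostate-cancer choline-PET
#' cohort: 92 patients carrying a mix of single- and multi-lesion disease,
#' lesion sites split roughly 18/22/60% between regional lymph nodes, distant
#' lymph nodes and bone, and per-site lognormal SUVmax laws.
#'
#' Each patient is assigned a latent phenotype archetype; lesion feature
#' vectors are the archetype mean plus an additive site-specific shift plus
#' spherical Gaussian within-patient noise. The ratio
#' `sigma_within / sigma_between` is the single knob that controls
#' intra-patient lesion cohesion, which is what the downstream silhouette
#' analysis measures.
#'
#' @param n_patients number of patients.
#' @param lesion_count_law named numeric vector of probabilities over
#'   per-patient lesion counts; names are the counts (positive integers).
#' @param site_probs probabilities over the three site classes
#'   `REGIONAL_LN`, `DISTANT_LN`, `BONE` (named, sum to 1).
#' @param n_archetypes number of latent phenotype archetypes. When
#'   `n_archetypes >= n_patients` archetypes are assigned without replacement
#'   (each patient gets its own phenotype); otherwise patients share
#'   archetypes, drawn with replacement.
#' @param sigma_between between-archetype dispersion per feature axis.
#' @param sigma_within within-patient lesion dispersion per feature axis.
#' @param site_effect_scale magnitude of the additive site-specific feature
#'   shift.
#' @param suv_law per-site lognormal SUVmax parameters: a named list with one
#'   `c(meanlog, sdlog)` entry per site class.
#' @param suv_coupling strength of the coupling between a patient-level
#'   latent metabolic trait (standard normal, part of the generated truth)
#'   and lesion SUVmax (added to the lognormal `meanlog`). Positive values
#'   make a patient's lesions metabolically alike, so SUVmax tertiles group
#'   whole patients. 0 disables the coupling.
#' @param within_count_slope relative growth of within-patient dispersion
#'   with tumour burden: a patient with `n` lesions uses
#'   `sigma_within * (1 + within_count_slope * min(n - 1, 3))`, i.e. the
#'   dispersion saturates above four lesions so the burden contrast
#'   concentrates at low lesion counts. 0 (default) keeps dispersion
#'   independent of burden.
#' @param psa_count_coupling additive shift of the PSA `meanlog` per lesion;
#'   the default reproduces the clinical pattern of higher PSA under higher
#'   tumour burden.
#' @param feature_names names of the generated feature axes; defaults to the
#'   42-feature extraction roster so synthetic feature tables are
#'   plug-compatible with extracted ones.
#' @param seed RNG seed; all randomness in [simulate_cohort()] flows from it.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_patients = 92,
                          lesion_count_law = default_count_law(),
                          site_probs = c(REGIONAL_LN = 68, DISTANT_LN = 81,
                                         BONE = 221) / 370,
                          n_archetypes = 8,
                          sigma_between = 1,
                          sigma_within = 1,
                          site_effect_scale = 0.5,
                          suv_law = default_suv_law(),
                          suv_coupling = 0,
                          within_count_slope = 0,
                          psa_count_coupling = 0.15,
                          feature_names = default_feature_roster(),
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, lesion_count_law = lesion_count_law,
              site_probs = site_probs, n_archetypes = n_archetypes,
              sigma_between = sigma_between, sigma_within = sigma_within,
              site_effect_scale = site_effect_scale, suv_law = suv_law,
              suv_coupling = suv_coupling,
              within_count_slope = within_count_slope,
              psa_count_coupling = psa_count_coupling,
              feature_names = feature_names, seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) rh_stop("config_error", "invalid '%s': %s", field, why)
  chk(is.numeric(cfg$n_patients) && length(cfg$n_patients) == 1 &&
        cfg$n_patients >= 1, "n_patients", "must be a positive count")
  law <- cfg$lesion_count_law
  chk(is.numeric(law) && !is.null(names(law)) && all(law >= 0) &&
        abs(sum(law) - 1) < 1e-9, "lesion_count_law",
      "must be named probabilities summing to 1")
  counts <- suppressWarnings(as.integer(names(law)))
  chk(!anyNA(counts) && all(counts >= 1), "lesion_count_law",
      "support must be positive integer lesion counts")
  sp <- cfg$site_probs
  chk(is.numeric(sp) && setequal(names(sp), SITE_CLASSES) &&
        all(sp >= 0) && abs(sum(sp) - 1) < 1e-9, "site_probs",
      "must be probabilities over REGIONAL_LN/DISTANT_LN/BONE summing to 1")
  chk(cfg$n_archetypes >= 1, "n_archetypes", "must be >= 1")
  chk(is.numeric(cfg$sigma_between) && cfg$sigma_between >= 0,
      "sigma_between", "must be >= 0")
  chk(is.numeric(cfg$sigma_within) && cfg$sigma_within >= 0,
      "sigma_within", "must be >= 0")
  chk(is.numeric(cfg$site_effect_scale) && cfg$site_effect_scale >= 0,
      "site_effect_scale", "must be >= 0")
  chk(is.list(cfg$suv_law) && all(SITE_CLASSES %in% names(cfg$suv_law)),
      "suv_law", "must name all three site classes")
  for (s in SITE_CLASSES)
    chk(length(cfg$suv_law[[s]]) == 2 && cfg$suv_law[[s]][2] >= 0,
        "suv_law", sprintf("entry '%s' must be c(meanlog, sdlog>=0)", s))
  chk(cfg$within_count_slope >= 0, "within_count_slope", "must be >= 0")
  chk(length(cfg$feature_names) >= 1 && !anyDuplicated(cfg$feature_names),
      "feature_names", "must be non-empty and unique")
  invisible(cfg)
}

#' Default per-patient lesion-count law
#'
#' Probabilities over lesion counts 1..9 chosen so realized cohorts carry a
#' realistic mix of single-lesion patients (about 37%), a 2-3 lesion band,
#' a 4-5 lesion band and a plurimetastatic tail, with roughly four lesions
#' per patient on average — the burden mix of a recurrent-PCa PET cohort in
#' which roughly 45% of patients are oligometastatic under a 3-lesion
#' threshold and two thirds under a 5-lesion threshold.
#'
#' @return named probability vector.
#' @export
default_count_law <- function() {
  law <- c(`1` = 0.37, `2` = 0.05, `3` = 0.05, `4` = 0.10, `5` = 0.10,
           `6` = 0.09, `7` = 0.08, `8` = 0.08, `9` = 0.08)
  law / sum(law)
}

#' Default per-site SUVmax lognormal law
#'
#' Choline-avid nodal recurrences typically sit at SUVmax 3-6 and bone
#' lesions somewhat higher; the defaults encode that ordering.
#'
#' @return named list of `c(meanlog, sdlog)` per site class.
#' @export
default_suv_law <- function() {
  list(REGIONAL_LN = c(meanlog = log(4.0), sdlog = 0.50),
       DISTANT_LN  = c(meanlog = log(4.5), sdlog = 0.50),
       BONE        = c(meanlog = log(5.5), sdlog = 0.55))
}
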