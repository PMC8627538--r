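#' Extract the full radiomic feature vector from one VOI
#'
#' Runs the whole per-lesion pipeline: resampling to the isotropic target
#' grid, grey-level discretization, then all six feature families (shape,
#' first-order, GLCM, GLRLM, NGLDM, GLZLM). Returns exactly the roster's
#' features in roster order; with the default roster that is 42 values.
#'
#' @param volume 3-D SUV array.
#' @param mask 3-D 0/1 array on the same grid.
#' @param spacing_mm input voxel spacing in mm.
#' @param config an [extraction_config()].
#' @param lesion_id optional id attached to error messages and the result.
#' @return object of class `feature_vector`: named numeric vector in roster
#'   order, with attributes `lesion_id` and `suv_max` (max in-mask SUV after
#'   resampling).
#' @examples
#' v <- generate_lesion_volume(list(mean_suv = 5, sd_suv = 1,
#'                                  corr_length_mm = 3),
#'                             radius_mm = 8, spacing_mm = 2, seed = 1)
#' fv <- extract_features(v$volume, v$mask, v$spacing_mm)
#' length(fv)  # 42
#' @export
extract_features <- function(volume, mask, spacing_mm,
                             config = extraction_config(),
                             lesion_id = NULL) {
  run <- function() {
      rs <- resample_voi(volume, mask, spacing_mm, config)
      voi <- discretize_voi(rs$volume, rs$mask, rs$spacing_mm, config)
      vals <- c(shape_features(rs$mask, rs$spacing_mm),
                first_order_features(voi),
                glcm_features(glcm_matrix(voi)),
                glrlm_features(voi),
                ngldm_features(voi),
                glzlm_features(voi))
      missing <- setdiff(config$feature_roster, names(vals))
      if (length(missing))
        rh_stop("config_error", "unknown roster feature(s): %s",
                paste(missing, collapse = ", "))
      out <- vals[config$feature_roster]
      attr(out, "lesion_id") <- lesion_id
      attr(out, "suv_max") <- max(voi$raw_suv)
      class(out) <- c("feature_vector", class(out))
      out
  }
  if (is.null(lesion_id)) return(run())
  tryCatch(run(), radiohet_error = function(e)
    rh_stop(sub("^radiohet_", "", class(e)[1]),
            "lesion %s: %s", lesion_id, conditionMessage(e)))
}

#' Extract features for every lesion volume of a cohort
#'
#' @param cohort a `synthetic_cohort` carrying `volumes` (see
#'   [simulate_cohort_volumes()]), or a named list of
#'   `list(volume, mask, spacing_mm)` plus a lesion table.
#' @param config an [extraction_config()].
#' @return a feature table data.frame: `lesion_id`, `patient_id`,
#'   `site_class`, `suv_max` plus one column per roster feature.
#' @export
extract_cohort_features <- function(cohort, config = extraction_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$volumes))
    rh_stop("input_error", "cohort has no volumes; run simulate_cohort_volumes()")
  lt <- cohort$lesion_table
  rows <- lapply(seq_len(nrow(lt)), function(i) {
    v <- cohort$volumes[[lt$lesion_id[i]]]
    fv <- extract_features(v$volume, v$mask, v$spacing_mm, config,
                           lesion_id = lt$lesion_id[i])
    c(list(lesion_id = lt$lesion_id[i], patient_id = lt$patient_id[i],
           site_class = lt$site_class[i], suv_max = attr(fv, "suv_max")),
      as.list(unclass(fv)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}
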