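# Table schemas: header-keyed comma-delimited text throughout, written with
# data.table::fwrite (shortest round-trip doubles) so read(write(t)) == t.

COHORT_COLS <- c("patient_id", "age", "gleason", "psa_ng_ml", "adt_status",
                 "primary_treatment")
LESION_COLS <- c("lesion_id", "patient_id", "site_class", "suv_max")

write_table <- function(df, path) {
  data.table::fwrite(df, path)
  invisible(path)
}

read_table <- function(path) {
  if (!file.exists(path)) rh_stop("io_error", "file not found: %s", path)
  as.data.frame(data.table::fread(path, stringsAsFactors = FALSE))
}

#' Read and validate a cohort table
#'
#' @param path CSV with the patient schema (`patient_id`, `age`, `gleason`,
#'   `psa_ng_ml`, `adt_status`, `primary_treatment`, optional `n_lesions`);
#'   column order is irrelevant (header-keyed).
#' @param lesions optional lesion table (data.frame or path) to check
#'   referential integrity against.
#' @return validated data.frame.
#' @export
read_cohort_table <- function(path, lesions = NULL) {
  df <- read_table(path)
  validate_cohort_df(df)
  if (!is.null(lesions)) {
    if (is.character(lesions)) lesions <- read_lesion_table(lesions)
    dangling <- setdiff(lesions$patient_id, df$patient_id)
    if (length(dangling))
      rh_stop("validation_error", "dangling patient_id in lesion table: %s",
              paste(utils::head(dangling, 5), collapse = ", "))
  }
  df
}

validate_cohort_df <- function(df) {
  miss <- setdiff(COHORT_COLS, names(df))
  if (length(miss))
    rh_stop("validation_error", "cohort table missing column(s): %s",
            paste(miss, collapse = ", "))
  bad <- which(df$psa_ng_ml < 0)
  if (length(bad))
    rh_stop("validation_error", "negative PSA at row %d", bad[1])
  if (anyDuplicated(df$patient_id))
    rh_stop("validation_error", "duplicated patient_id")
  invisible(df)
}

#' Read and validate a lesion table
#'
#' @param path CSV with columns `lesion_id`, `patient_id`, `site_class`,
#'   `suv_max`.
#' @return validated data.frame.
#' @export
read_lesion_table <- function(path) {
  df <- read_table(path)
  miss <- setdiff(LESION_COLS, names(df))
  if (length(miss))
    rh_stop("validation_error", "lesion table missing column(s): %s",
            paste(miss, collapse = ", "))
  bad <- which(!df$site_class %in% SITE_CLASSES)
  if (length(bad))
    rh_stop("validation_error",
            "unknown site_class '%s' at row %d (column site_class)",
            df$site_class[bad[1]], bad[1])
  df
}

#' Read a feature table
#'
#' @param path CSV with `lesion_id`, `patient_id`, `site_class`, `suv_max`
#'   plus numeric feature columns.
#' @return validated data.frame.
#' @export
read_feature_table <- function(path) {
  df <- read_table(path)
  miss <- setdiff(c("lesion_id", "patient_id"), names(df))
  if (length(miss))
    rh_stop("validation_error", "feature table missing column(s): %s",
            paste(miss, collapse = ", "))
  if ("site_class" %in% names(df)) {
    bad <- which(!df$site_class %in% SITE_CLASSES)
    if (length(bad))
      rh_stop("validation_error",
              "unknown site_class '%s' at row %d", df$site_class[bad[1]],
              bad[1])
  }
  df
}

#' Write a feature table
#' @param features feature table data.frame.
#' @param path output CSV path.
#' @export
write_feature_table <- function(features, path) write_table(features, path)

#' Write a cohort (tables, optional volumes, manifest) to a directory
#'
#' Tables go out as comma-delimited text, volumes and masks (when present)
#' as NIfTI pairs, and a `manifest.yaml` lists every file with its MD5
#' checksum so a run is traceable.
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest (named list).
#' @export
write_cohort <- function(cohort, directory) {
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    rh_stop("io_error", "cannot create directory %s", directory)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(directory, name)
    write_table(df, p)
    files <<- c(files, name)
  }
  wr(cohort$cohort_table, "patients.csv")
  wr(cohort$lesion_table, "lesions.csv")
  if (!is.null(cohort$feature_table)) wr(cohort$feature_table, "features.csv")
  if (!is.null(cohort$volumes)) {
    for (id in names(cohort$volumes)) {
      v <- cohort$volumes[[id]]
      pv <- file.path(directory, sprintf("%s_pet.nii.gz", id))
      pm <- file.path(directory, sprintf("%s_mask.nii.gz", id))
      RNifti::writeNifti(RNifti::asNifti(v$volume,
                                         pixdim = v$spacing_mm), pv)
      RNifti::writeNifti(RNifti::asNifti(v$mask, pixdim = v$spacing_mm), pm)
      files <- c(files, basename(pv), basename(pm))
    }
  }
  sums <- as.list(tools::md5sum(file.path(directory, files)))
  names(sums) <- files
  manifest <- list(n_patients = nrow(cohort$cohort_table),
                   n_lesions = nrow(cohort$lesion_table),
                   seed = cohort$config$seed %||% NA,
                   files = sums)
  yaml::write_yaml(manifest, file.path(directory, "manifest.yaml"))
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory the cohort directory.
#' @param volumes read NIfTI volume/mask pairs too?
#' @return list with `cohort_table`, `lesion_table`, `feature_table`
#'   (NULL when absent), `manifest`, and optionally `volumes`.
#' @export
read_cohort <- function(directory, volumes = FALSE) {
  mf <- file.path(directory, "manifest.yaml")
  if (!file.exists(mf)) rh_stop("io_error", "no manifest at %s", mf)
  manifest <- yaml::read_yaml(mf)
  lesions <- read_lesion_table(file.path(directory, "lesions.csv"))
  out <- list(
    cohort_table = read_cohort_table(file.path(directory, "patients.csv"),
                                     lesions = lesions),
    lesion_table = lesions,
    feature_table = if (file.exists(file.path(directory, "features.csv")))
      read_feature_table(file.path(directory, "features.csv")),
    manifest = manifest)
  if (volumes) {
    vids <- lesions$lesion_id
    out$volumes <- lapply(stats::setNames(vids, vids), function(id) {
      v <- RNifti::readNifti(file.path(directory,
                                       sprintf("%s_pet.nii.gz", id)))
      m <- RNifti::readNifti(file.path(directory,
                                       sprintf("%s_mask.nii.gz", id)))
      list(volume = array(as.numeric(v), dim = dim(v)),
           mask = array(as.integer(m), dim = dim(m)),
           spacing_mm = RNifti::pixdim(v))
    })
  }
  out
}

#' Write / read a run configuration (lossless YAML round-trip)
#'
#' @param config nested list of stage configurations plus `seed`,
#'   `out_dir`.
#' @param path YAML path.
#' @return `read_run_config` returns the list; `write_run_config` the path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rh_stop("io_error", "config not found: %s", path)
  yaml::read_yaml(path)
}

#' Write a silhouette report as structured text
#'
#' Per-lesion values, per-patient means with excluded flags, and the cohort
#' mean index for one slicing.
#'
#' @param result a `silhouette_result` or `lesion_similarity` fit.
#' @param path output YAML path.
#' @export
write_report <- function(result, path) {
  if (inherits(result, "lesion_similarity")) {
    rep <- list(
      patient_based = report_one(result$patient),
      anatomy_based = lapply(result$anatomy, report_one),
      metabolism_based = lapply(result$metabolism, report_one),
      paired_tests = if (!is.null(result$paired))
        lapply(seq_len(nrow(result$paired)),
               function(i) as.list(result$paired[i, ])))
  } else rep <- report_one(result)
  yaml::write_yaml(rep, path, precision = 15)
  invisible(path)
}

report_one <- function(sr) {
  list(slicing = sr$slicing, mean_index = sr$mean_index,
       per_patient = lapply(seq_len(nrow(sr$per_patient)), function(i)
         as.list(sr$per_patient[i, ])),
       per_lesion = lapply(seq_len(nrow(sr$per_lesion)), function(i)
         as.list(sr$per_lesion[i, ])))
}
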