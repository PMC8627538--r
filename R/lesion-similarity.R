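#' Intra-patient lesion similarity analysis
#'
#' The package's central fit: given a lesion feature table it embeds the
#' lesions in a standardized feature space, computes per-lesion silhouette
#' values with patients as groups (patient-based analysis), and — when the
#' metadata allow — repeats the computation restricted to each anatomical
#' site class (anatomy-based analysis) and to each SUVmax tertile
#' (metabolism-based analysis), each restriction independently re-embedded.
#' Each restricted slicing is compared to the patient-based result with a
#' paired t-test on per-patient means.
#'
#' A silhouette near 1 means a patient's lesions cluster tightly relative
#' to other patients' lesions; negative values mean lesions sit closer to
#' other patients' lesions than to their sibling lesions — high
#' intra-patient heterogeneity. Single-lesion patients are set to zero and
#' excluded from every cohort mean.
#'
#' @param features feature table data.frame: `lesion_id`, `patient_id`,
#'   optional `site_class` and `suv_max`, plus numeric feature columns.
#' @param slicings subset of `c("patient", "anatomy", "metabolism")`.
#' @param method embedding method, `"zscore"` (default) or `"pca"`.
#' @param d PCA dimension (see [embed_features()]).
#' @return object of class `lesion_similarity`: list with `embedding`,
#'   `patient` (a `silhouette_result`), `anatomy` and `metabolism` (named
#'   lists of `silhouette_result`s, possibly empty), `paired` (data.frame
#'   of paired t-tests of each restricted slicing against the patient-based
#'   one), and `call`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 15, seed = 2))
#' fit <- lesion_similarity(cohort$feature_table)
#' fit$patient$mean_index
#' @export
lesion_similarity <- function(features,
                              slicings = c("patient", "anatomy",
                                           "metabolism"),
                              method = c("zscore", "pca"), d = NULL) {
  method <- match.arg(method)
  slicings <- match.arg(slicings, several.ok = TRUE)
  if (!all(c("lesion_id", "patient_id") %in% names(features)))
    rh_stop("input_error", "features must carry lesion_id and patient_id")
  emb <- embed_features(features, method = method, d = d)
  pl <- lesion_silhouettes(emb$coordinates, features$patient_id)
  patient_res <- patient_silhouette(pl, slicing = "ALL")

  anatomy <- list(); metabolism <- list(); paired <- NULL
  if ("anatomy" %in% slicings && "site_class" %in% names(features)) {
    for (site in intersect(SITE_CLASSES, unique(features$site_class))) {
      res <- tryCatch(anatomy_silhouette(features, site, method, d),
                      radiohet_silhouette_undefined = function(e) NULL)
      if (!is.null(res)) anatomy[[site]] <- res
    }
  }
  if ("metabolism" %in% slicings && "suv_max" %in% names(features)) {
    tert <- suv_tertiles(features$suv_max)
    for (t in sort(unique(tert))) {
      res <- tryCatch(metabolism_silhouette(features, t, method, d),
                      radiohet_silhouette_undefined = function(e) NULL)
      if (!is.null(res)) metabolism[[paste0("T", t)]] <- res
    }
  }
  restricted <- c(anatomy, metabolism)
  if (length(restricted)) {
    paired <- do.call(rbind, lapply(names(restricted), function(nm) {
      pt <- tryCatch(paired_slicing_test(patient_res, restricted[[nm]]),
                     radiohet_test_undefined = function(e) NULL)
      if (is.null(pt)) return(NULL)
      data.frame(slicing = restricted[[nm]]$slicing, t = pt$t, df = pt$df,
                 p = pt$p, n_pairs = pt$n_pairs, mean_diff = pt$mean_diff,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(embedding = emb, patient = patient_res, anatomy = anatomy,
                 metabolism = metabolism, paired = paired,
                 call = match.call()),
            class = "lesion_similarity")
}

#' @export
print.lesion_similarity <- function(x, digits = 4, ...) {
  cat("Intra-patient lesion similarity analysis\n")
  pp <- x$patient$per_patient
  cat(sprintf("  lesions: %d   patients: %d (%d single-lesion, excluded)\n",
              nrow(x$patient$per_lesion), nrow(pp), sum(pp$excluded)))
  cat(sprintf("  patient-based mean similarity index: %s\n",
              format(x$patient$mean_index, digits = digits)))
  for (nm in names(x$anatomy))
    cat(sprintf("  anatomy-based  [%s]: %s\n", nm,
                format(x$anatomy[[nm]]$mean_index, digits = digits)))
  for (nm in names(x$metabolism))
    cat(sprintf("  metabolism-based [%s]: %s\n", nm,
                format(x$metabolism[[nm]]$mean_index, digits = digits)))
  invisible(x)
}

#' @export
summary.lesion_similarity <- function(object, ...) {
  out <- list(
    mean_index = object$patient$mean_index,
    per_patient = object$patient$per_patient,
    slicing_means = c(
      ALL = object$patient$mean_index,
      vapply(object$anatomy, `[[`, numeric(1), "mean_index"),
      vapply(object$metabolism, `[[`, numeric(1), "mean_index")),
    paired = object$paired,
    dropped_features = object$embedding$dropped)
  class(out) <- "summary.lesion_similarity"
  out
}

#' @export
print.summary.lesion_similarity <- function(x, digits = 4, ...) {
  cat("Cohort mean similarity index per slicing:\n")
  print(round(x$slicing_means, digits))
  if (!is.null(x$paired)) {
    cat("\nPaired t-tests (restricted slicing vs patient-based):\n")
    print(x$paired, digits = digits)
  }
  if (length(x$dropped_features))
    cat("\nDropped constant features:",
        paste(x$dropped_features, collapse = ", "), "\n")
  invisible(x)
}

#' Plot per-lesion silhouettes by patient
#'
#' Patient-indexed scatter of per-lesion silhouette values (single-lesion
#' patients shown at zero as open symbols), with per-patient means overlaid.
#'
#' @param x a `lesion_similarity` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lesion_similarity <- function(x, ...) {
  pl <- x$patient$per_lesion
  pats <- unique(pl$label)
  idx <- match(pl$label, pats)
  cols <- grDevices::hcl.colors(length(pats), "Dark 3")[idx]
  graphics::plot(idx, pl$s, pch = ifelse(pl$excluded, 1, 16), col = cols,
                 xlab = "patient index", ylab = "silhouette value",
                 ylim = c(-1, 1), ...)
  pp <- x$patient$per_patient
  graphics::points(match(pp$patient_id, pats), pp$mean_s, pch = 3,
                   col = "black")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
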