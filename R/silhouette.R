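#' Per-lesion silhouette values against patient labels
#'
#' For lesion `i` of patient `P` with at least two lesions,
#' `a(i)` is the mean Euclidean distance to the other lesions of `P`,
#' `b(i)` the minimum over other patients `Q` of the mean distance to the
#' lesions of `Q`, and `s(i) = (b - a) / max(a, b)`. A lesion whose patient
#' has a single lesion gets `s = 0` and is flagged excluded — the
#' convention for single-lesion patients, which are set to zero and kept
#' apart from every cohort average.
#'
#' @param coordinates numeric matrix (lesions x d) or an `embedded_table`.
#' @param labels grouping labels, one per lesion (patient ids).
#' @return data.frame with `lesion_id`, `label`, `s`, `excluded`.
#' @export
lesion_silhouettes <- function(coordinates, labels) {
  if (inherits(coordinates, "embedded_table")) {
    if (missing(labels)) labels <- coordinates$patient_ids
    coordinates <- coordinates$coordinates
  }
  labels <- as.character(labels)
  n <- nrow(coordinates)
  if (length(labels) != n)
    rh_stop("input_error", "labels length (%d) != lesions (%d)",
            length(labels), n)
  groups <- unique(labels)
  if (length(groups) < 2)
    rh_stop("silhouette_undefined", "need >= 2 distinct labels")
  D <- as.matrix(stats::dist(coordinates))
  # mean distance from each lesion to each group
  G <- vapply(groups, function(g) {
    cols <- labels == g
    rowSums(D[, cols, drop = FALSE]) / sum(cols)
  }, numeric(n))
  sizes <- vapply(groups, function(g) sum(labels == g), numeric(1))
  own <- match(labels, groups)
  s <- numeric(n)
  excluded <- sizes[own] == 1
  for (i in seq_len(n)) {
    if (excluded[i]) { s[i] <- 0; next }
    ng <- sizes[own[i]]
    a <- G[i, own[i]] * ng / (ng - 1)  # exclude self-distance 0
    b <- min(G[i, -own[i]])
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  data.frame(lesion_id = rownames(coordinates) %||%
               as.character(seq_len(n)),
             label = labels, s = s, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Per-patient silhouette means and the cohort mean index
#'
#' Averages per-lesion silhouettes within each patient; single-lesion
#' (excluded) patients are reported with value 0 and an excluded flag and do
#' not enter the cohort mean, which averages over the non-excluded patients.
#'
#' @param per_lesion data.frame from [lesion_silhouettes()].
#' @param slicing character label recorded on the result (`"ALL"`,
#'   `"SITE:<class>"`, `"TERTILE:<t>"`).
#' @return object of class `silhouette_result`: list with `per_lesion`,
#'   `per_patient` (data.frame `patient_id`, `mean_s`, `n_lesions`,
#'   `excluded`), `slicing`, `mean_index`.
#' @export
patient_silhouette <- function(per_lesion, slicing = "ALL") {
  sp <- split(per_lesion, per_lesion$label)
  per_patient <- do.call(rbind, lapply(sp, function(df) {
    excl <- all(df$excluded)
    data.frame(patient_id = df$label[1],
               mean_s = if (excl) 0 else mean(df$s[!df$excluded]),
               n_lesions = nrow(df), excluded = excl,
               stringsAsFactors = FALSE)
  }))
  rownames(per_patient) <- NULL
  keep <- !per_patient$excluded
  mean_index <- if (any(keep)) mean(per_patient$mean_s[keep]) else NA_real_
  structure(list(per_lesion = per_lesion, per_patient = per_patient,
                 slicing = slicing, mean_index = mean_index),
            class = "silhouette_result")
}

#' @export
print.silhouette_result <- function(x, ...) {
  cat(sprintf("Silhouette result [%s]: %d lesions, %d patients (%d excluded)\n",
              x$slicing, nrow(x$per_lesion), nrow(x$per_patient),
              sum(x$per_patient$excluded)))
  cat(sprintf("  cohort mean index: %.4f\n", x$mean_index))
  invisible(x)
}

# shared restrict -> re-embed -> silhouette path for the sliced analyses
restricted_silhouette <- function(features, rows, slicing, method, d) {
  sub <- features[rows, , drop = FALSE]
  if (length(unique(sub$patient_id)) < 2)
    rh_stop("silhouette_undefined",
            "fewer than 2 patients in slicing %s", slicing)
  emb <- embed_features(sub, method = method, d = d)
  pl <- lesion_silhouettes(emb$coordinates, sub$patient_id)
  patient_silhouette(pl, slicing = slicing)
}

#' Anatomy-based (site-restricted) silhouette analysis
#'
#' Restricts the cohort to lesions of one anatomical site class, re-embeds
#' on the subset (each slicing is an independent analysis), and recomputes
#' patient-labelled silhouettes. Patients with fewer than two lesions of the
#' site are excluded-zero.
#'
#' @param features feature table with `site_class`.
#' @param site one of `"REGIONAL_LN"`, `"DISTANT_LN"`, `"BONE"`.
#' @param method,d embedding options passed to [embed_features()].
#' @return a `silhouette_result`.
#' @export
anatomy_silhouette <- function(features, site, method = "zscore", d = NULL) {
  if (!site %in% SITE_CLASSES)
    rh_stop("input_error", "unknown site class '%s'", site)
  rows <- features$site_class == site
  if (!any(rows))
    rh_stop("silhouette_undefined", "no lesions of site %s", site)
  restricted_silhouette(features, rows, paste0("SITE:", site), method, d)
}

#' SUVmax tertile assignment
#'
#' Boundaries are the empirical 1/3 and 2/3 quantiles (inclusive empirical
#' quantile) of lesion SUVmax over the whole cohort; lesions at a boundary
#' go to the lower tertile, so an all-equal cohort falls wholly in tertile 1.
#'
#' @param suv_max numeric vector of lesion SUVmax.
#' @return integer vector of tertiles 1..3.
#' @export
suv_tertiles <- function(suv_max) {
  q <- stats::quantile(suv_max, c(1, 2) / 3, type = 7, names = FALSE)
  ifelse(suv_max <= q[1], 1L, ifelse(suv_max <= q[2], 2L, 3L))
}

#' Metabolism-based (SUVmax-tertile) silhouette analysis
#'
#' Restricts the cohort to lesions in one SUVmax tertile (boundaries from
#' the whole cohort), re-embeds, and recomputes patient-labelled
#' silhouettes.
#'
#' @param features feature table with `suv_max`.
#' @param tertile 1, 2 or 3.
#' @param method,d embedding options.
#' @return a `silhouette_result`.
#' @export
metabolism_silhouette <- function(features, tertile, method = "zscore",
                                  d = NULL) {
  stopifnot(tertile %in% 1:3)
  tert <- suv_tertiles(features$suv_max)
  rows <- tert == tertile
  if (!any(rows))
    rh_stop("silhouette_undefined", "no lesions in tertile %d", tertile)
  restricted_silhouette(features, rows, paste0("TERTILE:", tertile),
                        method, d)
}

#' Paired comparison of two slicings' per-patient silhouettes
#'
#' Classical paired t-test on per-patient mean silhouettes, pairing by
#' patient id over patients present and non-excluded in both slicings.
#' Conventions for degenerate inputs: all differences exactly zero gives
#' `t = 0, p = 1`; constant non-zero differences give `t = Inf`-free output
#' `NaN` with a `degenerate` flag.
#'
#' @param all_result,restricted_result `silhouette_result` objects.
#' @return list with `t`, `df`, `p`, `n_pairs`, `mean_diff`, `degenerate`.
#' @export
paired_slicing_test <- function(all_result, restricted_result) {
  a <- all_result$per_patient
  b <- restricted_result$per_patient
  a <- a[!a$excluded, ]; b <- b[!b$excluded, ]
  common <- intersect(a$patient_id, b$patient_id)
  if (length(common) < 2)
    rh_stop("test_undefined", "fewer than 2 paired patients")
  d <- b$mean_s[match(common, b$patient_id)] -
    a$mean_s[match(common, a$patient_id)]
  n <- length(d)
  if (all(d == 0))
    return(list(t = 0, df = n - 1, p = 1, n_pairs = n, mean_diff = 0,
                degenerate = FALSE))
  sdd <- stats::sd(d)
  if (sdd == 0)
    return(list(t = NaN, df = n - 1, p = NaN, n_pairs = n,
                mean_diff = mean(d), degenerate = TRUE))
  tstat <- mean(d) / (sdd / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * stats::pt(-abs(tstat), n - 1),
       n_pairs = n, mean_diff = mean(d), degenerate = FALSE)
}
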