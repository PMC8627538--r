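#' Embed a feature table into the standardized analysis space
#'
#' Z-scores every feature over all lesions (zero-variance columns are
#' dropped and recorded, never divided by zero), optionally followed by a
#' PCA projection onto the leading principal axes. The embedded space is
#' where all silhouette and clustering computations happen, with Euclidean
#' distance.
#'
#' @param features a feature table data.frame (`lesion_id`, `patient_id`,
#'   and optionally `site_class`, `suv_max`, plus numeric feature columns),
#'   or a numeric matrix with rownames as lesion ids.
#' @param method `"zscore"` (default) or `"pca"`.
#' @param d number of principal components to keep in PCA mode; `NULL`
#'   keeps the smallest number explaining at least `var_explained`.
#' @param var_explained variance fraction target for automatic `d`.
#' @return object of class `embedded_table`: list with `coordinates`
#'   (lesions x d matrix), `lesion_ids`, `patient_ids`, `scaler_params`
#'   (per-feature center/scale), `dropped` (zero-variance columns),
#'   `method`.
#' @export
embed_features <- function(features, method = c("zscore", "pca"), d = NULL,
                           var_explained = 0.9) {
  method <- match.arg(method)
  meta_cols <- c("lesion_id", "patient_id", "site_class", "suv_max")
  if (is.data.frame(features)) {
    lesion_ids <- features$lesion_id %||% as.character(seq_len(nrow(features)))
    patient_ids <- features$patient_id
    X <- as.matrix(features[, setdiff(names(features), meta_cols),
                            drop = FALSE])
  } else {
    X <- as.matrix(features)
    lesion_ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
    patient_ids <- NULL
  }
  storage.mode(X) <- "double"
  if (nrow(X) < 2) rh_stop("input_error", "need >= 2 lesions to embed")
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | is.na(sds)]
  keep <- setdiff(colnames(X), dropped)
  if (length(keep) == 0)
    rh_stop("embedding_degenerate", "all features are constant")
  X <- X[, keep, drop = FALSE]
  ctr <- colMeans(X)
  scl <- sds[keep]
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  if (method == "pca") {
    pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    if (is.null(d)) {
      cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      d <- which(cum >= var_explained)[1]
    }
    d <- min(d, ncol(pc$x))
    Z <- pc$x[, seq_len(d), drop = FALSE]
  }
  rownames(Z) <- lesion_ids
  structure(list(coordinates = Z, lesion_ids = lesion_ids,
                 patient_ids = patient_ids,
                 scaler_params = list(center = ctr, scale = scl),
                 dropped = dropped, method = method),
            class = "embedded_table")
}
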