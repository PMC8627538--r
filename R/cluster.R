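#' Unsupervised clustering of lesions with silhouette model selection
#'
#' Runs k-means (default; Ward agglomerative behind a flag) on the embedded
#' lesion coordinates for every k in `k_range`, scores each solution by its
#' mean silhouette over lesions (cluster labels as groups, singleton
#' clusters contributing zero), and picks the k with the highest score —
#' the operationalization of choosing the "best interpretable" number of
#' clusters. Deterministic given `seed`.
#'
#' @param space an `embedded_table` or a numeric coordinate matrix.
#' @param k_range candidate cluster counts, within `2..n_lesions-1`.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of seeded k-means restarts per k.
#' @param method `"kmeans"` (default) or `"ward"`.
#' @return object of class `cluster_solution`: list with `k` (chosen),
#'   `labels` (named integer vector, lesion -> cluster), `selection_scores`
#'   (named: k -> mean silhouette), `chosen_k`, `method`, `degenerate`
#'   (TRUE when all points coincide).
#' @export
cluster_lesions <- function(space, k_range = 2:6, seed = 1, nstart = 20,
                            method = c("kmeans", "ward")) {
  method <- match.arg(method)
  X <- if (inherits(space, "embedded_table")) space$coordinates else
    as.matrix(space)
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    rh_stop("input_error",
            "k_range must lie within 2..n_lesions-1 (n=%d)", n)
  n_distinct <- nrow(unique(X))
  if (n_distinct < 2) {
    labels <- stats::setNames(rep(1L, n), rownames(X))
    return(structure(list(k = 1L, labels = labels,
                          selection_scores = stats::setNames(
                            rep(NA_real_, length(k_range)), k_range),
                          chosen_k = 1L, method = method, degenerate = TRUE),
                     class = "cluster_solution"))
  }
  k_range <- k_range[k_range <= n_distinct]
  hc <- if (method == "ward") stats::hclust(stats::dist(X), "ward.D2")
  scores <- stats::setNames(numeric(length(k_range)), k_range)
  labs <- vector("list", length(k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    if (method == "kmeans") {
      lab <- with_seed(seed, stats::kmeans(X, centers = k, nstart = nstart,
                                           iter.max = 50)$cluster)
    } else {
      lab <- stats::cutree(hc, k = k)
    }
    sil <- lesion_silhouettes(X, lab)
    scores[j] <- mean(sil$s)  # singleton clusters contribute their 0
    labs[[j]] <- lab
  }
  best <- which.max(scores)   # ties -> smallest k
  labels <- stats::setNames(as.integer(labs[[best]]),
                            rownames(X) %||% as.character(seq_len(n)))
  structure(list(k = k_range[best], labels = labels,
                 selection_scores = scores, chosen_k = k_range[best],
                 method = method, degenerate = FALSE),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Lesion clustering (%s): chosen k = %d\n", x$method,
              x$chosen_k))
  cat("  mean-silhouette scores per k:\n")
  print(round(x$selection_scores, 4))
  invisible(x)
}

#' Characterize clusters by categorical lesion metadata
#'
#' Per-cluster proportions over each metadata category (anatomical site,
#' SUVmax tertile, burden class...), with an enrichment flag whenever a
#' cluster's proportion exceeds the cohort proportion, and a descriptive
#' chi-square test of the cluster-by-category table.
#'
#' @param solution a `cluster_solution`.
#' @param metadata data.frame with `lesion_id` plus one or more categorical
#'   columns covering every clustered lesion.
#' @return object of class `cluster_profile`: named list (one entry per
#'   metadata column) of lists with `proportions` (clusters x categories,
#'   rows sum to 1), `cohort` (cohort proportions), `enriched` (logical
#'   matrix), `chisq_p`.
#' @export
characterize_clusters <- function(solution, metadata) {
  stopifnot(inherits(solution, "cluster_solution"))
  ids <- names(solution$labels)
  miss <- setdiff(ids, metadata$lesion_id)
  if (length(miss))
    rh_stop("input_error", "metadata missing for lesion(s): %s",
            paste(utils::head(miss, 5), collapse = ", "))
  md <- metadata[match(ids, metadata$lesion_id), , drop = FALSE]
  cl <- solution$labels
  cols <- setdiff(names(md), "lesion_id")
  out <- lapply(cols, function(col) {
    v <- as.character(md[[col]])
    tab <- table(cluster = cl, category = v)
    prop <- prop.table(tab, 1)
    cohort <- prop.table(table(v))
    enriched <- sweep(prop, 2, as.numeric(cohort[colnames(prop)]), `>`)
    chip <- if (nrow(tab) > 1 && ncol(tab) > 1)
      suppressWarnings(stats::chisq.test(tab)$p.value) else NA_real_
    list(proportions = prop, cohort = cohort, enriched = enriched,
         chisq_p = chip)
  })
  names(out) <- cols
  class(out) <- "cluster_profile"
  out
}

#' @export
print.cluster_profile <- function(x, digits = 3, ...) {
  for (nm in names(x)) {
    cat(sprintf("-- %s (chi-square p = %s)\n", nm,
                format(x[[nm]]$chisq_p, digits = digits)))
    print(round(x[[nm]]$proportions, digits))
  }
  invisible(x)
}
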