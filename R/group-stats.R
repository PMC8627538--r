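#' Classify tumour burden under the 3- and 5-lesion definitions
#'
#' Each patient is classified twice, under the two most used oligometastatic
#' definitions. In inclusive mode (default) OLIGO means `n <= threshold`
#' ("up to" 3 or 5 lesions); in exclusive mode OLIGO means `n < threshold`.
#' The boundary ambiguity between the two conventions is real in the
#' literature, so both are implemented; the three-way class separates
#' OLIGO3 / INTERMEDIATE (pluri under 3, oligo under 5) / PLURI5.
#'
#' @param lesion_counts named integer vector (patient id -> lesion count) or
#'   a cohort table with `patient_id` and `n_lesions`.
#' @param inclusive logical; threshold convention (see above).
#' @return object of class `burden_classification`: data.frame with
#'   `patient_id`, `n_lesions`, `class3`, `class5`, `class3way`.
#' @export
classify_burden <- function(lesion_counts, inclusive = TRUE) {
  if (is.data.frame(lesion_counts)) {
    counts <- stats::setNames(lesion_counts$n_lesions,
                              lesion_counts$patient_id)
  } else counts <- lesion_counts
  if (any(counts < 1))
    rh_stop("invalid_record", "lesion count must be >= 1 (patient %s)",
            names(counts)[which(counts < 1)[1]])
  oligo <- function(n, thr) if (inclusive) n <= thr else n < thr
  class3 <- ifelse(oligo(counts, 3), "OLIGO", "PLURI")
  class5 <- ifelse(oligo(counts, 5), "OLIGO", "PLURI")
  class3way <- ifelse(class3 == "OLIGO", "OLIGO3",
                      ifelse(class5 == "OLIGO", "INTERMEDIATE", "PLURI5"))
  structure(data.frame(patient_id = names(counts) %||%
                         as.character(seq_along(counts)),
                       n_lesions = as.integer(counts),
                       class3 = class3, class5 = class5,
                       class3way = class3way, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("burden_classification", "data.frame"))
}

#' Build a clinical split (patient or lesion grouping)
#'
#' Pre-specified clinical categories: tumour burden under either threshold
#' (`BURDEN3`, `BURDEN5`, three-way `BURDEN3WAY`), Gleason score `<= 7` vs
#' `> 7` (`GLEASON`), PSA at or below vs above the cohort's own median
#' (`PSA_MEDIAN`), ongoing ADT (`ADT`), and the lesion-level site contrasts
#' `SITE_NODAL` (regional vs distant lymph nodes) and `SITE_BONE` (nodal vs
#' bone).
#'
#' @param cohort cohort table (patient rows with `patient_id`, `gleason`,
#'   `psa_ng_ml`, `adt_status`, `n_lesions`).
#' @param name split name (see above).
#' @param lesions lesion table, required for the `SITE_*` splits.
#' @param inclusive burden threshold convention for `BURDEN*`.
#' @return object of class `clinical_split`: list with `name`, `level`
#'   (`"patient"` or `"lesion"`), and `assignment` (named character vector
#'   id -> group).
#' @export
clinical_split <- function(cohort, name = c("BURDEN3", "BURDEN5",
                                            "BURDEN3WAY", "GLEASON",
                                            "PSA_MEDIAN", "ADT",
                                            "SITE_NODAL", "SITE_BONE"),
                           lesions = NULL, inclusive = TRUE) {
  name <- match.arg(name)
  level <- if (name %in% c("SITE_NODAL", "SITE_BONE")) "lesion" else "patient"
  if (level == "lesion") {
    if (is.null(lesions))
      rh_stop("split_error", "%s split needs a lesion table", name)
    g <- switch(name,
      SITE_NODAL = ifelse(lesions$site_class == "REGIONAL_LN", "REGIONAL",
                          ifelse(lesions$site_class == "DISTANT_LN",
                                 "DISTANT", NA)),
      SITE_BONE = ifelse(lesions$site_class == "BONE", "BONE", "NODAL"))
    assignment <- stats::setNames(g, lesions$lesion_id)
    assignment <- assignment[!is.na(assignment)]
  } else {
    bc <- classify_burden(cohort, inclusive = inclusive)
    g <- switch(name,
      BURDEN3 = bc$class3, BURDEN5 = bc$class5, BURDEN3WAY = bc$class3way,
      GLEASON = ifelse(cohort$gleason <= 7, "GS<=7", "GS>7"),
      PSA_MEDIAN = ifelse(cohort$psa_ng_ml <=
                            stats::median(cohort$psa_ng_ml),
                          "PSA_low", "PSA_high"),
      ADT = cohort$adt_status)
    assignment <- stats::setNames(g, cohort$patient_id)
  }
  if (any(table(assignment) == 0) || length(unique(assignment)) < 2)
    rh_stop("split_error", "split %s does not yield >= 2 non-empty groups",
            name)
  structure(list(name = name, level = level, assignment = assignment),
            class = "clinical_split")
}

# group vector for a set of rows keyed by patient or lesion id
split_groups <- function(split, patient_ids, lesion_ids = NULL) {
  key <- if (split$level == "patient") patient_ids else lesion_ids
  unname(split$assignment[key])
}

#' Univariate Mann-Whitney screen of radiomic features
#'
#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test per feature between the
#' two groups of a clinical split. By default the test compares lesion rows
#' labelled by their patient's group; `level = "patient"` aggregates to
#' per-patient feature medians first. Default alpha follows the screening
#' convention: 0.01 for the Gleason split, 0.001 for every other category.
#'
#' @param features feature table.
#' @param split a `clinical_split` (two groups) or a group vector aligned
#'   with the feature rows.
#' @param alpha significance level; `NULL` picks the convention above.
#' @param level `"lesion"` (default) or `"patient"` (median aggregation).
#' @param adjust optionally add a Benjamini-Hochberg adjusted column
#'   (`p_bh`); off by default as the screen reports raw p at fixed alpha.
#' @return data.frame with `feature`, `U`, `p`, `significant` (and `p_bh`
#'   when `adjust`).
#' @export
univariate_screen <- function(features, split, alpha = NULL,
                              level = c("lesion", "patient"),
                              adjust = FALSE) {
  level <- match.arg(level)
  if (inherits(split, "clinical_split")) {
    if (is.null(alpha)) alpha <- if (split$name == "GLEASON") 0.01 else 0.001
    g <- split_groups(split, features$patient_id, features$lesion_id)
  } else {
    g <- as.character(split)
    if (is.null(alpha)) alpha <- 0.001
  }
  if (is.null(alpha)) alpha <- 0.001
  keep <- !is.na(g)
  feats <- features[keep, , drop = FALSE]; g <- g[keep]
  groups <- unique(g)
  if (length(groups) != 2)
    rh_stop("split_error", "screen requires exactly 2 groups, got %d",
            length(groups))
  meta <- c("lesion_id", "patient_id", "site_class", "suv_max")
  fcols <- setdiff(names(feats), meta)
  fcols <- fcols[vapply(feats[fcols], is.numeric, logical(1))]
  if (level == "patient") {
    agg <- stats::aggregate(feats[fcols], by = list(pid = feats$patient_id),
                            FUN = stats::median)
    gp <- g[match(agg$pid, feats$patient_id)]
    feats <- agg; g <- gp
  }
  if (min(table(g)) < 1)
    rh_stop("split_error", "a group is empty")
  res <- lapply(fcols, function(f) {
    x <- feats[[f]][g == groups[1]]
    y <- feats[[f]][g == groups[2]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                              alternative = "two.sided"))
    data.frame(feature = f, U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p <= alpha
  if (adjust) out$p_bh <- stats::p.adjust(out$p, "BH")
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- groups
  out
}

#' Compare PSA distributions across clinical groups
#'
#' PSA is analysed apart from the radiomic screen, at alpha 0.05, with
#' Mann-Whitney tests (PSA is heavily right-skewed, so a rank test is the
#' natural choice). A two-group split gives one test; a three-or-more-group
#' split (three-way burden, site contrasts) gives all pairwise tests.
#'
#' @param cohort cohort table with `psa_ng_ml`.
#' @param split a `clinical_split` at patient level, or a group vector.
#' @param alpha significance level (default 0.05).
#' @return data.frame with `group1`, `group2`, `W`, `p`, `significant`.
#' @export
psa_test <- function(cohort, split, alpha = 0.05) {
  g <- if (inherits(split, "clinical_split"))
    split_groups(split, cohort$patient_id) else as.character(split)
  keep <- !is.na(g)
  psa <- cohort$psa_ng_ml[keep]; g <- g[keep]
  groups <- sort(unique(g))
  if (length(groups) < 2)
    rh_stop("split_error", "PSA test needs >= 2 groups")
  pairs <- utils::combn(groups, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    wt <- suppressWarnings(stats::wilcox.test(psa[g == g1], psa[g == g2],
                                              alternative = "two.sided"))
    data.frame(group1 = g1, group2 = g2, W = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  }))
  out$significant <- out$p <= alpha
  attr(out, "alpha") <- alpha
  out
}

#' Kruskal-Wallis test of per-patient silhouettes across groups
#'
#' Compares per-patient mean silhouette values between the groups of a
#' patient-level clinical split, after removing excluded (single-lesion)
#' patients. Tie-corrected H with a chi-square p on `groups - 1` degrees of
#' freedom (stats::kruskal.test).
#'
#' @param sil a `silhouette_result` (typically `fit$patient`) or a
#'   `lesion_similarity` fit.
#' @param split a `clinical_split` at patient level, or a named group
#'   vector (patient id -> group).
#' @return list with `H`, `df`, `p`, `groups` (per-group n).
#' @export
silhouette_group_test <- function(sil, split) {
  if (inherits(sil, "lesion_similarity")) sil <- sil$patient
  pp <- sil$per_patient[!sil$per_patient$excluded, , drop = FALSE]
  g <- if (inherits(split, "clinical_split"))
    unname(split$assignment[pp$patient_id])
  else unname(split[pp$patient_id])
  keep <- !is.na(g)
  pp <- pp[keep, , drop = FALSE]; g <- g[keep]
  tab <- table(g)
  if (length(tab) < 2 || any(tab == 0))
    rh_stop("split_error",
            "need >= 2 non-empty groups after excluding single-lesion patients")
  kt <- stats::kruskal.test(pp$mean_s, factor(g))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, groups = tab)
}
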