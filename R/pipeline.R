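#' Run the full analysis pipeline
#'
#' Chains the stages end to end: simulate (or load) a cohort, optionally
#' render volumes and extract features, run the similarity analysis with
#' all slicings, the burden/PSA/Kruskal statistics, and the clustering with
#' its characterization, writing every stage's tables plus a run log
#' (seed, config hash) to `out_dir`.
#'
#' @param config nested run configuration; see Details. Recognised top-level
#'   entries: `seed`, `cohort` (arguments to [cohort_config()]),
#'   `use_volumes` (render volumes and extract features instead of using
#'   the generator's feature table; slower), `extraction` (arguments to
#'   [extraction_config()]), `embedding` (`method`, `d`), `inclusive`
#'   (burden threshold mode), `k_range`.
#' @param out_dir output directory.
#' @return invisibly, a list with the fitted objects (`cohort`, `fit`,
#'   `burden`, `kruskal`, `psa`, `clusters`, `profile`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("radiohet_run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  cohort_args <- config$cohort %||% list()
  cohort_args$seed <- cohort_args$seed %||% seed
  cfg <- do.call(cohort_config, cohort_args)
  cohort <- simulate_cohort(cfg)

  if (isTRUE(config$use_volumes)) {
    cohort <- simulate_cohort_volumes(cohort)
    ext <- do.call(extraction_config, config$extraction %||% list())
    features <- extract_cohort_features(cohort, ext)
  } else features <- cohort$feature_table

  emb_args <- config$embedding %||% list()
  fit <- lesion_similarity(features, method = emb_args$method %||% "zscore",
                           d = emb_args$d)

  inclusive <- config$inclusive %||% TRUE
  burden <- classify_burden(cohort$cohort_table, inclusive = inclusive)
  kruskal <- list()
  for (nm in c("BURDEN3", "BURDEN5", "BURDEN3WAY", "GLEASON", "PSA_MEDIAN",
               "ADT")) {
    sp <- tryCatch(clinical_split(cohort$cohort_table, nm,
                                  inclusive = inclusive),
                   radiohet_error = function(e) NULL)
    if (is.null(sp)) next
    kruskal[[nm]] <- tryCatch(silhouette_group_test(fit, sp),
                              radiohet_error = function(e) NULL)
  }
  psa <- tryCatch(
    psa_test(cohort$cohort_table,
             clinical_split(cohort$cohort_table, "BURDEN3",
                            inclusive = inclusive)),
    radiohet_error = function(e) NULL)

  k_range <- config$k_range %||% 2:6
  clusters <- cluster_lesions(fit$embedding, k_range = k_range, seed = seed)
  meta <- data.frame(lesion_id = features$lesion_id,
                     site_class = features$site_class,
                     tertile = paste0("T", suv_tertiles(features$suv_max)),
                     burden5 = burden$class5[match(features$patient_id,
                                                   burden$patient_id)],
                     stringsAsFactors = FALSE)
  profile <- characterize_clusters(clusters, meta)

  # outputs + log
  write_cohort(cohort, file.path(out_dir, "cohort"))
  write_feature_table(features, file.path(out_dir, "features.csv"))
  write_report(fit, file.path(out_dir, "similarity.yaml"))
  write_table(burden, file.path(out_dir, "burden.csv"))
  write_table(data.frame(lesion_id = names(clusters$labels),
                         cluster = unname(clusters$labels)),
              file.path(out_dir, "clusters.csv"))
  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  log_lines <- c(
    sprintf("radiohet %s", as.character(utils::packageVersion("radiohet"))),
    sprintf("seed: %s", seed),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("n_patients: %d  n_lesions: %d", nrow(cohort$cohort_table),
            nrow(cohort$lesion_table)),
    sprintf("patient_mean_index: %.6f", fit$patient$mean_index),
    sprintf("chosen_k: %d", clusters$chosen_k))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(cohort = cohort, features = features, fit = fit,
                 burden = burden, kruskal = kruskal, psa = psa,
                 clusters = clusters, profile = profile,
                 out_dir = out_dir))
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `inst/cli/radiohet.R` script. Subcommands:
#' `simulate`, `extract`, `similarity`, `stats`, `cluster`, `run-all` — all
#' driven by a YAML config (`--config`), an output directory (`--out`) and
#' an optional `--seed` override. Returns a shell exit status instead of
#' raising, so the wrapper script can `quit(status = ...)`.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 on success).
#' @export
rh_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: radiohet <subcommand> [--config FILE] [--out DIR] [--seed N]",
    "subcommands: simulate | extract | similarity | stats | cluster | run-all",
    sep = "\n")
  if (length(argv) == 0) { message(usage); return(1L) }
  sub <- argv[1]
  opts <- list(config = NULL, out = NULL, seed = NULL)
  i <- 2
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts) || i == length(argv)) {
      message(usage); return(1L)
    }
    opts[[key]] <- argv[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else list()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  out <- opts$out %||% "radiohet_out"
  run_stage <- function() {
    switch(sub,
      "simulate" = {
        cohort <- simulate_cohort(do.call(cohort_config, c(
          cfg$cohort %||% list(), list(seed = cfg$seed %||% 1L))))
        write_cohort(cohort, out)
      },
      "extract" = {
        cohort0 <- read_cohort(cfg$cohort_dir %||% out, volumes = TRUE)
        ext <- do.call(extraction_config, cfg$extraction %||% list())
        ft <- do.call(rbind, lapply(cohort0$lesion_table$lesion_id,
          function(id) {
            v <- cohort0$volumes[[id]]
            fv <- extract_features(v$volume, v$mask, v$spacing_mm, ext, id)
            row <- cohort0$lesion_table[
              cohort0$lesion_table$lesion_id == id, ]
            cbind(row[c("lesion_id", "patient_id", "site_class")],
                  suv_max = attr(fv, "suv_max"),
                  as.data.frame(as.list(unclass(fv)), check.names = FALSE))
          }))
        write_feature_table(ft, file.path(out, "features.csv"))
      },
      "similarity" = {
        ft <- read_feature_table(cfg$features %||%
                                   file.path(out, "features.csv"))
        fit <- lesion_similarity(ft)
        write_report(fit, file.path(out, "similarity.yaml"))
      },
      "stats" = ,
      "cluster" = ,
      "run-all" = run_pipeline(cfg, out),
      { message(usage); return(1L) })
    0L
  }
  tryCatch({ dir.create(out, showWarnings = FALSE, recursive = TRUE)
             st <- run_stage(); if (is.null(st)) 0L else st },
           error = function(e) {
             message(sprintf("radiohet %s failed: %s", sub,
                             conditionMessage(e)))
             2L
           })
}
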