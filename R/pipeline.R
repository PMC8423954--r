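#' Full-run configuration
#'
#' Bundles every tunable of the three analysis stages behind one object. All
#' stage seeds are derived from `seed` by stable counters, so any stage can
#' be re-run in isolation and the whole run is bit-reproducible.
#'
#' @param cohort A [cohort_config()]; its own seed is overridden by the
#'   master seed.
#' @param stats A [stats_options()].
#' @param tasks Character vector of tasks to run (subset of `"genotype"`,
#'   `"treatment"`).
#' @param combos Character vector of [model_combo()] names.
#' @param n_permutations Train/test permutations per combo (default 1000).
#' @param max_per_class Per-class subject cap before splitting (default 13).
#' @param zscore_scope `"full"` or `"train"` (see [run_stability()]).
#' @param contaminate Apply [inject_contamination()] between generation and
#'   analysis (default FALSE).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       stats = stats_options(),
                       tasks = c("genotype", "treatment"),
                       combos = c("SVM-KNN", "SVM-RFC", "XGB-KNN", "XGB-RFC"),
                       n_permutations = 1000L,
                       max_per_class = 13L,
                       zscore_scope = "full",
                       contaminate = FALSE,
                       seed = 1L) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  combos <- vapply(combos, function(x) model_combo(x)$name, character(1))
  structure(
    list(cohort = cohort, stats = stats, tasks = tasks, combos = unname(combos),
         n_permutations = as.integer(n_permutations),
         max_per_class = as.integer(max_per_class),
         zscore_scope = zscore_scope, contaminate = isTRUE(contaminate),
         seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized top-level keys: `seed`, `n_permutations`, `tasks`, `combos`,
#' `max_per_class`, `zscore_scope`, `contaminate`, and a `cohort` block with
#' `group_sizes`, `correlation_rho`, `outlier_rate`, `outlier_scale`,
#' `detection_floor`, `noise`. Unknown keys raise an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("seed", "n_permutations", "tasks", "combos", "max_per_class",
             "zscore_scope", "contaminate", "cohort", "stats")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  ck <- raw$cohort %||% list()
  known_c <- c("group_sizes", "correlation_rho", "outlier_rate",
               "outlier_scale", "detection_floor", "noise", "seed")
  unknown <- setdiff(names(ck), known_c)
  if (length(unknown)) {
    abort(paste("unknown cohort config keys:", paste(unknown, collapse = ", ")))
  }
  cohort_args <- ck[intersect(names(ck), known_c)]
  if (!is.null(cohort_args$group_sizes)) {
    cohort_args$group_sizes <- unlist(cohort_args$group_sizes)
  }
  sk <- raw$stats %||% list()
  unknown <- setdiff(names(sk), c("alpha", "q", "outlier_filter",
                                  "min_group", "max_missing_frac"))
  if (length(unknown)) {
    abort(paste("unknown stats config keys:", paste(unknown, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), setdiff(known, c("cohort", "stats")))]
  args$cohort <- do.call(cohort_config, cohort_args)
  args$stats <- do.call(stats_options, sk)
  do.call(run_config, args)
}

#' Run the full generate / analyze / select pipeline
#'
#' Executes the three stages in order -- synthetic cohort generation
#' (optionally contaminated), univariate feature statistics, and the
#' stability-selection machine-learning stage (logistic coefficient ranking
#' plus every requested ranker-classifier combo on every requested task) --
#' and optionally writes all tabular artifacts to `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; created if missing. Writes the
#'   cohort CSV (+ JSON sidecar), per-contrast statistics CSV, stability
#'   curves CSV, occurrence CSV, logistic coefficients CSV and a JSON run
#'   report.
#' @return An object of class `run_report`: list with `cohort`, `stats`,
#'   `logistic`, `stability` (named list of `stability_result`),
#'   `comparison` (per-task [compare_models()] tables when >= 2 combos ran)
#'   and `provenance`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(run_config(n_permutations = 10, combos = "SVM-KNN",
#'                                tasks = "genotype", seed = 1))
#' rep$stability[["genotype/SVM-KNN"]]
#' }
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 3L + length(config$tasks) * length(config$combos))

  cohort_cfg <- config$cohort
  cohort_cfg$seed <- seeds[1L]
  cohort <- generate_cohort(cohort_cfg)
  if (config$contaminate) cohort <- inject_contamination(cohort, cohort_cfg)

  stats_res <- analyze_features(cohort, config$stats)

  logistic <- purrr::map(setNames(config$tasks, config$tasks), function(tk) {
    logistic_rank(cohort, classification_task(tk))
  })

  stab <- list()
  i <- 3L
  for (tk in config$tasks) {
    for (cb in config$combos) {
      i <- i + 1L
      stab[[paste(tk, cb, sep = "/")]] <- run_stability(
        cohort, classification_task(tk), cb,
        n_permutations = config$n_permutations, seed = seeds[i],
        max_per_class = config$max_per_class,
        zscore_scope = config$zscore_scope)
    }
  }

  comparison <- purrr::map(setNames(config$tasks, config$tasks), function(tk) {
    rs <- stab[grepl(paste0("^", gsub("([/])", "\\\\\\1", tk), "/"), names(stab))]
    if (length(rs) >= 2) compare_models(unname(rs)) else NULL
  })

  report <- structure(
    list(cohort = cohort, stats = stats_res, logistic = logistic,
         stability = stab, comparison = comparison,
         provenance = list(seed = config$seed,
                           n_permutations = config$n_permutations,
                           tasks = config$tasks, combos = config$combos,
                           package_version = as.character(utils::packageVersion("stabmark")))),
    class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, "\n")
  cat("  cohort:", nrow(x$cohort), "subjects x", length(feature_names(x$cohort)),
      "features\n")
  cat("  stats :", sum(x$stats$results$q_decision), "FDR-rejected contrasts\n")
  for (nm in names(x$stability)) {
    g <- glance(x$stability[[nm]])
    cat(sprintf("  %s: best accuracy %.3f at k = %d\n",
                nm, g$accuracy_best, g$best_k))
  }
  invisible(x)
}

#' Write a biomarker table to CSV with a JSON metadata sidecar
#'
#' The CSV has columns `subject_id`, `genotype`, `treatment`, then one column
#' per feature (UTF-8, comma-separated, header row). Feature metadata and the
#' contamination ground truth (when present) go to `<path>.meta.json`.
#'
#' @param table A `biomarker_tbl`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_biomarker_csv <- function(table, path) {
  readr::write_csv(as_tibble(table), path, na = "")
  sidecar <- list(feature_meta = feature_meta(table))
  cont <- attr(table, "contamination")
  if (!is.null(cont) && nrow(cont)) sidecar$contamination <- cont
  jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a biomarker table from CSV
#'
#' Inverse of [write_biomarker_csv()]; the round trip is lossless. Malformed
#' headers, duplicated subject ids and non-numeric feature cells raise parse
#' errors naming the offending row/column; empty cells are read as missing.
#'
#' @param path CSV path; `<path>.meta.json` is read when present, otherwise
#'   minimal metadata is inferred.
#' @return A `biomarker_tbl`.
#' @export
read_biomarker_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         na = c("", "NA"), progress = FALSE)
  req <- c("subject_id", "genotype", "treatment")
  if (!identical(names(tbl)[1:3], req)) {
    abort(paste("malformed header: first columns must be",
                paste(req, collapse = ", ")))
  }
  dup <- tbl$subject_id[duplicated(tbl$subject_id)]
  if (length(dup)) {
    abort(paste("duplicated subject id(s):", paste(unique(dup), collapse = ", ")))
  }
  feats <- setdiff(names(tbl), req)
  for (f in feats) {
    if (!is.numeric(tbl[[f]])) {
      bad <- which(!is.na(tbl[[f]]) & is.na(suppressWarnings(as.numeric(tbl[[f]]))))
      abort(sprintf("non-numeric cell(s) in column '%s', row(s) %s",
                    f, paste(head(bad, 5), collapse = ", ")))
    }
  }
  bad_geno <- setdiff(unique(tbl$genotype), c("WT", "R6/2"))
  if (length(bad_geno)) abort(paste("unknown genotype:", paste(bad_geno, collapse = ", ")))
  bad_trt <- setdiff(unique(tbl$treatment), c("Veh", "C31"))
  if (length(bad_trt)) abort(paste("unknown treatment:", paste(bad_trt, collapse = ", ")))
  tbl$genotype <- factor(tbl$genotype, levels = c("WT", "R6/2"))
  tbl$treatment <- factor(tbl$treatment, levels = c("Veh", "C31"))

  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    as_tibble(jsonlite::read_json(meta_path, simplifyVector = TRUE)$feature_meta)
  } else {
    tibble(feature = feats, modality = NA_character_,
           roi = NA_character_, units = NA_character_)
  }
  new_biomarker_tbl(tbl, feature_meta = meta)
}

#' Write all tabular artifacts of a run report
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_biomarker_csv(report$cohort, file.path(out_dir, "cohort.csv"))
  readr::write_csv(tidy(report$stats), file.path(out_dir, "feature_stats.csv"))
  curves <- bind_rows(purrr::map(report$stability, tidy))
  if (nrow(curves)) readr::write_csv(curves, file.path(out_dir, "stability_curves.csv"))
  occ <- bind_rows(purrr::map2(report$stability, names(report$stability),
                               ~ mutate(.x$occurrence, run = .y, .before = 1)))
  if (nrow(occ)) readr::write_csv(occ, file.path(out_dir, "occurrence.csv"))
  logi <- bind_rows(purrr::map2(report$logistic, names(report$logistic),
                                ~ mutate(as_tibble(.x), task = .y, .before = 1)))
  if (nrow(logi)) readr::write_csv(logi, file.path(out_dir, "logistic_coefficients.csv"))
  jsonlite::write_json(
    list(provenance = report$provenance,
         glance = bind_rows(purrr::map(report$stability, glance)),
         exclusions = report$stats$exclusions,
         outliers_removed = report$stats$removed),
    file.path(out_dir, "run_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
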