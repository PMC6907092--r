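#' Pipeline run configuration
#'
#' One configuration object for the whole simulate / extract / select /
#' evaluate chain, with one section per stage. Can also be read from a YAML
#' file with the same section names; unknown keys are rejected.
#'
#' @param cohort A [cohort_config()].
#' @param geometry A [geometry_config()].
#' @param activation An [activation_config()].
#' @param selection A [selection_config()].
#' @param grids A [default_model_grids()].
#' @param scheme `"per_maneuver"` or `"combined"`.
#' @param fss `"none"`, `"bb"` or `"rfe"` — the subset search applied before
#'   the nested evaluation.
#' @param fss_scope `"outer_fold"` (leakage-free) or `"global"` (search sees
#'   the full table once, before the outer loop).
#' @param subset_dim Search output dimension (default 6).
#' @param top_features Number of most frequently selected features to
#'   summarize (default 6).
#' @return A `pf_pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            geometry = geometry_config(),
                            activation = activation_config(),
                            selection = selection_config(),
                            grids = default_model_grids(),
                            scheme = c("combined", "per_maneuver"),
                            fss = c("bb", "rfe", "none"),
                            fss_scope = c("outer_fold", "global"),
                            subset_dim = 6,
                            top_features = 6) {
  structure(
    list(cohort = cohort, geometry = geometry, activation = activation,
         selection = selection, grids = grids,
         scheme = match.arg(scheme), fss = match.arg(fss),
         fss_scope = match.arg(fss_scope),
         subset_dim = subset_dim, top_features = top_features),
    class = "pf_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Each top-level section maps onto the arguments of the corresponding
#' constructor ([cohort_config()], [geometry_config()],
#' [activation_config()], [selection_config()], [default_model_grids()]);
#' scalar options (`scheme`, `fss`, `fss_scope`, `subset_dim`,
#' `top_features`) sit at the top level. Unknown sections or keys abort.
#'
#' @param path YAML file path.
#' @return A `pf_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cohort", "geometry", "activation", "selection", "grids",
             "scheme", "fss", "fss_scope", "subset_dim", "top_features")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    rlang::abort(paste0("Unknown config section(s): ",
                        paste(unknown, collapse = ", ")))
  }
  build <- function(ctor, args) {
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad)) {
      rlang::abort(paste0("Unknown key(s): ", paste(bad, collapse = ", ")))
    }
    if ("effect" %in% names(args)) {
      args$effect <- do.call(class_effect, args$effect)
    }
    do.call(ctor, args)
  }
  args <- list(
    cohort = build(cohort_config, raw$cohort),
    geometry = build(geometry_config, raw$geometry),
    activation = build(activation_config, raw$activation),
    selection = build(selection_config, raw$selection),
    grids = build(default_model_grids, raw$grids)
  )
  for (k in c("scheme", "fss", "fss_scope", "subset_dim", "top_features")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Simulate a cohort, extract per-maneuver feature tables, run the
#' configured selection scheme and nested leave-one-out evaluation, and
#' write a report directory: label table, per-maneuver feature CSVs, metric
#' and selection-frequency CSVs, per-fold predictions, pairwise McNemar
#' tests, a top-feature summary, and a manifest JSON with the configuration
#' snapshot, seeds, package version and MD5 hashes of every written file.
#' All randomness flows from the seeds recorded in the manifest, so
#' re-running a manifest reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()] or a YAML path accepted by
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory results (`cohort` labels,
#'   `features`, `report`, `top_features`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pf_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] seed %d, %d subjects per class",
      config$cohort$seed, config$cohort$n_per_class)
  cohort <- generate_cohort(config$cohort)
  labels <- cohort_labels(cohort)
  readr::write_csv(labels, file.path(out_dir, "labels.csv"))

  say("[extract] %d recordings", nrow(cohort))
  catalog <- build_superset_catalog(config$geometry)
  features <- extract_cohort_features(cohort, catalog, config$activation)
  for (m in names(features)) {
    write_feature_table(features[[m]],
                        file.path(out_dir, paste0("features_", m, ".csv")))
  }

  say("[select+evaluate] scheme %s, fss %s (%s)",
      config$scheme, config$fss, config$fss_scope)
  if (config$scheme == "combined") {
    res <- combined_scheme(features, config$grids, selection = config$fss,
                           selection_scope = config$fss_scope,
                           cfg = config$selection, dim = config$subset_dim,
                           subset_dim = config$subset_dim)
    report <- res$report
    eval_table <- res$table
    subsets <- lapply(res$per_maneuver, function(s) {
      list(selected = s$selected, criterion = s$criterion_value,
           nodes = s$nodes_evaluated)
    })
    jsonlite::write_json(subsets, file.path(out_dir, "subsets.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    report <- purrr::map(features, function(tbl) {
      nested_loo_evaluate(tbl, config$grids, selection = config$fss,
                          selection_scope = config$fss_scope,
                          cfg = config$selection,
                          subset_dim = config$subset_dim)
    })
    eval_table <- NULL
  }

  reports <- if (inherits(report, "pf_evaluation")) {
    list(combined = report)
  } else {
    report
  }
  metrics <- dplyr::bind_rows(
    lapply(names(reports), function(nm) {
      dplyr::bind_cols(tibble::tibble(scheme = nm), reports[[nm]]$metrics)
    })
  )
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
  freq <- dplyr::bind_rows(
    lapply(names(reports), function(nm) {
      dplyr::bind_cols(tibble::tibble(scheme = nm),
                       reports[[nm]]$selection_frequency)
    })
  )
  readr::write_csv(freq, file.path(out_dir, "selection_frequency.csv"))
  preds <- dplyr::bind_rows(
    lapply(names(reports), function(nm) {
      dplyr::bind_cols(
        tibble::tibble(scheme = nm),
        dplyr::select(reports[[nm]]$outer_predictions, -"selected_features")
      )
    })
  )
  readr::write_csv(preds, file.path(out_dir, "outer_predictions.csv"))
  mcn <- dplyr::bind_rows(
    lapply(names(reports), function(nm) {
      dplyr::bind_cols(tibble::tibble(scheme = nm),
                       pairwise_model_tests(reports[[nm]]))
    })
  )
  readr::write_csv(mcn, file.path(out_dir, "mcnemar.csv"))

  top <- NULL
  first <- reports[[1]]
  if (config$fss != "none" && config$fss_scope == "outer_fold") {
    ff <- feature_selection_frequency(first)
    top_names <- utils::head(ff$feature, config$top_features)
    src_table <- if (!is.null(eval_table)) eval_table else features[[1]]
    have <- intersect(top_names, feature_names(src_table))
    if (length(have)) {
      top <- top_feature_report(src_table, have)
      readr::write_csv(
        dplyr::left_join(top, ff, by = "feature"),
        file.path(out_dir, "top_features.csv")
      )
    }
  }

  # chance-level flag: is the fold-best accuracy compatible with coin
  # flipping? (exact binomial test against 0.5)
  n_subj <- nrow(first$outer_predictions)
  n_correct <- sum(first$outer_predictions$pred_best ==
                     first$outer_predictions$truth)
  chance_p <- stats::binom.test(n_correct, n_subj, 0.5)$p.value
  summary_tbl <- tibble::tibble(
    scheme = names(reports)[1],
    n_subjects = n_subj,
    best_accuracy = n_correct / n_subj,
    chance_level = chance_p > 0.05
  )
  readr::write_csv(summary_tbl, file.path(out_dir, "summary.csv"))
  if (summary_tbl$chance_level) {
    say("[report] fold-best accuracy %.3f is not distinguishable from chance",
        summary_tbl$best_accuracy)
  }

  files <- sort(list.files(out_dir, full.names = TRUE, pattern = "\\.(csv|json)$"))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "pfpress",
    version = as.character(utils::packageVersion("pfpress")),
    seeds = list(cohort = config$cohort$seed,
                 selection = config$selection$seed),
    scheme = config$scheme, fss = config$fss, fss_scope = config$fss_scope,
    subset_dim = config$subset_dim,
    config = unclass_deep(config),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] %.1f s elapsed", as.numeric(Sys.time() - t0, units = "secs"))

  invisible(list(labels = labels, features = features, reports = reports,
                 top_features = top, manifest = manifest))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
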