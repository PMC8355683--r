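#' Pipeline configuration
#'
#' Collects everything one analysis run needs: input paths (or fixture mode),
#' study constants, node merging, kernel-density and Markov chain settings,
#' and the output directory. Can also be read from a YAML file with the same
#' field names.
#'
#' @param out_dir output directory.
#' @param detections,stations,sharks input CSV paths (ignored in fixture
#'   mode).
#' @param from_table if `TRUE`, skip raw detections and run the metric,
#'   grouping and regression stages directly on the packaged per-shark table
#'   (regression-test mode).
#' @param study a [study_config()].
#' @param kde list of kernel-density settings (`h_m`, `cell_m`, `step_min`,
#'   `min_distinct_nodes`, `min_relocations`).
#' @param edmc list of Markov chain settings (`tol`, `max_iter`, `group_by`).
#' @param merge receiver groups to merge, as in [default_node_map()].
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            detections = NULL, stations = NULL, sharks = NULL,
                            from_table = FALSE,
                            study = study_config(),
                            kde = list(h_m = 1000, cell_m = 100, step_min = 30,
                                       min_distinct_nodes = 3, min_relocations = 10),
                            edmc = list(tol = 1e-10, max_iter = 1e5,
                                        group_by = "sex_size"),
                            merge = list(c("15", "16"), c("18", "19"))) {
  if (!from_table) {
    for (p in c(detections, stations, sharks))
      if (!is.null(p) && is.character(p) && !file.exists(p))
        stop("input file does not exist: ", p)
  }
  stopifnot(kde$h_m > 0, kde$cell_m > 0, edmc$tol > 0, edmc$max_iter > 0)
  structure(list(out_dir = out_dir, detections = detections,
                 stations = stations, sharks = sharks,
                 from_table = from_table, study = study, kde = kde,
                 edmc = edmc, merge = merge),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the configuration fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  study <- do.call(study_config, if (is.null(y$study)) list() else y$study)
  args <- y[setdiff(names(y), "study")]
  args$study <- study
  do.call(pipeline_config, args)
}

.round_df <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

.log_line <- function(con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                             tz = "UTC")), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  message("[", stage, "] ", paste(names(rec[-(1:2)]), unlist(rec[-(1:2)]),
                                  sep = "=", collapse = " "))
}

#' Run the full analysis pipeline
#'
#' Executes filtering, residency metrics, cohort summary and regressions,
#' kernel-density activity spaces and Markov chain networks, writing every
#' stage's outputs plus a machine-readable `report.json` into the configured
#' output directory. In `from_table` mode the raw-detection stages are
#' skipped and all cohort statistics are recomputed from the packaged
#' per-shark summary table.
#'
#' @param cfg a [pipeline_config()] or path to a YAML config.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$out_dir, "run_log.jsonl"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  manifest <- character()
  report <- list(schema = "atollnet-report/1",
                 rounding = list(indices = 3L, regression = 4L, areas_km2 = 3L))

  if (cfg$from_table) {
    tbl <- lighthouse_table1()
    .log_line(log_con, "fixture", rows = nrow(tbl))
    tbl$size_class <- assign_size_class(as.character(tbl$sex), tbl$tl_cm)
    tbl$roaming_recomputed <- round(
      compute_roaming_index(tbl$receivers_visited, cfg$study$n_stations), 3)
    summary_tbl <- tbl
  } else {
    ds <- read_detections(cfg$detections, cfg$stations, cfg$sharks)
    .log_line(log_con, "read", events = nrow(ds$events))
    ds <- remove_false_detections(ds)
    .log_line(log_con, "false_detection_filter",
              removed = sum(ds$filter_log$rows_removed))
    flt <- apply_minimum_days_filter(ds, min_days = 5)
    ds <- flt$retained
    .log_line(log_con, "min_days_filter", excluded = length(flt$excluded_ids),
              retained = length(unique(ds$events$transmitter_id)))
    ds <- merge_receiver_nodes(ds, default_node_map(ds$stations$receiver_id,
                                                    merge = cfg$merge))
    write_filter_log(ds, file.path(cfg$out_dir, "filter_log.csv"))
    manifest <- c(manifest, "filter_log.csv")
    summary_tbl <- residency_summary(ds, cfg$study)
    report$excluded_ids <- flt$excluded_ids

    kd <- core_activity_spaces(ds, h_m = cfg$kde$h_m, cell_m = cfg$kde$cell_m,
                               step_min = cfg$kde$step_min,
                               min_distinct_nodes = cfg$kde$min_distinct_nodes,
                               min_relocations = cfg$kde$min_relocations)
    .log_line(log_con, "kde", eligible = sum(kd$eligible))
    utils::write.csv(.round_df(kd), file.path(cfg$out_dir, "activity_spaces.csv"),
                     row.names = FALSE)
    manifest <- c(manifest, "activity_spaces.csv")
    summary_tbl <- merge(summary_tbl, kd[c("shark_id", "kd50_km2", "kd95_km2")],
                         by = "shark_id", all.x = TRUE)

    fit <- edmc(ds, group_by = cfg$edmc$group_by, tol = cfg$edmc$tol,
                max_iter = cfg$edmc$max_iter)
    .log_line(log_con, "edmc", chains = length(fit$chains))
    net_dir <- file.path(cfg$out_dir, "networks")
    for (ch in fit$chains) {
      export_network(ch, net_dir)
      utils::write.csv(as.data.frame(ch$P),
                       file.path(net_dir, paste0(ch$label, "_transition_matrix.csv")))
      utils::write.csv(data.frame(state = names(ch$pi), centrality = as.numeric(ch$pi)),
                       file.path(net_dir, paste0(ch$label, "_centrality.csv")),
                       row.names = FALSE)
    }
    manifest <- c(manifest, "networks/")
    report$edmc <- lapply(fit$chains, function(ch)
      list(label = ch$label, n_transitions = ch$n_transitions,
           pi_absent = if ("ABSENT" %in% names(ch$pi)) unname(ch$pi["ABSENT"]) else NA))
  }

  utils::write.csv(.round_df(summary_tbl),
                   file.path(cfg$out_dir, "residency_summary.csv"), row.names = FALSE)
  manifest <- c(manifest, "residency_summary.csv")
  coh <- summarize_cohort(summary_tbl)
  .log_line(log_con, "residency", n = coh$n)
  jsonlite::write_json(unclass(coh)[names(coh) != "size_class_by_sex"],
                       file.path(cfg$out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = 6)
  manifest <- c(manifest, "cohort_summary.json")

  glm_ri <- fit_linear_model("ri", summary_tbl, select = TRUE)
  glm_roam <- fit_linear_model("roaming_index", summary_tbl, select = TRUE)
  report$glm <- list(
    ri = list(terms = glm_ri$terms,
              coefficients = .round_df(cbind(term = rownames(glm_ri$coefficients),
                                             glm_ri$coefficients), 4)),
    roaming = list(terms = glm_roam$terms,
                   coefficients = .round_df(cbind(term = rownames(glm_roam$coefficients),
                                                  glm_roam$coefficients), 4)))

  if ("kd50_km2" %in% names(summary_tbl) && any(!is.na(summary_tbl$kd50_km2))) {
    act <- summarize_activity_by_class(summary_tbl)
    report$activity_space <- act
  }
  report$cohort <- unclass(coh)[names(coh) != "size_class_by_sex"]
  report$size_class_counts <- as.data.frame(coh$size_class_by_sex)

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, force = TRUE)
  manifest <- c(manifest, c("cohort_summary.json", "report.json", "run_log.jsonl"))
  writeLines(c("complete", sort(unique(manifest))),
             file.path(cfg$out_dir, "MANIFEST"))
  invisible(report)
}
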