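# Result serialization: tidy CSV/JSON writers and a reproducibility manifest.

#' One-row data frame view of a strategy summary
#' @param s a `headsim_summary`.
#' @return a single-row data frame of means (and the run metadata).
#' @export
summary_row <- function(s) {
  stopifnot(inherits(s, "headsim_summary"))
  data.frame(strategy = s$strategy, perspective = s$perspective, n = s$n,
             n_referred = s$n_referred, n_censored_wait = s$n_censored_wait,
             prop_em = s$prop_em, nmb = s$nmb, seed = s$seed,
             t(s$means), check.names = FALSE)
}

#' Export an event log as CSV or JSON lines
#'
#' One row/object per event (`time`, `patient`, `kind`). The result must
#' have been produced with `simulate_pathways(..., collect_log = TRUE)`.
#'
#' @param result a `headsim_result` carrying an event log.
#' @param path output file path.
#' @param format `"csv"` (RFC-4180) or `"jsonl"` (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(result, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  log <- result$event_log
  if (is.null(log))
    stop("result has no event log; rerun simulate_pathways(collect_log = TRUE)",
         call. = FALSE)
  if (format == "csv") {
    write.csv(log, path, row.names = FALSE)
  } else {
    rows <- vapply(seq_len(nrow(log)), function(i)
      as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                    digits = NA)),
      character(1))
    writeLines(rows, path)
  }
  invisible(path)
}

#' Write a strategy summary to JSON
#' @param s a `headsim_summary`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(s, path) {
  stopifnot(inherits(s, "headsim_summary"))
  x <- unclass(s)
  x$means <- as.list(x$means)
  x$sds <- as.list(x$sds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-replication summaries to CSV
#' @param repset a `headsim_repset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_replication_csv <- function(repset, path) {
  df <- data.frame(strategy = repset$strategy, rep = seq_len(repset$n_reps),
                   seed = repset$seeds, repset$rep_means, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a comparison (and optional population scaling) to JSON
#' @param cmp a `headsim_comparison`.
#' @param path output JSON path.
#' @param extra optional named list merged into the report.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(cmp, path, extra = NULL) {
  keep <- c("strategy_a", "strategy_b", "n_reps", "paired", "delta_qaly",
            "delta_cost", "delta_wait", "nmb_a", "nmb_b", "inmb", "inmb_se",
            "wtp")
  x <- unclass(cmp)[intersect(keep, names(cmp))]
  if (!is.null(extra)) x <- c(x, extra)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the configuration file and
#' its MD5 hash, the command/description, the seed, the package version, a
#' timestamp, and the list of output files written.
#'
#' @param path manifest path (JSON).
#' @param config_path configuration file consumed.
#' @param seed base seed used.
#' @param command free-text description of the run.
#' @param outputs character vector of output files.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config_path, seed, command, outputs) {
  man <- list(
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    seed = as.integer(seed),
    command = command,
    package_version = as.character(utils::packageVersion("headsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Boxplot-style view of scenario results
#'
#' Per-replication distributions of an outcome across scenarios and
#' strategies. Requires ggplot2.
#'
#' @param scn a `headsim_scenarios` object.
#' @param outcome column of the replication table to plot.
#' @return a ggplot object.
#' @export
plot_scenarios <- function(scn, outcome = "wait_days") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- scn$rep_table
  df$scenario <- factor(df$scenario)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[["scenario"]],
                                   y = .data[[outcome]],
                                   fill = .data[["strategy"]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "scenario (0 = base case)", y = outcome) +
    ggplot2::theme_minimal()
}
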