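#' Pipeline configuration
#'
#' Bundles the analysis constants of the extraction pipeline. Exactly one of
#' `short_k` (adaptive threshold, `k` times the minimum interval of each
#' series, the default rule) or `threshold_ms` (a fixed absolute cut such as
#' 3900 ms) governs the within-bout filtering.
#'
#' @param retain_labels Annotation labels retained as calls (default
#'   `"MAC"`, the mother-attraction calls).
#' @param tier TextGrid tier name; `NULL` uses all interval tiers.
#' @param strip Whitespace-strip labels before matching (default `TRUE`).
#' @param min_pitch Intensity-analysis minimum pitch, Hz (default 100).
#' @param time_step Intensity frame step, seconds (default `0.8/min_pitch`).
#' @param short_k Adaptive threshold multiplier (default 4).
#' @param threshold_ms Optional fixed threshold in ms overriding `short_k`.
#' @param boundary_inclusive Keep intervals equal to the threshold
#'   (default `TRUE`).
#' @param round_digits CSV rounding digits (default 1, i.e. 0.1 ms).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(retain_labels = "MAC", tier = NULL, strip = TRUE,
                            min_pitch = 100, time_step = 0.8 / min_pitch,
                            short_k = 4, threshold_ms = NULL,
                            boundary_inclusive = TRUE, round_digits = 1) {
  stopifnot(min_pitch > 0, time_step > 0, short_k > 0,
            is.null(threshold_ms) || threshold_ms > 0)
  structure(list(
    retain_labels = retain_labels, tier = tier, strip = strip,
    min_pitch = min_pitch, time_step = time_step,
    short_k = short_k, threshold_ms = threshold_ms,
    boundary_inclusive = boundary_inclusive, round_digits = round_digits
  ), class = "pipeline_config")
}

series_filenames <- c(
  duration = "durations_all.csv", IOI = "IOI_all.csv", IPI = "IPI_all.csv",
  IOI_short = "IOI_short.csv", IPI_short = "IPI_short.csv"
)

#' Run the full extraction pipeline
#'
#' The end-to-end workflow: parse the TextGrid, retain the labelled calls,
#' read the audio and locate each call's maximum-intensity peak, derive the
#' five interval series (durations, IOI, IPI and their within-bout subsets),
#' write them as CSV, and compute the descriptive statistics and the two
#' Kolmogorov–Smirnov comparisons (IOI vs IPI, IOI_short vs IPI_short).
#'
#' With fewer than two retained calls only the duration series is
#' meaningful; the interval CSVs are still written (header only) and a
#' warning is raised.
#'
#' @param audio Path to the WAV recording.
#' @param textgrid Path to the TextGrid annotation.
#' @param out_dir Output directory for the five CSVs and `report.json`.
#' @param config A [pipeline_config()].
#' @return A `rhythm_report` (invisibly): summary statistics for every
#'   non-empty series, the KS comparisons, the config, and the file paths
#'   written.
#' @export
run_extraction <- function(audio, textgrid, out_dir,
                           config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tg <- read_textgrid(textgrid)
  if (!is.null(config$tier) && !config$tier %in% tg$tier) {
    abort(paste0("tier '", config$tier, "' missing from ", textgrid))
  }
  calls <- select_calls(tg, labels = config$retain_labels, tier = config$tier,
                        strip = config$strip)
  w <- read_wav(audio)
  contour <- intensity_contour(w, min_pitch = config$min_pitch,
                               time_step = config$time_step)
  if (nrow(calls) > 0) calls <- call_peaks(calls, contour)

  series <- list(duration = call_durations(calls))
  if (nrow(calls) >= 2) {
    ioi <- inter_onset_intervals(calls)
    ipi <- inter_peak_intervals(calls)
    thr_ioi <- if (!is.null(config$threshold_ms)) config$threshold_ms else
      short_threshold(ioi, config$short_k)
    thr_ipi <- if (!is.null(config$threshold_ms)) config$threshold_ms else
      short_threshold(ipi, config$short_k)
    series$IOI <- ioi
    series$IPI <- ipi
    series$IOI_short <- filter_short(ioi, thr_ioi, config$boundary_inclusive)
    series$IPI_short <- filter_short(ipi, thr_ipi, config$boundary_inclusive)
  } else {
    warn("fewer than 2 retained calls: interval series are empty, reporting durations only")
    series$IOI <- interval_series(numeric(0), "IOI")
    series$IPI <- interval_series(numeric(0), "IPI")
    series$IOI_short <- interval_series(numeric(0), "IOI_short")
    series$IPI_short <- interval_series(numeric(0), "IPI_short")
  }

  paths <- character(0)
  for (k in names(series_filenames)) {
    p <- file.path(out_dir, series_filenames[[k]])
    write_interval_csv(series[[k]], p, digits = config$round_digits)
    paths[k] <- p
  }

  report <- rhythm_report(series, config)
  report$files <- as.list(paths)
  write_report_json(report, file.path(out_dir, "report.json"))
  invisible(report)
}

#' Compute the statistics report from interval CSVs
#'
#' Recomputes the descriptive statistics and KS comparisons from CSV files
#' alone (the schema of [write_interval_csv()], which also covers the
#' deposited data files) — no audio needed.
#'
#' @param csvs Character vector of CSV paths; series kinds are inferred
#'   from the header row.
#' @param out Optional path for a JSON report.
#' @return A `rhythm_report`.
#' @export
run_stats <- function(csvs, out = NULL) {
  series <- lapply(csvs, read_interval_csv)
  names(series) <- vapply(series, series_kind, character(1))
  if (anyDuplicated(names(series))) {
    names(series) <- make.unique(names(series))
  }
  report <- rhythm_report(series, config = NULL)
  if (!is.null(out)) write_report_json(report, out)
  report
}

# Shared report builder: summaries for every non-empty series + the two
# planned KS comparisons when both sides exist.
rhythm_report <- function(series, config = NULL) {
  stats <- bind_rows(lapply(series[vapply(series, nrow, integer(1)) > 0],
                            summarize_series))
  ks <- list()
  if (all(c("IOI", "IPI") %in% names(series)) &&
      nrow(series$IOI) > 0 && nrow(series$IPI) > 0) {
    ks$IOI_vs_IPI <- ks_two_sample(series$IOI, series$IPI)
  }
  if (all(c("IOI_short", "IPI_short") %in% names(series)) &&
      nrow(series$IOI_short) > 0 && nrow(series$IPI_short) > 0) {
    ks$IOI_short_vs_IPI_short <- ks_two_sample(series$IOI_short, series$IPI_short)
  }
  structure(list(
    stats = stats, ks = ks, series = series, config = config,
    version = as.character(utils::packageVersion("sealrhythm"))
  ), class = "rhythm_report")
}

write_report_json <- function(report, path) {
  ks <- lapply(report$ks, function(k) list(d = k$d, p = k$p, n1 = k$n1, n2 = k$n2))
  payload <- list(
    stats = as.data.frame(report$stats),
    ks = ks,
    config = if (!is.null(report$config)) unclass(report$config) else NULL,
    version = report$version
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       null = "null")
  invisible(path)
}

#' @export
print.rhythm_report <- function(x, ...) {
  cat("Vocal rhythm report (sealrhythm ", x$version, ")\n\n", sep = "")
  print(as.data.frame(x$stats), row.names = FALSE, digits = 6)
  for (nm in names(x$ks)) {
    k <- x$ks[[nm]]
    cat(sprintf("\n%s: D = %.2f, p = %.2f (n1 = %d, n2 = %d)",
                gsub("_", " ", nm), k$d, k$p, k$n1, k$n2))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a rhythm report
#'
#' @param x A `rhythm_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-series summary tibble. `glance()`: one row per
#'   KS comparison.
#' @exportS3Method generics::tidy
tidy.rhythm_report <- function(x, ...) x$stats

#' @rdname tidy.rhythm_report
#' @exportS3Method generics::glance
glance.rhythm_report <- function(x, ...) {
  bind_rows(lapply(names(x$ks), function(nm) {
    dplyr::mutate(tidy(x$ks[[nm]]), comparison = nm, .before = 1)
  }))
}

#' Generate a synthetic fixture from a spec
#'
#' Thin wrapper around [emit_fixture()] that also accepts a JSON spec file
#' (the format written into `truth.json`).
#'
#' @param spec A [synthetic_spec()] or path to a JSON file with a `spec`
#'   object (or the spec fields at top level).
#' @param out_dir Output directory.
#' @param seed Seed override (default: the spec's own seed).
#' @return Invisibly, the file list from [emit_fixture()].
#' @export
run_simulate <- function(spec, out_dir, seed = NULL) {
  if (is.character(spec)) {
    raw <- jsonlite::read_json(spec, simplifyVector = TRUE)
    fields <- if (!is.null(raw$spec)) raw$spec else raw
    fields <- fields[names(fields) %in% names(formals(synthetic_spec))]
    dists <- intersect(names(fields), c("calls_per_bout", "within_ioi",
                                        "between_gap", "duration", "peak_rel_pos"))
    fields[dists] <- lapply(fields[dists], as_dist_spec)
    spec <- do.call(synthetic_spec, fields)
  }
  if (is.null(seed)) seed <- spec$seed
  emit_fixture(spec, out_dir, seed = seed)
}
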