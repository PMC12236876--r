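#' Default pipeline run configuration
#'
#' Assembles the full configuration for [run_pipeline()]: cohort
#' generation spec, geometry, QC rules, load thresholds, the adherence
#' minimum and the significance level. The adherence default (1.0 h
#' median daily loading time) is chosen to separate a participant who
#' records only an hour or three per day from one wearing the insole
#' through a normal day (roughly 1-2.5 loading hours).
#'
#' @param seed integer seed (mandatory for simulation).
#' @param n_participants,n_days cohort dimensions.
#' @param schedule_scale duration scale of the synthetic days (see
#'   [default_schedule_spec()]).
#' @param adherence_min_h adherence threshold in hours.
#' @param alpha significance level for correlations.
#' @param output_dir optional directory for stage CSV outputs (`NULL`
#'   keeps everything in memory).
#' @return a nested config list.
#' @export
default_run_config <- function(seed = 1, n_participants = 15, n_days = 10,
                               schedule_scale = 1, adherence_min_h = 1.0,
                               alpha = 0.05, output_dir = NULL) {
  list(seed = seed,
       cohort = list(n_participants = n_participants, n_days = n_days,
                     schedule_scale = schedule_scale),
       geometry = list(r_heel = -0.06, r_mid = 0.04, r_fore = 0.11,
                       r_at = 0.05, size_factor = 1),
       qc = qc_rules(),
       thresholds = list(overall = 0.3, high = 3.0),
       adherence_min_h = adherence_min_h,
       alpha = alpha,
       output_dir = output_dir)
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_run_config()] values; thresholds
#' are validated.
#'
#' @param path YAML file path.
#' @return a config list as from [default_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_into(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  validate_run_config(merge_into(cfg, user))
}

validate_run_config <- function(config) {
  if (is.null(config$seed))
    stop("config: seed is mandatory", call. = FALSE)
  if (config$cohort$n_participants < 1)
    stop("config: n_participants must be >= 1", call. = FALSE)
  th <- config$thresholds
  if (!(th$overall > 0 && th$high > th$overall))
    stop("config: thresholds must satisfy 0 < overall < high",
         call. = FALSE)
  if (config$adherence_min_h < 0)
    stop("config: adherence_min_h must be >= 0", call. = FALSE)
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("config: alpha must be in (0, 1)", call. = FALSE)
  config
}

config_geometry <- function(config) {
  g <- config$geometry
  sensor_geometry(r_heel = g$r_heel, r_mid = g$r_mid, r_fore = g$r_fore,
                  r_at = g$r_at, size_factor = g$size_factor)
}

config_thresholds <- function(config)
  load_thresholds(config$thresholds$overall, config$thresholds$high)

#' Run the full monitoring analysis pipeline
#'
#' Orchestrates simulate -> QC -> estimate -> summarize -> subsample ->
#' correlate on either a synthetic cohort (generated from the config
#' seed) or a pre-built cohort bundle. Every dropped recording and
#' excluded participant is logged with its reason; rerunning with the
#' same config reproduces identical results.
#'
#' @param config a config list from [default_run_config()] or
#'   [read_run_config()].
#' @param cohort optional `synthetic_cohort` (or compatible list with
#'   `recordings`, `clinical`, `profiles`) to analyze instead of
#'   simulating; `NULL` simulates from the config.
#' @param artifacts optional artifact spec forwarded to the simulator.
#' @return object of class `tendon_run`: config, QC report table, day
#'   and participant summaries, excluded participants, subsampling
#'   curve, correlation table, ground truth (when synthetic) and the run
#'   log. Stage CSVs are written when `config$output_dir` is set.
#' @export
run_pipeline <- function(config = default_run_config(), cohort = NULL,
                         artifacts = NULL) {
  config <- validate_run_config(config)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  geometry <- config_geometry(config)
  thresholds <- config_thresholds(config)

  if (is.null(cohort)) {
    say("simulate: %d participants x %d days, seed %s",
        config$cohort$n_participants, config$cohort$n_days,
        format(config$seed))
    cohort <- simulate_cohort(
      n_participants = config$cohort$n_participants,
      n_days = config$cohort$n_days, seed = config$seed,
      schedule_spec = default_schedule_spec(
        scale = config$cohort$schedule_scale),
      artifacts = artifacts, geometry = geometry,
      thresholds = thresholds)
  } else {
    say("using provided cohort (%d recordings)",
        length(cohort$recordings))
  }
  bw <- stats::setNames(cohort$profiles$bw_n,
                        cohort$profiles$participant_id)

  # QC + estimate + per-recording summaries, one recording at a time
  qc_rows <- vector("list", length(cohort$recordings))
  sum_rows <- vector("list", length(cohort$recordings))
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    res <- qc_recording(rec, bw[[rec$participant_id]], geometry,
                        config$qc,
                        overall_threshold_bw = thresholds$overall)
    qc_rows[[i]] <- as.data.frame(res$report)
    if (res$report$disposition == "drop") {
      say("qc: drop %s day %d session %d (%s)", rec$participant_id,
          rec$day, rec$session, paste(res$report$flags, collapse = ";"))
      next
    }
    series <- estimate_tendon_load(res$recording, geometry,
                                   bw[[rec$participant_id]])
    sum_rows[[i]] <- as.data.frame(summarize_series(series, thresholds))
  }
  qc_report <- do.call(rbind, qc_rows)
  rec_df <- do.call(rbind, sum_rows)
  if (is.null(rec_df) || nrow(rec_df) == 0)
    stop("summarize: no recordings survived quality control",
         call. = FALSE)
  day_df <- day_summaries(rec_df)

  # adherence
  excluded <- character(0)
  for (id in unique(day_df$participant_id)) {
    sub <- day_df[day_df$participant_id == id, , drop = FALSE]
    if (check_adherence(sub, config$adherence_min_h) == "exclude") {
      excluded <- c(excluded, id)
      say("adherence: exclude %s (median daily loading %.2f h < %.2f h)",
          id, stats::median(sub$t_load_h), config$adherence_min_h)
    }
  }
  day_kept <- day_df[!day_df$participant_id %in% excluded, , drop = FALSE]
  if (nrow(day_kept) == 0)
    stop("all participants excluded by the adherence check",
         call. = FALSE)
  part_df <- participant_summaries(day_kept)

  subsampling <- tryCatch(subsampling_curve(day_kept),
                          error = function(e) {
                            say("subsample: skipped (%s)",
                                conditionMessage(e))
                            NULL
                          })
  correlations <- tryCatch(
    correlation_table(part_df, cohort$clinical, config$alpha),
    error = function(e) {
      say("correlate: skipped (%s)", conditionMessage(e))
      NULL
    })

  out <- structure(list(config = config, qc_report = qc_report,
                        day_summaries = day_df,
                        participant_summaries = part_df,
                        excluded = excluded, subsampling = subsampling,
                        correlations = correlations,
                        ground_truth = cohort$ground_truth,
                        clinical = cohort$clinical, log = log),
                   class = "tendon_run")
  if (!is.null(config$output_dir)) write_run(out, config$output_dir)
  out
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$qc_report, file.path(dir, "qc_report.csv"),
                   row.names = FALSE)
  utils::write.csv(run$day_summaries,
                   file.path(dir, "day_summaries.csv"), row.names = FALSE)
  utils::write.csv(run$participant_summaries,
                   file.path(dir, "participant_summaries.csv"),
                   row.names = FALSE)
  if (!is.null(run$subsampling))
    utils::write.csv(as.data.frame(run$subsampling),
                     file.path(dir, "subsampling.csv"), row.names = FALSE)
  if (!is.null(run$correlations))
    utils::write.csv(as.data.frame(run$correlations),
                     file.path(dir, "correlations.csv"),
                     row.names = FALSE)
  writeLines(run$log, file.path(dir, "run.log"))
  writeLines(yaml::as.yaml(run$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.tendon_run <- function(x, ...) {
  cat("<tendon_run>\n")
  cat(sprintf("  %d recordings through QC, %d dropped\n",
              nrow(x$qc_report),
              sum(x$qc_report$disposition == "drop")))
  cat(sprintf("  %d participants summarized, %d excluded by adherence\n",
              nrow(x$participant_summaries), length(x$excluded)))
  invisible(x)
}

#' @export
summary.tendon_run <- function(object, ...) {
  p <- object$participant_summaries
  cat("Per-participant normalized cumulative Achilles tendon load\n")
  cat(sprintf("  L_overall (xBW per loading h): mean %.3f, SD %.3f, range %.3f-%.3f\n",
              mean(p$l_overall), stats::sd(p$l_overall),
              min(p$l_overall), max(p$l_overall)))
  cat(sprintf("  L_high    (xBW per loading h): mean %.3f, SD %.3f, range %.3f-%.3f\n",
              mean(p$l_high), stats::sd(p$l_high), min(p$l_high),
              max(p$l_high)))
  cat(sprintf("  total loading time (h): mean %.1f, range %.1f-%.1f\n",
              mean(p$t_load_h), min(p$t_load_h), max(p$t_load_h)))
  if (!is.null(object$correlations)) {
    strong <- as.data.frame(object$correlations)
    strong <- strong[!is.na(strong$strength) &
                       strong$strength == "strong", ]
    cat(sprintf("  strong correlations: %d of %d\n", nrow(strong),
                nrow(object$correlations)))
  }
  invisible(object)
}
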