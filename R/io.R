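#' Write an insole recording to CSV
#'
#' Session dialect: four `key,value` header lines (`participant_id`,
#' `day`, `session`, `sample_rate_hz`), a column header
#' `time_s,f_heel_n,f_mid_n,f_fore_n`, then one row per sample. Time is
#' stored explicitly (3 decimal places) even though it is implied by the
#' rate, so that logger gaps can be detected at read time; forces are
#' serialized at 6 significant digits. Output is deterministic: two
#' writes of the same recording are byte-identical.
#'
#' @param recording an [insole_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "insole_recording"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(sprintf("participant_id,%s", recording$participant_id),
           sprintf("day,%d", recording$day),
           sprintf("session,%d", recording$session),
           sprintf("sample_rate_hz,%s",
                   format(recording$sample_rate_hz, digits = 6)),
           "time_s,f_heel_n,f_mid_n,f_fore_n")
  writeLines(hdr, con, sep = "\n")
  n <- n_samples(recording)
  if (n > 0) {
    rows <- sprintf("%.3f,%s,%s,%s", sample_times(recording),
                    formatC(recording$f_heel, format = "g", digits = 6),
                    formatC(recording$f_mid, format = "g", digits = 6),
                    formatC(recording$f_fore, format = "g", digits = 6))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Read an insole recording from CSV
#'
#' Parses the session dialect written by [write_recording()]. The parse
#' is strict: missing header keys or columns, non-numeric cells, and a
#' non-uniform implied timestep all raise a format error naming the
#' offending line.
#'
#' @param path file path.
#' @return an [insole_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 5)
    stop("format error in ", path, ": expected 4 header lines and a ",
         "column header", call. = FALSE)
  hdr <- strsplit(lines[1:4], ",", fixed = TRUE)
  keys <- vapply(hdr, `[`, character(1), 1)
  need <- c("participant_id", "day", "session", "sample_rate_hz")
  if (!identical(keys, need))
    stop("format error in ", path, " line ", which(keys != need)[1],
         ": expected header key '", need[which(keys != need)[1]], "'",
         call. = FALSE)
  vals <- vapply(hdr, function(x) paste(x[-1], collapse = ","),
                 character(1))
  cols <- strsplit(lines[5], ",", fixed = TRUE)[[1]]
  expected_cols <- c("time_s", "f_heel_n", "f_mid_n", "f_fore_n")
  if (!identical(cols, expected_cols))
    stop("format error in ", path, " line 5: column header must be ",
         paste(expected_cols, collapse = ","), call. = FALSE)
  rate <- suppressWarnings(as.numeric(vals[4]))
  if (!is.finite(rate) || rate <= 0)
    stop("format error in ", path, " line 4: invalid sample rate",
         call. = FALSE)
  body <- lines[-(1:5)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(insole_recording(numeric(0), numeric(0), numeric(0),
                            sample_rate_hz = rate,
                            participant_id = vals[1],
                            day = as.integer(vals[2]),
                            session = as.integer(vals[3])))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4))
    stop("format error in ", path, " line ", which(nf != 4)[1] + 5,
         ": expected 4 fields", call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 4,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("format error in ", path, " line ", bad + 5,
         ": non-numeric cell", call. = FALSE)
  }
  if (nrow(m) > 1) {
    dts <- diff(m[, 1])
    off <- which(abs(dts - 1 / rate) > 1.5e-3)
    if (length(off) > 0)
      stop("format error in ", path, " line ", off[1] + 6,
           ": non-uniform timestep (logger gap?)", call. = FALSE)
  }
  insole_recording(m[, 2], m[, 3], m[, 4], sample_rate_hz = rate,
                   participant_id = vals[1], day = as.integer(vals[2]),
                   session = as.integer(vals[3]))
}

#' The 13 canonical clinical measure column names
#'
#' Seven dynamometer-based plantar flexor capacity measures (peak moment
#' isometric / slow / fast isokinetic; peak power and mechanical work at
#' slow / fast isokinetic speed), three motion-capture dynamic function
#' measures (double-leg heel raise height, single-leg countermovement
#' jump height, inclined single-leg heel raise repetitions), and three
#' survey measures (age, VISA-A, PAS).
#'
#' @return character vector of length 13.
#' @export
clinical_measure_names <- function() {
  c("pf_moment_isometric", "pf_moment_isokinetic_slow",
    "pf_moment_isokinetic_fast", "pf_power_isokinetic_slow",
    "pf_power_isokinetic_fast", "pf_work_isokinetic_slow",
    "pf_work_isokinetic_fast", "heel_raise_height_pbh",
    "cmj_height_pbh", "heel_raise_reps_incline",
    "age_y", "visa_a", "pas")
}

#' Write / read a cohort session manifest
#'
#' The manifest lists every session file: one row per
#' (participant, day, session) with its relative file path and nominal
#' date.
#'
#' @param manifest data frame with columns `participant_id`, `day`,
#'   `session`, `path`, `date`.
#' @param path manifest CSV path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the
#'   manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("participant_id", "day", "session", "path", "date")
  stopifnot(is.data.frame(manifest), all(need %in% names(manifest)))
  utils::write.csv(manifest[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "day", "session", "path", "date")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(m$participant_id, m$day, m$session)
  if (anyDuplicated(key))
    stop("manifest has duplicate (participant, day, session) entries",
         call. = FALSE)
  m
}

#' Write a clinical table to CSV
#'
#' @param clinical data frame with `participant_id`, `mass_kg`,
#'   `height_m` and the [clinical_measure_names()] columns. Missing
#'   values are written as empty cells.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  stopifnot(is.data.frame(clinical))
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read and validate cohort tables
#'
#' Loads the session manifest and the clinical table, then validates
#' both: every manifest path must resolve (relative to the manifest's
#' directory), participant ids must be unique in the clinical table, the
#' 13 canonical measures plus mass and height must be present (missing
#' values are allowed as empty cells and propagate as `NA`), unknown
#' columns are dropped with a warning, and VISA-A / PAS values must lie
#' in their defined ranges (0-100 and 1-6).
#'
#' @param manifest_path manifest CSV path.
#' @param clinical_path clinical table CSV path.
#' @return list with `manifest` and `clinical` data frames.
#' @export
read_cohort_tables <- function(manifest_path, clinical_path) {
  manifest <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  full <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$path), manifest$path,
                 file.path(base, manifest$path))
  missing_files <- !file.exists(full)
  if (any(missing_files))
    stop("manifest references missing file(s): ",
         paste(utils::head(manifest$path[missing_files], 3),
               collapse = ", "), call. = FALSE)
  manifest$resolved_path <- full

  if (!file.exists(clinical_path))
    stop("file not found: ", clinical_path, call. = FALSE)
  clin <- utils::read.csv(clinical_path, stringsAsFactors = FALSE)
  if (anyDuplicated(clin$participant_id))
    stop("clinical table has duplicate participant id(s)", call. = FALSE)
  need <- c("participant_id", "mass_kg", "height_m",
            clinical_measure_names())
  miss <- setdiff(need, names(clin))
  if (length(miss) > 0)
    stop("clinical table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(clin), need)
  if (length(extra) > 0) {
    warning("ignoring unknown clinical column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    clin <- clin[need]
  }
  v <- clin$visa_a
  if (any(!is.na(v) & (v < 0 | v > 100)))
    stop("clinical table: VISA-A out of range 0-100", call. = FALSE)
  p <- clin$pas
  if (any(!is.na(p) & (p < 1 | p > 6)))
    stop("clinical table: PAS out of range 1-6", call. = FALSE)
  if (any(!is.na(clin$mass_kg) & clin$mass_kg <= 0))
    stop("clinical table: non-positive body mass", call. = FALSE)
  list(manifest = manifest, clinical = clin)
}

#' Write a synthetic cohort to disk
#'
#' Writes every session recording, the manifest and the clinical table
#' under `dir` in the formats read by [read_recording()] and
#' [read_cohort_tables()], plus the ground-truth table and the
#' generation seed (for provenance).
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- lapply(cohort$recordings, function(r) {
    rel <- sprintf("sessions/%s_d%02d_s%02d.csv", r$participant_id,
                   r$day, r$session)
    write_recording(r, file.path(dir, rel))
    data.frame(participant_id = r$participant_id, day = r$day,
               session = r$session, path = rel,
               date = format(as.Date("2026-01-01") + r$day - 1),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.csv"))
  utils::write.csv(cohort$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  writeLines(format(cohort$seed), file.path(dir, "seed.txt"))
  invisible(list(manifest = file.path(dir, "manifest.csv"),
                 clinical = file.path(dir, "clinical.csv"),
                 ground_truth = file.path(dir, "ground_truth.csv")))
}
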