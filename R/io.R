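# Readers/writers for motion-capture text formats (TRC, MOT/STO), run
# configuration and model serialization.

#' Write marker trajectories to a TRC file
#'
#' Standard tab-separated TRC with DataRate/NumFrames header; planar
#' markers are written with Z = 0.
#'
#' @param trial a `gait_trial` (markers + time)
#' @param path output path
#' @param units `"m"` or `"mm"`
#' @return `path`, invisibly
#' @export
write_trc <- function(trial, path, units = "m") {
  mk <- trial$markers
  n <- dim(mk)[1L]; nm <- dim(mk)[2L]
  rate <- trial$meta$fs %||% round(1 / mean(diff(trial$time)))
  scale <- if (units == "mm") 1000 else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d",
                     rate, rate, n, nm, units, rate, n), con)
  hdr <- c("Frame#", "Time",
           as.vector(rbind(dimnames(mk)[[2L]], "", "")))
  writeLines(paste(hdr, collapse = "\t"), con)
  sub <- c("", "", as.vector(vapply(seq_len(nm), function(k)
    paste0(c("X", "Y", "Z"), k), character(3L))))
  writeLines(paste(sub, collapse = "\t"), con)
  for (i in seq_len(n)) {
    vals <- as.vector(vapply(seq_len(nm), function(k)
      c(mk[i, k, 1L] * scale, mk[i, k, 2L] * scale, 0), numeric(3L)))
    writeLines(paste(c(i, sprintf("%.12g", trial$time[i]),
                       sprintf("%.12g", vals)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read marker trajectories from a TRC file
#'
#' Honors the Units header (mm converted to m on load).
#'
#' @param path TRC file path
#' @return list with `time`, `markers` (frames x markers x 2, planar X/Y),
#'   `rate`, `units` (always `"m"` after conversion)
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) stop("malformed TRC: fewer than 6 lines")
  meta_keys <- strsplit(lines[2L], "\t")[[1L]]
  meta_vals <- strsplit(lines[3L], "\t")[[1L]]
  if (length(meta_vals) < length(meta_keys))
    stop("malformed TRC header at line 3: expected ",
         length(meta_keys), " fields")
  meta <- stats::setNames(as.list(meta_vals), meta_keys)
  units <- meta$Units
  if (!units %in% c("m", "mm"))
    stop("malformed TRC header at line 3: unknown Units '", units, "'")
  scale <- if (units == "mm") 1 / 1000 else 1
  hdr <- strsplit(lines[4L], "\t")[[1L]]
  mnames <- hdr[seq(3L, length(hdr), by = 3L)]
  mnames <- mnames[nzchar(mnames)]
  dat <- utils::read.table(text = lines[-(1L:5L)], sep = "\t",
                           header = FALSE, fill = TRUE)
  n <- nrow(dat); nm <- length(mnames)
  if (ncol(dat) < 2L + 3L * nm)
    stop("malformed TRC data: expected ", 2L + 3L * nm, " columns")
  markers <- array(0, dim = c(n, nm, 2L),
                   dimnames = list(NULL, mnames, c("x", "y")))
  for (k in seq_len(nm)) {
    markers[, k, 1L] <- dat[[2L + 3L * (k - 1L) + 1L]] * scale
    markers[, k, 2L] <- dat[[2L + 3L * (k - 1L) + 2L]] * scale
  }
  list(time = dat[[2L]], markers = markers,
       rate = as.numeric(meta$DataRate), units = "m")
}

#' Write a data table to an OpenSim-style MOT/STO file
#'
#' @param df data.frame whose first column is `time`
#' @param path output path
#' @param name dataset name written in the header
#' @param in_degrees value for the `inDegrees` header flag
#' @return `path`, invisibly
#' @export
write_mot <- function(df, path, name = "gaitsim", in_degrees = FALSE) {
  if (names(df)[1L] != "time") stop("first column must be 'time'")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               "version=1",
               sprintf("nRows=%d", nrow(df)),
               sprintf("nColumns=%d", ncol(df)),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(df), collapse = "\t")), con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an OpenSim-style MOT/STO file
#'
#' @param path file path
#' @return data.frame (first column `time`) with attributes `name` and
#'   `in_degrees`
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "endheader")
  if (!length(end))
    stop("malformed MOT/STO: missing 'endheader' (", path, ")")
  end <- end[1L]
  hdr <- lines[seq_len(end - 1L)]
  getval <- function(key) {
    hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA
  }
  cn <- strsplit(lines[end + 1L], "\t")[[1L]]
  dat <- utils::read.table(text = lines[-(1L:(end + 1L))], sep = "\t",
                           header = FALSE, col.names = cn,
                           check.names = FALSE)
  nrows <- suppressWarnings(as.integer(getval("nRows")))
  if (!is.na(nrows) && nrows != nrow(dat))
    stop(sprintf("malformed MOT/STO: nRows=%d but %d data rows (line %d)",
                 nrows, nrow(dat), end + 2L))
  attr(dat, "name") <- hdr[1L]
  attr(dat, "in_degrees") <- identical(getval("inDegrees"), "yes")
  dat
}

#' Default run configuration
#'
#' Every tunable of the pipeline with its documented default; serialize
#' with [write_config()] / [read_config()] (JSON).
#'
#' @return a named list
#' @export
default_config <- function() {
  list(
    cohorts = list(
      normal = unclass(cohort_spec("normal")),
      obese = unclass(cohort_spec("obese"))),
    obesity_severity = 1,
    filter_cutoff_hz = 6,
    event_threshold_n = 20,
    reserve_weight = 1000,
    marker_noise_sd = 0.002,
    iaa = list(constraint = "pin_at_cop", dt = 0.01),
    t_test = list(var_equal = TRUE),
    seed = 42,
    output_dir = "gaitsim_out")
}

#' @rdname default_config
#' @param config configuration list
#' @param path file path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  out <- utils::modifyList(base, cfg)
  for (gname in names(out$cohorts))
    out$cohorts[[gname]] <- structure(
      utils::modifyList(unclass(cohort_spec(gname)), out$cohorts[[gname]]),
      class = "cohort_spec")
  out
}

#' Serialize / load a waveform template set (JSON)
#'
#' @param wf a [gait_waveforms()] set
#' @param path file path
#' @export
write_waveforms <- function(wf, path) {
  jsonlite::write_json(unclass(wf), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gait_waveforms(
    hip = as.data.frame(raw$knots$hip),
    knee = as.data.frame(raw$knots$knee),
    ankle = as.data.frame(raw$knots$ankle),
    pelvis_tilt_deg = raw$pelvis_tilt_deg,
    pelvis_osc_amp = raw$pelvis_osc_amp,
    pelvis_fore_aft_amp = raw$pelvis_fore_aft_amp,
    cadence_slope = raw$cadence_slope,
    cadence_intercept = raw$cadence_intercept,
    stance_fraction = raw$stance_fraction,
    smooth_sd = raw$smooth_sd %||% 2,
    interp = stats::setNames(unlist(raw$interp), c("hip", "knee", "ankle")),
    pelvis_vert_phase = raw$pelvis_vert_phase %||% 0.045,
    trunk_lean_deg = raw$trunk_lean_deg %||% 5,
    cop_rollover = if (is.null(raw$cop_rollover)) NULL else
      lapply(raw$cop_rollover, as.numeric))
}

#' Serialize / load a scaled model as structured text (JSON)
#'
#' @param model a scaled `gait_model`
#' @param path file path
#' @export
write_model <- function(model, path) {
  m <- model
  m$.com_specs <- NULL
  # named length-1 vectors lose names under auto_unbox; store arms as lists
  m$muscles <- lapply(m$muscles, function(mu) {
    mu$arms <- as.list(mu$arms)
    mu
  })
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$subject <- structure(raw$subject, class = "subject_anthropometry")
  raw$muscles <- lapply(raw$muscles, function(m) {
    m$arms <- unlist(m$arms)
    for (f in c("origin", "insertion", "via"))
      if (!is.null(m[[f]])) m[[f]]$local <- as.numeric(m[[f]]$local)
    m
  })
  raw$segments <- lapply(raw$segments, as.list)
  raw$gravity <- as.numeric(raw$gravity)
  structure(raw, class = "gait_model")
}
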