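#' Frame schedule for a dynamic PET acquisition
#'
#' Builds and validates a table of PET time frames. Frames are half-open
#' intervals `[frame_start, frame_end)` in seconds from injection start;
#' they must be strictly increasing and non-overlapping. Frame mid-times
#' and durations are added as derived columns.
#'
#' @param frame_start Numeric vector of frame start times (s).
#' @param frame_end Numeric vector of frame end times (s).
#' @return A tibble with columns `frame_start`, `frame_end`, `mid`, `dur`.
#' @examples
#' frame_schedule(c(0, 2, 4), c(2, 4, 10))
#' @export
frame_schedule <- function(frame_start, frame_end) {
  if (length(frame_start) != length(frame_end)) {
    stop("frame_start and frame_end must have equal length", call. = FALSE)
  }
  if (length(frame_start) == 0) stop("schedule must have at least one frame", call. = FALSE)
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end))) {
    stop("frame boundaries must be finite", call. = FALSE)
  }
  bad <- which(frame_end <= frame_start)
  if (length(bad) > 0) {
    stop(sprintf("frame %d ends (%.6g s) at or before it starts (%.6g s)",
                 bad[1], frame_end[bad[1]], frame_start[bad[1]]), call. = FALSE)
  }
  if (length(frame_start) > 1) {
    ov <- which(frame_start[-1] < frame_end[-length(frame_end)])
    if (length(ov) > 0) {
      stop(sprintf("frame %d starts (%.6g s) before frame %d ends (%.6g s)",
                   ov[1] + 1, frame_start[ov[1] + 1], ov[1], frame_end[ov[1]]),
           call. = FALSE)
    }
  }
  tibble::tibble(
    frame_start = as.numeric(frame_start),
    frame_end = as.numeric(frame_end),
    mid = (frame_start + frame_end) / 2,
    dur = frame_end - frame_start
  )
}

#' Default mouse PET frame schedule
#'
#' A 45.5-minute schedule with frames that shorten towards the injection:
#' 30 x 2 s, 14 x 5 s, 10 x 10 s, 10 x 30 s, 22 x 100 s (2730 s total).
#'
#' @return A frame-schedule tibble (see [frame_schedule()]).
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(2, 30), rep(5, 14), rep(10, 10), rep(30, 10), rep(100, 22))
  end <- cumsum(dur)
  frame_schedule(end - dur, end)
}

#' Construct a dense (regularly sampled) curve
#'
#' Continuous detector traces and model curves are represented as tibbles
#' with a `time` column (seconds) and a `value` column. The default dense
#' sampling step used throughout the package is 1 s.
#'
#' @param time Sample times (s), sorted.
#' @param value Values at those times.
#' @param units Units label, `"SUV"` or `"kBq/ml"` (or `"counts"` for raw
#'   detector traces).
#' @param region Optional region label.
#' @return A tibble with columns `time`, `value`, `units`, `region`.
#' @export
dense_curve <- function(time, value, units = "SUV", region = "whole_blood") {
  if (length(time) != length(value)) stop("time and value lengths differ", call. = FALSE)
  if (is.unsorted(time)) stop("time must be sorted increasing", call. = FALSE)
  if (any(!is.finite(value))) stop("curve values must be finite", call. = FALSE)
  tibble::tibble(time = as.numeric(time), value = as.numeric(value),
                 units = units, region = region)
}

#' Construct a framed time-activity curve
#'
#' @param schedule Frame-schedule tibble.
#' @param value Per-frame mean activity concentration.
#' @param units `"SUV"` or `"kBq/ml"`.
#' @param region Region label (`brain`, `myocardium`, `left_ventricle`,
#'   `liver`, `whole_blood`, `plasma`).
#' @return A tibble with the schedule columns plus `value`, `units`, `region`.
#' @export
tac <- function(schedule, value, units = "SUV", region = "whole_blood") {
  stopifnot(is.data.frame(schedule))
  if (length(value) == 1) value <- rep(value, nrow(schedule))
  if (nrow(schedule) != length(value)) stop("value length must match schedule", call. = FALSE)
  if (any(!is.finite(value))) stop("TAC values must be finite", call. = FALSE)
  dplyr::mutate(schedule, value = as.numeric(value), units = units, region = region)
}

#' Manual blood samples
#'
#' @param time Sample times on the scan clock (s).
#' @param concentration Measured whole-blood concentration (same units as
#'   the curves they calibrate).
#' @return A tibble with columns `time` and `concentration`.
#' @export
blood_samples <- function(time, concentration) {
  if (length(time) != length(concentration)) stop("lengths differ", call. = FALSE)
  if (any(concentration < 0)) stop("sample concentrations must be >= 0", call. = FALSE)
  tibble::tibble(time = as.numeric(time), concentration = as.numeric(concentration))
}

#' Experiment configuration
#'
#' Bundles the protocol knobs of one imaging experiment. Defaults follow a
#' reference mouse FDG protocol: 15 MBq injected in 100 ul saline over
#' 30 s into a 20 g mouse, continuous arterial withdrawal at 120 ul/min,
#' PET/CT scanning for 45.5 min, left-ventricle recovery coefficient 0.42.
#'
#' @param dose_mbq Injected activity (MBq).
#' @param body_weight_g Body weight (g).
#' @param injection_volume_ul Injected volume (ul).
#' @param injection_duration_s Injection duration (s).
#' @param withdrawal_rate_ul_min Arterial withdrawal rate (ul/min).
#' @param recovery_coefficient Left-ventricle recovery coefficient in (0, 1].
#' @param tracer Tracer label.
#' @param scanner `"PET/CT"` or `"PET/MR"`.
#' @param scan_length_s Total scan length (s).
#' @param isotope_half_life_s Isotope half-life (s); F-18 by default.
#' @param decay_corrected Whether curves are assumed decay-corrected to
#'   injection time before modelling (the standard convention; all curve
#'   arithmetic in this package assumes it).
#' @return A list with class `experiment_config`.
#' @export
experiment_config <- function(dose_mbq = 15,
                              body_weight_g = 20,
                              injection_volume_ul = 100,
                              injection_duration_s = 30,
                              withdrawal_rate_ul_min = 120,
                              recovery_coefficient = 0.42,
                              tracer = "FDG",
                              scanner = c("PET/CT", "PET/MR"),
                              scan_length_s = 2730,
                              isotope_half_life_s = 6586.2,
                              decay_corrected = TRUE) {
  scanner <- match.arg(scanner)
  num <- c(dose_mbq = dose_mbq, body_weight_g = body_weight_g,
           injection_volume_ul = injection_volume_ul,
           injection_duration_s = injection_duration_s,
           withdrawal_rate_ul_min = withdrawal_rate_ul_min,
           recovery_coefficient = recovery_coefficient,
           scan_length_s = scan_length_s,
           isotope_half_life_s = isotope_half_life_s)
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad) > 0) stop("config fields must be positive: ", paste(bad, collapse = ", "),
                            call. = FALSE)
  if (recovery_coefficient > 1) stop("recovery_coefficient must be <= 1", call. = FALSE)
  structure(list(dose_mbq = dose_mbq, body_weight_g = body_weight_g,
                 injection_volume_ul = injection_volume_ul,
                 injection_duration_s = injection_duration_s,
                 withdrawal_rate_ul_min = withdrawal_rate_ul_min,
                 recovery_coefficient = recovery_coefficient,
                 tracer = tracer, scanner = scanner,
                 scan_length_s = scan_length_s,
                 isotope_half_life_s = isotope_half_life_s,
                 decay_corrected = decay_corrected),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  %s on %s: %.3g MBq / %.3g ul over %.3g s, %.3g g mouse\n",
              x$tracer, x$scanner, x$dose_mbq, x$injection_volume_ul,
              x$injection_duration_s, x$body_weight_g))
  cat(sprintf("  withdrawal %.3g ul/min, RC %.2f, scan %.4g s\n",
              x$withdrawal_rate_ul_min, x$recovery_coefficient, x$scan_length_s))
  invisible(x)
}

# ---- SUV conversion -------------------------------------------------------

#' Convert activity concentration to standardized uptake value
#'
#' SUV (g/ml) = concentration (kBq/ml) x body weight (g) / dose (kBq).
#' Operates on any curve tibble carrying `value` and `units` columns.
#'
#' @param curve A dense-curve or TAC tibble with `value` and `units` columns.
#' @param dose_mbq Injected dose (MBq).
#' @param weight_g Body weight (g).
#' @return The curve with values rescaled and `units` set to `"SUV"`.
#' @seealso [to_activity()] for the inverse conversion.
#' @export
to_suv <- function(curve, dose_mbq, weight_g) {
  stopifnot(is.data.frame(curve), all(c("value", "units") %in% names(curve)))
  if (dose_mbq <= 0 || weight_g <= 0) stop("dose and weight must be positive", call. = FALSE)
  if (all(curve$units == "SUV")) {
    warning("curve is already in SUV units; returning unchanged")
    return(curve)
  }
  dplyr::mutate(curve, value = .data$value * weight_g / (dose_mbq * 1000),
                units = "SUV")
}

#' Convert SUV back to activity concentration (kBq/ml)
#'
#' @inheritParams to_suv
#' @export
to_activity <- function(curve, dose_mbq, weight_g) {
  stopifnot(is.data.frame(curve), all(c("value", "units") %in% names(curve)))
  if (dose_mbq <= 0 || weight_g <= 0) stop("dose and weight must be positive", call. = FALSE)
  if (all(curve$units == "kBq/ml")) {
    warning("curve is already in kBq/ml; returning unchanged")
    return(curve)
  }
  dplyr::mutate(curve, value = .data$value * (dose_mbq * 1000) / weight_g,
                units = "kBq/ml")
}

# ---- Injection-volume guideline ------------------------------------------

#' Maximum intravenous bolus volume for a given body weight
#'
#' Welfare guidelines limit intravenous bolus injections in mice to
#' 5 ml/kg; for a 20 g mouse this is 100 ul.
#'
#' @param weight_g Body weight (g).
#' @param limit_ml_per_kg Guideline limit (ml per kg body weight).
#' @return Maximum volume in ul.
#' @examples
#' max_bolus_volume(20)  # 100
#' @export
max_bolus_volume <- function(weight_g, limit_ml_per_kg = 5) {
  if (any(weight_g <= 0)) stop("weight must be positive", call. = FALSE)
  if (limit_ml_per_kg <= 0) stop("limit must be positive", call. = FALSE)
  # ml/kg == ul/g, so the conversion is a plain product
  weight_g * limit_ml_per_kg
}

#' Check planned injection volumes against the bolus guideline
#'
#' @param volumes_ul Planned injection volumes (ul); for repeated
#'   injections give one entry per injection.
#' @param weight_g Body weight (g).
#' @param limit_ml_per_kg Guideline limit.
#' @return `TRUE` if the summed volume is within the limit.
#' @export
check_injection_volume <- function(volumes_ul, weight_g, limit_ml_per_kg = 5) {
  sum(volumes_ul) <= max_bolus_volume(weight_g, limit_ml_per_kg)
}

# ---- File I/O -------------------------------------------------------------

#' Read a time-activity-curve table
#'
#' Reads the package's TAC interchange format: a comma-separated file with
#' one `#`-prefixed metadata line (`key=value` pairs, at least `units`),
#' then a header `frame_start,frame_end,<region>,...` and one row per
#' frame.
#'
#' @param path Path to the file.
#' @return A list with elements `schedule` (frame-schedule tibble), `tacs`
#'   (long tibble with columns `frame_start`, `frame_end`, `mid`, `dur`,
#'   `region`, `value`, `units`) and `meta` (named character vector).
#' @export
read_tac_table <- function(path) {
  lines <- readLines(path)
  meta <- character(0)
  if (length(lines) > 0 && startsWith(lines[1], "#")) {
    kv <- strsplit(trimws(sub("^#", "", lines[1])), "\\s+")[[1]]
    kv <- kv[nzchar(kv)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    meta <- stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
    lines <- lines[-1]
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"), check.names = FALSE,
                        colClasses = "character")
  need <- c("frame_start", "frame_end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing required columns: ", paste(miss, collapse = ", "),
                             call. = FALSE)
  regions <- setdiff(names(df), need)
  if (length(regions) == 0) stop("no region columns found", call. = FALSE)
  num <- suppressWarnings(lapply(df, as.numeric))
  for (cn in names(num)) {
    bad <- which(is.na(num[[cn]]) & nzchar(trimws(df[[cn]])))
    nas <- which(is.na(num[[cn]]))
    if (length(bad) > 0 || length(nas) > 0) {
      row <- if (length(bad) > 0) bad[1] else nas[1]
      stop(sprintf("non-numeric cell in column '%s', data row %d", cn, row),
           call. = FALSE)
    }
  }
  schedule <- frame_schedule(num$frame_start, num$frame_end)
  units <- if ("units" %in% names(meta)) unname(meta[["units"]]) else "SUV"
  tacs <- purrr::map_dfr(regions, function(r) {
    tac(schedule, num[[r]], units = units, region = r)
  })
  list(schedule = schedule, tacs = tacs, meta = meta)
}

#' Write a time-activity-curve table
#'
#' Inverse of [read_tac_table()]: writes the long TAC tibble as a wide CSV
#' with a single metadata header line.
#'
#' @param tacs Long TAC tibble (columns `frame_start`, `frame_end`,
#'   `region`, `value`, `units`).
#' @param path Output path.
#' @param meta Named character vector of extra metadata (e.g. `dose_MBq`).
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(tacs, path, meta = character(0)) {
  stopifnot(is.data.frame(tacs),
            all(c("frame_start", "frame_end", "region", "value", "units") %in% names(tacs)))
  units <- unique(tacs$units)
  if (length(units) != 1) stop("all curves must share one unit", call. = FALSE)
  wide <- tidyr::pivot_wider(
    dplyr::select(tacs, "frame_start", "frame_end", "region", "value"),
    names_from = "region", values_from = "value")
  meta <- c(units = units, meta[setdiff(names(meta), "units")])
  hdr <- paste0("# ", paste(names(meta), unname(meta), sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(wide, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Recognised result-record schemas, in stable column order.
.result_schemas <- list(
  curve_features = c("curve", "suv_max", "ttp", "fwhm", "auc_peak", "auc_tail",
                     "auc_ratio", "break_point"),
  group_comparison = c("quantity", "group_a", "group_b", "mean_a", "mean_b",
                       "ci95_a", "ci95_b", "u_statistic", "p_value", "significant")
)

#' Write a homogeneous table of result records
#'
#' Writes curve-feature or group-comparison records as CSV with a stable
#' column order so that files are diffable across runs. Refuses a list
#' mixing the two record types.
#'
#' @param records A tibble of one record type, or a list of single-row
#'   tibbles of the same type.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.data.frame(records)) records <- list(records)
  if (!is.list(records)) stop("records must be a tibble or list of tibbles", call. = FALSE)
  kind_of <- function(df) {
    for (k in names(.result_schemas)) {
      if (all(.result_schemas[[k]] %in% names(df))) return(k)
    }
    stop("unrecognised record type with columns: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  kinds <- vapply(records, kind_of, "")
  if (length(unique(kinds)) > 1) {
    stop("mixed record types in one table: ", paste(unique(kinds), collapse = " vs "),
         call. = FALSE)
  }
  df <- dplyr::bind_rows(records)
  df <- df[, .result_schemas[[kinds[1]]], drop = FALSE]
  if (nrow(df) == 0) warning("no records; writing header-only file")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

# ---- shared numeric helpers ----------------------------------------------

# trapezoidal integral of y(t); both vectors, possibly irregular spacing
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

# linear interpolation that errors outside the support
interp_strict <- function(t, y, t_out, what = "curve") {
  if (any(t_out < min(t) - 1e-9) || any(t_out > max(t) + 1e-9)) {
    stop(sprintf("requested time outside %s support [%.6g, %.6g]",
                 what, min(t), max(t)), call. = FALSE)
  }
  stats::approx(t, y, xout = t_out, rule = 2)$y
}
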