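# AIF / IDIF processing: everything between the raw detector trace and a
# kinetic-model-ready plasma input function.

#' Calibrate a continuous detector trace against manual blood samples
#'
#' The external radiation detector reports arbitrary count units; manual
#' blood samples anchor it to absolute concentration. A single
#' multiplicative factor is estimated as the through-origin least-squares
#' slope of sample concentration on trace value at the sample times
#' (regression rather than a mean of ratios, for robustness to sample
#' noise).
#'
#' Because a single dense-trace sample is noisy, the trace value paired
#' with each blood sample is averaged over a short window centred on the
#' sample time (mirroring the finite draw duration of a manual sample).
#'
#' @param trace Dense detector-trace tibble (`time`, `value`).
#' @param samples A [blood_samples()] tibble (at least one sample; the
#'   trace must cover the sample times).
#' @param window Full width (s) of the trace-averaging window around each
#'   sample time; clipped to the trace support.
#' @return A list with class `calibrated_aif`: `curve` (the calibrated
#'   dense curve), `factor`, and slots `fit` / `rms` filled in by a later
#'   [fit_feng()].
#' @export
calibrate_trace <- function(trace, samples, window = 30) {
  stopifnot(is.data.frame(trace), is.data.frame(samples))
  if (nrow(samples) < 1) stop("need at least one blood sample", call. = FALSE)
  interp_strict(trace$time, trace$value, samples$time, "detector trace")
  tv <- vapply(samples$time, function(ts) {
    keep <- trace$time >= ts - window / 2 & trace$time <= ts + window / 2
    mean(trace$value[keep])
  }, 0)
  if (all(abs(tv) < 1e-12)) {
    stop("detector trace is zero at every sample time; cannot calibrate", call. = FALSE)
  }
  factor <- sum(tv * samples$concentration) / sum(tv^2)
  if (factor <= 0) stop("non-positive calibration factor", call. = FALSE)
  curve <- dplyr::mutate(trace, value = .data$value * factor)
  if ("units" %in% names(curve)) curve$units <- "SUV"
  structure(list(curve = curve, factor = factor, fit = NULL, rms = NULL),
            class = "calibrated_aif")
}

#' @export
print.calibrated_aif <- function(x, ...) {
  cat(sprintf("<calibrated_aif>  factor %.5g, %d samples span [%g, %g] s\n",
              x$factor, nrow(x$curve), min(x$curve$time), max(x$curve$time)))
  if (!is.null(x$fit)) print(x$fit$model)
  invisible(x)
}

#' Invert catheter dispersion on a smooth curve
#'
#' The mono-exponential dispersion kernel has the exact left inverse
#' `c_corrected(t) = c(t) + tau * dc/dt`. For a dense curve the
#' derivative is taken by central differences; for a [fit_feng()] result
#' the analytic model derivative is used (preferred: differentiation
#' amplifies noise, so correction should run on the parametric fit or on
#' smoothed data).
#'
#' @param curve Dense-curve tibble, or a `feng_fit`.
#' @param tau Dispersion time constant (s); 0 is the identity.
#' @param times Evaluation grid when `curve` is a fit.
#' @return Corrected dense curve tibble. If more than 10% of points go
#'   negative a warning is raised; negatives are clipped to zero.
#' @export
correct_dispersion <- function(curve, tau, times = NULL) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (inherits(curve, "feng_fit")) {
    if (is.null(times)) times <- curve$data$time
    v <- feng_curve(curve$model, times) + tau * feng_curve(curve$model, times, deriv = 1)
    out <- tibble::tibble(time = times, value = v)
  } else {
    stopifnot(is.data.frame(curve))
    if (tau == 0) return(curve)
    t <- curve$time; v <- curve$value
    n <- length(v)
    dv <- numeric(n)
    dv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    dv[1] <- (v[2] - v[1]) / (t[2] - t[1])
    dv[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
    out <- dplyr::mutate(curve, value = v + tau * dv)
  }
  neg <- out$value < 0
  if (mean(neg) > 0.10) {
    warning(sprintf("dispersion correction drove %.0f%% of points negative; clipping to 0",
                    100 * mean(neg)))
  }
  out$value[neg] <- 0
  out
}

#' Convert a whole-blood curve to a plasma curve
#'
#' Pointwise multiplication by the plasma-to-whole-blood concentration
#' ratio, either a constant or a function of time. The default ratio of
#' 1 leaves the values unchanged (appropriate for tracers that
#' equilibrate rapidly between plasma and red cells).
#'
#' @param whole_blood Curve tibble (dense or framed).
#' @param ratio Positive constant, or a function of time (s).
#' @return The plasma curve, `region` relabelled.
#' @export
to_plasma <- function(whole_blood, ratio = 1.0) {
  stopifnot(is.data.frame(whole_blood))
  t <- if ("time" %in% names(whole_blood)) whole_blood$time else whole_blood$mid
  r <- if (is.function(ratio)) ratio(t) else rep(ratio, length(t))
  if (any(r <= 0)) stop("plasma ratio must be positive", call. = FALSE)
  out <- dplyr::mutate(whole_blood, value = .data$value * r)
  if ("region" %in% names(out)) out$region <- "plasma"
  out
}

#' Correct a left-ventricle TAC for partial volume
#'
#' Inverts the two-compartment spill model
#' `measured = RC * blood + (1 - RC) * background`, with the surrounding
#' myocardium as background:
#' `corrected = (lv - (1 - RC) * myocardium) / RC`.
#'
#' @param lv,myocardium Framed TAC tibbles on the same schedule.
#' @param rc Recovery coefficient in (0, 1].
#' @return Corrected whole-blood TAC. Warns if more than 20% of frames
#'   turn negative (a sign the RC or background is off).
#' @export
pvc_left_ventricle <- function(lv, myocardium, rc) {
  stopifnot(is.data.frame(lv), is.data.frame(myocardium))
  if (rc <= 0 || rc > 1) stop("recovery coefficient must be in (0, 1]", call. = FALSE)
  if (nrow(lv) != nrow(myocardium) ||
      any(abs(lv$frame_start - myocardium$frame_start) > 1e-9)) {
    stop("curves must share one frame schedule", call. = FALSE)
  }
  out <- dplyr::mutate(lv,
                       value = (.data$value - (1 - rc) * myocardium$value) / rc,
                       region = "whole_blood")
  if (mean(out$value < 0) > 0.20) {
    warning("partial-volume correction produced negative values on >20% of frames")
  }
  out
}

# second derivative by non-uniform three-point differences
.second_diff <- function(t, y) {
  n <- length(y)
  h0 <- t[2:(n - 1)] - t[1:(n - 2)]
  h1 <- t[3:n] - t[2:(n - 1)]
  d2 <- 2 * (h0 * y[3:n] - (h0 + h1) * y[2:(n - 1)] + h1 * y[1:(n - 2)]) /
    (h0 * h1 * (h0 + h1))
  c(NA_real_, d2, NA_real_)
}

.moving_average <- function(y, window) {
  if (window <= 1) return(y)
  k <- rep(1 / window, window)
  out <- stats::filter(y, k, sides = 2)
  out[is.na(out)] <- y[is.na(out)]
  as.numeric(out)
}

#' Locate the left-ventricle / liver hand-over time
#'
#' The junction between the early (left-ventricle) and late (liver)
#' segments of an image-derived input function is defined objectively as
#' the maximum of the (smoothed) second derivative of the left-ventricle
#' signal after its peak -- the point where the washout stops
#' accelerating and the curve settles onto its tail.
#'
#' @param lv_corrected Partial-volume-corrected LV curve, framed (`mid`)
#'   or dense (`time`).
#' @param smooth_window Moving-average window (samples) applied before
#'   differencing.
#' @return The hand-over time (s). Earliest time wins on ties.
#' @export
find_lv_liver_intersection <- function(lv_corrected, smooth_window = 3) {
  stopifnot(is.data.frame(lv_corrected))
  t <- if ("time" %in% names(lv_corrected)) lv_corrected$time else lv_corrected$mid
  y <- .moving_average(lv_corrected$value, smooth_window)
  ip <- which.max(y)
  if (ip == 1 || ip == length(y)) {
    stop("left-ventricle curve has no interior peak", call. = FALSE)
  }
  if (length(y) - ip < 5) stop("need at least 5 frames past the peak", call. = FALSE)
  d2 <- .second_diff(t, y)
  cand <- seq_along(t) > ip & !is.na(d2)
  if (!any(cand)) stop("no usable frames after the peak", call. = FALSE)
  idx <- which(cand)
  best <- idx[which.max(d2[idx])]   # which.max returns the earliest maximum
  t[best]
}

#' Scale a liver TAC to a late blood sample
#'
#' The liver curve tracks the blood pool at late times up to a scale;
#' anchoring it to one manual blood sample turns it into a surrogate
#' blood curve for the tail of an IDIF.
#'
#' @param liver Framed liver TAC.
#' @param sample One-row [blood_samples()] tibble (the latest sample is
#'   used if several are given).
#' @return Scaled TAC, relabelled `whole_blood`.
#' @export
scale_liver <- function(liver, sample) {
  stopifnot(is.data.frame(liver), is.data.frame(sample))
  s <- sample[which.max(sample$time), ]
  if (s$time < min(liver$frame_start) || s$time > max(liver$frame_end)) {
    stop(sprintf("sample time %.6g s outside liver curve support [%.6g, %.6g]",
                 s$time, min(liver$frame_start), max(liver$frame_end)),
         call. = FALSE)
  }
  # flat extension beyond the first/last frame mid-time
  lv_at <- stats::approx(liver$mid, liver$value, xout = s$time, rule = 2)$y
  if (lv_at <= 0) stop("liver value is not positive at the sample time", call. = FALSE)
  factor <- s$concentration / lv_at
  dplyr::mutate(liver, value = .data$value * factor, region = "whole_blood")
}

#' Build an image-derived input function
#'
#' Combines the partial-volume-corrected left ventricle (early frames,
#' where the blood peak is only visible in the heart) with the
#' blood-sample-scaled liver (late frames, where the LV signal is
#' contaminated but the liver tracks the blood pool). The hand-over time
#' comes from [find_lv_liver_intersection()]; no interpolation is done
#' across the junction.
#'
#' @param lv,myocardium,liver Framed TAC tibbles on a shared schedule.
#' @param sample Late blood sample(s) used to scale the liver.
#' @param rc Left-ventricle recovery coefficient.
#' @param smooth_window Smoothing window for the junction search.
#' @param qc_jump Relative-jump threshold at the junction above which a
#'   warning is raised.
#' @return Whole-blood TAC tibble with attributes `junction` (s) and
#'   `junction_jump` (relative discontinuity at the hand-over).
#' @export
build_idif <- function(lv, myocardium, liver, sample, rc,
                       smooth_window = 3, qc_jump = 0.15) {
  lv_corr <- pvc_left_ventricle(lv, myocardium, rc)
  junction <- find_lv_liver_intersection(lv_corr, smooth_window = smooth_window)
  liver_scaled <- scale_liver(liver, sample)
  use_liver <- lv_corr$mid > junction
  if (!any(use_liver)) stop("junction fell on the last frame; no liver segment", call. = FALSE)
  out <- lv_corr
  out$value[use_liver] <- liver_scaled$value[use_liver]
  out$region <- "whole_blood"
  # discontinuity: liver vs LV estimate of the same first hand-over frame
  j <- which(use_liver)[1]
  jump <- abs(liver_scaled$value[j] - lv_corr$value[j]) /
    max(abs(lv_corr$value[j]), 1e-12)
  if (jump > qc_jump) {
    warning(sprintf("IDIF junction discontinuity %.0f%% exceeds QC threshold %.0f%%",
                    100 * jump, 100 * qc_jump))
  }
  attr(out, "junction") <- junction
  attr(out, "junction_jump") <- jump
  out
}

# ---- triple injection -----------------------------------------------------

# shift a feng model along the time axis (negative delta moves it earlier)
shift_feng <- function(model, delta) {
  feng_model(model$A1, model$A2, model$A3, model$lambda1, model$lambda2,
             model$lambda3, t0 = max(model$t0 + delta, 0))
}

# joint fit of three Feng components with shared decay constants.
# Within one subject the washout eigenvalues are a property of tracer
# clearance, so sharing them across injections is physiologically sound
# and -- crucially -- makes the split of the three overlapping tails
# well-posed (free per-injection tails are nearly collinear).
# `measure` maps a dense model curve to measurement space (injection
# shaping + dispersion); identity when the protocol knobs are unknown.
# theta: per injection (logA1, logA2, logA3, t0) x3, then shared
# (log(l1-l2), log(l2-l3), log l3)
.fit_feng_triple <- function(curve, fits, measure = identity) {
  time <- curve$time; value <- curve$value
  lam <- vapply(fits, function(f) c(f$model$lambda1, f$model$lambda2,
                                    f$model$lambda3), numeric(3))
  lbar <- pmax(rowMeans(lam), 1e-8)
  if (lbar[2] <= lbar[3]) lbar[2] <- lbar[3] * 2
  if (lbar[1] <= lbar[2]) lbar[1] <- lbar[2] * 2
  theta0 <- c(unlist(lapply(fits, function(f) {
    c(log(f$model$A1), log(max(f$model$A2, 1e-8)), log(max(f$model$A3, 1e-8)),
      f$model$t0)
  })), log(lbar[1] - lbar[2]), log(lbar[2] - lbar[3]), log(lbar[3]))
  unpack <- function(theta) {
    l3 <- exp(theta[15]); l2 <- l3 + exp(theta[14]); l1 <- l2 + exp(theta[13])
    lapply(0:2, function(i) {
      feng_model(A1 = exp(theta[4 * i + 1]), A2 = exp(theta[4 * i + 2]),
                 A3 = exp(theta[4 * i + 3]), lambda1 = l1, lambda2 = l2,
                 lambda3 = l3, t0 = max(theta[4 * i + 4], 0))
    })
  }
  predict_one <- function(m) {
    measure(tibble::tibble(time = time, value = feng_curve(m, time)))$value
  }
  resid_fn <- function(theta) {
    ms <- try(unpack(theta), silent = TRUE)
    if (inherits(ms, "try-error")) return(rep(1e6, length(value)))
    Reduce(`+`, lapply(ms, predict_one)) - value
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = theta0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)))
  models <- unpack(fit$par)
  lapply(seq_along(models), function(i) {
    f <- fits[[i]]
    f$model <- models[[i]]
    pred <- stats::approx(time, predict_one(models[[i]]), xout = f$data$time,
                          rule = 2)$y
    f$fitted <- tibble::tibble(time = f$data$time, value = pred)
    f
  })
}

#' Correct a triple-injection trace for circulating activity
#'
#' In a repeated-injection experiment the second and third measured
#' curves ride on the circulating tail of the earlier injections. The
#' correction fits the parametric model to the first segment, subtracts
#' its extrapolation from the second segment before fitting that, then
#' subtracts both extrapolations from the third; finally the corrected
#' curves are aligned to the first injection time.
#'
#' A purely sequential pass must extrapolate each tail from one
#' inter-injection window, which barely constrains the slowest washout
#' exponential and lets the three overlapping tails trade area. With
#' `refine = TRUE` (the default) the three models are therefore re-fitted
#' jointly to the whole calibrated trace with washout decay constants
#' shared across injections -- within one subject the clearance
#' eigenvalues are a property of the tracer and animal, not of the
#' injection, and sharing them makes the tail split well-posed.
#'
#' @param trace Dense trace tibble. If `samples` are given the trace is
#'   first calibrated against them ([calibrate_trace()]); pass
#'   `samples = NULL` for an already-calibrated trace.
#' @param injection_times Increasing injection start times (s).
#' @param samples One blood sample per injection (or `NULL`).
#' @param refine Jointly re-fit the three models with shared washout
#'   decay constants after the sequential pass.
#' @param injection_duration,tau Optional protocol knobs. When given, the
#'   parametric model is fitted through the measurement operator
#'   (injection boxcar of `injection_duration` seconds, dispersion kernel
#'   of time constant `tau`), removing the shape mismatch between the
#'   bolus model and the measured, dispersed curve.
#' @return A list with class `triple_correction`: `curves` (list of three
#'   dense tibbles, time axes aligned to injection 1), `fits` (list of
#'   three `feng_fit`s on the aligned clock; models live in bolus space),
#'   `model_curves` (measurement-space model prediction per injection on
#'   the aligned clock), `factor` (calibration factor used, or 1).
#' @export
correct_triple_injection <- function(trace, injection_times, samples = NULL,
                                     refine = TRUE,
                                     injection_duration = NULL, tau = NULL) {
  stopifnot(is.data.frame(trace), length(injection_times) == 3)
  if (is.unsorted(injection_times, strictly = TRUE)) {
    stop("injection times must be strictly increasing", call. = FALSE)
  }
  if (max(trace$time) <= injection_times[3]) {
    stop("trace does not span the third injection", call. = FALSE)
  }
  factor <- 1
  curve <- trace
  if (!is.null(samples)) {
    cal <- calibrate_trace(trace, samples)
    curve <- cal$curve
    factor <- cal$factor
  }
  # measurement operator: the protocol's injection shaping and the known
  # withdrawal-line dispersion, when supplied
  measure <- identity
  if (!is.null(injection_duration) || !is.null(tau)) {
    measure <- function(cv) {
      if (!is.null(injection_duration)) {
        cv <- suppressWarnings(shape_injection(cv, injection_duration))
      }
      if (!is.null(tau) && tau > 0) cv <- apply_dispersion(cv, dispersion_spec(tau, 0))
      cv
    }
  }
  predict_component <- function(model, times) {
    # evaluate on the full trace grid so the convolutions see the whole
    # component history, then interpolate
    grid <- tibble::tibble(time = curve$time, value = feng_curve(model, curve$time))
    stats::approx(grid$time, measure(grid)$value, xout = times, rule = 2)$y
  }
  bounds <- c(injection_times, max(curve$time) + 1)
  segments <- lapply(1:3, function(i) {
    dplyr::filter(curve, .data$time >= bounds[i], .data$time < bounds[i + 1])
  })
  fits <- vector("list", 3)
  for (i in 1:3) {
    seg <- segments[[i]]
    v <- seg$value
    if (i > 1) {
      for (j in seq_len(i - 1)) v <- v - predict_component(fits[[j]]$model, seg$time)
    }
    fits[[i]] <- tryCatch(fit_feng(dplyr::mutate(seg, value = v)),
                          error = function(e) {
                            stop(sprintf("parametric fit failed for injection %d: %s",
                                         i, conditionMessage(e)), call. = FALSE)
                          })
  }
  if (refine) {
    fits <- tryCatch(.fit_feng_triple(curve, fits, measure = measure),
                     error = function(e) {
                       stop("joint refinement of the three parametric fits failed: ",
                            conditionMessage(e), call. = FALSE)
                     })
  }
  # corrected curves: each segment minus the final fitted overlap
  corrected <- lapply(1:3, function(i) {
    seg <- segments[[i]]
    v <- seg$value
    for (j in seq_len(i - 1)) v <- v - predict_component(fits[[j]]$model, seg$time)
    dplyr::mutate(seg, value = v)
  })
  # measurement-space model curve per injection, full remaining span
  model_curves <- lapply(1:3, function(i) {
    span <- curve$time[curve$time >= injection_times[i]]
    tibble::tibble(time = span, value = predict_component(fits[[i]]$model, span))
  })
  shift <- injection_times - injection_times[1]
  align <- function(cv, s) dplyr::mutate(cv, time = .data$time - s)
  aligned <- purrr::map2(corrected, as.list(shift), align)
  model_aligned <- purrr::map2(model_curves, as.list(shift), align)
  fits_aligned <- purrr::map2(fits, as.list(shift), function(f, s) {
    f$model <- shift_feng(f$model, -s)
    f$data$time <- f$data$time - s
    f$fitted$time <- f$fitted$time - s
    f
  })
  structure(list(curves = aligned, fits = fits_aligned,
                 model_curves = model_aligned, factor = factor,
                 injection_times = injection_times),
            class = "triple_correction")
}
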