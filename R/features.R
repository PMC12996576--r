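# Objective input-function curve features: peak height, time to peak,
# FWHM, and the peak/tail area split at an objectively defined break
# point derived from first- and second-derivative landmarks.

# resolve an input-function argument into (time, value, d1, d2) vectors;
# derivatives come from the parametric model when one is available,
# otherwise from smoothed finite differences on the dense grid
.curve_landmark_grid <- function(x, times = NULL, smooth_window = 5) {
  if (inherits(x, "feng_fit")) x <- x$model
  if (inherits(x, "feng_model")) {
    if (is.null(times)) {
      stop("evaluating a model needs a 'times' grid", call. = FALSE)
    }
    return(list(time = times,
                value = feng_curve(x, times),
                d1 = feng_curve(x, times, deriv = 1),
                d2 = feng_curve(x, times, deriv = 2),
                analytic = TRUE))
  }
  stopifnot(is.data.frame(x))
  t <- if ("time" %in% names(x)) x$time else x$mid
  y <- .moving_average(x$value, smooth_window)
  n <- length(y)
  if (n < 7) stop("too few points for derivative landmarks", call. = FALSE)
  d1 <- numeric(n)
  d1[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d1[1] <- d1[2]; d1[n] <- d1[n - 1]
  d2 <- .second_diff(t, y)
  d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  list(time = t, value = y, d1 = d1, d2 = d2, analytic = FALSE)
}

# indices of strict-or-plateau local maxima, earliest index per plateau
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1
  idx
}

#' Locate the peak/tail break point of an input function
#'
#' Implements a derivative-landmark definition of where the bolus peak
#' ends and the washout tail begins: (1) the minimum of the first
#' derivative after the peak marks the steepest descent; (2) the second
#' positive peak of the second derivative marks the inflection where the
#' curve changes concavity (if the curve is so idealised that only one
#' positive second-derivative peak exists after the global peak, that one
#' is used); (3) the break point is the inflection time plus half the
#' distance from the steepest-descent time to the inflection.
#'
#' @param x A `feng_fit`, [feng_model()] (analytic derivatives), or a
#'   dense-curve tibble (smoothed finite differences).
#' @param times Evaluation grid when `x` is a model; defaults to the
#'   fit's data grid for a `feng_fit`.
#' @param smooth_window Smoothing window for tabulated curves.
#' @return One-row tibble: `break_point`, `t_minslope`, `t_inflection`
#'   (all seconds).
#' @export
find_break_point <- function(x, times = NULL, smooth_window = 5) {
  if (inherits(x, "feng_fit") && is.null(times)) {
    rng <- range(x$data$time)
    times <- seq(rng[1], rng[2], by = min(0.05, diff(rng) / 2000))
  }
  g <- .curve_landmark_grid(x, times = times, smooth_window = smooth_window)
  ip <- which.max(g$value)
  if (ip == length(g$value)) stop("curve has no interior peak", call. = FALSE)
  after <- seq_along(g$time) > ip
  i_min <- which(after)[which.min(g$d1[after])]
  t_minslope <- g$time[i_min]
  pk <- .local_maxima(g$d2)
  pk <- pk[g$d2[pk] > 0]
  if (length(pk) >= 2 && pk[2] > ip) {
    i_inf <- pk[2]
  } else {
    pk_after <- pk[pk > ip]
    if (length(pk_after) == 0) {
      stop("no positive second-derivative peak after the curve peak", call. = FALSE)
    }
    i_inf <- pk_after[1]
  }
  t_inflection <- g$time[i_inf]
  tibble::tibble(break_point = t_inflection + (t_inflection - t_minslope) / 2,
                 t_minslope = t_minslope,
                 t_inflection = t_inflection)
}

# linearly interpolated crossing time of level within segment [i, i+1]
.cross_time <- function(t, y, i, level) {
  t[i] + (level - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
}

#' Compute the objective curve features of an input function
#'
#' The six features used to compare input functions across experimental
#' groups, plus the break point that defines the peak/tail split:
#' * `suv_max` -- maximum of the curve (g/ml);
#' * `ttp` -- time of the maximum, relative to injection (s);
#' * `fwhm` -- width of the peak at half maximum, by linear interpolation
#'   between grid points (s);
#' * `auc_peak` -- trapezoidal area from injection to the break point;
#' * `auc_tail` -- area from the break point to scan end;
#' * `auc_ratio` -- their ratio.
#'
#' @param curve Dense-curve tibble covering `[injection_time, end]`, or a
#'   `feng_fit` / [feng_model()] evaluated on `times`.
#' @param injection_time Injection start on the curve clock (s).
#' @param times Evaluation grid when `curve` is a model.
#' @param label Value for the `curve` identifier column.
#' @param smooth_window Smoothing window for break-point detection on
#'   tabulated curves (the feature values themselves use the raw curve).
#' @return One-row tibble: `curve`, `suv_max`, `ttp`, `fwhm`, `auc_peak`,
#'   `auc_tail`, `auc_ratio`, `break_point`.
#' @export
compute_features <- function(curve, injection_time = 0, times = NULL,
                             label = "aif", smooth_window = 5) {
  if (inherits(curve, "feng_fit") && is.null(times)) {
    rng <- range(curve$data$time)
    times <- seq(rng[1], rng[2], by = min(0.05, diff(rng) / 2000))
  }
  bp <- find_break_point(curve, times = times, smooth_window = smooth_window)
  if (inherits(curve, "feng_fit")) curve <- curve$model
  if (inherits(curve, "feng_model")) {
    t <- times; y <- feng_curve(curve, t)
  } else {
    t <- if ("time" %in% names(curve)) curve$time else curve$mid
    y <- curve$value
  }
  keep <- t >= injection_time
  t <- t[keep]; y <- y[keep]
  ip <- which.max(y)
  suv_max <- y[ip]
  ttp <- t[ip] - injection_time
  half <- suv_max / 2
  left_below <- which(y[seq_len(ip)] < half)
  if (length(left_below) == 0) {
    t_left <- t[1]  # curve starts above half max
  } else {
    i <- max(left_below)
    t_left <- .cross_time(t, y, i, half)
  }
  right_below <- which(y[ip:length(y)] < half)
  if (length(right_below) == 0) {
    stop("curve never falls below half maximum after the peak; FWHM undefined",
         call. = FALSE)
  }
  j <- ip + right_below[1] - 2
  t_right <- .cross_time(t, y, j, half)
  brk <- bp$break_point
  split_t <- min(max(brk, t[1]), t[length(t)])
  pre <- t <= split_t
  t_peak_seg <- c(t[pre], split_t)
  y_peak_seg <- c(y[pre], stats::approx(t, y, xout = split_t)$y)
  auc_peak <- trapz(t_peak_seg, y_peak_seg)
  auc_total <- trapz(t, y)
  auc_tail <- auc_total - auc_peak
  if (auc_tail <= 0) stop("tail area is zero; AUC ratio undefined", call. = FALSE)
  tibble::tibble(curve = label,
                 suv_max = suv_max,
                 ttp = ttp,
                 fwhm = t_right - t_left,
                 auc_peak = auc_peak,
                 auc_tail = auc_tail,
                 auc_ratio = auc_peak / auc_tail,
                 break_point = brk)
}
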