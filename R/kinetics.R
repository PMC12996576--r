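#' Two-tissue compartment model parameters
#'
#' Rate constants of the reversible two-tissue compartment model in the
#' conventional units: `K1` in ml/min/ml, `k2`-`k4` in 1/min, and the
#' fractional blood volume `vB` (unitless, in `[0, 1]`). The net influx
#' macro-parameter `Ki = K1 k3 / (k2 + k3)` is derived automatically.
#'
#' @param K1 Plasma-to-tissue transport (ml/min/ml).
#' @param k2 Tissue-to-plasma efflux (1/min).
#' @param k3 Binding / phosphorylation (1/min).
#' @param k4 Release (1/min); 0 gives the irreversible model.
#' @param vB Fractional blood volume.
#' @return A list with class `two_tissue_params` (includes `Ki`).
#' @export
two_tissue_params <- function(K1, k2, k3, k4 = 0, vB = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rate constants must be finite and >= 0", call. = FALSE)
  }
  if (vB < 0 || vB > 1) stop("vB must be in [0, 1]", call. = FALSE)
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB,
                 Ki = macro_ki_value(K1, k2, k3)),
            class = "two_tissue_params")
}

macro_ki_value <- function(K1, k2, k3) {
  if (k2 + k3 > 0) K1 * k3 / (k2 + k3) else 0
}

#' Net influx rate constant of a 2TCM parameter set
#'
#' `Ki = K1 k3 / (k2 + k3)`, the steady-state trapping rate. When both
#' `k2` and `k3` are zero the ratio is indeterminate and 0 is returned
#' with a warning.
#'
#' @param params A [two_tissue_params()].
#' @return Ki in ml/min/ml.
#' @export
macro_ki <- function(params) {
  stopifnot(inherits(params, "two_tissue_params"))
  if (params$k2 + params$k3 == 0) {
    warning("k2 = k3 = 0: net influx is indeterminate, returning 0")
    return(0)
  }
  macro_ki_value(params$K1, params$k2, params$k3)
}

#' @export
print.two_tissue_params <- function(x, ...) {
  cat(sprintf("<two_tissue_params>  K1 %.4g ml/min/ml, k2 %.4g, k3 %.4g, k4 %.4g /min, vB %.3g, Ki %.4g\n",
              x$K1, x$k2, x$k3, x$k4, x$vB, x$Ki))
  invisible(x)
}

# ---- 2TCM fitting ---------------------------------------------------------

.tcm_default_inits <- list(
  c(0.1, 0.2, 0.05, 0.005, 0.05),
  c(0.5, 0.5, 0.05, 0.01, 0.05),
  c(0.3, 1.0, 0.10, 0.02, 0.10),
  c(1.0, 2.0, 0.20, 0.05, 0.10),
  c(2.0, 3.0, 0.50, 0.10, 0.20)
)

#' Fit the reversible two-tissue compartment model to a tissue TAC
#'
#' Weighted nonlinear least squares of the frame-averaged 2TCM forward
#' model against a measured tissue curve, with weights proportional to
#' frame duration (long frames carry more counts). All five parameters
#' (`K1`, `k2`, `k3`, `k4`, `vB`) are free within bounds `[0, 5]` for the
#' rates and `[0, 1]` for `vB`. Five deterministic starting points are
#' tried (plus an optional user start); the lowest weighted SSE wins.
#'
#' @param tissue Framed tissue TAC tibble.
#' @param plasma Dense plasma input curve.
#' @param blood Dense whole-blood curve (defaults to `plasma`).
#' @param init Optional [two_tissue_params()] starting point.
#' @param lower,upper Bounds on `(K1, k2, k3, k4, vB)`.
#' @param n_starts How many of the deterministic starts to use (1-5).
#' @return An object of class `tcm_fit`: `params`
#'   ([two_tissue_params()]), `fitted` (per-frame model values), `data`,
#'   `sse`, `rms`, `niter`.
#' @export
fit_2tcm <- function(tissue, plasma, blood = plasma, init = NULL,
                     lower = c(0, 0, 0, 0, 0), upper = c(5, 5, 5, 5, 1),
                     n_starts = 5) {
  stopifnot(is.data.frame(tissue), all(c("frame_start", "frame_end", "value") %in% names(tissue)))
  if (any(plasma$value < -1e-9)) stop("negative input curve", call. = FALSE)
  schedule <- frame_schedule(tissue$frame_start, tissue$frame_end)
  y <- tissue$value
  w <- sqrt(schedule$dur / mean(schedule$dur))
  model_frames <- function(par) {
    p <- two_tissue_params(par[1], par[2], par[3], par[4], par[5])
    dense <- forward_2tcm(p, plasma, blood)
    frame_average(dense, schedule)$value
  }
  resid_fn <- function(par) w * (model_frames(par) - y)
  starts <- .tcm_default_inits[seq_len(max(1, min(n_starts, 5)))]
  if (!is.null(init)) {
    stopifnot(inherits(init, "two_tissue_params"))
    starts <- c(list(c(init$K1, init$k2, init$k3, init$k4, init$vB)), starts)
  }
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = p0, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                           ptol = 1e-13))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("2TCM fit failed to converge from any start", call. = FALSE)
  par <- best$fit$par
  params <- two_tissue_params(par[1], par[2], par[3], par[4], par[5])
  fitted_vals <- model_frames(par)
  structure(list(params = params,
                 fitted = tibble::tibble(mid = schedule$mid, value = fitted_vals),
                 data = tibble::tibble(mid = schedule$mid, dur = schedule$dur, value = y),
                 sse = best$sse,
                 rms = sqrt(mean((fitted_vals - y)^2)),
                 niter = best$fit$niter),
            class = "tcm_fit")
}

#' @export
print.tcm_fit <- function(x, ...) {
  cat("<tcm_fit>  residual RMS:", format(x$rms, digits = 4), "\n")
  print(x$params)
  invisible(x)
}

# ---- Patlak ---------------------------------------------------------------

#' Patlak graphical analysis
#'
#' Ordinary least squares of `tissue(t)/plasma(t)` against the normalised
#' time `int_0^t plasma du / plasma(t)` over frames with mid-time past
#' `t_star`. For an (effectively) irreversible tracer the late points are
#' linear with slope equal to the net influx rate `Ki`.
#'
#' @param tissue Framed tissue TAC tibble.
#' @param plasma Dense plasma input curve.
#' @param t_star Start of the linear phase (s); default 10 minutes.
#' @return An object of class `patlak_fit`: `Ki_patlak` (ml/min/ml),
#'   `intercept` (ml/ml), `t_star`, `r_squared`, and the regression
#'   points in `data`.
#' @export
fit_patlak <- function(tissue, plasma, t_star = 600) {
  stopifnot(is.data.frame(tissue), is.data.frame(plasma))
  schedule <- frame_schedule(tissue$frame_start, tissue$frame_end)
  mid <- schedule$mid
  use <- mid >= t_star
  if (sum(use) < 3) stop("need at least 3 frames past t_star", call. = FALSE)
  t <- plasma$time; v <- plasma$value
  n <- length(t)
  cum <- c(0, cumsum((v[-1] + v[-n]) * diff(t) / 2))
  cp_mid <- interp_strict(t, v, mid[use], "plasma curve")
  if (any(cp_mid <= 0)) stop("plasma input is not positive past t_star", call. = FALSE)
  x <- interp_strict(t, cum, mid[use], "plasma curve") / cp_mid   # seconds
  y <- tissue$value[use] / cp_mid
  fit <- stats::lm(y ~ x)
  slope_per_s <- unname(stats::coef(fit)[2])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(Ki_patlak = slope_per_s * 60,
                 intercept = unname(stats::coef(fit)[1]),
                 t_star = t_star,
                 r_squared = max(min(r2, 1), 0),
                 data = tibble::tibble(mid = mid[use], x = x, y = y,
                                       fitted = stats::fitted(fit))),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit>  Ki %.4g ml/min/ml, intercept %.4g, r2 %.4f (t* = %g s, %d frames)\n",
              x$Ki_patlak, x$intercept, x$r_squared, x$t_star, nrow(x$data)))
  invisible(x)
}
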