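# Synthetic-data generator: forward models for everything the analysis
# pipeline later inverts (injection shaping, catheter dispersion and delay,
# detector calibration, tissue kinetics, partial volume, frame averaging,
# count noise). Ground truth is always retained so recovery can be tested.

# ---- low-level numeric kernels -------------------------------------------

# (e^{-alpha s} * c)(t) on a regular grid, exact for piecewise-linear c,
# via a recursive filter (runs at C speed through stats::filter)
exp_conv <- function(c_vals, dt, alpha) {
  n <- length(c_vals)
  if (n < 2) return(rep(0, n))
  if (alpha * dt < 1e-12) {
    # alpha ~ 0: plain running trapezoidal integral
    return(c(0, cumsum((c_vals[-1] + c_vals[-n]) * dt / 2)))
  }
  E <- exp(-alpha * dt)
  c0 <- c_vals[-n]; c1 <- c_vals[-1]
  contrib <- c1 * (1 - E) / alpha +
    (c0 - c1) / dt * ((1 - E) / alpha^2 - dt * E / alpha)
  y <- stats::filter(c(0, contrib), E, method = "recursive")
  as.numeric(y)
}

# grid step of a dense curve; errors if irregular
.grid_step <- function(time) {
  dt <- diff(time)
  if (length(dt) == 0) stop("curve has a single sample", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * max(dt)) {
    stop("dense operations need a regular time grid", call. = FALSE)
  }
  mean(dt)
}

# ---- dispersion -----------------------------------------------------------

#' Dispersion and delay specification for a withdrawal line
#'
#' The external detector sees the arterial curve smeared by transport
#' through the catheter, modelled as convolution with a mono-exponential
#' kernel `(1/tau) exp(-t/tau)`, plus a pure transit delay.
#'
#' @param tau Dispersion time constant (s), `>= 0` (0 disables smearing).
#' @param delay Catheter transit delay (s), `>= 0`.
#' @return A list with class `dispersion_spec`.
#' @export
dispersion_spec <- function(tau = 5, delay = 30.4) {
  if (tau < 0 || delay < 0) stop("tau and delay must be >= 0", call. = FALSE)
  structure(list(tau = tau, delay = delay), class = "dispersion_spec")
}

#' Dispersion spec implied by an experiment configuration
#'
#' Dispersion scales inversely with the withdrawal rate,
#' `tau = kappa / withdrawal_rate`, with `kappa` chosen so that the
#' reference rate of 120 ul/min gives `tau = 5 s`. A PET/MR scanner adds
#' 10 s of dispersion and 30 s of delay to emulate the longer tubing its
#' geometry requires. The baseline transit delay is 30.4 s, the measured
#' detector-to-Y-connector delay of the reference setup.
#'
#' @param config An [experiment_config()].
#' @param kappa Dispersion-withdrawal coupling (s * ul/min).
#' @param base_delay Catheter transit delay at reference geometry (s).
#' @return A [dispersion_spec()].
#' @export
dispersion_for_config <- function(config, kappa = 600, base_delay = 30.4) {
  stopifnot(inherits(config, "experiment_config"))
  tau <- kappa / config$withdrawal_rate_ul_min
  delay <- base_delay
  if (config$scanner == "PET/MR") {
    tau <- tau + 10
    delay <- delay + 30
  }
  dispersion_spec(tau = tau, delay = delay)
}

#' Apply catheter dispersion and delay to a dense curve
#'
#' Convolves with the unit-area kernel `(1/tau) exp(-t/tau)` (identity at
#' `tau = 0`), then shifts by the transit delay. The signal is assumed to
#' be zero before the start of the grid.
#'
#' @param curve Dense-curve tibble (`time`, `value`) on a regular grid.
#' @param spec A [dispersion_spec()], or a numeric `tau` (with `delay`).
#' @param delay Transit delay (s) when `spec` is numeric.
#' @return The dispersed curve as a tibble.
#' @export
apply_dispersion <- function(curve, spec, delay = 0) {
  if (is.numeric(spec)) spec <- dispersion_spec(tau = spec, delay = delay)
  stopifnot(is.data.frame(curve), inherits(spec, "dispersion_spec"))
  dt <- .grid_step(curve$time)
  v <- curve$value
  if (spec$tau > 0) v <- exp_conv(v, dt, 1 / spec$tau) / spec$tau
  if (spec$delay > 0) {
    v <- stats::approx(curve$time + spec$delay, v, xout = curve$time,
                       yleft = 0, rule = 2)$y
  }
  dplyr::mutate(curve, value = v)
}

# ---- injection shaping ----------------------------------------------------

#' Widen an instantaneous bolus by a finite injection duration
#'
#' Convolves the curve with a unit-area boxcar of the injection duration,
#' i.e. `out(t)` is the running mean of the input over `[t - D, t]`. Total
#' area is preserved, so a fixed injected dose spread over a longer
#' injection lowers the peak without changing the AUC.
#'
#' @param curve Dense-curve tibble on a regular grid.
#' @param duration Injection duration (s).
#' @return Shaped curve tibble.
#' @export
shape_injection <- function(curve, duration) {
  stopifnot(is.data.frame(curve))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  dt <- .grid_step(curve$time)
  if (duration < dt) {
    warning("injection duration shorter than the grid step; returning curve unchanged")
    return(curve)
  }
  t <- curve$time; v <- curve$value
  n <- length(t)
  cum <- c(0, cumsum((v[-1] + v[-n]) * dt / 2))  # running integral from t[1]
  lag <- stats::approx(t, cum, xout = t - duration, yleft = 0, rule = 2)$y
  dplyr::mutate(curve, value = (cum - lag) / duration)
}

# ---- frame averaging ------------------------------------------------------

#' Average a dense curve over a PET frame schedule
#'
#' Each frame value is the time-average (trapezoidal integral divided by
#' frame duration) of the dense curve over `[frame_start, frame_end)`.
#'
#' @param curve Dense-curve tibble.
#' @param schedule Frame-schedule tibble.
#' @param units,region Labels for the resulting TAC.
#' @return A framed TAC tibble (see [tac()]).
#' @export
frame_average <- function(curve, schedule, units = "SUV", region = "whole_blood") {
  stopifnot(is.data.frame(curve), is.data.frame(schedule))
  t <- curve$time; v <- curve$value
  if (min(schedule$frame_start) < min(t) - 1e-9 ||
      max(schedule$frame_end) > max(t) + 1e-9) {
    stop("frame schedule extends outside the dense grid", call. = FALSE)
  }
  n <- length(t)
  cum <- c(0, cumsum((v[-1] + v[-n]) * diff(t) / 2))
  cum_at <- function(x) stats::approx(t, cum, xout = x, rule = 2)$y
  vals <- (cum_at(schedule$frame_end) - cum_at(schedule$frame_start)) / schedule$dur
  tac(schedule, vals, units = units, region = region)
}

# ---- noise ----------------------------------------------------------------

#' Add duration-weighted Gaussian count noise to a curve
#'
#' Noise approximates decay-corrected Poisson counting: zero-mean Gaussian
#' with standard deviation `scale * sqrt(max(value, 0) / duration)`, so
#' long frames (or slow dense sampling) are less noisy. Reproducible:
#' the output is a pure function of the inputs and `seed`.
#'
#' @param curve Dense-curve or framed TAC tibble.
#' @param scale Noise scale (dimensionless); 0 returns the curve unchanged.
#' @param seed Integer seed.
#' @return The noisy curve.
#' @export
add_noise <- function(curve, scale, seed) {
  stopifnot(is.data.frame(curve))
  if (scale < 0) stop("noise scale must be >= 0", call. = FALSE)
  if (scale == 0) return(curve)
  dur <- if ("dur" %in% names(curve)) curve$dur else rep(.grid_step(curve$time), nrow(curve))
  sd <- scale * sqrt(pmax(curve$value, 0) / dur)
  eps <- withr::with_seed(seed, stats::rnorm(nrow(curve), 0, 1)) * sd
  dplyr::mutate(curve, value = .data$value + eps)
}

#' Draw noisy manual blood samples from a true curve
#'
#' @param curve Dense-curve tibble holding the true blood concentration.
#' @param times Sample times (s); defaults to three late-scan draws.
#' @param cv Coefficient of variation of the measurement error.
#' @param seed Integer seed.
#' @return A [blood_samples()] tibble.
#' @export
draw_blood_samples <- function(curve, times = c(2100, 2400, 2700), cv = 0.05, seed = 1) {
  stopifnot(is.data.frame(curve))
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  truth <- interp_strict(curve$time, curve$value, times, "blood curve")
  mult <- 1 + withr::with_seed(seed, stats::rnorm(length(times), 0, 1)) * cv
  blood_samples(times, pmax(truth * mult, 0))
}

# ---- tissue forward model -------------------------------------------------

#' Simulate a tissue curve from the two-tissue compartment model
#'
#' Solves the reversible 2TCM
#' \deqn{dC_1/dt = K_1 c_p - (k_2 + k_3) C_1 + k_4 C_2, \quad
#'       dC_2/dt = k_3 C_1 - k_4 C_2}
#' via the model's analytic bi-exponential impulse response convolved with
#' the plasma input (exact for piecewise-linear inputs), and returns the
#' PET-visible mixture `(1 - vB)(C1 + C2) + vB * cb`.
#'
#' Rate constants are in the conventional per-minute units; curve time
#' axes are in seconds.
#'
#' @param params A [two_tissue_params()].
#' @param plasma Dense plasma input curve (tibble `time`, `value`).
#' @param blood Dense whole-blood curve; defaults to `plasma`.
#' @return Dense tissue curve tibble.
#' @export
forward_2tcm <- function(params, plasma, blood = plasma) {
  stopifnot(inherits(params, "two_tissue_params"), is.data.frame(plasma))
  if (!identical(plasma$time, blood$time)) {
    stop("plasma and blood must share one dense grid", call. = FALSE)
  }
  dt <- .grid_step(plasma$time)
  # per-second rates
  K1 <- params$K1 / 60; k2 <- params$k2 / 60
  k3 <- params$k3 / 60; k4 <- params$k4 / 60
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  a1 <- (s - disc) / 2
  a2 <- (s + disc) / 2
  cp <- plasma$value
  if (K1 == 0) {
    ct <- rep(0, length(cp))
  } else if (a2 - a1 < 1e-12) {
    # repeated eigenvalue: h(t) = K1 e^{-a t} (1 + (k3 + k4 - a) t)
    e0 <- exp_conv(cp, dt, a1)
    # t e^{-at} * cp  ==  d/da is awkward; build by finite difference of alpha
    h <- 1e-7
    e_minus <- exp_conv(cp, dt, a1 - h)
    e_plus <- exp_conv(cp, dt, a1 + h)
    te <- (e_minus - e_plus) / (2 * h)
    ct <- K1 * (e0 + (k3 + k4 - a1) * te)
  } else {
    c1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
    c2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
    ct <- c1 * exp_conv(cp, dt, a1) + c2 * exp_conv(cp, dt, a2)
  }
  vB <- params$vB
  dplyr::mutate(plasma, value = (1 - vB) * ct + vB * blood$value,
                region = "tissue")
}

# ---- reference truth ------------------------------------------------------

#' Reference input-function model of the simulator
#'
#' A Feng bolus parameterised so that, after shaping by the reference
#' 30 s injection and the reference withdrawal-line dispersion (tau = 5 s),
#' the measured-AIF peak lands near 8.8 SUV with a tail near 0.9 SUV at
#' scan end -- the scale of a calibrated mouse FDG arterial curve.
#'
#' @param onset Arterial arrival time after injection start (s).
#' @return A [feng_model()].
#' @export
default_feng_model <- function(onset = 5) {
  feng_model(A1 = 10.57, A2 = 4, A3 = 1.5,
             lambda1 = 0.25, lambda2 = 0.02, lambda3 = 3e-4, t0 = onset)
}

#' Reference tissue kinetic parameters
#'
#' Per-minute rate constants typical of mouse FDG brain and myocardium.
#'
#' @return Named list of [two_tissue_params()] for `brain` and `myocardium`.
#' @export
default_tissue_params <- function() {
  list(
    brain = two_tissue_params(K1 = 0.24, k2 = 0.43, k3 = 0.05, k4 = 0.004, vB = 0.03),
    myocardium = two_tissue_params(K1 = 1.14, k2 = 2.6, k3 = 0.15, k4 = 0.04, vB = 0.15)
  )
}

#' Assemble the ground truth description for one simulated subject
#'
#' @param feng True arterial bolus model (pre-injection-shaping).
#' @param tissues Named list of [two_tissue_params()] (needs `brain` and
#'   `myocardium`).
#' @param liver_scale Liver-to-blood scale. The simulated liver curve is a
#'   scaled copy of whole blood (a perfusion-dominated blood-pool
#'   approximation), which makes the liver-based IDIF tail exactly
#'   invertible.
#' @param cal_factor True detector counts-per-concentration factor.
#' @param plasma_ratio Plasma-to-whole-blood concentration ratio.
#' @return A list with class `subject_truth`.
#' @export
subject_truth <- function(feng = default_feng_model(),
                          tissues = default_tissue_params(),
                          liver_scale = 0.6,
                          cal_factor = 0.8,
                          plasma_ratio = 1.0) {
  stopifnot(inherits(feng, "feng_model"),
            all(c("brain", "myocardium") %in% names(tissues)))
  if (liver_scale <= 0 || cal_factor <= 0 || plasma_ratio <= 0) {
    stop("scales must be positive", call. = FALSE)
  }
  structure(list(feng = feng, tissues = tissues, liver_scale = liver_scale,
                 cal_factor = cal_factor, plasma_ratio = plasma_ratio),
            class = "subject_truth")
}

# ---- subject-level simulation --------------------------------------------

#' Simulate one complete subject dataset
#'
#' Produces everything the analysis pipeline consumes for a single mouse:
#' the true arterial input function (Feng bolus shaped by the injection
#' duration), the continuous detector trace (calibration factor x
#' dispersed and delayed AIF, plus count noise), three late-scan manual
#' blood samples, and framed time-activity curves for brain, myocardium,
#' left ventricle and liver. The left ventricle mixes blood and
#' myocardial spill as `RC * blood + (1 - RC) * myocardium`; the liver is
#' a scaled blood-pool curve. Ground truth is retained for recovery
#' tests.
#'
#' @param config An [experiment_config()].
#' @param truth A [subject_truth()].
#' @param seed Integer seed driving every noise source.
#' @param noise_scale Count-noise scale (0 for a noiseless subject).
#' @param sample_cv CV of the manual blood-sample measurement error.
#' @param sample_times Manual sample times (s).
#' @param schedule Frame schedule; defaults to [default_frame_schedule()].
#' @param kappa,base_delay Passed to [dispersion_for_config()].
#' @return A list with class `pet_subject`: `config`, `truth`,
#'   `dispersion`, `grid` (dense time grid), `aif_true` (dense tibble),
#'   `trace` (dense detector tibble), `samples`, `tacs` (long framed
#'   tibble), `schedule`, `seed`.
#' @export
simulate_subject <- function(config = experiment_config(),
                             truth = subject_truth(),
                             seed = 1,
                             noise_scale = 0.05,
                             sample_cv = 0.05,
                             sample_times = NULL,
                             schedule = default_frame_schedule(),
                             kappa = 600, base_delay = 30.4) {
  stopifnot(inherits(config, "experiment_config"), inherits(truth, "subject_truth"))
  t <- seq(0, config$scan_length_s, by = 1)
  if (is.null(sample_times)) {
    sample_times <- config$scan_length_s - c(630, 330, 30)
  }
  bolus <- dense_curve(t, feng_curve(truth$feng, t))
  aif <- shape_injection(bolus, config$injection_duration_s)
  disp <- dispersion_for_config(config, kappa = kappa, base_delay = base_delay)
  trace_clean <- apply_dispersion(aif, disp)
  trace_clean$value <- trace_clean$value * truth$cal_factor
  trace <- add_noise(dplyr::mutate(trace_clean, units = "counts"),
                     noise_scale, seed = seed)
  samples <- draw_blood_samples(aif, times = sample_times, cv = sample_cv,
                                seed = seed + 1L)
  plasma <- dplyr::mutate(aif, value = .data$value * truth$plasma_ratio,
                          region = "plasma")
  blood_framed <- frame_average(aif, schedule, region = "whole_blood")
  rc <- config$recovery_coefficient
  region_curves <- list()
  for (rg in c("brain", "myocardium")) {
    dense <- forward_2tcm(truth$tissues[[rg]], plasma, aif)
    region_curves[[rg]] <- frame_average(dense, schedule, region = rg)
  }
  lv <- blood_framed
  lv$value <- rc * blood_framed$value + (1 - rc) * region_curves$myocardium$value
  lv$region <- "left_ventricle"
  liver <- blood_framed
  liver$value <- truth$liver_scale * blood_framed$value
  liver$region <- "liver"
  tacs <- dplyr::bind_rows(region_curves$brain, region_curves$myocardium, lv, liver)
  if (noise_scale > 0) {
    tacs <- tacs |>
      dplyr::group_by(.data$region) |>
      dplyr::group_modify(function(df, key) {
        off <- match(key$region, c("brain", "myocardium", "left_ventricle", "liver"))
        add_noise(df, noise_scale, seed = seed + 10L + off)
      }) |>
      dplyr::ungroup() |>
      dplyr::relocate("region", .after = "units")
  }
  structure(list(config = config, truth = truth, dispersion = disp,
                 aif_true = aif, trace = trace, samples = samples,
                 tacs = tacs, schedule = schedule, seed = seed,
                 noise_scale = noise_scale, sample_cv = sample_cv),
            class = "pet_subject")
}

#' @export
print.pet_subject <- function(x, ...) {
  cat("<pet_subject>  seed", x$seed, "\n")
  print(x$config)
  cat(sprintf("  dispersion tau %.3g s, delay %.3g s; %d frames; %d blood samples\n",
              x$dispersion$tau, x$dispersion$delay, nrow(x$schedule), nrow(x$samples)))
  invisible(x)
}

# ---- cohort simulation ----------------------------------------------------

#' Cohort specification
#'
#' Describes a group of subjects sharing one experimental configuration,
#' with between-subject biological variability expressed as coefficients
#' of variation around the truth means. Parameters are drawn from
#' mean-preserving log-normal distributions (rates and amplitudes are
#' positive quantities).
#'
#' @param n_subjects Number of subjects.
#' @param config Shared [experiment_config()].
#' @param truth Mean [subject_truth()].
#' @param feng_cv CV of the Feng amplitudes and decay constants.
#' @param kinetic_cv CV of the tissue rate constants and vB.
#' @param noise_scale,sample_cv Passed to [simulate_subject()].
#' @param kappa Dispersion-withdrawal coupling.
#' @return A list with class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 9,
                        config = experiment_config(),
                        truth = subject_truth(),
                        feng_cv = 0.15,
                        kinetic_cv = 0.15,
                        noise_scale = 0.05,
                        sample_cv = 0.05,
                        kappa = 600) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (feng_cv < 0 || kinetic_cv < 0) stop("CVs must be >= 0", call. = FALSE)
  structure(list(n_subjects = n_subjects, config = config, truth = truth,
                 feng_cv = feng_cv, kinetic_cv = kinetic_cv,
                 noise_scale = noise_scale, sample_cv = sample_cv,
                 kappa = kappa),
            class = "cohort_spec")
}

# mean-preserving log-normal draw around m with coefficient of variation cv
.ln_draw <- function(m, cv, z) {
  if (cv == 0) return(m)
  sig <- sqrt(log(1 + cv^2))
  m * exp(sig * z - sig^2 / 2)
}

# draw one subject's truth from the cohort distributions
.draw_truth <- function(spec, seed) {
  z <- withr::with_seed(seed, stats::rnorm(32))
  fm <- spec$truth$feng
  lam <- sort(c(.ln_draw(fm$lambda1, spec$feng_cv, z[4]),
                .ln_draw(fm$lambda2, spec$feng_cv, z[5]),
                .ln_draw(fm$lambda3, spec$feng_cv, z[6])), decreasing = TRUE)
  feng <- feng_model(A1 = .ln_draw(fm$A1, spec$feng_cv, z[1]),
                     A2 = .ln_draw(fm$A2, spec$feng_cv, z[2]),
                     A3 = .ln_draw(fm$A3, spec$feng_cv, z[3]),
                     lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
                     t0 = max(fm$t0 * (1 + 0.1 * z[7] * (spec$feng_cv > 0)), 0))
  ti <- spec$truth$tissues
  zi <- 8
  tissues <- lapply(ti, function(p) {
    vals <- vapply(c("K1", "k2", "k3", "k4"), function(nm) {
      v <- .ln_draw(p[[nm]], spec$kinetic_cv, z[zi]); zi <<- zi + 1; v
    }, 0)
    vB <- min(.ln_draw(p$vB, spec$kinetic_cv, z[zi]), 1); zi <<- zi + 1
    two_tissue_params(vals[["K1"]], vals[["k2"]], vals[["k3"]], vals[["k4"]], vB)
  })
  subject_truth(feng = feng, tissues = tissues,
                liver_scale = spec$truth$liver_scale,
                cal_factor = spec$truth$cal_factor,
                plasma_ratio = spec$truth$plasma_ratio)
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from `seed`, so the
#' whole cohort is reproducible bit-for-bit.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A list of [simulate_subject()] results.
#' @export
simulate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 100L,
                                                 spec$n_subjects))
  lapply(seq_len(spec$n_subjects), function(i) {
    truth_i <- .draw_truth(spec, seed = sub_seeds[i])
    simulate_subject(config = spec$config, truth = truth_i,
                     seed = sub_seeds[i] + 1L,
                     noise_scale = spec$noise_scale,
                     sample_cv = spec$sample_cv,
                     kappa = spec$kappa)
  })
}

# ---- triple injection -----------------------------------------------------

#' Simulate a triple-injection experiment
#'
#' Three small boluses are injected into the same animal (15 minutes
#' apart in the reference protocol); the detector trace is the sum of the
#' three dispersed, delayed components plus noise, and one blood sample
#' is drawn 10 minutes after each injection. The individual ground-truth
#' components (in concentration units, dispersion included) are retained.
#'
#' @param models List of three [feng_model()]s, one per injection; each
#'   `t0` is relative to its own injection time.
#' @param injection_times Increasing injection start times (s).
#' @param config [experiment_config()]; the scan must span the last
#'   injection (default scan length is stretched to
#'   `injection_times[3] + 900`).
#' @param truth [subject_truth()] supplying the calibration factor.
#' @param seed Integer seed.
#' @param noise_scale Detector-noise scale.
#' @param sample_cv Blood-sample error CV.
#' @return A list with class `triple_injection`: `trace` (dense detector
#'   tibble), `samples` (one per injection), `components` (list of dense
#'   ground-truth tibbles on the full grid), `injection_times`, `config`,
#'   `dispersion`.
#' @export
simulate_triple_injection <- function(models = replicate(3, default_feng_model(),
                                                         simplify = FALSE),
                                      injection_times = c(0, 900, 1800),
                                      config = experiment_config(
                                        injection_volume_ul = 30,
                                        dose_mbq = 4.5,
                                        scan_length_s = 2700),
                                      truth = subject_truth(),
                                      seed = 1,
                                      noise_scale = 0.05,
                                      sample_cv = 0.05) {
  stopifnot(length(models) == 3, length(injection_times) == 3)
  if (is.unsorted(injection_times, strictly = TRUE)) {
    stop("injection times must be strictly increasing", call. = FALSE)
  }
  t_end <- max(config$scan_length_s, injection_times[3] + 900)
  t <- seq(0, t_end, by = 1)
  disp <- dispersion_for_config(config)
  components <- purrr::map2(models, as.list(injection_times), function(m, t_inj) {
    m_abs <- feng_model(m$A1, m$A2, m$A3, m$lambda1, m$lambda2, m$lambda3,
                        t0 = m$t0 + t_inj)
    shaped <- shape_injection(dense_curve(t, feng_curve(m_abs, t)),
                              config$injection_duration_s)
    apply_dispersion(shaped, disp)
  })
  total <- components[[1]]
  total$value <- components[[1]]$value + components[[2]]$value + components[[3]]$value
  trace <- dplyr::mutate(total, value = .data$value * truth$cal_factor,
                         units = "counts")
  trace <- add_noise(trace, noise_scale, seed = seed)
  samples <- draw_blood_samples(total, times = injection_times + 600,
                                cv = sample_cv, seed = seed + 1L)
  structure(list(trace = trace, samples = samples, components = components,
                 injection_times = injection_times, config = config,
                 dispersion = disp, models = models, seed = seed),
            class = "triple_injection")
}
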