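test_that("injection shaping preserves area and orders peaks by duration", {
  t <- seq(0, 600, by = 0.5)
  # finite-support bolus so no mass leaves the grid
  bolus <- dense_curve(t, feng_curve(feng_model(10, 0.5, 0.1, 0.2, 0.03,
                                                0.005, t0 = 5), t))
  auc0 <- sum(diff(t) * (bolus$value[-1] + bolus$value[-length(t)]) / 2)
  peaks <- sapply(c(15, 30, 60), function(d) {
    sh <- shape_injection(bolus, d)
    auc <- sum(diff(t) * (sh$value[-1] + sh$value[-length(t)]) / 2)
    expect_lt(abs(auc - auc0) / auc0, 1e-3)
    max(sh$value)
  })
  expect_true(peaks[1] > peaks[2] && peaks[2] > peaks[3])
  # sub-grid duration degenerates to identity with a warning
  expect_warning(out <- shape_injection(bolus, 0.1), "shorter than the grid step")
  expect_identical(out$value, bolus$value)
  expect_error(shape_injection(bolus, -1), "positive")
})

test_that("dispersion matches the closed-form step response and shrinks peaks", {
  t <- seq(0, 200, by = 0.1)
  step <- dense_curve(t, rep(1, length(t)))
  for (tau in c(3, 10)) {
    out <- apply_dispersion(step, dispersion_spec(tau, 0))
    expect_equal(out$value, 1 - exp(-t / tau), tolerance = 1e-4)
  }
  # tau = 0, delay = 0 is the identity
  aif <- ref_shaped_aif()
  expect_identical(apply_dispersion(aif, dispersion_spec(0, 0))$value, aif$value)
  # unit-area kernel preserves AUC on (effectively) finite support
  t2 <- seq(0, 3000, 1)
  bolus <- dense_curve(t2, feng_curve(feng_model(10, 0.5, 0, 0.2, 0.01, 1e-4), t2))
  for (tau in c(5, 30)) {
    out <- apply_dispersion(bolus, dispersion_spec(tau, 0))
    a0 <- sum(bolus$value); a1 <- sum(out$value)
    expect_lt(abs(a1 - a0) / a0, 0.005)
  }
  # peak height decreases and width grows monotonically in tau
  peaks <- sapply(c(0, 2, 5, 10, 30), function(tau) {
    max(apply_dispersion(aif, dispersion_spec(tau, 0))$value)
  })
  expect_true(all(diff(peaks) < 0))
  # delay shifts the curve
  sh <- apply_dispersion(aif, dispersion_spec(0, 30))
  expect_equal(sh$value[aif$time >= 30], aif$value[aif$time <= max(aif$time) - 30],
               tolerance = 1e-9)
})

test_that("the 2TCM forward model obeys its closed forms", {
  t <- seq(0, 1200, 1)
  const <- dense_curve(t, rep(1, length(t)))
  # K1 = 0 (and vB = 0) gives identically zero tissue
  z <- forward_2tcm(two_tissue_params(0, 0.5, 0.1, 0.05, 0), const)
  expect_equal(max(abs(z$value)), 0)
  # constant input, one-tissue limit: (K1/k2)(1 - e^{-k2 t}) in minutes
  p <- two_tissue_params(0.3, 0.6, 0, 0, 0)
  out <- forward_2tcm(p, const)
  expected <- (0.3 / 0.6) * (1 - exp(-0.6 * t / 60))
  expect_equal(out$value, expected, tolerance = 1e-5)
  expect_error(two_tissue_params(-0.1, 0.5, 0.1, 0, 0), ">= 0")
})

test_that("the analytic 2TCM solution agrees with a stiff ODE integrator", {
  skip_if_not_installed("deSolve")
  plasma <- ref_shaped_aif()
  p <- default_tissue_params()$myocardium
  ours <- forward_2tcm(p, plasma)
  cp_fun <- stats::approxfun(plasma$time, plasma$value, rule = 2)
  rhs <- function(t, y, parms) {
    with(as.list(parms), {
      cp <- cp_fun(t)
      list(c(K1 * cp - (k2 + k3) * y[1] + k4 * y[2],
             k3 * y[1] - k4 * y[2]))
    })
  }
  sol <- deSolve::lsoda(c(0, 0), times = plasma$time, func = rhs,
                        parms = c(K1 = p$K1 / 60, k2 = p$k2 / 60,
                                  k3 = p$k3 / 60, k4 = p$k4 / 60),
                        rtol = 1e-10, atol = 1e-12)
  oracle <- (1 - p$vB) * (sol[, 2] + sol[, 3]) + p$vB * plasma$value
  expect_lt(max(abs(ours$value - oracle)) / max(oracle), 1e-4)
})

test_that("frame averaging is the exact time-average over each frame", {
  t <- seq(0, 10, 0.01)
  sched <- frame_schedule(c(0, 2, 5), c(2, 5, 10))
  const <- frame_average(dense_curve(t, rep(1, length(t))), sched)
  expect_equal(const$value, rep(1, 3))
  ramp <- frame_average(dense_curve(t, t), frame_schedule(0, 2))
  expect_equal(ramp$value, 1.0, tolerance = 1e-6)
  # quadrature oracle on the reference bolus
  m <- default_feng_model()
  f <- function(x) {  # integrate() evaluates at unsorted nodes
    o <- order(x)
    out <- numeric(length(x))
    out[o] <- feng_curve(m, x[o])
    out
  }
  framed <- frame_average(ref_bolus(t = seq(0, 2730, 0.1)),
                          default_frame_schedule())
  oracle <- mapply(function(a, b) {
    stats::integrate(f, a, b, rel.tol = 1e-10)$value / (b - a)
  }, framed$frame_start, framed$frame_end)
  expect_lt(max(abs(framed$value - oracle)) / max(oracle), 5e-4)
  expect_error(frame_average(dense_curve(t, t), frame_schedule(0, 20)),
               "outside the dense grid")
})

test_that("count noise is reproducible and has the nominal spread", {
  curve <- frame_average(ref_shaped_aif(), default_frame_schedule())
  expect_identical(add_noise(curve, 0, seed = 1), curve)
  n1 <- add_noise(curve, 0.05, seed = 7)
  n2 <- add_noise(curve, 0.05, seed = 7)
  expect_identical(n1$value, n2$value)
  expect_false(identical(add_noise(curve, 0.05, seed = 8)$value, n1$value))
  # empirical SD at a fixed frame across many seeds matches the model
  i <- 20
  nominal <- 0.1 * sqrt(curve$value[i] / curve$dur[i])
  draws <- vapply(1:1000, function(s) add_noise(curve, 0.1, seed = s)$value[i], 0)
  expect_lt(abs(sd(draws) - nominal) / nominal, 0.05)
})

test_that("manual blood samples are seeded draws around the true curve", {
  aif <- ref_shaped_aif()
  s0 <- draw_blood_samples(aif, cv = 0, seed = 1)
  expect_equal(s0$concentration,
               approx(aif$time, aif$value, s0$time)$y, tolerance = 1e-12)
  expect_identical(draw_blood_samples(aif, cv = 0.05, seed = 3),
                   draw_blood_samples(aif, cv = 0.05, seed = 3))
  expect_error(draw_blood_samples(aif, times = 5000), "outside")
  truth <- approx(aif$time, aif$value, 2400)$y
  draws <- vapply(1:1000, function(s) {
    draw_blood_samples(aif, times = 2400, cv = 0.05, seed = s)$concentration
  }, 0)
  expect_lt(abs(mean(draws) - truth) / truth, 0.01)
})

test_that("a noiseless ideal subject reduces to its own ground truth", {
  cfg <- experiment_config()
  truth <- subject_truth(cal_factor = 1)
  sub <- simulate_subject(config = cfg, truth = truth, seed = 1,
                          noise_scale = 0, sample_cv = 0,
                          kappa = 0, base_delay = 0)
  expect_equal(sub$trace$value, sub$aif_true$value, tolerance = 1e-12)
  # RC = 1 means the left ventricle sees pure blood
  cfg_rc1 <- experiment_config(recovery_coefficient = 1)
  sub2 <- simulate_subject(config = cfg_rc1, seed = 2, noise_scale = 0,
                           sample_cv = 0)
  lv <- subject_tac(sub2, "left_ventricle")
  blood <- frame_average(sub2$aif_true, sub2$schedule)
  expect_equal(lv$value, blood$value, tolerance = 1e-12)
})

test_that("subjects regenerate bit-identically from (config, seed)", {
  a <- simulate_subject(seed = 11)
  b <- simulate_subject(seed = 11)
  expect_identical(a$trace$value, b$trace$value)
  expect_identical(a$samples$concentration, b$samples$concentration)
  expect_identical(a$tacs$value, b$tacs$value)
})

test_that("cohorts are deterministic and mean-preserving", {
  spec <- cohort_spec(n_subjects = 3, noise_scale = 0.02)
  c1 <- simulate_cohort(spec, seed = 5)
  c2 <- simulate_cohort(spec, seed = 5)
  expect_identical(c1[[2]]$trace$value, c2[[2]]$trace$value)
  # zero-CV cohort carries the spec's truth unchanged
  spec0 <- cohort_spec(n_subjects = 1, feng_cv = 0, kinetic_cv = 0)
  c0 <- simulate_cohort(spec0, seed = 1)
  expect_equal(c0[[1]]$truth$feng$A1, spec0$truth$feng$A1)
  expect_equal(c0[[1]]$truth$tissues$brain$K1, spec0$truth$tissues$brain$K1)
  # law of large numbers on the K1 draw (draw level, no imaging needed)
  k1s <- vapply(1:200, function(i) {
    petaif:::.draw_truth(spec, seed = i)$tissues$brain$K1
  }, 0)
  expect_lt(abs(mean(k1s) - spec$truth$tissues$brain$K1) /
              spec$truth$tissues$brain$K1, 0.02)
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(feng_cv = -0.1), "CVs must be")
})

test_that("triple-injection traces are exact sums of their components", {
  tri <- simulate_triple_injection(seed = 2, noise_scale = 0, sample_cv = 0)
  total <- tri$components[[1]]$value + tri$components[[2]]$value +
    tri$components[[3]]$value
  expect_equal(tri$trace$value, total * 0.8, tolerance = 1e-12)
  expect_error(
    simulate_triple_injection(injection_times = c(0, 900, 900), seed = 1),
    "strictly increasing")
  # injections many half-lives apart: segments equal the individual curves
  m <- feng_model(10, 1, 0.05, 0.3, 0.03, 0.004)  # fast-clearing bolus
  far <- simulate_triple_injection(models = list(m, m, m),
                                   injection_times = c(0, 4000, 8000),
                                   config = experiment_config(scan_length_s = 12000),
                                   truth = subject_truth(cal_factor = 1),
                                   seed = 1, noise_scale = 0, sample_cv = 0)
  seg2 <- far$trace$value[far$trace$time >= 4000 & far$trace$time < 8000]
  comp2 <- far$components[[2]]$value[far$components[[2]]$time >= 4000 &
                                       far$components[[2]]$time < 8000]
  expect_lt(max(abs(seg2 - comp2)) / max(comp2), 1e-3)
})
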