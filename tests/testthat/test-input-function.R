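test_that("trace calibration recovers the true scale factor", {
  aif <- ref_shaped_aif()
  trace <- dplyr::mutate(aif, value = value * 2)
  samples <- draw_blood_samples(aif, cv = 0, seed = 1)
  cal <- calibrate_trace(trace, samples)
  expect_equal(cal$factor, 0.5, tolerance = 1e-4)
  expect_equal(cal$curve$value, aif$value, tolerance = 1e-3)
  # one sample reduces to the plain ratio against the windowed trace mean
  one <- blood_samples(2400, 3.7)
  cal1 <- calibrate_trace(trace, one)
  wm <- mean(trace$value[trace$time >= 2385 & trace$time <= 2415])
  expect_equal(cal1$factor, 3.7 / wm, tolerance = 1e-12)
  # scale equivariance: scaling the trace by a scales the factor by 1/a
  cal_a <- calibrate_trace(dplyr::mutate(trace, value = value * 4), samples)
  expect_equal(cal_a$factor, cal$factor / 4, tolerance = 1e-12)
  expect_error(calibrate_trace(dplyr::mutate(trace, value = value * 0), samples),
               "zero at every sample time")
})

test_that("calibration is unbiased under sample noise", {
  aif <- ref_shaped_aif()
  trace <- dplyr::mutate(aif, value = value / 0.5)
  factors <- vapply(1:500, function(s) {
    calibrate_trace(trace, draw_blood_samples(aif, cv = 0.05, seed = s))$factor
  }, 0)
  expect_lt(abs(mean(factors) - 0.5) / 0.5, 0.01)
})

test_that("dispersion correction inverts the dispersion kernel", {
  aif <- ref_shaped_aif()
  expect_identical(correct_dispersion(aif, 0), aif)
  for (tau in c(2, 5, 10, 30)) {
    rt <- correct_dispersion(apply_dispersion(aif, dispersion_spec(tau, 0)), tau)
    expect_lt(max(abs(rt$value - aif$value)) / max(aif$value), 0.01)
  }
  # dispersed unit step comes back to the step
  t <- seq(0, 300, 0.1)
  tau <- 8
  dispersed <- dense_curve(t, 1 - exp(-t / tau))
  rec <- correct_dispersion(dispersed, tau)
  expect_lt(max(abs(rec$value[t > 1] - 1)), 0.01)
  expect_error(correct_dispersion(aif, -2), ">= 0")
})

test_that("plasma conversion is pointwise and unit-safe", {
  aif <- ref_shaped_aif()
  expect_equal(to_plasma(aif, 1.0)$value, aif$value)
  scaled <- to_plasma(aif, 1.1)
  expect_equal(sum(scaled$value), 1.1 * sum(aif$value), tolerance = 1e-12)
  r <- function(t) 1 + 0.1 * exp(-t / 600)
  tv <- to_plasma(aif, r)
  expect_equal(tv$value, aif$value * r(aif$time), tolerance = 1e-12)
  expect_equal(unique(tv$region), "plasma")
  expect_error(to_plasma(aif, -1), "positive")
})

test_that("partial-volume correction inverts the spill model", {
  sched <- default_frame_schedule()
  blood <- frame_average(ref_shaped_aif(), sched)
  myo <- tac(sched, rep(1, nrow(sched)), region = "myocardium")
  rc <- 0.42
  lv <- tac(sched, rc * 5 + (1 - rc) * 1, region = "left_ventricle")
  corr <- pvc_left_ventricle(lv, myo, rc)
  expect_equal(corr$value, rep(5, nrow(sched)), tolerance = 1e-12)
  # RC = 1 is the identity
  expect_equal(pvc_left_ventricle(blood, myo, 1)$value, blood$value)
  # lv == myo is a fixed point for any RC
  expect_equal(pvc_left_ventricle(myo, myo, 0.42)$value, myo$value)
  expect_error(pvc_left_ventricle(lv, myo, 0), "in \\(0, 1\\]")
  expect_warning(
    pvc_left_ventricle(tac(sched, rep(0, nrow(sched))),
                       tac(sched, rep(1, nrow(sched))), 0.5),
    "negative values")
})

test_that("the LV/liver hand-over sits at the analytic second-derivative peak", {
  # c(t) = t e^{-t}: c'' = (t - 2) e^{-t} has its post-peak max at t = 3
  t <- seq(0, 12, 0.01)
  expect_equal(find_lv_liver_intersection(texp_curve(t), smooth_window = 1),
               3, tolerance = 0.02)
  # ties after the peak resolve to the earliest candidate
  tt <- 0:19
  vals <- c(0, 5, 3, 1, 1, 3, 1, 1, 3, 1, rep(1, 10))  # equal bumps at t = 5, 8
  d2 <- petaif:::.second_diff(tt, vals)
  post <- which(seq_along(tt) > which.max(vals) & !is.na(d2))
  expect_gte(sum(d2[post] == max(d2[post])), 2)  # genuinely tied
  expect_equal(find_lv_liver_intersection(dense_curve(tt, vals),
                                          smooth_window = 1),
               tt[post[which.max(d2[post])]])
  expect_error(find_lv_liver_intersection(dense_curve(0:20, 0:20)), "no interior peak")
  # framed noisy LV lands within 2 frames of the noiseless oracle
  sub0 <- simulate_subject(seed = 9, noise_scale = 0, sample_cv = 0)
  subn <- simulate_subject(seed = 9, noise_scale = 0.05, sample_cv = 0)
  rc <- 0.42
  j0 <- find_lv_liver_intersection(
    pvc_left_ventricle(subject_tac(sub0, "left_ventricle"),
                       subject_tac(sub0, "myocardium"), rc))
  jn <- find_lv_liver_intersection(
    pvc_left_ventricle(subject_tac(subn, "left_ventricle"),
                       subject_tac(subn, "myocardium"), rc))
  sched <- sub0$schedule
  fidx <- function(x) findInterval(x, sched$frame_start)
  expect_lte(abs(fidx(jn) - fidx(j0)), 2)
})

test_that("liver scaling anchors the curve to the blood sample", {
  sched <- default_frame_schedule()
  liver <- tac(sched, rep(2, nrow(sched)), region = "liver")
  s <- blood_samples(2000, 1)
  # factor = 1/2, so the scaled curve sits at the sample concentration
  expect_equal(scale_liver(liver, s)$value, rep(1, nrow(sched)))
  # a sample drawn from the curve itself gives factor 1
  aifed <- frame_average(ref_shaped_aif(), sched, region = "liver")
  self <- blood_samples(2400, approx(aifed$mid, aifed$value, 2400)$y)
  expect_equal(scale_liver(aifed, self)$value, aifed$value, tolerance = 1e-12)
  expect_error(scale_liver(tac(sched, rep(0, nrow(sched))), s), "not positive")
})

test_that("the IDIF is an exact inverse of the forward spill/scale model", {
  sub <- simulate_subject(seed = 4, noise_scale = 0, sample_cv = 0)
  idif <- build_idif(subject_tac(sub, "left_ventricle"),
                     subject_tac(sub, "myocardium"),
                     subject_tac(sub, "liver"),
                     sub$samples, rc = sub$config$recovery_coefficient)
  blood <- frame_average(sub$aif_true, sub$schedule)
  expect_lt(max(abs(idif$value - blood$value)) / max(blood$value), 0.01)
  expect_lt(attr(idif, "junction_jump"), 0.15)
  expect_true(attr(idif, "junction") > 30 && attr(idif, "junction") < 300)
})

test_that("an ideal LV with RC = 1 and liver = blood passes through unchanged", {
  sub <- simulate_subject(config = experiment_config(recovery_coefficient = 1),
                          truth = subject_truth(liver_scale = 1),
                          seed = 5, noise_scale = 0, sample_cv = 0,
                          sample_times = c(2100, 2400, 2600))
  blood <- frame_average(sub$aif_true, sub$schedule)
  idif <- build_idif(subject_tac(sub, "left_ventricle"),
                     subject_tac(sub, "myocardium"),
                     subject_tac(sub, "liver"),
                     sub$samples, rc = 1)
  expect_lt(max(abs(idif$value - blood$value)) / max(blood$value), 1e-3)
})

test_that("triple-injection correction recovers each component's features", {
  cfg <- experiment_config(injection_volume_ul = 30, dose_mbq = 4.5,
                           injection_duration_s = 9, scan_length_s = 2700)
  tri <- simulate_triple_injection(config = cfg, seed = 3,
                                   noise_scale = 0.05, sample_cv = 0)
  corr <- correct_triple_injection(tri$trace, tri$injection_times, tri$samples,
                                   injection_duration = 9,
                                   tau = tri$dispersion$tau)
  ests <- vector("list", 3)
  for (i in 1:3) {
    est <- dplyr::filter(corr$model_curves[[i]], time < 900)
    truth <- dplyr::filter(tri$components[[i]],
                           time >= tri$injection_times[i],
                           time < tri$injection_times[i] + 900)
    truth$time <- truth$time - tri$injection_times[i]
    f_est <- feature_vec(compute_features(est, label = "est"))
    f_tru <- feature_vec(compute_features(truth, label = "tru"))
    expect_lt(max(rel_err(f_est, f_tru)), 0.03)
    ests[[i]] <- f_est
  }
  # identical true components: features agree across the three injections
  for (i in 2:3) expect_lt(max(rel_err(ests[[i]], ests[[1]])), 0.05)
})

test_that("triple correction reduces to identity for disjoint injections", {
  m <- feng_model(10, 1, 0.05, 0.3, 0.03, 0.004)
  far <- simulate_triple_injection(models = list(m, m, m),
                                   injection_times = c(0, 4000, 8000),
                                   config = experiment_config(scan_length_s = 12000),
                                   truth = subject_truth(cal_factor = 1),
                                   seed = 1, noise_scale = 0, sample_cv = 0)
  corr <- correct_triple_injection(far$trace, far$injection_times, samples = NULL)
  for (i in 1:3) {
    seg <- far$trace$value[far$trace$time >= far$injection_times[i] &
                             far$trace$time < far$injection_times[i] + 4000]
    got <- corr$curves[[i]]$value[seq_along(seg)]
    expect_lt(max(abs(got - seg)) / max(seg), 0.002)
  }
  expect_error(correct_triple_injection(far$trace, c(0, 1, 1)), "strictly increasing")
})
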