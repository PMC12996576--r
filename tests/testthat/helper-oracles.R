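# Shared fixtures and independent oracles used across the test files.

# reference bolus on the standard 1 s grid
ref_grid <- seq(0, 2730, by = 1)

ref_bolus <- function(t = ref_grid, model = default_feng_model()) {
  dense_curve(t, feng_curve(model, t))
}

ref_shaped_aif <- function(duration = 30, t = ref_grid) {
  shape_injection(ref_bolus(t), duration)
}

# c(t) = t e^{-t}: the analytic playground curve for derivative landmarks
texp_curve <- function(t) dense_curve(t, t * exp(-t))

# exact two-sided Mann-Whitney p by full enumeration of group labelings,
# independent of the implementation under test
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  us <- utils::combn(length(pooled), na, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# relative error helper
rel_err <- function(est, truth) abs(est - truth) / abs(truth)

expect_rel <- function(est, truth, tol) {
  expect_lt(max(rel_err(est, truth)), tol)
}

# extract one region's TAC from a simulated subject
subject_tac <- function(subject, region) {
  out <- subject$tacs[subject$tacs$region == region, ]
  stopifnot(nrow(out) > 0)
  out
}

# feature vector (the six Table-style features) as a named numeric
feature_vec <- function(f) {
  unlist(f[c("suv_max", "ttp", "fwhm", "auc_peak", "auc_tail", "auc_ratio")])
}
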