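# Group-comparison statistics and the end-to-end cohort study driver.

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The reported statistic
#' is `U = min(U_a, U_b)` with midrank tie handling. The two-sided
#' p-value is exact (full enumeration of labelings) when the combined
#' sample size is at most 16 and there are no ties, and otherwise uses
#' the normal approximation with tie and continuity corrections --
#' appropriate for the small group sizes (4-9 animals) these experiments
#' use.
#'
#' @param a,b Numeric vectors.
#' @return One-row tibble: `u_statistic`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (na + nb) <= 16 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  tibble::tibble(u_statistic = min(ua, ub), p_value = min(p, 1),
                 method = if (exact) "exact" else "normal")
}

#' Mean and 95% confidence half-width
#'
#' The half-width is `t(0.975, n-1) * sd / sqrt(n)`; with a single
#' observation it is reported as missing.
#'
#' @param x Numeric vector.
#' @return One-row tibble: `mean`, `ci95`, `n`.
#' @export
mean_ci95 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) stop("no finite observations", call. = FALSE)
  hw <- if (n >= 2) stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n) else NA_real_
  tibble::tibble(mean = mean(x), ci95 = hw, n = n)
}

#' Compare quantities between groups against a reference group
#'
#' For every quantity and every non-reference group, reports group means
#' with 95% confidence intervals and a Mann-Whitney U test against the
#' reference at `alpha` (no multiplicity correction: each comparison is
#' reported at its own per-test level).
#'
#' @param data Long tibble with columns `group`, `quantity`, `value`, and
#'   optionally `subject` (used to check completeness).
#' @param reference Label of the reference group.
#' @param alpha Significance level.
#' @return A group-comparison tibble: `quantity`, `group_a` (reference),
#'   `group_b`, `mean_a`, `mean_b`, `ci95_a`, `ci95_b`, `u_statistic`,
#'   `p_value`, `significant`.
#' @export
compare_groups <- function(data, reference, alpha = 0.05) {
  stopifnot(is.data.frame(data),
            all(c("group", "quantity", "value") %in% names(data)))
  if (!reference %in% data$group) {
    stop("reference group '", reference, "' not present", call. = FALSE)
  }
  if ("subject" %in% names(data)) {
    miss <- data |>
      dplyr::filter(!is.finite(.data$value))
    if (nrow(miss) > 0) {
      stop(sprintf("missing value for quantity '%s' in subject '%s'",
                   miss$quantity[1], miss$subject[1]), call. = FALSE)
    }
    counts <- data |>
      dplyr::count(.data$subject, name = "k")
    if (length(unique(counts$k)) > 1) {
      full <- unique(data$quantity)
      for (s in unique(data$subject)) {
        have <- data$quantity[data$subject == s]
        lack <- setdiff(full, have)
        if (length(lack) > 0) {
          stop(sprintf("quantity '%s' missing for subject '%s'", lack[1], s),
               call. = FALSE)
        }
      }
    }
  }
  groups <- setdiff(unique(data$group), reference)
  ref <- dplyr::filter(data, .data$group == reference)
  purrr::map_dfr(unique(data$quantity), function(q) {
    a <- ref$value[ref$quantity == q]
    sa <- mean_ci95(a)
    purrr::map_dfr(groups, function(g) {
      b <- data$value[data$group == g & data$quantity == q]
      sb <- mean_ci95(b)
      u <- mann_whitney_u(a, b)
      tibble::tibble(quantity = q, group_a = reference, group_b = g,
                     mean_a = sa$mean, mean_b = sb$mean,
                     ci95_a = sa$ci95, ci95_b = sb$ci95,
                     u_statistic = u$u_statistic, p_value = u$p_value,
                     significant = u$p_value < alpha)
    })
  })
}

# ---- per-subject processing pipeline -------------------------------------

#' Run the full analysis pipeline on one subject
#'
#' Mirrors the processing a real experiment receives: calibrate the
#' detector trace against the manual blood samples, fit the parametric
#' input-function model, correct the fit for catheter delay and
#' dispersion, convert to plasma, build the IDIF from the image curves,
#' extract curve features from both input functions, and fit the 2TCM
#' and Patlak models to brain and myocardium with both input functions.
#'
#' @param subject A [simulate_subject()] result (or a list with the same
#'   fields built from real data).
#' @param t_star Patlak linear-phase start (s).
#' @param plasma_ratio Plasma-to-whole-blood ratio.
#' @param with_kinetics Set `FALSE` to skip the (slower) kinetic fits and
#'   return curve features only.
#' @return Long tibble with columns `quantity` and `value`. Quantities
#'   are named `<source>_<feature>` for curve features and
#'   `<region>_<param>_<source>` for kinetic parameters, with source
#'   `aif` or `idif`.
#' @export
process_subject <- function(subject, t_star = 600, plasma_ratio = 1.0,
                            with_kinetics = TRUE) {
  stopifnot(inherits(subject, "pet_subject"))
  cal <- calibrate_trace(subject$trace, subject$samples)
  disp <- subject$dispersion
  dur <- subject$config$injection_duration_s
  # fit the bolus model through the known measurement chain (injection
  # boxcar + withdrawal-line dispersion); the fitted t0 absorbs the
  # catheter delay, which is then subtracted to return to the scan clock
  measure <- function(cv) {
    apply_dispersion(suppressWarnings(shape_injection(cv, dur)),
                     dispersion_spec(disp$tau, 0))
  }
  fit <- fit_feng(cal$curve, measure = measure)
  m_delay <- shift_feng(fit$model, -disp$delay)
  grid <- subject$aif_true$time
  bolus <- dense_curve(grid, feng_curve(m_delay, grid))
  # features are computed on the measured-space curve (dispersion left
  # in, as the detector sees it), delay-corrected to the scan clock
  aif_meas <- measure(bolus)
  aif_feat <- compute_features(aif_meas, label = "aif")
  # kinetic modelling uses the dispersion-free arterial curve
  aif_corr <- suppressWarnings(shape_injection(bolus, dur))
  tacs <- subject$tacs
  get_tac <- function(rg) dplyr::filter(tacs, .data$region == rg)
  idif <- build_idif(get_tac("left_ventricle"), get_tac("myocardium"),
                     get_tac("liver"), subject$samples,
                     rc = subject$config$recovery_coefficient)
  idif_fit <- fit_feng(idif)
  idif_feat <- compute_features(idif_fit, label = "idif")
  feats <- dplyr::bind_rows(aif_feat, idif_feat) |>
    tidyr::pivot_longer(-"curve", names_to = "feature", values_to = "value") |>
    dplyr::mutate(quantity = paste(.data$curve, .data$feature, sep = "_")) |>
    dplyr::select("quantity", "value")
  if (!with_kinetics) return(feats)
  inputs <- list(
    aif = to_plasma(aif_corr, plasma_ratio),
    idif = to_plasma(dense_from_tac(idif, grid), plasma_ratio)
  )
  bloods <- list(aif = aif_corr, idif = dense_from_tac(idif, grid))
  kin <- purrr::map_dfr(c("brain", "myocardium"), function(rg) {
    tt <- get_tac(rg)
    purrr::map_dfr(names(inputs), function(src) {
      f2 <- fit_2tcm(tt, inputs[[src]], bloods[[src]])
      pk <- fit_patlak(tt, inputs[[src]], t_star = t_star)
      tibble::tibble(
        quantity = paste(rg, c("K1", "k2", "k3", "k4", "vB", "Ki", "Ki_patlak"),
                         src, sep = "_"),
        value = c(f2$params$K1, f2$params$k2, f2$params$k3, f2$params$k4,
                  f2$params$vB, f2$params$Ki, pk$Ki_patlak))
    })
  })
  dplyr::bind_rows(feats, kin)
}

#' Interpolate a framed TAC onto a dense grid
#'
#' Linear interpolation through the frame mid-points, clamped to zero at
#' the scan start (the tracer is not in the blood before injection).
#'
#' @param tac Framed TAC tibble.
#' @param times Dense output grid (s).
#' @return Dense-curve tibble.
#' @export
dense_from_tac <- function(tac, times) {
  stopifnot(is.data.frame(tac), "mid" %in% names(tac))
  anchor_t <- c(min(tac$frame_start), tac$mid)
  anchor_v <- c(0, tac$value)
  v <- stats::approx(anchor_t, anchor_v, xout = times, rule = 2)$y
  v[times < anchor_t[1]] <- 0
  dense_curve(times, pmax(v, 0),
              units = tac$units[1], region = tac$region[1])
}

# ---- cohort study driver --------------------------------------------------

#' Run a multi-group variability study end to end
#'
#' Simulates every cohort, processes every subject through the full
#' pipeline, and compares every quantity of every non-reference group
#' against the reference group. This is the in-silico analogue of a
#' one-variable-at-a-time experiment design: each non-reference cohort
#' spec should differ from the reference in a single knob.
#'
#' @param specs Named list of [cohort_spec()]s; `reference` names the
#'   reference entry.
#' @param seed Integer seed (per-group seeds are derived from it).
#' @param reference Name of the reference group in `specs`.
#' @param t_star,with_kinetics Passed to [process_subject()].
#' @param alpha Significance level for the comparisons.
#' @return A list with class `variability_study`: `subjects` (long tibble
#'   of per-subject quantities), `summary` (per-group means and CIs), and
#'   `comparisons` (group-comparison tibble; zero rows when only the
#'   reference group is given).
#' @export
run_variability_study <- function(specs, seed = 1, reference = "reference",
                                  t_star = 600, with_kinetics = TRUE,
                                  alpha = 0.05) {
  stopifnot(is.list(specs), !is.null(names(specs)))
  if (!reference %in% names(specs)) {
    stop("no spec named '", reference, "'", call. = FALSE)
  }
  group_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 100L, length(specs)))
  subjects <- purrr::imap_dfr(specs, function(sp, gname) {
    gi <- match(gname, names(specs))
    cohort <- simulate_cohort(sp, seed = group_seeds[gi])
    purrr::imap_dfr(cohort, function(sub, i) {
      q <- process_subject(sub, t_star = t_star, with_kinetics = with_kinetics)
      dplyr::mutate(q, group = gname, subject = paste0(gname, "_", i))
    })
  })
  summary <- subjects |>
    dplyr::group_by(.data$group, .data$quantity) |>
    dplyr::reframe(mean_ci95(.data$value))
  comparisons <- if (length(specs) > 1) {
    compare_groups(subjects, reference = reference, alpha = alpha)
  } else {
    compare_groups(subjects, reference = reference, alpha = alpha)[0, ]
  }
  structure(list(subjects = subjects, summary = summary,
                 comparisons = comparisons, seed = seed),
            class = "variability_study")
}

#' @export
print.variability_study <- function(x, ...) {
  cat("<variability_study> ", length(unique(x$subjects$group)), "groups,",
      length(unique(x$subjects$subject)), "subjects,",
      nrow(x$comparisons), "comparisons\n")
  if (nrow(x$comparisons) > 0) {
    sig <- dplyr::filter(x$comparisons, .data$significant)
    cat("  significant at alpha:", nrow(sig), "of", nrow(x$comparisons), "\n")
  }
  invisible(x)
}
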