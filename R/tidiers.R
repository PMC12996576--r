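# broom-style tidiers for the fitted-object classes

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.feng_model <- function(x, ...) {
  tibble::tibble(term = c("A1", "A2", "A3", "lambda1", "lambda2", "lambda3", "t0"),
                 estimate = c(x$A1, x$A2, x$A3, x$lambda1, x$lambda2,
                              x$lambda3, x$t0))
}

#' @export
tidy.feng_fit <- function(x, ...) tidy(x$model)

#' @export
glance.feng_fit <- function(x, ...) {
  tibble::tibble(rms = x$rms, sse = x$sse, nobs = nrow(x$data),
                 niter = x$niter,
                 auc_inf = feng_auc_inf(x$model))
}

#' @export
tidy.two_tissue_params <- function(x, ...) {
  tibble::tibble(term = c("K1", "k2", "k3", "k4", "vB", "Ki"),
                 estimate = c(x$K1, x$k2, x$k3, x$k4, x$vB, x$Ki))
}

#' @export
tidy.tcm_fit <- function(x, ...) tidy(x$params)

#' @export
glance.tcm_fit <- function(x, ...) {
  tibble::tibble(rms = x$rms, sse = x$sse, nobs = nrow(x$data), niter = x$niter)
}

#' @export
tidy.patlak_fit <- function(x, ...) {
  tibble::tibble(term = c("Ki_patlak", "intercept"),
                 estimate = c(x$Ki_patlak, x$intercept))
}

#' @export
glance.patlak_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, t_star = x$t_star, nobs = nrow(x$data))
}
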