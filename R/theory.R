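#' Standardized prediction under simple linear regression
#'
#' For a least-squares fit of y on x, the standardized predicted value is
#' the correlation times the standardized input:
#' `(yhat - ybar)/s_y = r_xy * (x - xbar)/s_x`. Since `|r_xy| <= 1`, the
#' standardized prediction is never further from its mean than the input is
#' from its own — regression toward the mean. Applied to age prediction,
#' this is why young ages are overestimated and old ages underestimated by
#' any imperfect model.
#'
#' @param r_xy Pearson correlation between x and y, in \[-1, 1\].
#' @param x_std Standardized input value(s).
#' @return `r_xy * x_std`.
#' @export
standardized_prediction <- function(r_xy, x_std) {
  stopifnot(length(r_xy) == 1)
  if (abs(r_xy) > 1) stop("|r_xy| must be <= 1")
  r_xy * x_std
}

#' Correlation between a response and its residuals
#'
#' With the variance partition `var(y) = sigma_X^2 + sigma_eps^2`
#' (explained + error), the correlation between y and the fitted residuals
#' is `sigma_eps / sqrt(sigma_X^2 + sigma_eps^2)`; the correlation between
#' y and the fitted values is `sigma_X / sqrt(sigma_X^2 + sigma_eps^2)`.
#' The two satisfy the Pythagorean identity (their squares sum to 1) and
#' are invariant to rescaling both sds. For BrainAGE (= minus the residual
#' of age prediction) this is the analytic size of the age-BrainAGE
#' correlation: it shrinks only as the fit improves.
#'
#' @param sigma_X Sd of the explained (fitted) component, `>= 0`.
#' @param sigma_eps Sd of the error component, `>= 0`; the two must not
#'   both be zero.
#' @return A correlation in \[0, 1\].
#' @export
corr_y_residual <- function(sigma_X, sigma_eps) {
  check_partition(sigma_X, sigma_eps)
  sigma_eps / sqrt(sigma_X^2 + sigma_eps^2)
}

#' @rdname corr_y_residual
#' @export
corr_y_fit <- function(sigma_X, sigma_eps) {
  check_partition(sigma_X, sigma_eps)
  sigma_X / sqrt(sigma_X^2 + sigma_eps^2)
}

check_partition <- function(sigma_X, sigma_eps) {
  stopifnot(length(sigma_X) == 1, length(sigma_eps) == 1,
            sigma_X >= 0, sigma_eps >= 0)
  if (sigma_X == 0 && sigma_eps == 0)
    stop("sigma_X and sigma_eps must not both be zero")
  invisible(NULL)
}

#' Demonstrate how corr(y, residual) shrinks as the fit improves
#'
#' Simulates `y = f(x) + eps` over a grid of noise sds with a fixed smooth
#' nonlinear `f` (default `sin(x) + x/2` on `x ~ U(0, 10)`), fits OLS of y
#' on the mean curve `f(x)` (one regressor, so the fit quality is governed
#' purely by the noise level), and tabulates the empirical correlation
#' between y and the residuals next to the analytic value
#' `sigma_eps_hat / sqrt(sigma_X_hat^2 + sigma_eps_hat^2)` evaluated at the
#' empirical component sds. As the noise shrinks (fit improves) both
#' columns fall toward 0; as it grows both rise toward 1.
#'
#' @param noise_grid Vector of noise sds.
#' @param n Sample size per grid point (at least 50).
#' @param f The smooth mean function.
#' @return A data.frame: `noise_sd`, `r_squared` (of the OLS fit),
#'   `corr_empirical`, `corr_analytic`.
#' @export
demo_fit_vs_residual_corr <- function(noise_grid = c(0.1, 0.25, 0.5, 1, 2, 4),
                                      n = 500,
                                      f = function(x) sin(x) + x / 2) {
  stopifnot(length(noise_grid) >= 1, n >= 50)
  rows <- lapply(noise_grid, function(s) {
    x <- stats::runif(n, 0, 10)
    fx <- f(x)
    y <- fx + stats::rnorm(n, 0, s)
    fit <- stats::lm(y ~ fx)
    res <- stats::residuals(fit)
    data.frame(
      noise_sd = s,
      r_squared = summary(fit)$r.squared,
      corr_empirical = stats::cor(y, res),
      corr_analytic = corr_y_residual(stats::sd(stats::fitted(fit)),
                                      stats::sd(res))
    )
  })
  do.call(rbind, rows)
}
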