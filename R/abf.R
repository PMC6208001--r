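#' Construct a set of age basis functions
#'
#' An age basis function (ABF) is a monotone non-increasing map from
#' chronological age to a bounded value, normalized to approximately
#' \[0, 1\] on the age range. Three qualitatively distinct shapes are used:
#'
#' * `f1` — linear decline: `(age_hi - A) / (age_hi - age_lo)`;
#' * `f2` — exponential early decline: `exp(-(A - age_lo) / exp_tau)`;
#' * `f3` — sigmoidal late decline: `1 / (1 + exp((A - sigmoid_center) /
#'   sigmoid_scale))`.
#'
#' Weighted sums of these three functions generate both the simulated
#' covariates and the simulated voxelwise imaging features, so a wide range
#' of nonlinear aging trajectories can be expressed with three weights.
#'
#' @param age_lo,age_hi Age range (years) on which the functions are defined.
#' @param exp_tau Decay time constant (years) of the exponential ABF.
#' @param sigmoid_center Inflection age (years) of the sigmoidal ABF.
#' @param sigmoid_scale Steepness scale (years) of the sigmoidal ABF; smaller
#'   values give a sharper late-life drop.
#' @return An object of class `abf_set`: a list with the three functions and
#'   their shape parameters.
#' @examples
#' abfs <- abf_set()
#' eval_abf(abfs, 1, 20) # top of the normalized range
#' eval_abf(abfs, 3, c(30, 60)) # monotone decreasing
#' @export
abf_set <- function(age_lo = 20, age_hi = 80, exp_tau = 20,
                    sigmoid_center = 50, sigmoid_scale = 5) {
  stopifnot(is.numeric(age_lo), is.numeric(age_hi), length(age_lo) == 1,
            length(age_hi) == 1, age_lo < age_hi,
            exp_tau > 0, sigmoid_scale > 0)
  force(age_lo); force(age_hi)
  f1 <- function(a) (age_hi - a) / (age_hi - age_lo)
  f2 <- function(a) exp(-(a - age_lo) / exp_tau)
  f3 <- function(a) 1 / (1 + exp((a - sigmoid_center) / sigmoid_scale))
  structure(
    list(
      functions = list(f1, f2, f3),
      age_lo = age_lo, age_hi = age_hi,
      shape_params = list(exp_tau = exp_tau, sigmoid_center = sigmoid_center,
                          sigmoid_scale = sigmoid_scale)
    ),
    class = "abf_set"
  )
}

#' @export
print.abf_set <- function(x, ...) {
  cat("Age basis function set (3 monotone-decreasing functions)\n")
  cat(sprintf("  age range: [%g, %g] years\n", x$age_lo, x$age_hi))
  cat(sprintf("  f1 linear; f2 exp decay (tau = %g y); f3 sigmoid (center = %g y, scale = %g y)\n",
              x$shape_params$exp_tau, x$shape_params$sigmoid_center,
              x$shape_params$sigmoid_scale))
  invisible(x)
}

#' Evaluate one age basis function
#'
#' @param abfs An [abf_set()].
#' @param m Index of the basis function, 1, 2 or 3.
#' @param age Age(s) in years, within the set's age range.
#' @return `f_m(age)`, vectorized over `age`.
#' @export
eval_abf <- function(abfs, m, age) {
  stopifnot(inherits(abfs, "abf_set"))
  if (length(m) != 1 || !m %in% 1:3)
    stop("'m' must be 1, 2 or 3")
  if (any(age < abfs$age_lo | age > abfs$age_hi))
    stop(sprintf("age out of range [%g, %g]", abfs$age_lo, abfs$age_hi))
  abfs$functions[[m]](age)
}

#' Evaluate all three age basis functions at once
#'
#' @inheritParams eval_abf
#' @return A `length(age)` x 3 matrix with column `m` holding `f_m(age)`.
#' @export
abf_matrix <- function(abfs, age) {
  stopifnot(inherits(abfs, "abf_set"))
  if (any(age < abfs$age_lo | age > abfs$age_hi))
    stop(sprintf("age out of range [%g, %g]", abfs$age_lo, abfs$age_hi))
  vapply(abfs$functions, function(f) f(age), numeric(length(age)))
}

#' Linear combination of age basis functions with Gaussian noise
#'
#' Computes `sum_m weights[m] * f_m(age) + eps`, with
#' `eps ~ N(0, noise_sd^2)` drawn independently per age value. With
#' `noise_sd = 0` the result is deterministic; with `noise_sd > 0` the draw
#' uses R's global random number generator (seed with [set.seed()]).
#'
#' @inheritParams eval_abf
#' @param weights Numeric vector of 3 coefficients, one per ABF.
#' @param noise_sd Standard deviation of the additive Gaussian term; `>= 0`.
#' @return Numeric vector, one value per element of `age`.
#' @export
combine_abf <- function(abfs, weights, age, noise_sd = 0) {
  stopifnot(length(weights) == 3, is.numeric(weights),
            length(noise_sd) == 1, noise_sd >= 0)
  y <- drop(abf_matrix(abfs, age) %*% weights)
  if (noise_sd > 0) y <- y + stats::rnorm(length(age), 0, noise_sd)
  y
}
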