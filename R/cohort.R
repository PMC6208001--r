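#' Draw chronological ages
#'
#' @param n Number of participants (at least 2; downstream regressions are
#'   undefined for fewer).
#' @param lo,hi Age range in years, `lo < hi`.
#' @return Numeric vector of `n` i.i.d. draws from `U(lo, hi)`.
#' @export
draw_ages <- function(n, lo = 20, hi = 80) {
  stopifnot(n >= 2, lo < hi)
  if ((hi - lo) < 1e-6)
    warning("age range is nearly degenerate; ages will be near-constant")
  stats::runif(n, lo, hi)
}

#' Build the 16-covariate design
#'
#' Covariates are indexed so that all 8 subsets of the three age basis
#' functions appear once among the contributing covariates (j = 1..8) and
#' are repeated, with freshly drawn coefficients, among the non-contributing
#' covariates (j = 9..16): S1 = {} (pure noise), S2 = {f1}, S3 = {f2},
#' S4 = {f3}, S5 = {f1,f2}, S6 = {f1,f3}, S7 = {f2,f3}, S8 = {f1,f2,f3},
#' and S_(j+8) = S_j. Nonzero coefficients alpha_mj are drawn from
#' U(-2, -1); since the ABFs decrease with age and the coefficients are
#' negative, every age-dependent covariate trends upward with age.
#'
#' The per-covariate noise sd is `noise_ratio` times the sd of the
#' covariate's age-driven signal under a uniform age distribution (computed
#' by quadrature), which puts the covariate-age correlations of the
#' age-dependent covariates around |r| 0.25--0.3. Empty-subset covariates
#' get unit noise sd.
#'
#' @param abfs An [abf_set()].
#' @param n_covariates Total covariates; must be twice the number of ABF
#'   subsets (16 for 3 ABFs).
#' @param q Number of contributing covariates (8).
#' @param noise_ratio Noise-to-signal sd ratio.
#' @return An object of class `covariate_design` with elements
#'   `alpha` (3 x n_covariates matrix), `membership` (list of ABF index
#'   subsets), `noise_sd`, `contributes` (logical), `q`.
#' @export
build_design <- function(abfs, n_covariates = 16, q = 8, noise_ratio = 3.2) {
  subsets <- list(integer(0), 1L, 2L, 3L, c(1L, 2L), c(1L, 3L),
                  c(2L, 3L), c(1L, 2L, 3L))
  stopifnot(n_covariates == 2 * length(subsets), q == length(subsets),
            noise_ratio >= 0)
  membership <- c(subsets, subsets)
  alpha <- matrix(0, nrow = 3, ncol = n_covariates)
  for (j in seq_len(n_covariates)) {
    s <- membership[[j]]
    if (length(s)) alpha[s, j] <- stats::runif(length(s), -2, -1)
  }
  noise_sd <- vapply(seq_len(n_covariates), function(j) {
    s <- signal_sd(abfs, alpha[, j])
    if (s == 0) 1 else noise_ratio * s
  }, numeric(1))
  structure(
    list(alpha = alpha, membership = membership, noise_sd = noise_sd,
         contributes = seq_len(n_covariates) <= q, q = q,
         n_covariates = n_covariates),
    class = "covariate_design"
  )
}

# sd of sum_m alpha_m f_m(A) for A ~ U(age_lo, age_hi), by quadrature
signal_sd <- function(abfs, alpha) {
  if (all(alpha == 0)) return(0)
  g <- function(a) drop(abf_matrix(abfs, a) %*% alpha)
  w <- 1 / (abfs$age_hi - abfs$age_lo)
  m1 <- stats::integrate(function(a) g(a) * w, abfs$age_lo, abfs$age_hi)$value
  m2 <- stats::integrate(function(a) g(a)^2 * w, abfs$age_lo, abfs$age_hi)$value
  sqrt(max(m2 - m1^2, 0))
}

#' Simulate the covariate matrix
#'
#' Each covariate is `Z_ij = sum_m alpha_mj f_m(A_i) + eps_ij` with
#' `eps_ij ~ N(0, noise_sd[j]^2)`.
#'
#' @param ages Vector of chronological ages.
#' @param design A [build_design()] object.
#' @param abfs An [abf_set()].
#' @return An `n x n_covariates` matrix with columns `Z1..Z16`.
#' @export
simulate_covariates <- function(ages, design, abfs) {
  stopifnot(inherits(design, "covariate_design"))
  F <- abf_matrix(abfs, ages)
  Z <- F %*% design$alpha
  n <- length(ages)
  for (j in seq_len(design$n_covariates)) {
    if (design$noise_sd[j] > 0)
      Z[, j] <- Z[, j] + stats::rnorm(n, 0, design$noise_sd[j])
  }
  colnames(Z) <- paste0("Z", seq_len(design$n_covariates))
  Z
}

#' Per-participant weight departures
#'
#' `D_i = gamma * sum_{j <= q} Z_ij`: only the contributing covariates enter,
#' including their realized noise.
#'
#' @param Z Covariate matrix.
#' @param design A [build_design()] object (supplies `contributes`).
#' @param gamma Departure scale.
#' @return Numeric vector `D`, one value per participant.
#' @export
compute_departures <- function(Z, design, gamma) {
  stopifnot(inherits(design, "covariate_design"),
            ncol(Z) == design$n_covariates)
  if (!any(design$contributes)) return(rep(0, nrow(Z)))
  gamma * rowSums(Z[, design$contributes, drop = FALSE])
}

#' Voxel model parameters
#'
#' @param n_voxels Number of age-related voxel features K.
#' @param sigma_w Sd of the base ABF weights `w_mk ~ N(0, sigma_w^2)`.
#' @param sigma_v Sd of voxel noise (and of the background features).
#' @param background_fraction Age-unrelated features as a proportion of K.
#' @return An object of class `voxel_model`.
#' @export
voxel_model <- function(n_voxels = 100, sigma_w = 1, sigma_v = 1.7,
                        background_fraction = 0.25) {
  stopifnot(n_voxels >= 1, sigma_w > 0, sigma_v > 0, background_fraction >= 0)
  structure(list(n_voxels = n_voxels, sigma_w = sigma_w, sigma_v = sigma_v,
                 background_fraction = background_fraction),
            class = "voxel_model")
}

#' Draw the base ABF weights of a voxel model
#'
#' @param model A [voxel_model()].
#' @return A `3 x n_voxels` matrix of `N(0, sigma_w^2)` draws.
#' @export
draw_base_weights <- function(model) {
  stopifnot(inherits(model, "voxel_model"))
  matrix(stats::rnorm(3 * model$n_voxels, 0, model$sigma_w),
         nrow = 3, ncol = model$n_voxels)
}

#' Simulate the voxelwise feature matrix
#'
#' Age-related voxel k of participant i is
#' `v_ik = sum_m (w_mk + D_i) f_m(A_i) + eps_ik`, with independent
#' `eps_ik ~ N(0, sigma_v^2)`; the departure `D_i` shifts all three weights
#' of every voxel equally, which is the channel through which contributing
#' covariates reach the imaging features. `round(background_fraction * K)`
#' pure-noise background columns are appended.
#'
#' @param ages Chronological ages.
#' @param model A [voxel_model()].
#' @param D Departure vector aligned with `ages` (use 0 for none).
#' @param abfs An [abf_set()].
#' @param base_weights Optional `3 x n_voxels` matrix; drawn with
#'   [draw_base_weights()] when `NULL`.
#' @return An `n x (K + n_background)` matrix, age-related columns
#'   `V1..VK` first, then `bg1..`; the weights used are attached as
#'   attribute `"base_weights"`.
#' @export
simulate_voxels <- function(ages, model, D, abfs, base_weights = NULL) {
  stopifnot(inherits(model, "voxel_model"))
  n <- length(ages)
  if (length(D) == 1) D <- rep(D, n)
  stopifnot(length(D) == n)
  if (is.null(base_weights)) base_weights <- draw_base_weights(model)
  stopifnot(nrow(base_weights) == 3, ncol(base_weights) == model$n_voxels)
  F <- abf_matrix(abfs, ages)                       # n x 3
  V <- F %*% base_weights + D * rowSums(F)          # departure shared over m, k
  V <- V + matrix(stats::rnorm(n * model$n_voxels, 0, model$sigma_v),
                  nrow = n)
  n_bg <- round(model$background_fraction * model$n_voxels)
  if (n_bg > 0) {
    B <- matrix(stats::rnorm(n * n_bg, 0, model$sigma_v), nrow = n)
    V <- cbind(V, B)
  }
  colnames(V) <- c(paste0("V", seq_len(model$n_voxels)),
                   if (n_bg > 0) paste0("bg", seq_len(n_bg)))
  attr(V, "base_weights") <- base_weights
  V
}

#' Summary fold change of the perturbed voxel weights
#'
#' The effect size of the covariate-to-brain pathway: the perturbed weights
#' are `w_mk + D_i`, and the cohort-level fold change is defined as
#' `1 + mean(D) / (sigma_w * sqrt(2/pi))` — the mean departure relative to
#' the mean magnitude `E|w_mk|` of the base weights.
#'
#' @param model A [voxel_model()] (supplies `sigma_w`).
#' @param D Departure vector.
#' @return The fold change (1 means no effect).
#' @export
fold_change <- function(model, D) {
  stopifnot(inherits(model, "voxel_model"))
  if (model$sigma_w <= 0) stop("sigma_w must be positive for a fold change")
  1 + mean(D) / (model$sigma_w * sqrt(2 / pi))
}

#' Calibrate the departure scale to a target fold change
#'
#' Inverts the linear relation FC(gamma) of [fold_change()] and
#' [compute_departures()]:
#' `gamma = (target_fc - 1) * sigma_w * sqrt(2/pi) / mean(rowSums(Z_contrib))`.
#'
#' @param target_fc Desired fold change.
#' @param Z Covariate matrix.
#' @param design A [build_design()] object.
#' @param model A [voxel_model()].
#' @return The calibrated `gamma`.
#' @export
calibrate_gamma <- function(target_fc, Z, design, model) {
  stopifnot(inherits(design, "covariate_design"), inherits(model, "voxel_model"))
  if (target_fc == 1) return(0)
  zbar <- mean(rowSums(Z[, design$contributes, drop = FALSE]))
  if (abs(zbar) < 1e-12)
    stop("mean contributing-covariate sum is ~0; fold change cannot be calibrated")
  (target_fc - 1) * model$sigma_w * sqrt(2 / pi) / zbar
}

#' Generate a full synthetic cohort
#'
#' Runs the whole generative chain: ages ~ U(lo, hi); 16 covariates from the
#' ABF design; departure scale calibrated to the configured fold change;
#' voxel features with covariate-driven weight departures plus background
#' noise features. All ground truth (design, weights, departures, gamma) is
#' kept for downstream true/false-positive scoring.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed set before generation (for
#'   reproducibility); `NULL` leaves the RNG state alone.
#' @return An object of class `brainage_cohort`: list with `ages`, `Z`, `V`,
#'   `D`, `gamma`, `fold_change`, `design`, `voxel_model`, `abfs`, `config`,
#'   `seed`.
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  abfs <- with(config$abf,
               abf_set(config$cohort$age_lo, config$cohort$age_hi,
                       exp_tau, sigmoid_center, sigmoid_scale))
  ages <- draw_ages(config$cohort$n, config$cohort$age_lo, config$cohort$age_hi)
  design <- build_design(abfs, config$design$n_covariates, config$design$q,
                         config$design$noise_ratio)
  Z <- simulate_covariates(ages, design, abfs)
  vm <- with(config$voxels,
             voxel_model(n_voxels, sigma_w, sigma_v, background_fraction))
  gamma <- if (!is.null(config$effect$gamma)) config$effect$gamma
           else calibrate_gamma(config$effect$target_fc, Z, design, vm)
  D <- compute_departures(Z, design, gamma)
  V <- simulate_voxels(ages, vm, D, abfs)
  structure(
    list(ages = ages, Z = Z, V = V, D = D, gamma = gamma,
         fold_change = fold_change(vm, D), design = design, voxel_model = vm,
         abfs = abfs, config = config, seed = seed),
    class = "brainage_cohort"
  )
}

#' @export
print.brainage_cohort <- function(x, ...) {
  cat("Simulated BrainAGE cohort\n")
  cat(sprintf("  participants: %d, ages %.1f-%.1f years\n",
              length(x$ages), min(x$ages), max(x$ages)))
  cat(sprintf("  covariates: %d (%d contributing)\n",
              ncol(x$Z), sum(x$design$contributes)))
  cat(sprintf("  features: %d (%d age-related + %d background)\n",
              ncol(x$V), x$voxel_model$n_voxels,
              ncol(x$V) - x$voxel_model$n_voxels))
  cat(sprintf("  gamma = %.4g, fold change = %.4g\n", x$gamma, x$fold_change))
  invisible(x)
}

#' Export / import a cohort as delimited text
#'
#' Writes three comma-separated files into `dir`: `participants.csv`
#' (participant id, age, departure, covariates), `features.csv` (the voxel
#' matrix) and `truth.yaml` (design coefficients, memberships, noise scales,
#' gamma, fold change, seed and the full configuration). Each CSV starts
#' with a `#`-comment header line recording the seed.
#'
#' @param cohort A `brainage_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "brainage_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# brainagesim cohort; seed = %s",
                 if (is.null(cohort$seed)) "NA" else cohort$seed)
  part <- data.frame(participant_id = seq_along(cohort$ages),
                     age = cohort$ages, departure = cohort$D,
                     as.data.frame(cohort$Z))
  write_csv_commented(part, file.path(dir, "participants.csv"), hdr)
  write_csv_commented(as.data.frame(cohort$V), file.path(dir, "features.csv"),
                      hdr)
  truth <- list(
    gamma = cohort$gamma, fold_change = cohort$fold_change,
    seed = cohort$seed,
    alpha = apply(cohort$design$alpha, 2, as.numeric, simplify = FALSE),
    membership = lapply(cohort$design$membership, as.integer),
    noise_sd = as.numeric(cohort$design$noise_sd),
    contributes = as.logical(cohort$design$contributes),
    config = unclass(cohort$config)
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"), precision = 12)
  invisible(dir)
}

write_csv_commented <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
}
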