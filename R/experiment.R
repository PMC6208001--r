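#' Run one simulation replicate end to end
#'
#' Generate a cohort, split it, fit the age model, predict BrainAGE and
#' BrainAGER on the validation half, and run the with- and without-age
#' covariate regressions there.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the replicate.
#' @return A list: `association` (an [association_table()] data.frame),
#'   `prediction` (`age_prediction`), `cohort`, `split`.
#' @export
run_replicate <- function(config = sim_config(), seed = NULL) {
  cohort <- generate_cohort(config, seed = seed)
  pipe <- run_age_pipeline(cohort)
  test <- pipe$split$test
  assoc <- association_table(pipe$prediction$brainage,
                             cohort$Z[test, , drop = FALSE],
                             cohort$ages[test],
                             truth = cohort$design$contributes)
  list(association = assoc, prediction = pipe$prediction, cohort = cohort,
       split = pipe$split)
}

#' Run a replicated multi-scenario experiment
#'
#' For each fold-change scenario and each replicate: generate a cohort
#' (replicate r uses seed `base_seed + r`), 50/50 split, SVR fit, BrainAGE /
#' BrainAGER on the validation half, and the with- / without-age covariate
#' regressions. Per-scenario outputs are written under
#' `output_dir/fc_<value>/`: the long-format association results
#' (`associations.csv`: replicate, covariate, model, estimate, p-value,
#' -log(p), truth label), per-covariate positive rates (`rates.csv`),
#' -log(p) quartiles (`neg_log_p_quartiles.csv`) and per-replicate
#' prediction accuracy (`prediction_summary.csv`). A `manifest.yaml` at the
#' top level records the configuration, seeds and package version.
#'
#' @param config A [sim_config()]; its `experiment` section supplies the
#'   defaults for the remaining arguments.
#' @param output_dir Output directory (created; must be writable).
#' @param n_replicates,base_seed,alpha,scenarios Overrides of the
#'   corresponding `config$experiment` values.
#' @param verbose Print a one-line log per replicate?
#' @return Invisibly, a list per scenario with the `rate_summary`, the
#'   prediction summary data.frame and the association tables.
#' @export
run_experiment <- function(config = sim_config(), output_dir,
                           n_replicates = NULL, base_seed = NULL,
                           alpha = NULL, scenarios = NULL, verbose = FALSE) {
  validate_config(config)
  exp_cfg <- config$experiment
  if (is.null(n_replicates)) n_replicates <- exp_cfg$n_replicates
  if (is.null(base_seed)) base_seed <- exp_cfg$base_seed
  if (is.null(alpha)) alpha <- exp_cfg$alpha
  if (is.null(scenarios)) scenarios <- exp_cfg$scenarios
  stopifnot(n_replicates >= 1, alpha > 0, alpha < 1, length(scenarios) >= 1)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(output_dir, mode = 2) != 0)
    stop("output directory is not writable: ", output_dir)

  results <- list()
  for (fc in scenarios) {
    cfg <- config
    cfg$effect$target_fc <- fc
    cfg$effect$gamma <- if (fc == 1) 0 else NULL
    sdir <- file.path(output_dir, sprintf("fc_%g", fc))
    dir.create(sdir, showWarnings = FALSE)
    tables <- vector("list", n_replicates)
    pred_rows <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      rep_seed <- base_seed + r
      out <- run_replicate(cfg, seed = rep_seed)
      tables[[r]] <- out$association
      p <- out$prediction
      pred_rows[[r]] <- data.frame(
        replicate = r, seed = rep_seed, mae = p$mae,
        r_squared = p$r_squared, age_brainage_corr = p$age_brainage_corr,
        pred_age_slope = p$pred_age_slope)
      if (verbose)
        message(sprintf(
          "fc=%g rep=%d seed=%d MAE=%.2f R2=%.3f corr(age,BrainAGE)=%.3f",
          fc, r, rep_seed, p$mae, p$r_squared, p$age_brainage_corr))
    }
    smry <- if (n_replicates >= 2) summarize_replicates(tables, alpha) else NULL
    preds <- do.call(rbind, pred_rows)
    long <- do.call(rbind, Map(function(tb, r) cbind(replicate = r, tb),
                               tables, seq_len(n_replicates)))
    utils::write.csv(long, file.path(sdir, "associations.csv"),
                     row.names = FALSE)
    utils::write.csv(preds, file.path(sdir, "prediction_summary.csv"),
                     row.names = FALSE)
    if (!is.null(smry)) {
      utils::write.csv(smry$rates, file.path(sdir, "rates.csv"),
                       row.names = FALSE)
      qt <- smry$neg_log_p_quartiles
      qt <- cbind(qt[c("covariate", "model", "truth_label")],
                  as.data.frame(qt$neg_log_p))
      names(qt)[4:6] <- c("q25", "median", "q75")
      utils::write.csv(qt, file.path(sdir, "neg_log_p_quartiles.csv"),
                       row.names = FALSE)
    }
    results[[sprintf("fc_%g", fc)]] <-
      list(rate_summary = smry, prediction_summary = preds, tables = tables)
  }
  yaml::write_yaml(list(
    config = unclass(config),
    n_replicates = n_replicates, base_seed = base_seed, alpha = alpha,
    scenarios = scenarios,
    package_version = as.character(utils::packageVersion("brainagesim"))
  ), file.path(output_dir, "manifest.yaml"))
  invisible(results)
}

#' Screen a user-supplied table of covariates
#'
#' Reads a delimited table with columns `age` and `predicted_age` (every
#' other numeric column is treated as a covariate), computes BrainAGE
#' (predicted minus chronological age) and BrainAGER, and runs
#' [screen_covariates()].
#'
#' @param input A data.frame, or the path of a comma-delimited file with a
#'   header row.
#' @param output Optional path to write the screen table as CSV.
#' @return The screen table data.frame (invisibly when `output` is given).
#' @export
run_screen <- function(input, output = NULL) {
  tab <- if (is.character(input))
    utils::read.csv(input, comment.char = "#") else as.data.frame(input)
  required <- c("age", "predicted_age")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  drop <- c(required, "participant_id", "brainage", "brainager")
  covar_names <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], drop)
  if (!length(covar_names)) stop("no covariate columns found")
  brainage <- tab$predicted_age - tab$age
  brainager <- residualize(brainage, tab$age)
  screen <- screen_covariates(tab$age, brainage, brainager,
                              as.matrix(tab[covar_names]))
  if (!is.null(output)) {
    utils::write.csv(screen, output, row.names = FALSE)
    return(invisible(screen))
  }
  screen
}
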