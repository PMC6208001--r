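#' Joint regression of BrainAGE on all covariates
#'
#' One multiple linear regression of BrainAGE on every covariate column,
#' optionally adding chronological age as an extra explanatory variable.
#' Per-covariate two-sided t-test p-values come from the usual OLS theory.
#'
#' @param brainage Response vector.
#' @param Z Covariate matrix (one column per covariate).
#' @param ages Chronological ages (needed only when `include_age = TRUE`).
#' @param include_age Add age to the model?
#' @return A data.frame with one row per covariate: `covariate`, `estimate`,
#'   `std_error`, `p_value`, `neg_log_p` (natural log), `model`
#'   (`"without_age"` / `"with_age"`). Age's own row is not included.
#' @export
regress_joint <- function(brainage, Z, ages = NULL, include_age = FALSE) {
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  stopifnot(nrow(Z) == length(brainage),
            length(brainage) > ncol(Z) + 2)
  df <- data.frame(brainage = brainage, Z, check.names = FALSE)
  if (include_age) {
    stopifnot(length(ages) == length(brainage))
    df$age <- ages
  }
  fit <- stats::lm(brainage ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  keep <- colnames(Z)
  data.frame(
    covariate = keep,
    estimate = sm[keep, "Estimate"],
    std_error = sm[keep, "Std. Error"],
    p_value = sm[keep, "Pr(>|t|)"],
    neg_log_p = -log(sm[keep, "Pr(>|t|)"]),
    model = if (include_age) "with_age" else "without_age",
    row.names = NULL
  )
}

#' Association table for one replicate
#'
#' Runs [regress_joint()] with and without age and labels each covariate by
#' its ground-truth status (contributing to the imaging features or not).
#'
#' @inheritParams regress_joint
#' @param truth Logical vector, `TRUE` for contributing covariates (e.g.
#'   `cohort$design$contributes`); `NULL` leaves the label `NA`.
#' @return A data.frame with both models stacked and a `truth_label` column
#'   (`"contributing"` / `"non_contributing"`).
#' @export
association_table <- function(brainage, Z, ages, truth = NULL) {
  out <- rbind(regress_joint(brainage, Z, ages, include_age = FALSE),
               regress_joint(brainage, Z, ages, include_age = TRUE))
  if (is.null(truth)) {
    out$truth_label <- NA_character_
  } else {
    stopifnot(length(truth) == ncol(Z))
    lab <- ifelse(truth, "contributing", "non_contributing")
    names(lab) <- colnames(Z)
    out$truth_label <- lab[out$covariate]
  }
  rownames(out) <- NULL
  out
}

#' Check coefficient equivalence of the two age-adjustment routes
#'
#' Regressing BrainAGE on (covariates, age) and regressing BrainAGER on
#' (covariates, age) must give identical covariate coefficients: BrainAGER
#' differs from BrainAGE by a linear function of age, which the age column
#' absorbs (Frisch–Waugh–Lovell logic).
#'
#' @inheritParams regress_joint
#' @param brainager The residualized gap scores.
#' @param tol Maximum allowed absolute coefficient deviation.
#' @return A list: `pass` (logical), `max_deviation`.
#' @export
fwl_equivalence_check <- function(brainage, brainager, Z, ages, tol = 1e-8) {
  a <- regress_joint(brainage, Z, ages, include_age = TRUE)
  b <- regress_joint(brainager, Z, ages, include_age = TRUE)
  dev <- max(abs(a$estimate - b$estimate))
  list(pass = dev < tol, max_deviation = dev)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()] (method `"BH"`):
#' monotone in the p-value ranks and capped at 1.
#'
#' @param pvalues Numeric vector with all values in (0, 1].
#' @return The adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Covariate screen against BrainAGE and BrainAGER
#'
#' For each covariate: Pearson correlation with BrainAGE and with BrainAGER,
#' two-sided p-values from the t-distribution of r on n-2 degrees of freedom,
#' FDR-adjusted within each outcome (the family is all covariates), plus the
#' covariate-age correlation. Missing values are handled pairwise-complete;
#' constant covariates yield `NA` with a warning.
#'
#' @param ages,brainage,brainager Aligned numeric vectors.
#' @param Z Covariate matrix (one column per covariate, named).
#' @return A data.frame, one row per covariate, columns `covariate`,
#'   `r_brainage`, `p_brainage`, `r_brainager`, `p_brainager`, `r_age`
#'   (adjusted p-values in the `p_*` columns, mirroring a published screen
#'   table layout).
#' @export
screen_covariates <- function(ages, brainage, brainager, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 1) stop("no covariates to screen")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  stopifnot(nrow(Z) == length(ages), length(brainage) == length(ages),
            length(brainager) == length(ages))
  degenerate <- apply(Z, 2, function(z) {
    ok <- !is.na(z)
    sum(ok) < 3 || stats::sd(z[ok]) == 0
  })
  if (any(degenerate))
    warning("constant or near-empty covariate(s) reported as NA: ",
            paste(colnames(Z)[degenerate], collapse = ", "))
  cor_with <- function(y) {
    apply(Z, 2, function(z) {
      ok <- stats::complete.cases(z, y)
      if (sum(ok) < 3 || stats::sd(z[ok]) == 0) {
        return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
      }
      r <- stats::cor(z[ok], y[ok])
      n <- sum(ok)
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      c(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
    })
  }
  ba <- cor_with(brainage); bar <- cor_with(brainager); ag <- cor_with(ages)
  adj <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    # p-values of 0 can arise from perfect correlation; clamp for fdr_adjust
    out[ok] <- fdr_adjust(pmax(p[ok], .Machine$double.xmin))
    out
  }
  data.frame(
    covariate = colnames(Z),
    r_brainage = ba["r", ], p_brainage = adj(ba["p", ]),
    r_brainager = bar["r", ], p_brainager = adj(bar["p", ]),
    r_age = ag["r", ],
    row.names = NULL
  )
}

#' Positive-rate summary across replicates
#'
#' Aggregates per-replicate association tables into per-covariate rejection
#' rates at a significance level, split by model (with / without age), and
#' into overall true-positive and false-positive rates by ground-truth
#' label. Also returns quartile summaries of the -log(p) distributions for
#' boxplot-style reporting.
#'
#' @param tables List of [association_table()] data.frames, one per
#'   replicate.
#' @param alpha Significance level.
#' @return A list of class `rate_summary`: `rates` (covariate x model
#'   rejection rates with truth labels), `aggregate` (tp_rate / fp_rate per
#'   model), `neg_log_p_quartiles`, `alpha`, `n_replicates`.
#' @export
summarize_replicates <- function(tables, alpha = 0.05) {
  stopifnot(length(tables) >= 2, alpha > 0, alpha < 1)
  long <- do.call(rbind, Map(function(tb, r) {
    tb$replicate <- r
    tb
  }, tables, seq_along(tables)))
  rates <- stats::aggregate(p_value ~ covariate + model + truth_label, long,
                            function(p) mean(p < alpha), na.action = NULL)
  names(rates)[names(rates) == "p_value"] <- "positive_rate"
  agg_for <- function(lab) {
    sub <- rates[!is.na(rates$truth_label) & rates$truth_label == lab, ]
    stats::setNames(
      vapply(split(sub$positive_rate, sub$model), mean, numeric(1)),
      names(split(sub$positive_rate, sub$model)))
  }
  aggregate <- list(tp_rate = agg_for("contributing"),
                    fp_rate = agg_for("non_contributing"))
  qt <- stats::aggregate(neg_log_p ~ covariate + model + truth_label, long,
                         function(x) stats::quantile(x, c(0.25, 0.5, 0.75)),
                         na.action = NULL)
  structure(list(rates = rates, aggregate = aggregate,
                 neg_log_p_quartiles = qt, alpha = alpha,
                 n_replicates = length(tables), long = long),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("Positive rates over %d replicates at alpha = %g\n",
              x$n_replicates, x$alpha))
  for (lab in names(x$aggregate)) {
    v <- x$aggregate[[lab]]
    if (length(v))
      cat(sprintf("  %s: %s\n", lab,
                  paste(sprintf("%s = %.3f", names(v), v), collapse = ", ")))
  }
  invisible(x)
}
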