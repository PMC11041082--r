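#' Patient-level platform-trial data
#'
#' Validates a data frame of patient-level records with columns `patient`
#' (1..N in recruitment order), `period` (1, 2 or 3), `arm` (0 = control,
#' 1, 2) and `y` (continuous response).  Periods must form contiguous blocks
#' in patient order and arms must respect the period membership (arm 1 only
#' in periods 1-2, arm 2 only in periods 2-3).
#'
#' @param df data frame with columns `patient`, `period`, `arm`, `y`.
#' @return The validated data frame with class `trial_data`.
#' @export
trial_data <- function(df) {
  need <- c("patient", "period", "arm", "y")
  if (!all(need %in% names(df))) {
    stop_platalloc(paste("trial data needs columns:", paste(need, collapse = ", ")),
                   "platalloc_invalid_data")
  }
  df <- df[order(df$patient), need]
  if (!all(df$patient == seq_len(nrow(df)))) {
    stop_platalloc("`patient` must be 1..N without gaps", "platalloc_invalid_data")
  }
  if (!all(df$period %in% 1:3) || !all(df$arm %in% 0:2)) {
    stop_platalloc("`period` must be in 1..3 and `arm` in 0..2",
                   "platalloc_invalid_data")
  }
  if (is.unsorted(df$period)) {
    stop_platalloc("periods must be contiguous blocks in patient order",
                   "platalloc_invalid_data")
  }
  arm_sets <- list(0:1, 0:2, c(0L, 2L))
  ok <- mapply(function(a, s) a %in% arm_sets[[s]], df$arm, df$period)
  if (!all(ok)) {
    stop_platalloc("arm assignments violate period membership (arm 1 recruits in periods 1-2, arm 2 in periods 2-3)",
                   "platalloc_invalid_data")
  }
  class(df) <- c("trial_data", "data.frame")
  df
}

#' Read patient-level trial data from CSV
#'
#' Expects a header `patient,period,arm,y` with arm 0 denoting the control.
#'
#' @param path CSV file path.
#' @return A [trial_data()] data frame.
#' @export
read_trial_data <- function(path) {
  trial_data(utils::read.csv(path))
}

new_effect_estimate <- function(arm, estimate, std_error, df, analysis_mode,
                                dropped = character(0)) {
  structure(
    list(arm = arm, estimate = estimate, std_error = std_error, df = df,
         statistic = NA_real_, p_one_sided = NA_real_,
         ci_low = NA_real_, ci_high = NA_real_, alpha = NA_real_,
         reject = NA, analysis_mode = analysis_mode, dropped = dropped),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Arm %d vs control (%s analysis)\n", x$arm, x$analysis_mode))
  cat(sprintf("  estimate = %.4f  SE = %.4f  df = %s\n",
              x$estimate, x$std_error,
              if (is.infinite(x$df)) "Inf (known sigma)" else format(x$df)))
  if (!is.na(x$p_one_sided)) {
    cat(sprintf("  one-sided p = %.4g  95%% CI [%.4f, %.4f]%s\n",
                x$p_one_sided, x$ci_low, x$ci_high,
                if (isTRUE(x$reject)) "  (reject)" else ""))
  }
  if (length(x$dropped)) {
    cat("  dropped inestimable terms:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

# design matrix for the period-adjusted regression on a subset of the data;
# aliased / empty columns are dropped (recorded), keeping the target column.
period_model <- function(df, target, periods, ref_period) {
  sub <- df[df$period %in% periods, ]
  X <- cbind(
    intercept = rep(1, nrow(sub)),
    arm1 = as.numeric(sub$arm == 1),
    arm2 = as.numeric(sub$arm == 2)
  )
  for (s in setdiff(periods, ref_period)) {
    X <- cbind(X, as.numeric(sub$period == s))
    colnames(X)[ncol(X)] <- paste0("period", s)
  }
  qrx <- qr(X)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  X <- X[, keep, drop = FALSE]
  if (!target %in% colnames(X)) {
    stop_platalloc(sprintf("effect of %s is not estimable from these data", target),
                   "platalloc_inestimable")
  }
  list(X = X, y = sub$y, target = which(colnames(X) == target),
       dropped = dropped, n = nrow(sub))
}

fit_effect <- function(mod, sigma = NULL) {
  XtX <- crossprod(mod$X)
  XtXinv <- solve(XtX)
  beta <- XtXinv %*% crossprod(mod$X, mod$y)
  resid <- mod$y - mod$X %*% beta
  df <- mod$n - ncol(mod$X)
  if (is.null(sigma)) {
    if (df <= 0) {
      stop_platalloc("no residual degrees of freedom; supply a known sigma",
                     "platalloc_inestimable")
    }
    s2 <- sum(resid^2) / df
  } else {
    s2 <- sigma^2
    df <- Inf
  }
  list(estimate = beta[mod$target],
       std_error = sqrt(s2 * XtXinv[mod$target, mod$target]),
       df = df)
}

#' Period-stratified treatment-effect estimate with concurrent controls
#'
#' Computes the stratified estimator: the inverse-variance-weighted
#' combination of the period-wise mean differences between the arm and its
#' concurrent controls, using the arm's two recruitment periods (periods 1-2
#' for arm 1, periods 2-3 for arm 2).  With a common variance the weights
#' reduce to harmonic cell-size weights
#' `w_s ~ (1/n_{i,s} + 1/n_{0,s})^{-1}`, and the estimator equals the
#' treatment coefficient of the period-adjusted linear regression on the
#' same periods (the regression is also used for the residual-variance
#' estimate).  A period in which either group is empty gets weight zero.
#'
#' @param data a [trial_data()] data frame.
#' @param arm experimental arm, 1 or 2.
#' @param sigma optional known response SD; when supplied the standard error
#'   uses it directly and the reference distribution is normal (`df = Inf`),
#'   otherwise the residual variance of the regression is used with a t
#'   reference.
#' @return An `effect_estimate`; complete it with [test_and_ci()].
#' @export
estimate_stratified_cc <- function(data, arm, sigma = NULL) {
  stopifnot(inherits(data, "trial_data"), arm %in% 1:2)
  periods <- if (arm == 1) 1:2 else 2:3
  # stratified arithmetic: period-wise differences + harmonic weights
  diffs <- info <- numeric(0)
  for (s in periods) {
    ya <- data$y[data$period == s & data$arm == arm]
    yc <- data$y[data$period == s & data$arm == 0]
    if (length(ya) >= 1 && length(yc) >= 1) {
      diffs <- c(diffs, mean(ya) - mean(yc))
      info <- c(info, 1 / (1 / length(ya) + 1 / length(yc)))
    }
  }
  if (!length(diffs)) {
    stop_platalloc(sprintf("arm %d has no period with both groups observed", arm),
                   "platalloc_inestimable")
  }
  est <- sum(diffs * info) / sum(info)
  mod <- period_model(data, paste0("arm", arm), periods, ref_period = periods[1])
  fit <- fit_effect(mod, sigma)
  out <- new_effect_estimate(arm, est, fit$std_error, fit$df,
                             analysis_mode = "cc", dropped = mod$dropped)
  out$weights <- info / sum(info)
  out
}

#' Arm-2 effect estimate pooling non-concurrent controls
#'
#' Fits the period-adjusted regression on all observed data from all
#' periods: response on an intercept, arm-1 and arm-2 indicators, and period
#' indicators (period 1 as reference).  The arm-2 coefficient pools
#' concurrent and non-concurrent controls through the shared period effects.
#' In a two-period trial it equals
#' `theta_hat_{2,2} + rho * (theta_hat_{1,1} - theta_hat_{1,2})` with `rho`
#' from [rho_coefficient()].  Inestimable terms (e.g. the period effect of an
#' empty period) are dropped and recorded in the result.
#'
#' @inheritParams estimate_stratified_cc
#' @return An `effect_estimate` for arm 2 with `analysis_mode = "ncc"`.
#' @export
estimate_ncc <- function(data, sigma = NULL) {
  stopifnot(inherits(data, "trial_data"))
  mod <- period_model(data, "arm2", 1:3, ref_period = 1)
  fit <- fit_effect(mod, sigma)
  out <- new_effect_estimate(2L, fit$estimate, fit$std_error, fit$df,
                             analysis_mode = "ncc", dropped = mod$dropped)
  out
}

#' One-sided test and confidence interval for a treatment effect
#'
#' Completes an `effect_estimate` with the one-sided test of the null
#' hypothesis that the treatment effect is at most zero (upper-tail p-value
#' of the t, or normal when sigma is known, reference at
#' `statistic = estimate / std_error`) and a two-sided confidence interval.
#'
#' @param est an `effect_estimate` from [estimate_stratified_cc()] or
#'   [estimate_ncc()].
#' @param alpha one-sided significance level (default 0.025).
#' @param ci_level two-sided confidence level for the interval (default 0.95).
#' @return The completed `effect_estimate` with `statistic`, `p_one_sided`,
#'   `ci_low`, `ci_high` and `reject` filled in.
#' @examples
#' \dontrun{
#' test_and_ci(estimate_stratified_cc(dat, arm = 1))
#' }
#' @export
test_and_ci <- function(est, alpha = 0.025, ci_level = 0.95) {
  stopifnot(inherits(est, "effect_estimate"))
  if (!is.finite(est$std_error) || est$std_error <= 0) {
    stop_platalloc("standard error must be positive and finite",
                   "platalloc_inestimable")
  }
  stat <- est$estimate / est$std_error
  if (is.infinite(est$df)) {
    p <- stats::pnorm(stat, lower.tail = FALSE)
    crit <- stats::qnorm(1 - (1 - ci_level) / 2)
  } else {
    p <- stats::pt(stat, df = est$df, lower.tail = FALSE)
    crit <- stats::qt(1 - (1 - ci_level) / 2, df = est$df)
  }
  est$statistic <- stat
  est$p_one_sided <- p
  est$alpha <- alpha
  est$reject <- p < alpha
  est$ci_low <- est$estimate - crit * est$std_error
  est$ci_high <- est$estimate + crit * est$std_error
  est
}
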