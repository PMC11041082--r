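#' Variance of a single-period treatment-control comparison
#'
#' For arm `i` active in period `s`, the period-wise effect estimate is the
#' mean difference between arm `i` and control within that period, with
#' variance `sigma_i^2 / n_{i,s} + sigma_0^2 / n_{0,s}` where
#' `n_{i,s} = N * r_s * p[s, i]` are (continuous) expected group sizes.
#'
#' @param design a [platform_design()].
#' @param arm experimental arm, 1 or 2.
#' @param period period index 1, 2 or 3; the arm must be active there
#'   (arm 1 in periods 1-2, arm 2 in periods 2-3).
#' @return The period-wise estimator variance (response units squared).
#' @export
period_effect_variance <- function(design, arm, period) {
  stopifnot(inherits(design, "platform_design"), arm %in% 1:2, period %in% 1:3)
  if (!arm %in% design$arm_sets[[period]]) {
    stop_platalloc(sprintf("arm %d is not active in period %d", arm, period),
                   "platalloc_invalid_design")
  }
  n <- expected_counts(design)
  n_arm <- n[period, arm + 1L]
  n_ctrl <- n[period, 1L]
  if (n_arm <= 0 || n_ctrl <= 0) {
    stop_platalloc(
      sprintf("inestimable period effect: empty group in period %d", period),
      "platalloc_inestimable"
    )
  }
  design$sigma[arm + 1L]^2 / n_arm + design$sigma[1L]^2 / n_ctrl
}

#' Inverse-variance stratification weights for two periods
#'
#' The period-stratified effect estimator combines the two period-wise mean
#' differences with inverse-variance weights, the choice that minimizes the
#' variance of the combination.  An infinite variance (arm absent from a
#' period) receives weight zero.
#'
#' @param var_a,var_b period-wise estimator variances (both positive; at most
#'   one may be infinite).
#' @return Numeric vector `(w_a, w_b)` summing to 1.
#' @examples
#' stratification_weights(0.04, 0.04) # c(0.5, 0.5)
#' @export
stratification_weights <- function(var_a, var_b) {
  stopifnot(var_a > 0, var_b > 0)
  if (is.infinite(var_a) && is.infinite(var_b)) {
    stop_platalloc("arm absent from both periods", "platalloc_inestimable")
  }
  if (is.infinite(var_a)) return(c(0, 1))
  if (is.infinite(var_b)) return(c(1, 0))
  ia <- 1 / var_a
  ib <- 1 / var_b
  c(ia, ib) / (ia + ib)
}

# information (inverse variance, in units N/sigma0^2) of the stratified
# estimator for one arm; shared by the variance report and the optimizers.
# Returns the per-period information terms r_s * g(p_arm, p_ctrl; ratio).
arm_information_terms <- function(r, p, arm, ratio = 1) {
  periods <- if (arm == 1) 1:2 else 2:3
  vapply(periods, function(s) {
    r[s] * g_pool(p[s, arm + 1L], p[s, 1L], ratio)
  }, numeric(1))
}

#' Variances of the stratified estimators using concurrent controls
#'
#' Closed-form variances of the period-stratified treatment-effect estimators
#' when each arm is compared against its concurrent controls only.  With a
#' common response variance the variance of arm i's estimator is
#' `sigma^2 / N * (r_i g(p_{i,i}, p_{0,i}) + r_{i+1} g(p_{i,i+1}, p_{0,i+1}))^{-1}`
#' with `g(a, b) = ab / (a + b)`; with unequal per-arm variances the pooling
#' term generalizes to `g(a, b) = ab / (a + (sigma_i^2/sigma_0^2) b)` and the
#' scale factor is `sigma_0^2 / N`.  An arm with no allocation in either of
#' its periods gets an infinite variance (flagged, not an error).
#'
#' @param design a [platform_design()].
#' @return An object of class `variance_report`: list with elements
#'   `var_arm1`, `var_arm2` (response units squared), `per_period_var` (2 x 2
#'   matrix, rows arms, columns the arm's two periods), `weights` (same
#'   layout, rows summing to 1), and `analysis_mode = "concurrent-only"`.
#' @export
var_stratified_cc <- function(design) {
  stopifnot(inherits(design, "platform_design"))
  s0 <- design$sigma[1]^2
  ratio <- (design$sigma[2:3] / design$sigma[1])^2
  info1 <- arm_information_terms(design$r, design$p, 1, ratio[1])
  info2 <- arm_information_terms(design$r, design$p, 2, ratio[2])
  v1 <- if (sum(info1) > 0) s0 / design$N / sum(info1) else Inf
  v2 <- if (sum(info2) > 0) s0 / design$N / sum(info2) else Inf

  per_period <- matrix(Inf, 2, 2,
                       dimnames = list(c("arm1", "arm2"),
                                       c("period_i", "period_i+1")))
  weights <- matrix(0, 2, 2, dimnames = dimnames(per_period))
  for (a in 1:2) {
    info <- if (a == 1) info1 else info2
    per_period[a, ] <- ifelse(info > 0, s0 / design$N / info, Inf)
    if (sum(info) > 0) weights[a, ] <- info / sum(info)
  }
  structure(
    list(var_arm1 = v1, var_arm2 = v2, per_period_var = per_period,
         weights = weights, analysis_mode = "concurrent-only"),
    class = "variance_report"
  )
}

#' Variances when non-concurrent controls are used for arm 2
#'
#' Arm 2's effect is estimated from the period-adjusted regression on all
#' three periods, which pools concurrent and non-concurrent controls.  Its
#' variance has the closed form
#' `sigma^2/N * (r3 q23 + r2 q22 - r2^2 p12^2 p22^2 / (r1 q11 + r2 q12))^{-1}`
#' with `q_{i,s} = p_{i,s} (1 - p_{i,s})`; when `r3 = 0` this is exactly the
#' two-period expression built on the correction coefficient
#' [rho_coefficient()].  Arm 1 is still analyzed with concurrent controls
#' only (its efficacy is evaluated when the arm closes), so its variance is
#' the concurrent-only stratified variance.
#'
#' The closed form is derived for a common response variance; unequal
#' per-arm standard deviations are rejected.
#'
#' @param design a [platform_design()] with equal `sigma` across arms and
#'   `r1 > 0`.
#' @return A `variance_report` (see [var_stratified_cc()]) with
#'   `analysis_mode = "non-concurrent"`; `weights`/`per_period_var` refer to
#'   the concurrent-only decomposition of arm 1 and are `NA` for arm 2,
#'   whose estimator pools all periods.
#' @export
var_ncc <- function(design) {
  stopifnot(inherits(design, "platform_design"))
  if (length(unique(design$sigma)) != 1) {
    stop_platalloc(
      "non-concurrent-control variances are derived for a common sigma across arms",
      "platalloc_unsupported"
    )
  }
  if (design$r[1] <= 0) {
    stop_platalloc("non-concurrent controls require r1 > 0",
                   "platalloc_invalid_design")
  }
  r <- design$r
  p <- design$p
  q <- p * (1 - p)
  denom_info <- r[3] * q[3, 3] + r[2] * q[2, 3]
  corr_num <- r[2]^2 * p[2, 2]^2 * p[2, 3]^2
  corr_den <- r[1] * q[1, 2] + r[2] * q[2, 2]
  corr <- if (corr_num > 0) corr_num / corr_den else 0
  info2 <- denom_info - corr
  s2 <- design$sigma[1]^2
  v2 <- if (info2 > 0) s2 / design$N / info2 else Inf

  cc <- var_stratified_cc(design)
  per_period <- cc$per_period_var
  weights <- cc$weights
  per_period[2, ] <- NA_real_
  weights[2, ] <- NA_real_
  structure(
    list(var_arm1 = cc$var_arm1, var_arm2 = v2, per_period_var = per_period,
         weights = weights, analysis_mode = "non-concurrent"),
    class = "variance_report"
  )
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf("Effect-estimator variances (%s analysis)\n", x$analysis_mode))
  cat(sprintf("  Var(arm 1) = %g\n  Var(arm 2) = %g\n", x$var_arm1, x$var_arm2))
  invisible(x)
}

#' Non-concurrent-control correction coefficient
#'
#' In a two-period trial (`r3 = 0`) the arm-2 estimator that pools
#' non-concurrent controls can be written as
#' `theta2_tilde = theta_hat_{2,2} + rho * (theta_hat_{1,1} - theta_hat_{1,2})`,
#' where `rho = n02^{-1} / (n01^{-1} + n02^{-1} + n11^{-1} + n12^{-1})` is
#' driven by the cell sizes of the control and arm-1 groups in the two
#' periods.
#'
#' @param n01,n02 control group sizes in periods 1 and 2.
#' @param n11,n12 arm-1 group sizes in periods 1 and 2.
#' @return The scalar coefficient `rho`.
#' @examples
#' rho_coefficient(10, 10, 10, 10) # 1/4
#' @export
rho_coefficient <- function(n01, n02, n11, n12) {
  counts <- c(n01, n02, n11, n12)
  if (any(counts <= 0)) {
    stop_platalloc("all four cell sizes must be positive", "platalloc_inestimable")
  }
  (1 / n02) / sum(1 / counts)
}
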