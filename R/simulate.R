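#' Time-trend specification
#'
#' Additive drift in the mean response, equal across arms (the setting under
#' which the period-adjusted analysis stays unbiased).  `"linear"` adds
#' `lambda * (j - 1) / (N - 1)` for patient index j (total drift `lambda`
#' over the trial); `"stepwise"` adds `lambda * (s - 1)` in period s
#' (per-period increment `lambda`).
#'
#' @param shape `"none"`, `"linear"` or `"stepwise"`.
#' @param lambda trend magnitude in response units; ignored for `"none"`.
#' @return An object of class `time_trend`.
#' @export
time_trend <- function(shape = c("none", "linear", "stepwise"), lambda = 0) {
  shape <- match.arg(shape)
  stopifnot(is.finite(lambda))
  if (shape == "none") lambda <- 0
  structure(list(shape = shape, lambda = lambda), class = "time_trend")
}

trend_values <- function(trend, period_of, N) {
  switch(trend$shape,
         none = numeric(N),
         linear = trend$lambda * (seq_len(N) - 1) / max(N - 1, 1),
         stepwise = trend$lambda * (period_of - 1))
}

#' Round a design to integer cell counts
#'
#' Converts the continuous expected cell sizes of a design to integers by
#' largest-remainder apportionment, first across periods (so period totals
#' sum to N) and then across arms within each period.  Remainder ties are
#' broken so that the two experimental arms stay interchangeable: across
#' periods the order is period 1, period 3, period 2 (the outer
#' single-comparison periods first, keeping the arm totals equal in
#' symmetric designs), and within a period arm 1, then arm 2, then control.
#'
#' @param design a [platform_design()].
#' @return 3 x 3 integer matrix of cell counts (rows periods, columns
#'   control, arm 1, arm 2).
#' @examples
#' d <- platform_design(92, c(1, 1, 1) / 3,
#'   rbind(c(.5, .5, 0), c(1 / 3, 1 / 3, 1 / 3), c(.5, 0, .5)))
#' rowSums(round_sample_sizes(d)) # 31 30 31
#' @export
round_sample_sizes <- function(design) {
  stopifnot(inherits(design, "platform_design"))
  period_totals <- largest_remainder(design$r, round(design$N),
                                     tie_order = c(1, 3, 2))
  counts <- matrix(0L, 3, 3,
                   dimnames = list(paste0("period", 1:3),
                                   c("control", "arm1", "arm2")))
  for (s in 1:3) {
    if (period_totals[s] == 0) next
    counts[s, ] <- largest_remainder(design$p[s, ], period_totals[s],
                                     tie_order = c(2, 3, 1))
  }
  counts
}

check_counts <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  if (counts[1, 3] != 0 || counts[3, 2] != 0) {
    stop_platalloc("counts assign patients to an inactive arm",
                   "platalloc_invalid_design")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Generate a synthetic platform trial
#'
#' Draws one patient-level trial with fixed cell counts (permuted-block
#' realization: within each period the arm labels are a random permutation
#' of exactly the nominal counts, so realized counts always equal nominal
#' counts).  Responses are
#' `y = mu_arm + trend(patient) + N(0, sigma_arm^2)`.
#'
#' @param design a [platform_design()]; used for its counts (via
#'   [round_sample_sizes()]) and SDs unless overridden.
#' @param counts optional 3 x 3 integer matrix of cell counts (periods x
#'   arms, control first) overriding the rounding rule, e.g. a printed
#'   sample-size table.
#' @param means per-arm means `(mu0, mu1, mu2)`.
#' @param sigma per-arm SDs; defaults to the design's.
#' @param trend a [time_trend()].
#' @param seed optional integer seed for reproducibility.
#' @return A [trial_data()] data frame.
#' @export
generate_trial <- function(design = NULL, counts = NULL,
                           means = c(0, 0, 0), sigma = NULL,
                           trend = time_trend("none"), seed = NULL) {
  if (is.null(counts)) {
    stopifnot(inherits(design, "platform_design"))
    counts <- round_sample_sizes(design)
  }
  counts <- check_counts(counts)
  if (is.null(sigma)) sigma <- if (is.null(design)) c(1, 1, 1) else design$sigma
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  if (!is.null(seed)) set.seed(seed)
  N <- sum(counts)
  arm <- integer(0)
  period <- integer(0)
  for (s in 1:3) {
    ns <- sum(counts[s, ])
    if (ns == 0) next
    labels <- rep(0:2, counts[s, ])
    arm <- c(arm, sample(labels, ns))
    period <- c(period, rep(s, ns))
  }
  tr <- trend_values(trend, period, N)
  y <- means[arm + 1L] + tr + stats::rnorm(N, 0, sigma[arm + 1L])
  trial_data(data.frame(patient = seq_len(N), period = period, arm = arm, y = y))
}

# Precomputed linear-algebra plan for one analysis (arm + mode) under fixed
# cell counts: row subset, coefficient functional, orthonormal basis for the
# fitted subspace, residual df and the unit standard error.
analysis_plan <- function(counts, arm, mode = c("cc", "ncc"), period_of, arm_of) {
  mode <- match.arg(mode)
  periods <- if (mode == "ncc") 1:3 else if (arm == 1) 1:2 else 2:3
  idx <- which(period_of %in% periods)
  sub_arm <- arm_of[idx]
  sub_per <- period_of[idx]
  X <- cbind(intercept = rep(1, length(idx)),
             arm1 = as.numeric(sub_arm == 1),
             arm2 = as.numeric(sub_arm == 2))
  for (s in setdiff(periods, periods[1])) {
    X <- cbind(X, as.numeric(sub_per == s))
    colnames(X)[ncol(X)] <- paste0("period", s)
  }
  qrx <- qr(X)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  X <- X[, keep, drop = FALSE]
  target <- paste0("arm", arm)
  if (!target %in% colnames(X)) {
    stop_platalloc(sprintf("arm %d effect not estimable under these counts", arm),
                   "platalloc_inestimable")
  }
  k <- which(colnames(X) == target)
  XtXinv <- solve(crossprod(X))
  list(idx = idx,
       coef_fun = (XtXinv %*% t(X))[k, ],
       Q = qr.Q(qr(X)),
       df = length(idx) - ncol(X),
       se_unit = sqrt(XtXinv[k, k]))
}

new_oc_result <- function(rates, mcse, widths, est_mean, est_sd,
                          nsim, seed, n_failed, meta) {
  structure(
    list(power_arm1 = rates[1], power_arm2 = rates[2],
         mc_se = mcse, mean_ci_width = widths,
         est_mean = est_mean, est_sd = est_sd,
         nsim = nsim, seed = seed, n_failed = n_failed, scenario = meta),
    class = "oc_result"
  )
}

#' @export
print.oc_result <- function(x, ...) {
  cat("Monte-Carlo operating characteristics\n")
  cat(sprintf("  rejection rate arm 1: %.4f (MC SE %.4f)\n",
              x$power_arm1, x$mc_se[1]))
  cat(sprintf("  rejection rate arm 2: %.4f (MC SE %.4f)\n",
              x$power_arm2, x$mc_se[2]))
  cat(sprintf("  mean 95%% CI width: arm 1 %.4f, arm 2 %.4f\n",
              x$mean_ci_width[1], x$mean_ci_width[2]))
  cat(sprintf("  nsim = %d, seed = %s\n", x$nsim, format(x$seed)))
  invisible(x)
}

#' Monte-Carlo operating characteristics of a platform-trial design
#'
#' Simulates trials with fixed cell counts and computes per-arm one-sided
#' rejection rates (power under alternative means, type-I error under the
#' null), Monte-Carlo standard errors and mean two-sided CI widths.  Arm 1
#' is always analyzed with the period-adjusted model on periods 1-2 with
#' concurrent controls; arm 2 uses concurrent controls (periods 2-3) or the
#' full-data regression pooling non-concurrent controls, per `analysis`.
#'
#' The engine is vectorized: the per-replicate estimators and test
#' statistics are linear-algebra functionals of the response matrix, so
#' 100,000 replicates run in seconds.  Randomized arm assignment within
#' periods matters only through the time-trend term; it is realized by
#' permuting the trend contributions within each period (equivalent to
#' permuted-block assignment under exchangeable errors).
#'
#' @param counts 3 x 3 integer matrix of cell counts (periods x arms,
#'   control first), e.g. from [round_sample_sizes()].
#' @param means per-arm means `(mu0, mu1, mu2)`.
#' @param sigma per-arm SDs (scalar recycled).
#' @param trend a [time_trend()].
#' @param analysis `"cc"` or `"ncc"` (for arm 2).
#' @param test `"t"` (residual-variance t test, default) or `"z"` (known
#'   sigma; requires a common SD).
#' @param alpha one-sided significance level.
#' @param ci_level two-sided confidence level for the width summary.
#' @param nsim number of simulated trials.
#' @param seed integer seed.
#' @param block replicates per vectorized block (memory knob).
#' @return An `oc_result` with per-arm rejection rates and their
#'   Monte-Carlo SEs, mean CI widths, and the mean and SD of the effect
#'   estimates across replicates (bias diagnostics).
#' @export
operating_characteristics <- function(counts, means, sigma = 1,
                                      trend = time_trend("none"),
                                      analysis = c("cc", "ncc"),
                                      test = c("t", "z"),
                                      alpha = 0.025, ci_level = 0.95,
                                      nsim = 10000, seed = NULL,
                                      block = 10000) {
  analysis <- match.arg(analysis)
  test <- match.arg(test)
  counts <- check_counts(counts)
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  if (test == "z" && length(unique(sigma)) != 1) {
    stop_platalloc("z analysis requires a common known sigma", "platalloc_unsupported")
  }
  if (!is.null(seed)) set.seed(seed)
  N <- sum(counts)
  period_of <- rep(1:3, rowSums(counts))
  arm_of <- unlist(lapply(1:3, function(s) rep(0:2, counts[s, ])))
  mu_vec <- means[arm_of + 1L]
  sd_vec <- sigma[arm_of + 1L]
  base_trend <- trend_values(trend, period_of, N)
  permute_trend <- trend$shape == "linear" && trend$lambda != 0

  plans <- list(
    arm1 = analysis_plan(counts, 1, "cc", period_of, arm_of),
    arm2 = analysis_plan(counts, 2, analysis, period_of, arm_of)
  )
  rej <- matrix(NA, nsim, 2)
  wid <- matrix(NA_real_, nsim, 2)
  ests <- matrix(NA_real_, nsim, 2)
  done <- 0
  while (done < nsim) {
    nb <- min(block, nsim - done)
    Y <- mu_vec + matrix(stats::rnorm(N * nb, 0, sd_vec), N, nb)
    if (any(base_trend != 0)) {
      if (permute_trend) {
        Tm <- matrix(0, N, nb)
        for (s in 1:3) {
          rows <- which(period_of == s)
          if (length(rows) > 1) {
            Tm[rows, ] <- apply(matrix(base_trend[rows], length(rows), nb),
                                2, sample)
          } else if (length(rows) == 1) {
            Tm[rows, ] <- base_trend[rows]
          }
        }
        Y <- Y + Tm
      } else {
        Y <- Y + base_trend
      }
    }
    for (a in 1:2) {
      pl <- plans[[a]]
      Ys <- Y[pl$idx, , drop = FALSE]
      est <- as.numeric(pl$coef_fun %*% Ys)
      if (test == "t") {
        rss <- pmax(colSums(Ys^2) - colSums(crossprod(pl$Q, Ys)^2), 0)
        se <- sqrt(rss / pl$df) * pl$se_unit
        stat <- est / se
        p <- stats::pt(stat, pl$df, lower.tail = FALSE)
        crit <- stats::qt(1 - (1 - ci_level) / 2, pl$df)
      } else {
        se <- sigma[1] * pl$se_unit
        stat <- est / se
        p <- stats::pnorm(stat, lower.tail = FALSE)
        crit <- stats::qnorm(1 - (1 - ci_level) / 2)
      }
      rows <- done + seq_len(nb)
      rej[rows, a] <- p < alpha
      wid[rows, a] <- 2 * crit * se
      ests[rows, a] <- est
    }
    done <- done + nb
  }
  ok <- stats::complete.cases(rej) & stats::complete.cases(wid) &
    is.finite(wid[, 1]) & is.finite(wid[, 2])
  n_failed <- nsim - sum(ok)
  rates <- colMeans(rej[ok, , drop = FALSE])
  new_oc_result(
    rates = rates,
    mcse = sqrt(rates * (1 - rates) / sum(ok)),
    widths = colMeans(wid[ok, , drop = FALSE]),
    est_mean = colMeans(ests[ok, , drop = FALSE]),
    est_sd = apply(ests[ok, , drop = FALSE], 2, stats::sd),
    nsim = nsim, seed = seed, n_failed = n_failed,
    meta = list(counts = counts, means = means, sigma = sigma,
                trend = trend, analysis = analysis, test = test,
                alpha = alpha)
  )
}

#' Case-study scenarios: designs, allocations and cell counts
#'
#' The ten design-by-allocation scenarios of the hypercholesterolemia case
#' study: total sample size 92, control mean 4.94, treatment means 5.66,
#' common SD 1, one-sided level 0.025.  Allocation labels are `"one"`
#' (1:1:1), `"sqrt"` (square-root-of-k) and `"opt"` (minmax-optimal).  The
#' one- and two-period counts come from largest-remainder rounding of the
#' allocation probabilities; the three-period counts are the case study's
#' printed sample-size tables, used verbatim (their totals are 94 and 93
#' rather than 92; see the package vignette).
#'
#' @return A list of scenarios, each with elements `design_label`, `r1`,
#'   `r2`, `allocation` and `counts` (3 x 3 matrix, periods x arms).
#' @export
case_study_scenarios <- function() {
  mk <- function(c1, c2, c3) {
    m <- rbind(c1, c2, c3)
    dimnames(m) <- list(paste0("period", 1:3), c("control", "arm1", "arm2"))
    m
  }
  zero <- c(0, 0, 0)
  arms_first <- c(2, 3, 1)  # within-period tie-break (see round_sample_sizes)
  # one-period (multi-arm) counts: N = 92 in the shared period
  one1 <- largest_remainder(rep(1, 3) / 3, 92, arms_first)
  p0 <- 1 / (1 + sqrt(2))
  one_sqrt <- largest_remainder(c(p0, (1 - p0) / 2, (1 - p0) / 2), 92, arms_first)
  # two-period design, r1 = 1/4: 23 then 69 patients
  per1 <- c(largest_remainder(c(.5, .5), 23, c(2, 1)), 0)
  two_one <- largest_remainder(rep(1, 3) / 3, 69, arms_first)
  two_sqrt <- largest_remainder(c(p0, (1 - p0) / 2, (1 - p0) / 2), 69, arms_first)
  p2_opt <- optimize_case2(0.25, "cc")$design$p[2, ]
  two_opt <- largest_remainder(p2_opt, 69, arms_first)
  list(
    list(design_label = "1-period", r1 = 1, r2 = 0, allocation = "one",
         counts = mk(zero, one1, zero)),
    list(design_label = "1-period", r1 = 1, r2 = 0, allocation = "opt (=sqrt)",
         counts = mk(zero, one_sqrt, zero)),
    list(design_label = "2-period", r1 = 0.25, r2 = 0.75, allocation = "one",
         counts = mk(per1, two_one, zero)),
    list(design_label = "2-period", r1 = 0.25, r2 = 0.75, allocation = "opt",
         counts = mk(per1, two_opt, zero)),
    list(design_label = "2-period", r1 = 0.25, r2 = 0.75, allocation = "sqrt",
         counts = mk(per1, two_sqrt, zero)),
    # three-period tables, printed counts used verbatim
    list(design_label = "3-period", r1 = 0.337, r2 = 0.326, allocation = "one",
         counts = mk(c(16, 16, 0), c(10, 10, 10), c(16, 0, 16))),
    list(design_label = "3-period", r1 = 0.337, r2 = 0.326, allocation = "opt (=sqrt)",
         counts = mk(c(16, 16, 0), c(12, 9, 9), c(16, 0, 16))),
    list(design_label = "3-period", r1 = 0.337, r2 = 0.446, allocation = "one",
         counts = mk(c(16, 16, 0), c(14, 14, 14), c(10, 0, 10))),
    list(design_label = "3-period", r1 = 0.337, r2 = 0.446, allocation = "opt",
         counts = mk(c(16, 16, 0), c(17, 8, 16), c(10, 0, 10))),
    list(design_label = "3-period", r1 = 0.337, r2 = 0.446, allocation = "sqrt",
         counts = mk(c(16, 16, 0), c(17, 12, 12), c(10, 0, 10)))
  )
}

#' Reproduce the case-study power comparison
#'
#' Runs the Monte-Carlo engine over the ten [case_study_scenarios()]
#' (means 4.94 control / 5.66 treatments, SD 1, one-sided 0.025,
#' concurrent-controls t analysis) and tabulates per-arm power and mean CI
#' widths with Monte-Carlo standard errors.
#'
#' @param nsim replicates per scenario (the full study uses 100,000).
#' @param seed integer seed; scenario s uses `seed + s`.
#' @param test `"t"` or `"z"` (see [operating_characteristics()]).
#' @return A data frame with one row per scenario: design, r1, r2,
#'   allocation, power and CI width per arm, and MC standard errors.
#' @export
reproduce_case_study <- function(nsim = 100000, seed = 1, test = "t") {
  scens <- case_study_scenarios()
  rows <- lapply(seq_along(scens), function(k) {
    sc <- scens[[k]]
    oc <- operating_characteristics(
      counts = sc$counts, means = c(4.94, 5.66, 5.66), sigma = 1,
      analysis = "cc", test = test, alpha = 0.025,
      nsim = nsim, seed = seed + k
    )
    data.frame(design = sc$design_label, r1 = sc$r1, r2 = sc$r2,
               allocation = sc$allocation,
               power_A1 = oc$power_arm1, power_A2 = oc$power_arm2,
               ci_width_A1 = oc$mean_ci_width[1],
               ci_width_A2 = oc$mean_ci_width[2],
               mc_se_A1 = oc$mc_se[1], mc_se_A2 = oc$mc_se[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "nsim") <- nsim
  attr(out, "seed") <- seed
  out
}
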