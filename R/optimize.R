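# Minmax-optimal allocation solvers.
#
# All solvers fix equal (or, under unequal variances, Neyman) allocation in
# periods 1 and 3 -- optimal because the stratified estimator makes the
# period-1 split affect Var(arm 1) only, and the harmonic pooling term
# p1*p0/(p1+p0) is maximized at the balanced split.  What remains is the
# period-2 allocation (and, in Cases 1-2, the period partition itself).

new_allocation_solution <- function(design, case, scenario, analysis,
                                    objective_fun = c("minmax", "sum"),
                                    converged = TRUE, trace = list()) {
  objective_fun <- match.arg(objective_fun)
  vr <- if (analysis == "ncc") var_ncc(design) else var_stratified_cc(design)
  v <- c(vr$var_arm1, vr$var_arm2) * design$N / design$sigma[1]^2
  structure(
    list(design = design,
         objective = if (objective_fun == "minmax") max(v) else sum(v),
         objective_fun = objective_fun,
         variances = c(arm1 = v[1], arm2 = v[2]),
         variance_gap = abs(v[1] - v[2]),
         case = case, scenario = scenario, analysis = analysis,
         converged = converged, trace = trace),
    class = "allocation_solution"
  )
}

#' @export
print.allocation_solution <- function(x, ...) {
  cat(sprintf("Optimal allocation (case %s, %s analysis, %s objective)\n",
              x$case, x$analysis,
              if (x$objective_fun == "minmax") "max-variance" else "sum-of-variances"))
  cat(sprintf("  scenario: %s\n", x$scenario))
  cat(sprintf("  r = (%s)\n",
              paste(formatC(x$design$r, digits = 4, format = "fg"), collapse = ", ")))
  cat("  period-2 allocation (control, arm1, arm2):",
      paste(round(x$design$p[2, ], 6), collapse = ", "), "\n")
  cat(sprintf("  objective = %.6f sigma^2/N, Var = (%.6f, %.6f)\n",
              x$objective, x$variances[1], x$variances[2]))
  invisible(x)
}

# design helper: equal split in periods 1 and 3, supplied period-2 row.
design_p13_equal <- function(r, p2, sigma = 1) {
  platform_design(
    N = 1, r = r,
    p = rbind(c(1 / 2, 1 / 2, 0), p2, c(1 / 2, 0, 1 / 2)),
    sigma = sigma
  )
}

# stationarity curve of the interior concurrent-controls optimum:
# p02^2 = p12^2 + p22^2, solved for p02 given p22 (p12 = 1 - p02 - p22).
p02_stationary <- function(p22) ((1 - p22)^2 + p22^2) / (2 * (1 - p22))

#' Optimal allocation with free entry and exit times (Case 1)
#'
#' When the entry time of arm 2 and the exit time of arm 1 are both design
#' parameters, the optimal trial is the classical one-period multi-arm trial
#' (`r = (0, 1, 0)`): every control patient is concurrent with both arms and
#' no stratification is needed.  The optimal within-period allocation is then
#' the square-root-of-k rule, `control : arm1 : arm2 = sqrt(2) : 1 : 1`, i.e.
#' `p02 = 1/(1 + sqrt(2))`.  The solution is the same whether or not
#' non-concurrent controls would be used, since none exist.
#'
#' @param analysis `"cc"` (concurrent controls only) or `"ncc"`.
#' @return An `allocation_solution`.
#' @export
optimize_case1 <- function(analysis = c("cc", "ncc")) {
  analysis <- match.arg(analysis)
  p0 <- 1 / (1 + sqrt(2))
  d <- design_p13_equal(c(0, 1, 0), c(p0, (1 - p0) / 2, (1 - p0) / 2))
  # one-period trial: no non-concurrent controls exist, analyze concurrently
  new_allocation_solution(d, case = "1", scenario = "one-period",
                          analysis = "cc", trace = list(requested = analysis))
}

#' Optimal allocation with fixed period sizes (Case 3)
#'
#' Both `r1` (entry of arm 2) and `r2` (exit of arm 1) are fixed; only the
#' within-period allocation is optimized, minimizing the larger of the two
#' effect-estimator variances.  Three scenarios arise:
#'
#' * `r1 >= 1/2`: arm 1 already dominates the objective; all period 2-3
#'   patients go to arm 2 and control in equal parts (`p12 = 0`).
#' * `r1 + r2 < 1/2`: symmetric situation for arm 2 (`p22 = 0`,
#'   `p02 = p12 = 1/2`).
#' * otherwise (interior): both arms recruit in period 2 and the optimum
#'   equalizes the variances.  With concurrent controls the solution lies on
#'   the stationarity curve `p02^2 = p12^2 + p22^2` and is found by a
#'   bracketed root-find of the equal-variance constraint in `p22`; with
#'   non-concurrent controls `Var(arm 1)` is minimized along the
#'   equal-variance curve numerically.
#'
#' @param r1,r2 fixed period fractions, `0 < r1 < 1`, `0 <= r2 <= 1 - r1`.
#' @param analysis `"cc"` or `"ncc"`; under `"ncc"` arm 2 pools
#'   non-concurrent controls (see [var_ncc()]), which shifts allocation away
#'   from the control arm.
#' @return An `allocation_solution`.
#' @examples
#' optimize_case3(1 / 3, 1 / 3)$design$p[2, ] # sqrt(2):1:1 rule
#' @export
optimize_case3 <- function(r1, r2, analysis = c("cc", "ncc")) {
  analysis <- match.arg(analysis)
  if (!(r1 > 0 && r1 < 1) || r2 < 0 || r1 + r2 > 1 + 1e-12) {
    stop_platalloc("need 0 < r1 < 1 and 0 <= r2 <= 1 - r1",
                   "platalloc_invalid_design")
  }
  r2 <- min(r2, 1 - r1)
  r <- c(r1, r2, 1 - r1 - r2)
  if (r1 >= 0.5) {
    d <- design_p13_equal(r, c(1 / 2, 0, 1 / 2))
    return(new_allocation_solution(d, "3", "r1>=1/2", analysis))
  }
  if (r1 + r2 <= 0.5) {
    d <- design_p13_equal(r, c(1 / 2, 1 / 2, 0))
    scen <- if (r1 + r2 < 0.5) "r1+r2<1/2" else "interior"
    return(new_allocation_solution(d, "3", scen, analysis))
  }
  if (analysis == "cc") {
    sol <- solve_case3_cc_interior(r)
  } else {
    sol <- solve_interior_ncc(r)
  }
  sol$case <- "3"
  sol
}

#' Optimal allocation with fixed entry time of arm 2 (Case 2)
#'
#' `r1` is fixed and the size of period 2 is optimized along with the
#' allocation.  For `r1 >= 1/2` the optimum runs two separate consecutive
#' trials (`r2 = 0`, equal splits).  For `r1 < 1/2` the optimum always sets
#' `r2 = 1 - r1` (arm 2 enters late but both arms run to the end, `r3 = 0`)
#' and the period-2 allocation is the Case-3 interior solution at
#' `(r1, 1 - r1)`.
#'
#' @param r1 fixed fraction of patients recruited before arm 2 enters,
#'   `0 < r1 < 1`.
#' @inheritParams optimize_case3
#' @return An `allocation_solution`.
#' @export
optimize_case2 <- function(r1, analysis = c("cc", "ncc")) {
  analysis <- match.arg(analysis)
  if (!(r1 > 0 && r1 < 1)) {
    stop_platalloc("need 0 < r1 < 1", "platalloc_invalid_design")
  }
  if (r1 >= 0.5) {
    d <- design_p13_equal(c(r1, 0, 1 - r1), c(0, 0, 0))
    sol <- new_allocation_solution(d, "2", "r1>=1/2 (separate trials)", analysis)
    return(sol)
  }
  sol <- optimize_case3(r1, 1 - r1, analysis)
  sol$case <- "2"
  sol$scenario <- "r1<1/2 (two-period)"
  sol
}

# ---- interior solvers ------------------------------------------------------

# Case 3, concurrent controls: root-find the equal-variance constraint
#   r1/4 + r2 g(p12, p02) = r3/4 + r2 g(p22, p02)
# along the stationarity curve p02 = ((1-p22)^2 + p22^2)/(2(1-p22)),
# p22 in (0, 1/2).  The constraint is strictly decreasing in p22 and
# brackets a root exactly under the interior scenario.
solve_case3_cc_interior <- function(r) {
  h <- function(p22) {
    p02 <- p02_stationary(p22)
    p12 <- 1 - p02 - p22
    r[1] / 4 + r[2] * g_pool(p12, p02) - r[3] / 4 - r[2] * g_pool(p22, p02)
  }
  root <- stats::uniroot(h, c(1e-12, 0.5 - 1e-12), tol = 1e-14)
  p22 <- root$root
  p02 <- p02_stationary(p22)
  d <- design_p13_equal(r, c(p02, 1 - p02 - p22, p22))
  new_allocation_solution(
    d, "3", "interior", "cc",
    trace = list(method = "stationarity-curve root-find",
                 iterations = root$iter, f_root = root$f.root)
  )
}

# Interior solver with non-concurrent controls: minimize Var(arm 1) along
# the equal-variance curve Var(arm 1) = Var(arm 2, pooled controls).
# For each p22 the constraint is solved for p12 by bracketed root-finds over
# all sign changes on a deterministic scan grid; the outer 1-D problem in
# p22 is scanned on a coarse grid, then refined with Brent's method.
solve_interior_ncc <- function(r) {
  var1 <- function(p12, p22) {
    info <- r[1] / 4 + r[2] * g_pool(p12, 1 - p12 - p22)
    1 / info
  }
  var2 <- function(p12, p22) {
    p02 <- 1 - p12 - p22
    q22 <- p22 * (1 - p22)
    corr_num <- r[2]^2 * p12^2 * p22^2
    corr_den <- r[1] / 4 + r[2] * p12 * (1 - p12)
    info <- r[3] / 4 + r[2] * q22 - if (corr_num > 0) corr_num / corr_den else 0
    if (info <= 0) Inf else 1 / info
  }
  # best (smallest) Var1 on the equal-variance curve for fixed p22; a large
  # finite sentinel marks p22 values with no equal-variance solution
  big <- 1e12
  curve_value <- function(p22) {
    lo <- 1e-9
    hi <- 1 - p22 - 1e-9
    if (hi <= lo) return(list(value = big))
    grid <- seq(lo, hi, length.out = 201)
    f <- vapply(grid, function(p12) var1(p12, p22) - var2(p12, p22), numeric(1))
    sgn <- sign(f)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (!length(idx)) return(list(value = big))
    best <- list(value = big)
    for (k in idx) {
      rt <- stats::uniroot(function(p12) var1(p12, p22) - var2(p12, p22),
                           c(grid[k], grid[k + 1]), tol = 1e-14)
      v <- var1(rt$root, p22)
      if (v < best$value) best <- list(value = v, p12 = rt$root)
    }
    best
  }
  p22_grid <- seq(0.005, 0.995, by = 0.005)
  vals <- vapply(p22_grid, function(x) curve_value(x)$value, numeric(1))
  if (all(vals >= big)) {
    stop_platalloc("no equal-variance solution found (non-interior scenario?)",
                   "platalloc_no_solution")
  }
  k <- which.min(vals)
  lo <- p22_grid[max(1, k - 1)]
  hi <- p22_grid[min(length(p22_grid), k + 1)]
  opt <- stats::optimize(function(x) curve_value(x)$value, c(lo, hi),
                         tol = 1e-10)
  p22 <- opt$minimum
  inner <- curve_value(p22)
  p12 <- inner$p12
  d <- design_p13_equal(r, c(1 - p12 - p22, p12, p22))
  new_allocation_solution(
    d, "3", "interior", "ncc",
    trace = list(method = "equal-variance curve minimization",
                 outer_grid = length(p22_grid), outer_tol = 1e-10)
  )
}

#' Optimal minmax allocation under unequal response variances
#'
#' With per-arm standard deviations `(sigma0, sigma1, sigma2)` the
#' single-comparison periods 1 and 3 are Neyman-allocated
#' (`p_arm : p_control = sigma_arm : sigma0`), and the period-2 allocation
#' minimizes the larger of the two stratified-estimator variances, which now
#' involve the variance ratios `sigma_i^2 / sigma0^2`.  The concurrent-only
#' analysis is assumed.  With equal standard deviations the solution
#' coincides with [optimize_case3()].
#'
#' @inheritParams optimize_case3
#' @param sigma per-arm standard deviations `(sigma0, sigma1, sigma2)`.
#' @return An `allocation_solution`; the objective is in units
#'   `sigma0^2 / N`.
#' @export
optimize_unequal_variances <- function(r1, r2, sigma = c(1, 1, 1)) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  stopifnot(length(sigma) == 3, all(sigma > 0))
  if (!(r1 > 0 && r1 < 1) || r2 < 0 || r1 + r2 > 1 + 1e-12) {
    stop_platalloc("need 0 < r1 < 1 and 0 <= r2 <= 1 - r1",
                   "platalloc_invalid_design")
  }
  r <- c(r1, min(r2, 1 - r1), 1 - r1 - min(r2, 1 - r1))
  ratio <- (sigma[2:3] / sigma[1])^2
  p11 <- sigma[2] / (sigma[1] + sigma[2])   # Neyman split, period 1
  p23 <- sigma[3] / (sigma[1] + sigma[3])   # Neyman split, period 3
  base_p <- function(p2) {
    rbind(c(1 - p11, p11, 0), p2, c(1 - p23, 0, p23))
  }
  mk <- function(p2) platform_design(1, r, base_p(p2), sigma = sigma)
  info1 <- function(p12, p22) {
    r[1] * g_pool(p11, 1 - p11, ratio[1]) +
      r[2] * g_pool(p12, 1 - p12 - p22, ratio[1])
  }
  info2 <- function(p12, p22) {
    r[3] * g_pool(p23, 1 - p23, ratio[2]) +
      r[2] * g_pool(p22, 1 - p12 - p22, ratio[2])
  }
  # boundary candidates: period 2 devoted to a single comparison with its
  # own Neyman split (degenerate scenarios)
  cand <- list(
    c(1 - sigma[3] / (sigma[1] + sigma[3]), 0, sigma[3] / (sigma[1] + sigma[3])),
    c(1 - sigma[2] / (sigma[1] + sigma[2]), sigma[2] / (sigma[1] + sigma[2]), 0)
  )
  scen <- c("boundary p12=0", "boundary p22=0")
  # interior candidate: minimize Var1 along the equal-variance curve
  big <- 1e12
  curve_value <- function(p22) {
    lo <- 1e-9
    hi <- 1 - p22 - 1e-9
    if (hi <= lo) return(list(value = big))
    grid <- seq(lo, hi, length.out = 201)
    f <- vapply(grid, function(p12) 1 / info1(p12, p22) - 1 / info2(p12, p22),
                numeric(1))
    sgn <- sign(f)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (!length(idx)) return(list(value = big))
    best <- list(value = big)
    for (k in idx) {
      rt <- stats::uniroot(function(p12) 1 / info1(p12, p22) - 1 / info2(p12, p22),
                           c(grid[k], grid[k + 1]), tol = 1e-14)
      v <- 1 / info1(rt$root, p22)
      if (v < best$value) best <- list(value = v, p12 = rt$root)
    }
    best
  }
  p22_grid <- seq(0.005, 0.995, by = 0.005)
  vals <- vapply(p22_grid, function(x) curve_value(x)$value, numeric(1))
  if (any(vals < big)) {
    k <- which.min(vals)
    opt <- stats::optimize(function(x) curve_value(x)$value,
                           c(p22_grid[max(1, k - 1)],
                             p22_grid[min(length(p22_grid), k + 1)]),
                           tol = 1e-10)
    p22 <- opt$minimum
    p12 <- curve_value(p22)$p12
    cand <- c(cand, list(c(1 - p12 - p22, p12, p22)))
    scen <- c(scen, "interior")
  }
  objective <- function(p2) {
    v1 <- 1 / info1(p2[2], p2[3])
    v2 <- 1 / info2(p2[2], p2[3])
    c(max(v1, v2), min(v1, v2))
  }
  obj <- t(vapply(cand, objective, numeric(2)))
  k <- order(obj[, 1], obj[, 2])[1]
  new_allocation_solution(
    mk(cand[[k]]), "3", scen[k], "cc",
    trace = list(method = "Neyman periods 1/3 + equal-variance curve",
                 candidates = length(cand))
  )
}

#' Optimal allocation minimizing the sum of the variances
#'
#' Same setting as [optimize_case3()] with concurrent controls and equal
#' variances, but the objective is `Var(arm 1) + Var(arm 2)` instead of the
#' maximum.  Periods 1 and 3 stay equally allocated; the period-2 allocation
#' is found by Nelder-Mead over `(p12, p22)` followed by a Newton polish on
#' the smooth objective.  At `r1 = r3` the solution coincides with the
#' minmax optimum (the square-root-of-k rule); otherwise it allocates more
#' patients to the control than the minmax solution does.
#'
#' @inheritParams optimize_case3
#' @return An `allocation_solution` with `objective_fun = "sum"`.
#' @export
optimize_sum_of_variances <- function(r1, r2) {
  if (!(r1 > 0 && r1 < 1) || r2 <= 0 || r1 + r2 >= 1 + 1e-12) {
    stop_platalloc("need 0 < r1 < 1 and 0 < r2 <= 1 - r1",
                   "platalloc_invalid_design")
  }
  r2 <- min(r2, 1 - r1)
  r <- c(r1, r2, 1 - r1 - r2)
  fobj <- function(x) {
    p12 <- x[1]; p22 <- x[2]; p02 <- 1 - p12 - p22
    if (p12 <= 0 || p22 <= 0 || p02 <= 0) return(1e10)
    1 / (r[1] / 4 + r[2] * g_pool(p12, p02)) +
      1 / (r[3] / 4 + r[2] * g_pool(p22, p02))
  }
  starts <- list(c(0.3, 0.3), c(0.15, 0.45), c(0.45, 0.15),
                 c(0.25, 0.25), c(1 - 1 / sqrt(2), 1 - 1 / sqrt(2)))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, fobj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # Newton polish on the smooth interior objective
  x <- best$par
  for (it in 1:5) {
    gr <- pracma::grad(fobj, x)
    he <- pracma::hessian(fobj, x)
    step <- tryCatch(solve(he, gr), error = function(e) NULL)
    if (is.null(step)) break
    xn <- x - step
    if (fobj(xn) <= fobj(x) + 1e-12) x <- xn
    if (sqrt(sum(gr^2)) < 1e-10) break
  }
  gr <- pracma::grad(fobj, x)
  d <- design_p13_equal(r, c(1 - x[1] - x[2], x[1], x[2]))
  new_allocation_solution(
    d, "3", "interior", "cc", objective_fun = "sum",
    converged = sqrt(sum(gr^2)) < 1e-6,
    trace = list(method = "Nelder-Mead multistart + Newton polish",
                 grad_norm = sqrt(sum(gr^2)))
  )
}
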