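# Independent oracles used across the suite.

# Variance of a treatment coefficient from the inverse information matrix of
# the period-adjusted regression built on expected (continuous) cell counts.
# mode: "cc1" (periods 1-2, arm-1 coefficient's model), "cc2" (periods 2-3),
# "ncc" (all periods).  Independent of the package's closed forms: it only
# assembles X'X from cell counts and inverts it.
oracle_model_variance <- function(N, r, p, coef = c("arm1", "arm2"),
                                  mode = c("cc1", "cc2", "ncc"), sigma = 1) {
  coef <- match.arg(coef)
  mode <- match.arg(mode)
  cells <- expand.grid(s = 1:3, i = 0:2)
  cells$n <- N * r[cells$s] * p[cbind(cells$s, cells$i + 1)]
  cells <- cells[cells$n > 0, ]
  if (mode == "cc1") cells <- cells[cells$s <= 2, ]
  if (mode == "cc2") cells <- cells[cells$s >= 2, ]
  X <- cbind(intercept = 1,
             arm1 = as.numeric(cells$i == 1),
             arm2 = as.numeric(cells$i == 2),
             period2 = as.numeric(cells$s == 2),
             period3 = as.numeric(cells$s == 3))
  XtX <- crossprod(X * sqrt(cells$n))
  qrx <- qr(XtX)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  if (!coef %in% colnames(X)[keep]) return(Inf)
  V <- solve(crossprod(X[, keep, drop = FALSE] * sqrt(cells$n))) * sigma^2
  k <- which(colnames(X)[keep] == coef)
  V[k, k]
}

# Dense grid search of the raw minmax objective over the period-2 allocation
# simplex (periods 1 and 3 held at the equal split), refined by two finer
# local grids so the enumerated argmin resolves the flat equal-variance
# valley.  Pure enumeration; shares no code with the solvers.
grid_minmax_oracle <- function(r, analysis = c("cc", "ncc"), step = 0.002) {
  analysis <- match.arg(analysis)
  gp <- function(a, b) ifelse(a > 0 & b > 0, a * b / (a + b), 0)
  eval_obj <- function(p12, p22) {
    p02 <- 1 - p12 - p22
    v1 <- 1 / (r[1] / 4 + r[2] * gp(p12, p02))
    if (analysis == "cc") {
      v2 <- 1 / (r[3] / 4 + r[2] * gp(p22, p02))
    } else {
      corr <- ifelse(p12 * p22 > 0,
                     r[2]^2 * p12^2 * p22^2 /
                       (r[1] / 4 + r[2] * p12 * (1 - p12)), 0)
      info2 <- r[3] / 4 + r[2] * p22 * (1 - p22) - corr
      v2 <- ifelse(info2 > 0, 1 / info2, Inf)
    }
    pmax(v1, v2)
  }
  search <- function(lo1, hi1, lo2, hi2, st) {
    g <- expand.grid(p12 = seq(max(lo1, st), min(hi1, 1 - st), by = st),
                     p22 = seq(max(lo2, st), min(hi2, 1 - st), by = st))
    g <- g[g$p12 + g$p22 < 1 - st / 2, ]
    obj <- eval_obj(g$p12, g$p22)
    k <- which.min(obj)
    c(g$p12[k], g$p22[k])
  }
  b <- search(0, 1, 0, 1, step)
  w <- 10 * step
  for (st in c(2e-4, 2e-5)) {
    b <- search(b[1] - w, b[1] + w, b[2] - w, b[2] + w, st)
    w <- 10 * 2e-4
  }
  c(p02 = 1 - b[1] - b[2], p12 = b[1], p22 = b[2])
}

# random valid three-period design with all cells populated
random_design <- function(N = 100) {
  repeat {
    r <- stats::runif(3, 0.05, 1)
    r <- r / sum(r)
    p2 <- stats::runif(3, 0.05, 1)
    p2 <- p2 / sum(p2)
    p1 <- stats::runif(1, 0.1, 0.9)
    p3 <- stats::runif(1, 0.1, 0.9)
    d <- try(platform_design(N, r, rbind(c(p1, 1 - p1, 0), p2,
                                         c(p3, 0, 1 - p3))),
             silent = TRUE)
    if (!inherits(d, "try-error")) return(d)
  }
}

case_study_printed_powers <- function() {
  data.frame(
    design = c("1-period", "1-period", "2-period", "2-period", "2-period",
               "3-period", "3-period", "3-period", "3-period", "3-period"),
    allocation = c("one", "opt (=sqrt)", "one", "opt", "sqrt",
                   "one", "opt (=sqrt)", "one", "opt", "sqrt"),
    power_A1 = c(0.798, 0.805, 0.844, 0.772, 0.851,
                 0.720, 0.725, 0.782, 0.737, 0.784),
    power_A2 = c(0.798, 0.805, 0.671, 0.757, 0.681,
                 0.722, 0.724, 0.687, 0.730, 0.682)
  )
}
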