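#' Construct a platform-trial design
#'
#' A three-period platform trial compares two experimental arms against a
#' shared control.  Arm 1 and the control recruit in period 1, all three arms
#' recruit in period 2, and arm 2 and the control recruit in period 3, so the
#' active-arm sets are `I1 = {0, 1}`, `I2 = {0, 1, 2}`, `I3 = {0, 2}` (arm 0
#' is the control).  Degenerate designs (one- or two-period trials) are
#' expressed by setting the corresponding period fraction to zero.
#'
#' @param N total sample size (a positive number; the variance engine treats
#'   sample sizes as continuous, integer rounding happens only in
#'   [round_sample_sizes()]).
#' @param r numeric vector of length 3, the period fractions
#'   `(r1, r2, r3) = (N1, N2, N3)/N`; must be nonnegative and sum to 1.
#' @param p 3 x 3 matrix of within-period allocation probabilities; rows are
#'   periods, columns are arms in the order control, arm 1, arm 2.  Each row
#'   of a non-empty period must sum to 1 over its active arms, and inactive
#'   arms must have probability 0.  Rows of empty periods (`r[s] == 0`) may be
#'   all zero.
#' @param sigma per-arm response standard deviations `(sigma0, sigma1,
#'   sigma2)`; scalar input is recycled.
#'
#' @return An object of class `platform_design`.
#' @examples
#' # symmetric three-period design, equal allocation everywhere
#' platform_design(
#'   N = 92, r = c(1, 1, 1) / 3,
#'   p = rbind(
#'     c(1 / 2, 1 / 2, 0),
#'     c(1 / 3, 1 / 3, 1 / 3),
#'     c(1 / 2, 0, 1 / 2)
#'   )
#' )
#' @export
platform_design <- function(N, r, p, sigma = c(1, 1, 1)) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  stopifnot(length(r) == 3, length(sigma) == 3)
  p <- as.matrix(p)
  if (!all(dim(p) == c(3, 3))) {
    stop_platalloc("`p` must be a 3 x 3 matrix (periods x arms, control first)",
                   "platalloc_invalid_design")
  }
  if (!(is.numeric(N) && length(N) == 1 && N > 0)) {
    stop_platalloc("`N` must be a positive number", "platalloc_invalid_design")
  }
  if (any(r < -1e-12) || abs(sum(r) - 1) > 1e-9) {
    stop_platalloc("period fractions `r` must be nonnegative and sum to 1",
                   "platalloc_invalid_design")
  }
  r <- pmax(r, 0)
  if (any(sigma <= 0)) {
    stop_platalloc("`sigma` must be positive", "platalloc_invalid_design")
  }
  if (any(p < -1e-12)) {
    stop_platalloc("allocation probabilities must be nonnegative",
                   "platalloc_invalid_design")
  }
  p[p < 0] <- 0
  inactive <- rbind(c(FALSE, FALSE, TRUE),   # period 1: arm 2 inactive
                    c(FALSE, FALSE, FALSE),  # period 2: all arms active
                    c(FALSE, TRUE, FALSE))   # period 3: arm 1 inactive
  if (any(p[inactive] != 0)) {
    stop_platalloc("inactive arms must have allocation probability 0",
                   "platalloc_invalid_design")
  }
  for (s in 1:3) {
    rs <- sum(p[s, ])
    if (r[s] > 0 && abs(rs - 1) > 1e-9) {
      stop_platalloc(sprintf("allocation probabilities in period %d sum to %.12g, not 1", s, rs),
                     "platalloc_invalid_design")
    }
    if (r[s] == 0 && rs != 0 && abs(rs - 1) > 1e-9) {
      stop_platalloc(sprintf("period %d is empty; its allocation row must sum to 0 or 1", s),
                     "platalloc_invalid_design")
    }
  }
  dimnames(p) <- list(paste0("period", 1:3), c("control", "arm1", "arm2"))
  structure(
    list(N = N, r = as.numeric(r), p = p, sigma = as.numeric(sigma),
         arm_sets = list(c(0L, 1L), c(0L, 1L, 2L), c(0L, 2L))),
    class = "platform_design"
  )
}

#' @export
print.platform_design <- function(x, ...) {
  cat("Platform-trial design (two experimental arms, shared control)\n")
  cat(sprintf("  N = %g, period fractions r = (%s)\n", x$N,
              paste(formatC(x$r, digits = 4, format = "fg"), collapse = ", ")))
  cat("  allocation probabilities (rows periods, cols arms):\n")
  print(round(x$p, 4))
  if (length(unique(x$sigma)) > 1) {
    cat(sprintf("  per-arm SDs: (%s)\n", paste(x$sigma, collapse = ", ")))
  } else {
    cat(sprintf("  common SD: %g\n", x$sigma[1]))
  }
  invisible(x)
}

#' Expected group sizes per arm and period
#'
#' Continuous (unrounded) expected cell sizes `N * r_s * p[s, i]`.
#'
#' @param design a [platform_design()].
#' @return 3 x 3 numeric matrix, rows periods, columns arms.
#' @export
expected_counts <- function(design) {
  stopifnot(inherits(design, "platform_design"))
  design$N * design$r * design$p
}

#' Read a design specification from a YAML or JSON file
#'
#' The file holds keys `N`, `r` (list of 3), `p` (3 x 3 matrix as a list of
#' period rows, control column first), optional `sigma` (list of 3, default
#' 1), and optional `analysis` (`"cc"` or `"ncc"`, recorded as an attribute).
#'
#' @param path file path; format is inferred from the extension
#'   (`.json` vs `.yaml`/`.yml`).
#' @return A [platform_design()]; the `analysis` key, if present, is attached
#'   as attribute `"analysis"`.
#' @export
read_design <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  spec <- fix_yaml_N(spec)
  required <- c("N", "r", "p")
  missing <- setdiff(required, names(spec))
  if (length(missing)) {
    stop_platalloc(paste("design file lacks keys:", paste(missing, collapse = ", ")),
                   "platalloc_invalid_design")
  }
  p <- spec$p
  if (is.list(p)) p <- do.call(rbind, p)
  p <- as.matrix(p)
  r <- unlist(spec$r)
  # decimals in config files carry limited precision; renormalize within a
  # loose tolerance and reject anything worse
  if (abs(sum(r) - 1) > 1e-5) {
    stop_platalloc("period fractions `r` must sum to 1", "platalloc_invalid_design")
  }
  r <- r / sum(r)
  for (s in 1:3) {
    rs <- sum(p[s, ])
    if (rs > 0) {
      if (abs(rs - 1) > 1e-5) {
        stop_platalloc(sprintf("allocation probabilities in period %d must sum to 1", s),
                       "platalloc_invalid_design")
      }
      p[s, ] <- p[s, ] / rs
    }
  }
  d <- platform_design(N = spec$N, r = r, p = p,
                       sigma = unlist(spec$sigma %||% 1))
  if (!is.null(spec$analysis)) {
    analysis <- match.arg(spec$analysis, c("cc", "ncc"))
    attr(d, "analysis") <- analysis
  }
  d
}
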