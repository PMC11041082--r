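# internal helpers shared across modules

# harmonic pooling term a*b/(a + ratio*b); the per-period information
# contribution of an arm/control pair with allocation probabilities (a, b).
# Returns 0 on the boundary (an empty group contributes no information).
g_pool <- function(a, b, ratio = 1) {
  out <- numeric(length(a))
  ok <- a > 0 & b > 0
  out[ok] <- (a[ok] * b[ok]) / (a[ok] + ratio * b[ok])
  out
}

# largest-remainder apportionment of `total` units to quotas `total*shares`.
# Ties in the remainders are broken in the order given by `tie_order`
# (indices into `shares`), then by index.
largest_remainder <- function(shares, total, tie_order = seq_along(shares)) {
  stopifnot(all(shares >= 0), abs(sum(shares) - 1) < 1e-8)
  quota <- shares * total
  base <- floor(quota + 1e-9)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    rem <- quota - base
    prio <- match(seq_along(shares), tie_order)
    ord <- order(-rem, prio)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# YAML 1.1 parses a bare key `N` as the boolean FALSE; restore it so design
# files can use the natural field name without quoting.
fix_yaml_N <- function(x) {
  if (is.list(x) && "FALSE" %in% names(x) && !"N" %in% names(x)) {
    names(x)[names(x) == "FALSE"] <- "N"
  }
  x
}

stop_platalloc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "platalloc_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
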