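# Scenario configuration, report serialization, Fig-2-style curve export.

scenario_defaults <- function() {
  list(
    design = list(N = 92, r = c(1, 1, 1) / 3, rule = "one", p = NULL),
    arms = list(means = c(0, 0, 0), sds = c(1, 1, 1)),
    analysis = list(mode = "cc", test = "t", alpha = 0.025),
    trend = list(shape = "none", lambda = 0),
    simulation = list(nsim = 10000, seed = 1)
  )
}

allocation_rule_p <- function(rule, r) {
  p0 <- 1 / (1 + sqrt(2))
  p2 <- switch(rule,
    one = c(1, 1, 1) / 3,
    sqrt = c(p0, (1 - p0) / 2, (1 - p0) / 2),
    opt = optimize_case3(r[1], r[2], "cc")$design$p[2, ]
  )
  rbind(c(.5, .5, 0), p2, c(.5, 0, .5))
}

#' Load and validate a simulation scenario configuration
#'
#' Reads a YAML or JSON scenario file with blocks `design` (`N`, `r`, and
#' either an explicit allocation matrix `p` or a rule name `rule` among
#' `"one"`, `"sqrt"`, `"opt"`), `arms` (`means`, `sds`), `analysis`
#' (`mode`, `test`, `alpha`), `trend` (`shape`, `lambda`) and `simulation`
#' (`nsim`, `seed`).  Unknown keys are rejected; omitted keys take the
#' defaults, which are materialized into the returned object so output
#' provenance is complete.
#'
#' @param path scenario file (`.yaml`/`.yml`/`.json`).
#' @return A list of class `scenario_config` with all defaults filled in,
#'   the resolved [platform_design()] in `$design_object` and its rounded
#'   `$counts`.
#' @export
load_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$design)) raw$design <- fix_yaml_N(raw$design)
  defaults <- scenario_defaults()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad)) {
    stop_platalloc(paste("unknown scenario blocks:", paste(bad, collapse = ", ")),
                   "platalloc_invalid_config")
  }
  cfg <- defaults
  problems <- character(0)
  for (blk in names(raw)) {
    extra <- setdiff(names(raw[[blk]]), names(defaults[[blk]]))
    if (length(extra)) {
      problems <- c(problems, paste0(blk, ": unknown keys ",
                                     paste(extra, collapse = ", ")))
    }
    cfg[[blk]] <- utils::modifyList(cfg[[blk]], raw[[blk]])
  }
  if (length(problems)) {
    stop_platalloc(paste("invalid scenario:", paste(problems, collapse = "; ")),
                   "platalloc_invalid_config")
  }
  r <- unlist(cfg$design$r)
  if (length(r) == 1) r <- c(r, 1 - r, 0)  # r1 shorthand
  if (length(r) == 2) r <- c(r, 1 - sum(r))
  cfg$design$r <- r
  if (is.null(cfg$design$p)) {
    cfg$design$p <- allocation_rule_p(match.arg(cfg$design$rule,
                                                c("one", "sqrt", "opt")), r)
  } else {
    p <- cfg$design$p
    if (is.list(p)) p <- do.call(rbind, p)
    p <- as.matrix(p)
    for (s in 1:3) {
      rs <- sum(p[s, ])
      if (r[s] > 0 && abs(rs - 1) > 1e-5) {
        stop_platalloc(sprintf("allocation row for period %d does not sum to 1", s),
                       "platalloc_invalid_config")
      }
      if (rs > 0) p[s, ] <- p[s, ] / rs
    }
    cfg$design$p <- p
  }
  cfg$design_object <- platform_design(cfg$design$N, r, cfg$design$p,
                                       sigma = unlist(cfg$arms$sds))
  cfg$counts <- round_sample_sizes(cfg$design_object)
  class(cfg) <- "scenario_config"
  cfg
}

#' Run the Monte-Carlo engine on a scenario configuration
#'
#' @param cfg a `scenario_config` from [load_scenario()].
#' @return An `oc_result` (see [operating_characteristics()]).
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  operating_characteristics(
    counts = cfg$counts,
    means = unlist(cfg$arms$means),
    sigma = unlist(cfg$arms$sds),
    trend = time_trend(cfg$trend$shape, cfg$trend$lambda),
    analysis = cfg$analysis$mode,
    test = cfg$analysis$test,
    alpha = cfg$analysis$alpha,
    nsim = cfg$simulation$nsim,
    seed = cfg$simulation$seed
  )
}

result_provenance <- function(extra = list()) {
  c(list(package = "platalloc",
         version = as.character(utils::packageVersion("platalloc"))),
    extra)
}

#' Serialize results to TSV or JSON with provenance
#'
#' Writes an optimizer solution, an `oc_result`, or any data frame (e.g.
#' the [reproduce_case_study()] table) to disk.  JSON output embeds a
#' provenance block (package version, seed, configuration digest);
#' TSV output carries the same information in `#`-prefixed header lines,
#' so re-running with identical inputs reproduces byte-identical files.
#'
#' @param results object to serialize.
#' @param path output file.
#' @param format `"tsv"` or `"json"` (default inferred from extension).
#' @param seed seed recorded in the provenance, if any.
#' @return `path`, invisibly.
#' @export
emit_report <- function(results, path, format = NULL, seed = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  payload <- if (is.data.frame(results)) {
    results
  } else if (inherits(results, "allocation_solution")) {
    list(case = results$case, scenario = results$scenario,
         analysis = results$analysis, objective = results$objective,
         variances = as.list(results$variances),
         variance_gap = results$variance_gap,
         r = results$design$r, p = results$design$p,
         converged = results$converged)
  } else if (inherits(results, "oc_result")) {
    list(power_arm1 = results$power_arm1, power_arm2 = results$power_arm2,
         mc_se = results$mc_se, mean_ci_width = results$mean_ci_width,
         nsim = results$nsim, n_failed = results$n_failed)
  } else {
    unclass(results)
  }
  txt <- paste(deparse(payload), collapse = "")
  digest <- sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1))
  prov <- result_provenance(list(seed = seed, config_digest = digest))
  if (format == "json") {
    jsonlite::write_json(list(provenance = prov, results = payload), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (!is.data.frame(payload)) {
      payload <- as.data.frame(lapply(payload, function(x) {
        if (is.matrix(x) || length(x) > 1) paste(signif(unlist(x), 10), collapse = ",") else x
      }))
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s=%s", names(prov),
                       vapply(prov, function(x) paste(format(x), collapse = ","),
                              character(1))), con)
    utils::write.table(payload, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Optimal period-2 allocation as a function of r2
#'
#' Computes the optimal period-2 allocation probabilities on a grid of
#' `r2` values for fixed `r1`, for the concurrent-only and (optionally)
#' non-concurrent-control analyses — the data behind the classic
#' allocation-vs-period-size curves.  The control share is minimal at
#' `r2 = 1 - 2 r1`, where equal allocation between the two experimental
#' arms (the square-root-of-k rule) is optimal.
#'
#' @param r1 fixed period-1 fraction, `0 < r1 < 1/2`.
#' @param r2 numeric vector of period-2 fractions (default a grid over
#'   `(0, 1 - r1)`).
#' @param analysis character vector among `"cc"`, `"ncc"`.
#' @return A data frame with columns `r1`, `r2`, `analysis`, `p02`, `p12`,
#'   `p22`, `scenario`.
#' @export
allocation_curves <- function(r1, r2 = seq(0.05, 1 - r1 - 0.01, length.out = 25),
                              analysis = c("cc", "ncc")) {
  rows <- list()
  for (mode in analysis) {
    for (x in r2) {
      sol <- optimize_case3(r1, x, mode)
      rows[[length(rows) + 1]] <- data.frame(
        r1 = r1, r2 = x, analysis = mode,
        p02 = sol$design$p[2, 1], p12 = sol$design$p[2, 2],
        p22 = sol$design$p[2, 3], scenario = sol$scenario
      )
    }
  }
  do.call(rbind, rows)
}
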