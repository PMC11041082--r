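test_that("design construction enforces the simplex and period-membership invariants", {
  p_ok <- rbind(c(.5, .5, 0), c(1, 1, 1) / 3, c(.5, 0, .5))
  d <- platform_design(92, c(1, 1, 1) / 3, p_ok)
  expect_s3_class(d, "platform_design")
  expect_equal(sum(d$r), 1)
  expect_equal(unname(rowSums(d$p)), rep(1, 3))

  expect_error(platform_design(0, c(1, 1, 1) / 3, p_ok), class = "platalloc_invalid_design")
  expect_error(platform_design(92, c(.5, .4, .2), p_ok), class = "platalloc_invalid_design")
  expect_error(platform_design(92, c(1, 1, 1) / 3,
                               rbind(c(.5, .4, .1), p_ok[2, ], p_ok[3, ])),
               class = "platalloc_invalid_design")  # arm 2 active in period 1
  bad <- p_ok; bad[2, ] <- c(.5, .4, .2)
  expect_error(platform_design(92, c(1, 1, 1) / 3, bad),
               class = "platalloc_invalid_design")  # row sum != 1
  expect_error(platform_design(92, c(1, 1, 1) / 3, p_ok, sigma = c(1, 0, 1)),
               class = "platalloc_invalid_design")
})

test_that("period-wise comparison variance follows 1/n_arm + 1/n_control", {
  # 50 per group in a single shared period
  d <- platform_design(100, c(0, 1, 0),
                       rbind(c(0, 0, 0), c(.5, .25, .25), c(0, 0, 0)))
  expect_equal(period_effect_variance(d, 1, 2), 1 / 25 + 1 / 50)

  # N = 92 in equal thirds at 1:1 gives continuous 15.33 per group
  d <- platform_design(92, c(1, 1, 1) / 3,
                       rbind(c(.5, .5, 0), c(1, 1, 1) / 3, c(.5, 0, .5)))
  expect_equal(period_effect_variance(d, 1, 1), 2 / (92 / 6), tolerance = 1e-12)
  expect_equal(period_effect_variance(d, 1, 1), 0.130435, tolerance = 1e-5)

  # unequal variances: sigma1 = 2 with n1 = 20, sigma0 = 1 with n0 = 10
  d <- platform_design(30, c(1, 0, 0),
                       rbind(c(1 / 3, 2 / 3, 0), c(0, 0, 0), c(0, 0, 0)),
                       sigma = c(1, 2, 1))
  expect_equal(period_effect_variance(d, 1, 1), 4 / 20 + 1 / 10)

  expect_error(period_effect_variance(d, 2, 1), class = "platalloc_invalid_design")
  d0 <- platform_design(30, c(1, 0, 0),
                        rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  expect_error(period_effect_variance(d0, 1, 1), class = "platalloc_inestimable")
})

test_that("stratification weights are inverse-variance and handle absent periods", {
  expect_equal(stratification_weights(0.04, 0.04), c(0.5, 0.5))
  w <- stratification_weights(0.125, 0.194444)
  expect_equal(w[1], 0.608696, tolerance = 1e-5)
  expect_equal(sum(w), 1)
  expect_equal(stratification_weights(0.04, Inf), c(1, 0))
  expect_equal(stratification_weights(Inf, 0.04), c(0, 1))
  expect_error(stratification_weights(Inf, Inf), class = "platalloc_inestimable")
})

test_that("concurrent-control stratified variances match the closed form", {
  # one shared period at 1:1(:0) is the classical two-sample variance 4/N
  d <- platform_design(80, c(1, 0, 0),
                       rbind(c(.5, .5, 0), c(0, 0, 0), c(0, 0, 0)))
  expect_equal(var_stratified_cc(d)$var_arm1, 4 / 80)
  expect_true(is.infinite(var_stratified_cc(d)$var_arm2))

  # symmetric thirds with sqrt-rule period 2
  p0 <- 1 / (1 + sqrt(2))
  d <- platform_design(1, c(1, 1, 1) / 3,
                       rbind(c(.5, .5, 0), c(p0, (1 - p0) / 2, (1 - p0) / 2),
                             c(.5, 0, .5)))
  v <- var_stratified_cc(d)
  expect_equal(v$var_arm1, 7.11621, tolerance = 1e-6)
  expect_equal(v$var_arm1, v$var_arm2, tolerance = 1e-12)
  expect_equal(unname(rowSums(v$weights)), c(1, 1))

  # two-period design: arm 1 pools both periods, arm 2 period 2 only
  d <- platform_design(1, c(.25, .75, 0),
                       rbind(c(.5, .5, 0), c(1, 1, 1) / 3, c(0, 0, 0)))
  v <- var_stratified_cc(d)
  expect_equal(v$var_arm1, 1 / (0.0625 + 0.125), tolerance = 1e-12)
  expect_equal(v$var_arm2, 8, tolerance = 1e-12)
})

test_that("stratified variance equals combining period variances with the weights", {
  set.seed(101)
  for (k in 1:20) {
    d <- random_design()
    v <- var_stratified_cc(d)
    for (arm in 1:2) {
      periods <- if (arm == 1) 1:2 else 2:3
      pv <- vapply(periods, function(s) period_effect_variance(d, arm, s),
                   numeric(1))
      w <- stratification_weights(pv[1], pv[2])
      expect_equal(sum(w^2 * pv),
                   if (arm == 1) v$var_arm1 else v$var_arm2,
                   tolerance = 1e-12)
    }
  }
})

test_that("variances equal the inverse information of the period-adjusted models", {
  set.seed(202)
  for (k in 1:50) {
    d <- random_design()
    v <- var_stratified_cc(d)
    expect_equal(v$var_arm1,
                 oracle_model_variance(d$N, d$r, d$p, "arm1", "cc1"),
                 tolerance = 1e-10)
    expect_equal(v$var_arm2,
                 oracle_model_variance(d$N, d$r, d$p, "arm2", "cc2"),
                 tolerance = 1e-10)
    expect_equal(var_ncc(d)$var_arm2,
                 oracle_model_variance(d$N, d$r, d$p, "arm2", "ncc"),
                 tolerance = 1e-10)
  }
})

test_that("pooling non-concurrent controls reduces the arm-2 variance", {
  # worked two-period example and its concurrent-only counterpart
  d <- platform_design(1, c(.25, .75, 0),
                       rbind(c(.5, .5, 0), c(1, 1, 1) / 3, c(0, 0, 0)))
  expect_equal(var_ncc(d)$var_arm2, 22 / 3, tolerance = 1e-10)
  expect_lt(var_ncc(d)$var_arm2, var_stratified_cc(d)$var_arm2)

  set.seed(303)
  for (k in 1:25) {
    d <- random_design()
    expect_lt(var_ncc(d)$var_arm2, var_stratified_cc(d)$var_arm2)
  }

  # without arm 1 in period 2 the correction vanishes: plain two-sample form
  d <- platform_design(1, c(.4, .6, 0),
                       rbind(c(.5, .5, 0), c(.5, 0, .5), c(0, 0, 0)))
  expect_equal(var_ncc(d)$var_arm2, 1 / (0.6 * 0.25), tolerance = 1e-12)
  expect_equal(var_ncc(d)$var_arm2, var_stratified_cc(d)$var_arm2,
               tolerance = 1e-12)
})

test_that("variances scale as 1/N and the unequal-variance form nests the common one", {
  set.seed(404)
  d <- random_design(N = 50)
  d2 <- platform_design(500, d$r, d$p, d$sigma)
  expect_equal(var_stratified_cc(d)$var_arm1,
               10 * var_stratified_cc(d2)$var_arm1, tolerance = 1e-12)
  expect_equal(var_ncc(d)$var_arm2, 10 * var_ncc(d2)$var_arm2,
               tolerance = 1e-12)

  dz <- platform_design(d$N, d$r, d$p, sigma = c(2, 2, 2))
  expect_equal(var_stratified_cc(dz)$var_arm1,
               4 * var_stratified_cc(d)$var_arm1, tolerance = 1e-14)
})

test_that("unequal-sigma variance matches direct weight combination", {
  set.seed(505)
  for (k in 1:10) {
    d <- random_design()
    du <- platform_design(d$N, d$r, d$p, sigma = c(1.3, 2.1, 0.7))
    v <- var_stratified_cc(du)
    for (arm in 1:2) {
      periods <- if (arm == 1) 1:2 else 2:3
      pv <- vapply(periods, function(s) period_effect_variance(du, arm, s),
                   numeric(1))
      w <- stratification_weights(pv[1], pv[2])
      expect_equal(sum(w^2 * pv),
                   if (arm == 1) v$var_arm1 else v$var_arm2,
                   tolerance = 1e-12)
    }
  }
  # equal sigmas reduce exactly to the common-variance formula
  d <- random_design()
  deq <- platform_design(d$N, d$r, d$p, sigma = c(1, 1, 1))
  expect_equal(var_stratified_cc(deq)$var_arm1,
               var_stratified_cc(d)$var_arm1, tolerance = 1e-14)
})

test_that("var_ncc rejects unequal sigmas and degenerate r1", {
  d <- random_design()
  du <- platform_design(d$N, d$r, d$p, sigma = c(1, 2, 1))
  expect_error(var_ncc(du), class = "platalloc_unsupported")
  d0 <- platform_design(10, c(0, 1, 0),
                        rbind(c(0, 0, 0), c(1, 1, 1) / 3, c(0, 0, 0)))
  expect_error(var_ncc(d0), class = "platalloc_invalid_design")
})

test_that("the non-concurrent correction coefficient follows the harmonic form", {
  expect_equal(rho_coefficient(10, 10, 10, 10), 1 / 4)
  expect_equal(rho_coefficient(10, 20, 10, 20), 1 / 6, tolerance = 1e-12)
  expect_lt(rho_coefficient(10, 1e9, 10, 10), 1e-6)  # huge n02: rho -> 0
  expect_error(rho_coefficient(0, 10, 10, 10), class = "platalloc_inestimable")
})

test_that("design files round-trip through YAML and JSON", {
  d <- platform_design(92, c(.25, .75, 0),
                       rbind(c(.5, .5, 0), c(1, 1, 1) / 3, c(0, 0, 0)),
                       sigma = c(1, 1, 1))
  spec <- list(N = 92, r = c(.25, .75, 0),
               p = list(c(.5, .5, 0), c(1, 1, 1) / 3, c(0, 0, 0)),
               sigma = c(1, 1, 1), analysis = "ncc")
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(spec, fy)
  dy <- read_design(fy)
  expect_equal(dy$p, d$p, tolerance = 1e-9)
  expect_identical(attr(dy, "analysis"), "ncc")
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(spec, fj, auto_unbox = TRUE, digits = NA)
  dj <- read_design(fj)
  expect_equal(dj$p, d$p, tolerance = 1e-9)
})
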