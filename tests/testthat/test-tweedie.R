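test_that("intercept-only fit on constant data is exact", {
  df <- data.frame(y = rep(2.5, 20))
  fit <- fit_tweedie_glm(df, y ~ 1)
  expect_equal(unname(coef(fit)), log(2.5), tolerance = 1e-10)
  expect_true(fit$converged)
  # score equation at convergence: weighted residuals sum to zero
  expect_lt(abs(sum((fit$y - fit$fitted) / fit$fitted^(fit$power - 1))),
            1e-6)
})

test_that("the IRLS fit matches an independent Tweedie GLM implementation", {
  library(mgcv)
  cat4 <- toy_catalog()
  tbl <- simulate_foraging(foraging_sim_params(catalog = cat4), n = 400,
                           seed = 61)
  dat <- prepare_foraging_data(tbl, cat4)
  form <- foraging_formula("bite_rate")
  mine <- fit_tweedie_glm(dat, form, power = 1.5)
  ref <- mgcv::gam(form, family = mgcv::Tweedie(p = 1.5, link = "log"),
                   data = dat)
  # agreement is limited by the two optimizers' stopping rules (~1e-5)
  expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(mine$dispersion, ref$scale, tolerance = 1e-3)
  expect_equal(unname(sqrt(diag(vcov(mine)))),
               unname(summary(ref)$se), tolerance = 1e-4)
})

test_that("near the gamma limit the fit matches a gamma GLM", {
  set.seed(67)
  x <- runif(500, 0, 4)
  mu <- exp(1 + 0.5 * x)
  y <- rgamma(500, shape = 2, scale = mu / 2)
  d <- data.frame(y = y, x = x)
  tw <- fit_tweedie_glm(d, y ~ x, power = 1.999)
  gam_glm <- stats::glm(y ~ x, family = Gamma(link = "log"), data = d)
  expect_equal(unname(coef(tw)), unname(coef(gam_glm)), tolerance = 1e-3)
})

test_that("fits are deterministic and respect model nesting", {
  cat4 <- toy_catalog()
  dat <- prepare_foraging_data(
    simulate_foraging(foraging_sim_params(catalog = cat4), n = 300,
                      seed = 71), cat4)
  f1 <- fit_tweedie_glm(dat, foraging_formula("bite_rate"), power = 1.5)
  f2 <- fit_tweedie_glm(dat, foraging_formula("bite_rate"), power = 1.5)
  expect_identical(coef(f1), coef(f2))
  # dropping the three-way interaction cannot decrease deviance
  reduced <- fit_tweedie_glm(
    dat, bite_rate ~ (origin + shoal_size + shoal_type)^2 + length_cm,
    power = 1.5)
  expect_gte(reduced$deviance, f1$deviance - 1e-8)
})

test_that("rank-deficient designs are refused with the aliased term named", {
  d <- data.frame(y = rgamma(30, 2), a = rnorm(30))
  d$b <- 2 * d$a
  expect_error(fit_tweedie_glm(d, y ~ a + b, power = 1.5), "\\bb\\b")
})

test_that("coefficients recover the generating values on synthetic data", {
  params <- foraging_sim_params()
  tbl <- simulate_foraging(params, n = 2000, seed = 73)
  dat <- prepare_foraging_data(tbl, default_catalog())
  fit <- fit_tweedie_glm(dat, foraging_formula("bite_rate"), power = 1.5)
  truth <- c(`(Intercept)` = params$beta[["intercept"]],
             originnative = params$beta[["origin_native"]],
             shoal_size = params$beta[["size"]],
             shoal_typemulti_specific = params$beta[["type_multi"]],
             length_cm = params$beta[["length"]],
             `originnative:shoal_size` = params$beta[["size_x_native"]],
             `originnative:shoal_typemulti_specific` =
               params$beta[["native_x_multi"]],
             `shoal_size:shoal_typemulti_specific` =
               params$beta[["size_x_multi"]],
             `originnative:shoal_size:shoal_typemulti_specific` =
               params$beta[["size_x_native_x_multi"]])
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - truth[names(coef(fit))]) <= 3 * se))
})

test_that("per-cell slopes and ratios are the right coefficient combinations", {
  params <- foraging_sim_params()
  tbl <- simulate_foraging(params, n = 2000, seed = 79)
  dat <- prepare_foraging_data(tbl, default_catalog())
  fit <- fit_tweedie_glm(dat, foraging_formula("bite_rate"), power = 1.5)
  gsc <- group_slopes_and_contrasts(fit, at_shoal_size = 3)
  b <- coef(fit)
  # hand-built slope for the native x multi cell
  want <- b[["shoal_size"]] + b[["originnative:shoal_size"]] +
    b[["shoal_size:shoal_typemulti_specific"]] +
    b[["originnative:shoal_size:shoal_typemulti_specific"]]
  got <- gsc$slopes$slope[gsc$slopes$origin == "native" &
                            gsc$slopes$shoal_type == "multi_specific"]
  expect_equal(got, want, tolerance = 1e-12)
  # ratio native/range-extending in mono shoals at size 3:
  # exp(origin effect + 3 * slope difference), length cancels
  lr <- b[["originnative"]] + 3 * b[["originnative:shoal_size"]]
  row <- gsc$rate_ratios[gsc$rate_ratios$contrast ==
                           "range_extending.mono_specific - native.mono_specific", ]
  expect_equal(row$ratio, exp(-lr), tolerance = 1e-12)
})

test_that("equal generating slopes rarely yield significant slope contrasts", {
  params <- foraging_sim_params(
    beta = c(size = 0.02, size_x_native = 0, size_x_multi = 0,
             size_x_native_x_multi = 0))
  n_sig <- withr::with_seed(83, sum(vapply(1:10, function(r) {
    tbl <- simulate_foraging(params, n = 1000, seed = NULL)
    dat <- prepare_foraging_data(tbl, default_catalog())
    fit <- fit_tweedie_glm(dat, foraging_formula("bite_rate"), power = 1.5)
    any(group_slopes_and_contrasts(fit)$slope_contrasts$p_adj < 0.05)
  }, logical(1))))
  expect_lte(n_sig, 2)  # ~5% familywise rate expected
})

test_that("power profiling orders datasets by their variance exponent", {
  grid <- seq(1.15, 1.85, by = 0.1)
  correct <- withr::with_seed(89, vapply(1:8, function(r) {
    n <- 1500
    x <- runif(n, 0, 3)
    mu <- exp(2 + 0.3 * x)
    d_lo <- data.frame(y = rtweedie(n, mu, 1.3, 1.2), x = x)
    d_hi <- data.frame(y = rtweedie(n, mu, 1.7, 1.2), x = x)
    p_lo <- profile_power(d_lo, y ~ x, grid = grid)$best_p
    p_hi <- profile_power(d_hi, y ~ x, grid = grid)$best_p
    p_lo < p_hi
  }, logical(1)))
  expect_gte(sum(correct), 6)

  # degenerate grid returns that power; zeros keep the objective finite
  d <- data.frame(y = c(0, 0, 1.5, 3, 0.2), x = 1:5)
  pp <- profile_power(d, y ~ 1, grid = 1.4)
  expect_equal(pp$best_p, 1.4)
  expect_true(all(is.finite(pp$profile$objective)))
})

test_that("rate summaries compute mean and standard error per origin", {
  cat4 <- toy_catalog()
  tbl <- data.frame(individual_id = c("a", "b", "c"),
                    species = c("sp1", "sp1", "sp3"), length_cm = 15,
                    shoal_size = 3, shoal_type = "mono_specific",
                    location_id = "L1", observer_id = "O1",
                    duration_s = 60, n_bites = c(10L, 30L, 12L),
                    n_bouts = c(2L, 6L, 3L), stringsAsFactors = FALSE)
  out <- summarize_rates(tbl, cat4)
  nat <- out[out$origin == "native", ]
  expect_equal(nat$bite_mean, 20)
  expect_equal(nat$bite_se, 10)
  re <- out[out$origin == "range_extending", ]
  expect_equal(re$bite_se, 0)  # single observation
})
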