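test_that("composition distribution matches hand-computed laws", {
  cat4 <- toy_catalog()
  # all thetas zero: the 15 non-empty subsets are equiprobable
  p0 <- assembly_params(cat4, theta_single = stats::setNames(rep(0, 4),
                                                             names(cat4)),
                        theta_pair = matrix(0, 4, 4))
  d0 <- composition_distribution(p0)
  expect_equal(nrow(d0$members), 15L)
  expect_equal(d0$prob, rep(1 / 15, 15))

  # two species, pair affinity log 2: weights 1, 1, 2 -> 1/4, 1/4, 1/2
  cat2 <- species_catalog(c(A = "native", B = "range_extending"))
  tp <- matrix(c(0, log(2), log(2), 0), 2, dimnames = list(c("A", "B"),
                                                           c("A", "B")))
  d2 <- composition_distribution(
    assembly_params(cat2, theta_single = c(A = 0, B = 0), theta_pair = tp,
                    size_law = data.frame(origin_config = c("native_only",
                                                            "range_extending_only",
                                                            "mixed_origin"),
                                          log_mean = 1.5, log_sd = 0.5)))
  both <- rowSums(d2$members) == 2
  expect_equal(d2$prob[both], 0.5)
  expect_equal(d2$prob[!both], c(0.25, 0.25))

  # normalization holds for arbitrary parameters
  set.seed(4)
  pr <- assembly_params(cat4,
                        theta_single = stats::setNames(rnorm(4), names(cat4)),
                        theta_pair = {
                          m <- matrix(0, 4, 4); m[upper.tri(m)] <- rnorm(6)
                          m + t(m)
                        })
  expect_equal(sum(composition_distribution(pr)$prob), 1, tolerance = 1e-12)
})

test_that("simulated shoal compositions follow the exact law", {
  cat4 <- toy_catalog()
  params <- assembly_params(cat4)
  d <- composition_distribution(params)
  tbl <- simulate_shoals(params, n_shoals = 5000, seed = 21)
  # goodness of fit of empirical subset frequencies at the 1% level
  pres <- as.matrix(tbl[, d$species]) >= 1
  key <- apply(pres, 1, function(z) paste(as.integer(z), collapse = ""))
  all_keys <- apply(d$members, 1, paste, collapse = "")
  obs <- table(factor(key, levels = all_keys))
  gof <- suppressWarnings(stats::chisq.test(obs, p = d$prob))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated shoals respect size bounds and determinism", {
  params <- assembly_params(toy_catalog())
  a <- simulate_shoals(params, 200, seed = 9)
  b <- simulate_shoals(params, 200, seed = 9)
  expect_identical(a, b)
  sz <- shoal_sizes(a)
  expect_true(all(sz >= 2 & sz <= 50))
  # every member species has at least one individual
  pres <- as.matrix(a[, shoal_species(a)])
  expect_true(all(pres[pres > 0] >= 1))
  expect_false(identical(a, simulate_shoals(params, 200, seed = 10)))
})

test_that("positive pair affinity produces positive association downstream", {
  cat2p <- toy_catalog()
  tp <- matrix(0, 4, 4, dimnames = list(names(cat2p), names(cat2p)))
  tp["sp1", "sp2"] <- tp["sp2", "sp1"] <- 2
  params <- assembly_params(cat2p,
                            theta_single = stats::setNames(rep(0, 4),
                                                           names(cat2p)),
                            theta_pair = tp)
  alphas <- withr::with_seed(31, vapply(1:50, function(r) {
    tbl <- simulate_shoals(params, 150, seed = NULL)
    m <- build_presence_matrix(tbl, cat2p)
    a <- association_strength(m, method = "analytic")
    a$alpha[a$species_a == "sp1" & a$species_b == "sp2"]
  }, numeric(1)))
  expect_gt(mean(alphas), 0)
})

test_that("the Tweedie sampler has the compound-Poisson-gamma moments", {
  mu <- 30; p <- 1.5; phi <- 1.5; n <- 1e5
  x <- withr::with_seed(41, rtweedie(n, mu, p, phi))
  se_mean <- sqrt(phi * mu^p / n)
  expect_lt(abs(mean(x) - mu), 3 * se_mean)
  expect_lt(abs(var(x) / (phi * mu^p) - 1), 0.05)
  # zero mass matches exp(-lambda)
  lambda <- mu^(2 - p) / (phi * (2 - p))
  expect_lt(abs(mean(x == 0) - exp(-lambda)), 3 * sqrt(exp(-lambda) / n) + 1e-4)

  # near-deterministic limit: variance tracks the variance function
  y <- withr::with_seed(42, rtweedie(1e5, 10, 1.5, 1e-3))
  expect_lt(abs(var(y) / (1e-3 * 10^1.5) - 1), 0.05)

  expect_identical(withr::with_seed(7, rtweedie(50, 5, 1.5, 2)),
                   withr::with_seed(7, rtweedie(50, 5, 1.5, 2)))
  expect_error(rtweedie(5, 10, power = 2.3), "power")
  expect_error(rtweedie(5, -1), "mu")
})

test_that("simulated foraging observations center on the intended mean", {
  cat4 <- toy_catalog()
  # flat model: intercept log(30) only
  params <- foraging_sim_params(
    beta = c(intercept = log(30), origin_native = 0, type_multi = 0,
             size = 0, size_x_native = 0, size_x_multi = 0,
             native_x_multi = 0, size_x_native_x_multi = 0, length = 0),
    catalog = cat4)
  tbl <- simulate_foraging(params, n = 2000, seed = 13)
  rates <- compute_rates(tbl)$bite_rate
  se <- sqrt(1.5 * 30^1.5 / 2000)
  expect_lt(abs(mean(rates) - 30), 3 * se + 0.5)  # 0.5 covers count rounding
  expect_true(all(tbl$n_bouts <= tbl$n_bites))
  expect_identical(tbl, simulate_foraging(params, n = 2000, seed = 13))
})
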