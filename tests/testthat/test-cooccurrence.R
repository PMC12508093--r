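test_that("presence matrix construction matches the records", {
  cat4 <- toy_catalog()
  tbl <- toy_shoal_table(list(c(sp1 = 2), c(sp2 = 3), c(sp1 = 1, sp2 = 4)))
  m <- suppressMessages(build_presence_matrix(tbl, cat4))
  expect_equal(m["sp1", ], c(t001 = 1L, t002 = 0L, t003 = 1L))
  expect_equal(m["sp2", ], c(t001 = 0L, t002 = 1L, t003 = 1L))
  # species never observed are dropped, so no all-zero rows
  expect_equal(rownames(m), c("sp1", "sp2"))
  # row sums = occurrence frequencies, column sums = richness
  expect_equal(unname(rowSums(m)), c(2, 2))
  expect_equal(unname(colSums(m)), c(1, 1, 2))

  dup <- tbl; dup$shoal_id[2] <- dup$shoal_id[1]
  expect_error(suppressMessages(build_presence_matrix(dup, cat4)),
               "duplicated")
})

test_that("fixed-row randomization preserves row sums and is marginally uniform", {
  set.seed(17)
  m <- matrix(rbinom(5 * 30, 1, 0.4), 5, 30,
              dimnames = list(paste0("sp", 1:5), paste0("s", 1:30)))
  r <- rowSums(m)
  B <- 2000
  occupancy <- matrix(0, nrow(m), ncol(m))
  for (b in seq_len(B)) {
    rm <- randomize_fixed_rows(m)
    expect_identical(rowSums(rm), r)
    occupancy <- occupancy + rm
  }
  # each cell occupied with frequency ~ r_i / n, within binomial error
  for (i in seq_len(nrow(m))) {
    p <- r[i] / ncol(m)
    tol <- 4 * sqrt(p * (1 - p) / B)
    expect_true(all(abs(occupancy[i, ] / B - p) <= tol))
  }
})

test_that("pair co-occurrence counts columns shared by both rows", {
  mk <- function(...) {
    rows <- list(...)
    matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
           dimnames = list(paste0("sp", seq_along(rows)), NULL))
  }
  expect_equal(pair_cooccurrence(mk(c(1, 1, 0, 0), c(0, 0, 1, 1)))$observed, 0)
  expect_equal(pair_cooccurrence(mk(c(1, 0, 1, 1), c(1, 0, 1, 1)))$observed, 3)
  expect_equal(pair_cooccurrence(mk(c(1, 1, 1, 0, 0),
                                    c(1, 1, 0, 1, 0)))$observed, 2)
  expect_error(pair_cooccurrence(mk(c(1, 0, 1))), "2 species")
})

test_that("closed-form null moments agree with the overlap distribution", {
  ex <- analytic_null_moments(10, 5, 4)
  expect_equal(ex$mu, 2)
  expect_equal(ex$sigma, sqrt(2 / 3), tolerance = 1e-12)
  # against direct summation over the overlap law, across a grid
  for (n in c(5, 12, 37)) for (ra in c(0, 1, floor(n / 2), n))
    for (rb in c(0, 2, n - 1)) {
      got <- analytic_null_moments(n, ra, rb)
      want <- overlap_moments_oracle(n, ra, rb)
      expect_equal(got$mu, want$mu, tolerance = 1e-10)
      expect_equal(got$sigma, want$sigma, tolerance = 1e-10)
    }
  # degenerate margins force the count
  expect_equal(analytic_null_moments(8, 8, 3), list(mu = 3, sigma = 0))
  expect_equal(analytic_null_moments(8, 0, 3), list(mu = 0, sigma = 0))
  expect_error(analytic_null_moments(1, 0, 0), "2 shoals")
})

test_that("association strength reproduces the closed-form example", {
  # two species, each in the same 4 of 8 shoals
  m <- rbind(sp1 = c(1, 1, 1, 1, 0, 0, 0, 0),
             sp2 = c(1, 1, 1, 1, 0, 0, 0, 0))
  a <- association_strength(m, method = "analytic")
  expect_equal(a$observed, 4)
  expect_equal(a$null_mean, 2)
  expect_equal(a$null_sd, 0.7559, tolerance = 1e-4)
  expect_equal(a$alpha, 2.6458, tolerance = 1e-4)
})

test_that("Monte-Carlo moments converge to the analytic ones", {
  set.seed(23)
  m <- matrix(rbinom(4 * 60, 1, 0.5), 4, 60,
              dimnames = list(paste0("sp", 1:4), paste0("s", 1:60)))
  B <- 5000
  mc <- association_strength(m, n_null = B, seed = 99)
  an <- association_strength(m, method = "analytic")
  ok <- !an$degenerate
  z <- abs(mc$alpha[ok] - an$alpha[ok]) /
    sqrt((1 + an$alpha[ok]^2 / 2) / B)
  expect_true(all(z <= 4))
  # reproducibility: identical tables for identical seeds
  expect_identical(mc, association_strength(m, n_null = B, seed = 99))
})

test_that("alpha is invariant to column order and tracks row permutations", {
  set.seed(29)
  m <- matrix(rbinom(4 * 40, 1, 0.5), 4, 40,
              dimnames = list(paste0("sp", 1:4), paste0("s", 1:40)))
  a1 <- association_strength(m, method = "analytic")
  a2 <- association_strength(m[, sample(ncol(m))], method = "analytic")
  expect_equal(a1$alpha, a2$alpha)
  # permuted rows: same values per unordered pair
  perm <- c(3, 1, 4, 2)
  a3 <- association_strength(m[perm, ], method = "analytic")
  key <- function(a) {
    k <- apply(cbind(a$species_a, a$species_b), 1,
               function(x) paste(sort(x), collapse = "|"))
    stats::setNames(a$alpha, k)[order(k)]
  }
  expect_equal(key(a1), key(a3))
})

test_that("degenerate pairs are flagged, not divided by zero", {
  m <- rbind(sp1 = c(1, 1, 1, 1), sp2 = c(1, 0, 1, 0),  # sp1 everywhere
             sp3 = c(0, 1, 1, 0))
  a <- association_strength(m, method = "analytic")
  deg <- a$species_a == "sp1"
  expect_true(all(a$degenerate[deg]))
  expect_true(all(is.na(a$alpha[deg])))
  expect_false(any(a$degenerate[!deg]))
  # forced co-occurrence with a ubiquitous species: mu = r_b
  expect_equal(a$null_mean[a$species_a == "sp1" & a$species_b == "sp2"], 2)
  m2 <- rbind(sp1 = c(1, 1, 1, 1), sp2 = c(1, 1, 1, 1))
  expect_warning(association_strength(m2, method = "analytic"),
                 "degenerate")
})
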