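#' Build a species-by-shoal presence-absence matrix
#'
#' Rows are species, columns are shoals; a cell is 1 when the species had at
#' least one individual in that shoal. Species with no occurrences at all
#' are dropped (with a message), so every row has a positive total. Row sums
#' are per-species occurrence frequencies; column sums are shoal species
#' richness.
#'
#' @param records a shoal table (see [read_shoal_table()]).
#' @param catalog a [species_catalog()]; fixes species order.
#' @return binary matrix with species rownames and shoal_id colnames.
#' @export
build_presence_matrix <- function(records, catalog) {
  stopifnot(nrow(records) >= 1L)
  validate_shoal_table(records, catalog)
  sp <- intersect(names(catalog), shoal_species(records))
  m <- t(as.matrix(records[, sp, drop = FALSE]) >= 1) * 1L
  dimnames(m) <- list(sp, records$shoal_id)
  empty <- rowSums(m) == 0L
  if (any(empty)) {
    message("dropping species never observed: ",
            paste(sp[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  m
}

#' Randomize a presence matrix keeping row totals fixed
#'
#' Each species' presences are reassigned to a uniformly random subset of
#' shoals of the same cardinality, independently across species: row totals
#' (occurrence frequencies) are preserved exactly, column totals are free
#' (empty shoal columns can occur). This is the equiprobable-columns null
#' used for the association-strength index.
#'
#' @param matrix binary presence matrix (species x shoals).
#' @return a randomized matrix of identical dimensions and row sums.
#' @export
randomize_fixed_rows <- function(matrix) {
  n <- ncol(matrix)
  out <- array(0L, dim(matrix), dimnames = dimnames(matrix))
  r <- rowSums(matrix)
  for (i in seq_len(nrow(matrix)))
    if (r[i] > 0L) out[i, sample.int(n, r[i])] <- 1L
  out
}

#' Pairwise co-occurrence counts
#'
#' For every unordered species pair, the number of shoals containing both.
#'
#' @param matrix binary presence matrix (>= 2 species).
#' @return `data.frame` with `species_a`, `species_b`, `observed` (one row
#'   per unordered pair, in row order).
#' @export
pair_cooccurrence <- function(matrix) {
  S <- nrow(matrix)
  if (S < 2L) stop("need at least 2 species", call. = FALSE)
  cross <- tcrossprod(matrix)
  idx <- which(upper.tri(cross), arr.ind = TRUE)
  data.frame(species_a = rownames(matrix)[idx[, 1L]],
             species_b = rownames(matrix)[idx[, 2L]],
             observed = cross[idx], stringsAsFactors = FALSE)
}

#' Closed-form null moments of a pair's co-occurrence count
#'
#' Under the fixed-row-totals / equiprobable-columns null, the two rows are
#' placed independently and uniformly, so the overlap of a pair with `r_a`
#' and `r_b` presences over `n` shoals is hypergeometric:
#' `mu = r_a r_b / n` and
#' `sigma^2 = r_a r_b (n - r_a)(n - r_b) / (n^2 (n - 1))`.
#' These are the exact large-`n_null` limits of the Monte-Carlo moments.
#'
#' @param n_shoals number of shoals (columns), >= 2.
#' @param r_a,r_b row totals of the two species (0..n). Vectorized.
#' @return list with `mu` and `sigma`.
#' @examples
#' analytic_null_moments(10, 5, 4)  # mu = 2, sigma = 0.8165
#' @export
analytic_null_moments <- function(n_shoals, r_a, r_b) {
  if (any(n_shoals < 2L)) stop("need at least 2 shoals", call. = FALSE)
  if (any(r_a < 0 | r_a > n_shoals | r_b < 0 | r_b > n_shoals))
    stop("row totals must lie in [0, n_shoals]", call. = FALSE)
  n <- n_shoals
  mu <- r_a * r_b / n
  v <- r_a * r_b * (n - r_a) * (n - r_b) / (n^2 * (n - 1))
  list(mu = mu, sigma = sqrt(v))
}

# Monte-Carlo null: for each species row, draw its placements for all n_null
# matrices at once (one uniformly random r-subset of the n columns per null),
# then count pair overlaps vectorized across nulls. Chunked to bound memory.
.mc_null_moments <- function(matrix, n_null, chunk = 2000L) {
  S <- nrow(matrix); n <- ncol(matrix)
  r <- rowSums(matrix)
  pairs <- which(upper.tri(diag(S)), arr.ind = TRUE)
  sum1 <- numeric(nrow(pairs)); sum2 <- numeric(nrow(pairs))
  done <- 0L
  while (done < n_null) {
    B <- min(chunk, n_null - done)
    place <- vector("list", S)
    for (i in seq_len(S)) {
      L <- matrix(FALSE, B, n)
      if (r[i] > 0L) {
        cols <- vapply(seq_len(B), function(b) sample.int(n, r[i]),
                       integer(r[i]))
        L[cbind(rep(seq_len(B), each = r[i]), as.integer(cols))] <- TRUE
      }
      place[[i]] <- L
    }
    for (k in seq_len(nrow(pairs))) {
      O <- rowSums(place[[pairs[k, 1L]]] & place[[pairs[k, 2L]]])
      sum1[k] <- sum1[k] + sum(O)
      sum2[k] <- sum2[k] + sum(O * O)
    }
    done <- done + B
  }
  mu <- sum1 / n_null
  v <- (sum2 - n_null * mu^2) / (n_null - 1)
  list(mu = mu, sigma = sqrt(pmax(v, 0)), pairs = pairs)
}

#' Pairwise association strength (standardized effect size)
#'
#' For every unordered species pair, compares the observed co-occurrence
#' count `O` with its distribution under the fixed-row-totals null and
#' returns the dimensionless index `alpha = (O - mu) / sigma`: positive
#' values indicate stronger-than-chance association, negative values
#' avoidance, zero neutrality. `mu` and `sigma` are either the empirical
#' mean and SD of `O` over `n_null` randomized matrices (`method =
#' "montecarlo"`, the field-standard procedure) or the closed-form
#' hypergeometric moments (`method = "analytic"`, exact and instantaneous).
#'
#' Pairs whose null SD is zero (a species present in every shoal or in
#' none) are flagged `degenerate` and get `alpha = NA` rather than a
#' division by zero.
#'
#' @param matrix binary presence matrix from [build_presence_matrix()].
#' @param n_null number of null matrices for the Monte-Carlo method
#'   (default 1000).
#' @param method `"montecarlo"` or `"analytic"`.
#' @param seed RNG seed for the Monte-Carlo draw; same seed, identical
#'   result table.
#' @return `data.frame` with one row per pair: `species_a`, `species_b`,
#'   `observed`, `null_mean`, `null_sd`, `alpha`, `n_null`, `method`,
#'   `degenerate`.
#' @examples
#' cat4 <- default_catalog()
#' tbl <- simulate_shoals(assembly_params(cat4), n_shoals = 100, seed = 7)
#' m <- build_presence_matrix(tbl, cat4)
#' association_strength(m, method = "analytic")
#' @export
association_strength <- function(matrix, n_null = 1000L,
                                 method = c("montecarlo", "analytic"),
                                 seed = NULL) {
  method <- match.arg(method)
  if (nrow(matrix) < 2L) stop("need at least 2 species", call. = FALSE)
  obs <- pair_cooccurrence(matrix)
  r <- rowSums(matrix)
  n <- ncol(matrix)
  if (method == "analytic") {
    idx <- which(upper.tri(diag(nrow(matrix))), arr.ind = TRUE)
    mom <- analytic_null_moments(n, r[idx[, 1L]], r[idx[, 2L]])
    mu <- mom$mu; sigma <- mom$sigma
    n_used <- NA_integer_
  } else {
    if (n_null < 2L) stop("montecarlo needs n_null >= 2", call. = FALSE)
    mc <- if (!is.null(seed)) {
      withr::with_seed(seed, .mc_null_moments(matrix, n_null))
    } else .mc_null_moments(matrix, n_null)
    mu <- mc$mu; sigma <- mc$sigma
    n_used <- as.integer(n_null)
  }
  degen <- sigma == 0
  alpha <- ifelse(degen, NA_real_, (obs$observed - mu) / sigma)
  if (all(degen))
    warning("all pairs degenerate (zero null SD); alpha undefined",
            call. = FALSE)
  data.frame(obs, null_mean = mu, null_sd = sigma, alpha = alpha,
             n_null = n_used, method = method, degenerate = degen,
             stringsAsFactors = FALSE)
}
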