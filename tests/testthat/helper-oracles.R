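# small fixture builders and independent oracles used across test files

toy_catalog <- function() {
  species_catalog(c(sp1 = "native", sp2 = "native",
                    sp3 = "range_extending", sp4 = "range_extending"))
}

# wide shoal table from a list of named count vectors
toy_shoal_table <- function(counts_list, catalog = toy_catalog()) {
  sp <- names(catalog)
  rows <- lapply(counts_list, function(cc) {
    v <- stats::setNames(rep(0L, length(sp)), sp)
    v[names(cc)] <- as.integer(cc)
    v
  })
  m <- do.call(rbind, rows)
  data.frame(shoal_id = sprintf("t%03d", seq_along(counts_list)),
             location_id = "L1", observer_id = "O1",
             as.data.frame(m), stringsAsFactors = FALSE)
}

# exhaustive-enumeration Fisher p-value: hypergeometric probabilities built
# from log-binomial coefficients, probability ordering with the customary
# relative tie tolerance
fisher_p_oracle <- function(m) {
  r1 <- m[1, 1] + m[1, 2]; r2 <- m[2, 1] + m[2, 2]; c1 <- m[1, 1] + m[2, 1]
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1))
  p_obs <- pr[m[1, 1] - support[1] + 1L]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# null moments of the pair overlap by direct summation over the overlap
# distribution P(O = k) = C(r_a, k) C(n - r_a, r_b - k) / C(n, r_b)
overlap_moments_oracle <- function(n, r_a, r_b) {
  k <- max(0, r_a + r_b - n):min(r_a, r_b)
  pk <- exp(lchoose(r_a, k) + lchoose(n - r_a, r_b - k) - lchoose(n, r_b))
  mu <- sum(k * pk)
  list(mu = mu, sigma = sqrt(sum((k - mu)^2 * pk)))
}
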