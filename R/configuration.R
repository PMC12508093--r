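#' Classify shoals by species origin and shoal type
#'
#' Each shoal is labelled by its origin configuration — `native_only`,
#' `range_extending_only`, or `mixed_origin` when it contains at least one
#' species of each origin — and by shoal type: `multi_specific` when two or
#' more species are present, `mono_specific` otherwise. A mixed-origin
#' shoal is necessarily multi-specific.
#'
#' @param records a shoal table.
#' @param catalog a [species_catalog()].
#' @return `data.frame` with `shoal_id`, `origin_config` (factor),
#'   `shoal_type` (factor), `shoal_size`.
#' @export
classify_shoals <- function(records, catalog) {
  validate_shoal_table(records, catalog)
  sp <- shoal_species(records)
  origins <- species_origin(catalog, sp)
  present <- as.matrix(records[, sp, drop = FALSE]) >= 1
  has_native <- rowSums(present[, origins == "native", drop = FALSE]) > 0
  has_re <- rowSums(present[, origins == "range_extending", drop = FALSE]) > 0
  cfg <- ifelse(has_native & has_re, "mixed_origin",
                ifelse(has_native, "native_only", "range_extending_only"))
  n_sp <- rowSums(present)
  data.frame(
    shoal_id = records$shoal_id,
    origin_config = factor(cfg, levels = c("native_only",
                                           "range_extending_only",
                                           "mixed_origin")),
    shoal_type = factor(ifelse(n_sp >= 2, "multi_specific", "mono_specific"),
                        levels = c("mono_specific", "multi_specific")),
    shoal_size = shoal_sizes(records),
    stringsAsFactors = FALSE
  )
}

#' Frequencies of shoal configurations
#'
#' Counts and percentages of shoals per origin configuration, and the full
#' origin-configuration by shoal-type cross-tabulation.
#'
#' @param classifications output of [classify_shoals()].
#' @return list with `by_origin` (`data.frame`: `origin_config`, `n`,
#'   `pct`), `by_origin_type` (`data.frame`: `origin_config`, `shoal_type`,
#'   `n`, `pct`) and `n_total`. Percentages are of all shoals and sum
#'   to 100.
#' @export
configuration_frequencies <- function(classifications) {
  stopifnot(nrow(classifications) >= 1L)
  n <- nrow(classifications)
  t1 <- table(classifications$origin_config)
  by_origin <- data.frame(origin_config = names(t1), n = as.integer(t1),
                          pct = 100 * as.integer(t1) / n,
                          stringsAsFactors = FALSE)
  t2 <- table(classifications$origin_config, classifications$shoal_type)
  by_ot <- as.data.frame(t2, stringsAsFactors = FALSE)
  names(by_ot) <- c("origin_config", "shoal_type", "n")
  by_ot$pct <- 100 * by_ot$n / n
  list(by_origin = by_origin, by_origin_type = by_ot, n_total = n)
}

#' 2x2 table: same-origin multi-specific shoaling by origin
#'
#' Among single-origin shoals, cross-tabulates origin (native-only vs
#' range-extending-only) against shoal type (multi- vs mono-specific). This
#' is the table behind the exact and chi-squared tests of whether
#' range-extenders shoal with heterospecifics of their own origin more
#' often than natives do. Mixed-origin shoals are excluded by construction.
#'
#' @param classifications output of [classify_shoals()].
#' @return 2x2 integer matrix, rows `native` / `range_extending`, columns
#'   `multi_specific` / `mono_specific`.
#' @export
multispecific_origin_table <- function(classifications) {
  sub <- classifications[classifications$origin_config != "mixed_origin", ]
  m <- matrix(c(
    sum(sub$origin_config == "native_only" & sub$shoal_type == "multi_specific"),
    sum(sub$origin_config == "native_only" & sub$shoal_type == "mono_specific"),
    sum(sub$origin_config == "range_extending_only" & sub$shoal_type == "multi_specific"),
    sum(sub$origin_config == "range_extending_only" & sub$shoal_type == "mono_specific")
  ), nrow = 2L, byrow = TRUE,
  dimnames = list(c("native", "range_extending"),
                  c("multi_specific", "mono_specific")))
  m
}

.as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L)))
    stop("need a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop("table entries must be non-negative integers", call. = FALSE)
  if (sum(m) < 1) stop("table total must be at least 1", call. = FALSE)
  m
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test on the hypergeometric null, with probability
#' ordering: the p-value sums the null probabilities of all tables with the
#' same margins that are no more probable than the observed one (with the
#' customary relative tolerance `1e-7` when comparing probabilities, so
#' floating-point ties count as ties). The odds ratio is the conditional
#' maximum-likelihood estimate and the 95% CI inverts the exact test at
#' 2.5% per tail; the sample cross-product ratio is reported alongside.
#' When a margin is zero the odds ratio is undefined and flagged, but the
#' p-value (1) is still returned.
#'
#' @param table 2x2 matrix or anything coercible to one.
#' @param estimate also compute the conditional-MLE odds ratio and CI
#'   (set `FALSE` when only the p-value is needed, e.g. in bulk runs).
#' @return list with `odds_ratio` (conditional MLE), `sample_or`, `ci95`,
#'   `p`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(table, estimate = TRUE) {
  m <- .as_2x2(table)
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  r1 <- m[1, 1] + m[1, 2]; r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[match(m[1, 1], support)]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (estimate && !degenerate) {
    ft <- stats::fisher.test(m, conf.level = 0.95)
    or <- unname(ft$estimate); ci <- unname(ft$conf.int)
  }
  list(odds_ratio = or,
       sample_or = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]),
       ci95 = ci, p = p, degenerate = degenerate)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' @param table 2x2 matrix; all margins must be positive.
#' @param yates apply the Yates continuity correction (default off).
#' @return list with `statistic`, `df` (1) and `p`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  m <- .as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-squared test undefined with a zero margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(ct$statistic), df = 1L, p = ct$p.value)
}

# compact letter display: groups share a letter iff they are connected in
# the non-significance graph; letters are maximal cliques, assigned from
# the largest group mean downwards
.letter_display <- function(groups, means, nonsig_pairs) {
  k <- length(groups)
  adj <- diag(TRUE, k)
  dimnames(adj) <- list(groups, groups)
  for (i in seq_len(nrow(nonsig_pairs))) {
    a <- nonsig_pairs[i, 1L]; b <- nonsig_pairs[i, 2L]
    adj[a, b] <- adj[b, a] <- TRUE
  }
  ord <- order(-means, groups)
  cliques <- list()
  for (g in ord) {
    covered <- any(vapply(cliques, function(cl) g %in% cl, logical(1)))
    clique <- g
    for (h in ord)
      if (h != g && all(adj[h, clique])) clique <- c(clique, h)
    clique <- sort(clique)
    dup <- any(vapply(cliques, function(cl) identical(cl, clique) ||
                        all(clique %in% cl), logical(1)))
    if (!dup && !(covered && length(clique) == 1L))
      cliques <- c(cliques, list(clique))
  }
  letters_out <- stats::setNames(rep("", k), groups)
  for (j in seq_along(cliques))
    for (g in cliques[[j]])
      letters_out[g] <- paste0(letters_out[g], letters[j])
  letters_out
}

#' Shoal-size model across origin configurations
#'
#' Ordinary least squares on log shoal size with the three-level origin
#' configuration as the single fixed factor (the final reduced model for
#' these data: random location/observer terms and the shoal-type factor
#' contribute negligibly). Returns group means on the log scale, all
#' pairwise Tukey (studentized-range) adjusted contrasts, unadjusted
#' pairwise-t p-values for reference, a compact letter display at the 5%
#' level, and AICs of the reduced and the full (configuration x type)
#' models.
#'
#' @param classifications output of [classify_shoals()]; needs >= 2 groups
#'   with >= 2 observations each.
#' @param alpha significance level for the letter display.
#' @return object of class `shoal_size_fit`: list with `model`,
#'   `group_means`, `contrasts`, `letters`, `aic`.
#' @export
fit_shoal_size_model <- function(classifications, alpha = 0.05) {
  cls <- droplevels(classifications)
  tab <- table(cls$origin_config)
  if (length(tab) < 2L)
    stop("need at least 2 origin-configuration groups", call. = FALSE)
  small <- names(tab)[tab < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  cls$log_size <- log(cls$shoal_size)
  fit <- stats::aov(log_size ~ origin_config, data = cls)
  gm <- tapply(cls$log_size, cls$origin_config, mean)
  group_means <- data.frame(origin_config = names(gm),
                            n = as.integer(tab[names(gm)]),
                            log_mean = as.numeric(gm),
                            mean_size = exp(as.numeric(gm)),
                            stringsAsFactors = FALSE)
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$origin_config
  pt_un <- stats::pairwise.t.test(cls$log_size, cls$origin_config,
                                  p.adjust.method = "none",
                                  pool.sd = TRUE)$p.value
  contrasts <- data.frame(
    contrast = rownames(tk), estimate = tk[, "diff"],
    lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  lookup_p <- function(a, b) {
    if (a %in% rownames(pt_un) && b %in% colnames(pt_un) &&
        !is.na(pt_un[a, b])) pt_un[a, b]
    else if (b %in% rownames(pt_un) && a %in% colnames(pt_un))
      pt_un[b, a]
    else NA_real_
  }
  contrasts$p_unadj <- vapply(strsplit(contrasts$contrast, "-", fixed = TRUE),
                              function(ab) lookup_p(ab[1], ab[2]), numeric(1))
  nonsig <- do.call(rbind, strsplit(
    contrasts$contrast[contrasts$p_adj >= alpha], "-", fixed = TRUE))
  if (is.null(nonsig)) nonsig <- matrix(character(), ncol = 2L)
  lets <- .letter_display(names(gm), as.numeric(gm), nonsig)
  reduced <- stats::lm(log_size ~ origin_config, data = cls)
  aic <- data.frame(model = "configuration_only", aic = stats::AIC(reduced),
                    stringsAsFactors = FALSE)
  if (nlevels(cls$shoal_type) >= 2L) {
    full <- stats::lm(log_size ~ origin_config * shoal_type, data = cls)
    aic <- rbind(aic, data.frame(model = "configuration_x_type",
                                 aic = stats::AIC(full)))
  }
  structure(list(model = fit, group_means = group_means,
                 contrasts = contrasts, letters = lets, aic = aic),
            class = "shoal_size_fit")
}

#' @export
print.shoal_size_fit <- function(x, ...) {
  cat("Shoal-size model: log(size) ~ origin configuration\n\n")
  gm <- x$group_means
  gm$letters <- x$letters[gm$origin_config]
  print(gm, row.names = FALSE, digits = 4)
  cat("\nTukey-adjusted contrasts:\n")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}
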