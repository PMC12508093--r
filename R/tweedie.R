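#' Tweedie deviance
#'
#' Sum of unit deviances
#' `d(y, mu) = 2 [ y^(2-p) / ((1-p)(2-p)) - y mu^(1-p) / (1-p) +
#'                 mu^(2-p) / (2-p) ]`
#' for `1 < p < 2`; zero responses contribute only the last term.
#'
#' @param y non-negative responses.
#' @param mu positive fitted means.
#' @param power Tweedie index in (1, 2).
#' @param total sum over observations (default) or per-observation vector.
#' @return deviance (scalar or vector).
#' @export
tweedie_deviance <- function(y, mu, power, total = TRUE) {
  p <- power
  d <- 2 * (ifelse(y > 0, y^(2 - p) / ((1 - p) * (2 - p)), 0) -
              y * mu^(1 - p) / (1 - p) + mu^(2 - p) / (2 - p))
  if (total) sum(d) else d
}

#' Fit a Tweedie GLM by iteratively reweighted least squares
#'
#' Log-link generalized linear model with Tweedie variance function
#' `V(mu) = mu^p`, `1 < p < 2` — the compound-Poisson-gamma family suited
#' to non-negative rates with exact zeros, such as per-minute bite and bout
#' rates. Fitting is by Fisher scoring / IRLS with working weights
#' `mu^(2-p)`, stopping when the relative deviance change drops below
#' `tol`. The dispersion is the Pearson estimate
#' `phi = sum((y - mu)^2 / mu^p) / (n - k)` and the coefficient covariance
#' is `phi (X' W X)^(-1)`.
#'
#' The canonical foraging-rate model is
#' `bite_rate ~ origin * shoal_size * shoal_type + length_cm`
#' (see [foraging_formula()]); reference levels are `range_extending` and
#' `mono_specific`, so the reported ratios for natives come out below 1
#' when natives forage more slowly.
#'
#' @param data `data.frame` holding response and covariates; for foraging
#'   tables run [prepare_foraging_data()] first.
#' @param formula model formula; the response must be non-negative.
#' @param power Tweedie index `p`, strictly in (1, 2) (default 1.5, the
#'   midpoint of the compound-Poisson range; see [profile_power()]).
#' @param tol relative-deviance convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns the fit with
#'   `converged = FALSE` and a warning.
#' @return object of class `tweedie_fit`: coefficients, `vcov`, `power`,
#'   `dispersion`, `deviance`, `fitted`, `n_iter`, `converged`,
#'   `df_residual`, plus the pieces needed for prediction (`terms`,
#'   `xlevels`).
#' @examples
#' df <- data.frame(y = c(2, 2, 2, 2))
#' coef(fit_tweedie_glm(df, y ~ 1))  # log(2) exactly
#' @export
fit_tweedie_glm <- function(data, formula, power = 1.5, tol = 1e-8,
                            max_iter = 100L) {
  if (power <= 1 || power >= 2)
    stop("power must lie strictly between 1 and 2", call. = FALSE)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0)) stop("response must be non-negative", call. = FALSE)
  if (all(y == 0)) stop("response is identically zero", call. = FALSE)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X); k <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < k) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("design matrix is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  mu <- (y + mean(y)) / 2            # strictly positive start
  eta <- log(mu)
  dev <- tweedie_deviance(y, mu, power)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu^(2 - power)              # log link: (dmu/deta)^2 / V(mu)
    z <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    eta <- drop(X %*% fit$coefficients)
    mu <- exp(eta)
    dev_new <- tweedie_deviance(y, mu, power)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged)
    warning("IRLS did not converge in ", max_iter, " iterations",
            call. = FALSE)
  beta <- fit$coefficients
  w <- mu^(2 - power)
  phi <- sum((y - mu)^2 / mu^power) / (n - k)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- phi * chol2inv(chol(XtWX))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vcov, power = power,
                 dispersion = phi, deviance = dev, fitted = mu,
                 linear_predictors = eta, y = y, n = n,
                 df_residual = n - k, n_iter = iter, converged = converged,
                 formula = formula, terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf)),
            class = "tweedie_fit")
}

#' @export
coef.tweedie_fit <- function(object, ...) object$coefficients

#' @export
vcov.tweedie_fit <- function(object, ...) object$vcov

#' @export
print.tweedie_fit <- function(x, ...) {
  cat("Tweedie GLM (log link), p =", format(x$power), " phi =",
      format(x$dispersion, digits = 4), "\n")
  cat("Deviance:", format(x$deviance, digits = 6), " iterations:",
      x$n_iter, if (!x$converged) "(NOT converged)" else "", "\n\n")
  se <- sqrt(diag(x$vcov))
  tval <- x$coefficients / se
  pval <- 2 * stats::pt(abs(tval), x$df_residual, lower.tail = FALSE)
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = se,
               `t value` = tval, `Pr(>|t|)` = pval)
  stats::printCoefmat(tab, digits = 4)
  invisible(x)
}

#' Canonical foraging-rate model formula
#'
#' @param response `"bite_rate"` or `"bout_rate"`.
#' @param species_term include species identity as an additional fixed
#'   covariate (off by default).
#' @param length_term include body length (on by default).
#' @return a formula `response ~ origin * shoal_size * shoal_type [+ ...]`.
#' @export
foraging_formula <- function(response = c("bite_rate", "bout_rate"),
                             species_term = FALSE, length_term = TRUE) {
  response <- match.arg(response)
  rhs <- "origin * shoal_size * shoal_type"
  if (length_term) rhs <- paste(rhs, "+ length_cm")
  if (species_term) rhs <- paste(rhs, "+ species")
  stats::as.formula(paste(response, "~", rhs))
}

#' Prepare a foraging table for model fitting
#'
#' Adds per-minute rates, the origin factor from the catalog (reference
#' level `range_extending`) and the shoal-type factor (reference
#' `mono_specific`).
#'
#' @param records a foraging table (usually the `kept` part of
#'   [filter_foraging_records()]).
#' @param catalog a [species_catalog()].
#' @param ref_origin,ref_type reference factor levels.
#' @return the table with `bite_rate`, `bout_rate`, `origin`, and factor
#'   codings applied.
#' @export
prepare_foraging_data <- function(records, catalog,
                                  ref_origin = "range_extending",
                                  ref_type = "mono_specific") {
  records <- compute_rates(records)
  records$origin <- stats::relevel(
    factor(species_origin(catalog, records$species),
           levels = c("native", "range_extending")), ref = ref_origin)
  records$shoal_type <- stats::relevel(
    factor(records$shoal_type,
           levels = c("mono_specific", "multi_specific")), ref = ref_type)
  records$species <- factor(records$species)
  records
}

#' Profile the Tweedie power index over a grid
#'
#' Refits the model at each candidate `p` and scores it with the extended
#' quasi-likelihood objective
#' `sum_i d_i / phi + sum_i log(2 pi phi max(y_i, eps)^p)`,
#' where `d_i` are unit deviances, `phi` the Pearson dispersion at that
#' `p`, and `eps` a small guard so exact zeros stay finite. Returns the
#' minimizing `p` and the full profile.
#'
#' @param data,formula as in [fit_tweedie_glm()].
#' @param grid candidate powers, all strictly in (1, 2).
#' @param eps zero guard in the log-variance term.
#' @return list with `best_p`, `profile` (`data.frame`: `power`,
#'   `objective`, `dispersion`), and `best_fit`.
#' @export
profile_power <- function(data, formula, grid = seq(1.1, 1.9, by = 0.1),
                          eps = 1e-6) {
  stopifnot(length(grid) >= 1L, all(grid > 1), all(grid < 2))
  rows <- lapply(grid, function(p) {
    fit <- fit_tweedie_glm(data, formula, power = p)
    d <- tweedie_deviance(fit$y, fit$fitted, p, total = FALSE)
    phi <- fit$dispersion
    obj <- sum(d) / phi + sum(log(2 * pi * phi * pmax(fit$y, eps)^p))
    list(power = p, objective = obj, dispersion = phi, fit = fit)
  })
  profile <- data.frame(power = vapply(rows, `[[`, numeric(1), "power"),
                        objective = vapply(rows, `[[`, numeric(1), "objective"),
                        dispersion = vapply(rows, `[[`, numeric(1), "dispersion"))
  best <- which.min(profile$objective)
  list(best_p = profile$power[best], profile = profile,
       best_fit = rows[[best]]$fit)
}

#' Mean and standard error of rates by species origin
#'
#' @param records a foraging table (rates are computed if absent).
#' @return `data.frame` with, per origin group, the arithmetic mean and
#'   standard error (`sd / sqrt(n)`) of bite and bout rates.
#' @param catalog a [species_catalog()] (needed when `records` lacks an
#'   `origin` column).
#' @export
summarize_rates <- function(records, catalog = NULL) {
  stopifnot(nrow(records) >= 1L)
  if (is.null(records$bite_rate)) records <- compute_rates(records)
  if (is.null(records$origin)) {
    if (is.null(catalog))
      stop("supply a catalog to derive species origins", call. = FALSE)
    records$origin <- species_origin(catalog, records$species)
  }
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  agg <- function(v) {
    data.frame(mean = tapply(v, records$origin, mean),
               se = tapply(v, records$origin, se))
  }
  a <- agg(records$bite_rate); b <- agg(records$bout_rate)
  data.frame(origin = rownames(a), n = as.integer(table(records$origin)[rownames(a)]),
             bite_mean = a$mean, bite_se = a$se,
             bout_mean = b$mean, bout_se = b$se,
             stringsAsFactors = FALSE, row.names = NULL)
}
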