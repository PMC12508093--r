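# model-matrix rows for arbitrary origin x type cells, used to build
# linear combinations of coefficients; any covariate not varied is held
# fixed and cancels in the differences taken below
.cell_model_rows <- function(fit, origin, shoal_type, shoal_size) {
  tt <- stats::delete.response(fit$terms)
  vars <- all.vars(tt)
  nd <- data.frame(origin = origin, shoal_type = shoal_type,
                   shoal_size = shoal_size, stringsAsFactors = FALSE)
  nd$origin <- factor(nd$origin, levels = fit$xlevels$origin)
  nd$shoal_type <- factor(nd$shoal_type, levels = fit$xlevels$shoal_type)
  for (v in setdiff(vars, names(nd))) {
    nd[[v]] <- if (v %in% names(fit$xlevels))
      factor(fit$xlevels[[v]][1L], levels = fit$xlevels[[v]]) else 0
  }
  stats::model.matrix(tt, nd, xlev = fit$xlevels)
}

.tukey_p <- function(tstat, nmeans, df) {
  stats::ptukey(sqrt(2) * abs(tstat), nmeans = nmeans, df = df,
                lower.tail = FALSE)
}

#' Per-cell shoal-size slopes, slope contrasts and rate ratios
#'
#' From a fitted three-way Tweedie model, derives for each origin by
#' shoal-type cell the shoal-size slope on the log-link scale (expected
#' proportional change in rate per added shoal member), all pairwise
#' slope-difference contrasts, and the between-cell rate ratios at a
#' reference shoal size (default 3, about the smallest groups observed).
#' Standard errors come from the delta method on the coefficient
#' covariance; p-values are Tukey-adjusted over the four-cell family by
#' the studentized-range method.
#'
#' @param fit a converged [fit_tweedie_glm()] whose design includes the
#'   `origin * shoal_size * shoal_type` interaction.
#' @param at_shoal_size reference shoal size for the rate ratios.
#' @return list with `slopes` (`origin`, `shoal_type`, `slope`, `se`),
#'   `slope_contrasts` (`contrast`, `estimate`, `se`, `t`, `p_adj`),
#'   `rate_ratios` (`contrast`, `ratio`, `log_ratio`, `se_log`, `t`,
#'   `p_adj`) and `at_shoal_size`.
#' @export
group_slopes_and_contrasts <- function(fit, at_shoal_size = 3) {
  stopifnot(inherits(fit, "tweedie_fit"))
  if (!fit$converged)
    warning("fit did not converge; contrasts may be unreliable",
            call. = FALSE)
  needed <- c("origin", "shoal_type")
  if (!all(needed %in% names(fit$xlevels)) ||
      !("shoal_size" %in% all.vars(fit$terms)))
    stop("fit must include origin, shoal_size and shoal_type", call. = FALSE)
  cells <- expand.grid(origin = fit$xlevels$origin,
                       shoal_type = fit$xlevels$shoal_type,
                       stringsAsFactors = FALSE)
  ncell <- nrow(cells)
  beta <- fit$coefficients
  V <- fit$vcov
  # slope of cell c = lp(c, s+1) - lp(c, s); linear in beta
  X1 <- .cell_model_rows(fit, cells$origin, cells$shoal_type,
                         at_shoal_size + 1)
  X0 <- .cell_model_rows(fit, cells$origin, cells$shoal_type, at_shoal_size)
  Ls <- X1 - X0
  slope <- drop(Ls %*% beta)
  slope_se <- sqrt(rowSums((Ls %*% V) * Ls))
  cell_label <- paste(cells$origin, cells$shoal_type, sep = ".")
  slopes <- data.frame(origin = cells$origin, shoal_type = cells$shoal_type,
                       slope = slope, se = slope_se,
                       stringsAsFactors = FALSE)
  pairs <- utils::combn(ncell, 2L)
  df <- fit$df_residual
  mk_contrasts <- function(L) {
    est <- numeric(ncol(pairs)); se <- numeric(ncol(pairs))
    lab <- character(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
      lj <- L[i1, ] - L[i2, ]
      est[j] <- sum(lj * beta)
      se[j] <- sqrt(drop(t(lj) %*% V %*% lj))
      lab[j] <- paste(cell_label[i1], "-", cell_label[i2])
    }
    t <- est / se
    data.frame(contrast = lab, estimate = est, se = se, t = t,
               p_adj = .tukey_p(t, ncell, df), stringsAsFactors = FALSE)
  }
  slope_contrasts <- mk_contrasts(Ls)
  ratio_contrasts <- mk_contrasts(X0)
  names(ratio_contrasts)[2] <- "log_ratio"
  names(ratio_contrasts)[3] <- "se_log"
  ratio_contrasts <- data.frame(
    contrast = ratio_contrasts$contrast,
    ratio = exp(ratio_contrasts$log_ratio),
    log_ratio = ratio_contrasts$log_ratio,
    se_log = ratio_contrasts$se_log,
    t = ratio_contrasts$t, p_adj = ratio_contrasts$p_adj,
    stringsAsFactors = FALSE
  )
  list(slopes = slopes, slope_contrasts = slope_contrasts,
       rate_ratios = ratio_contrasts, at_shoal_size = at_shoal_size)
}
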