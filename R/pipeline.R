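#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_full_pipeline()].
#' Provide either paths to observed shoal/foraging tables or
#' `simulate = TRUE` to generate both from the default synthetic
#' parameters. A seed is mandatory whenever any stochastic stage runs
#' (simulation, Monte-Carlo null matrices).
#'
#' @param shoal_table path to a shoal CSV/TSV, or NULL when simulating.
#' @param foraging_table path to a foraging CSV/TSV, or NULL.
#' @param catalog a [species_catalog()] or path to a catalog file.
#' @param simulate generate both tables synthetically.
#' @param n_shoals,n_foraging simulated table sizes.
#' @param n_null null matrices for the association stage.
#' @param method association method (`"montecarlo"` / `"analytic"`).
#' @param power Tweedie index for the foraging fits.
#' @param at_shoal_size reference size for rate ratios.
#' @param seed root RNG seed; stage seeds are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(shoal_table = NULL, foraging_table = NULL,
                            catalog = default_catalog(), simulate = FALSE,
                            n_shoals = 250L, n_foraging = 294L,
                            n_null = 1000L,
                            method = c("montecarlo", "analytic"),
                            power = 1.5, at_shoal_size = 3, seed = NULL) {
  method <- match.arg(method)
  if (!inherits(catalog, "species_catalog") && is.character(catalog) &&
      length(catalog) == 1L)
    catalog <- read_species_catalog(catalog)
  stopifnot(inherits(catalog, "species_catalog"))
  stochastic <- simulate || method == "montecarlo"
  if (stochastic && is.null(seed))
    stop("a seed is required when simulation or Monte-Carlo nulls run",
         call. = FALSE)
  if (!simulate && (is.null(shoal_table) || is.null(foraging_table)))
    stop("supply input tables or set simulate = TRUE", call. = FALSE)
  structure(list(shoal_table = shoal_table, foraging_table = foraging_table,
                 catalog = catalog, simulate = simulate,
                 n_shoals = as.integer(n_shoals),
                 n_foraging = as.integer(n_foraging),
                 n_null = as.integer(n_null), method = method, power = power,
                 at_shoal_size = at_shoal_size, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipeline_config()]; `catalog` may be an
#' inline species-to-origin mapping or a path.
#'
#' @param path config file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  if (!is.null(raw$catalog) && !is.character(raw$catalog))
    raw$catalog <- species_catalog(raw$catalog)
  do.call(pipeline_config, raw)
}

#' Run the full shoaling-and-foraging analysis pipeline
#'
#' Executes every stage in order: load or simulate the shoal and foraging
#' tables; classify shoals by origin configuration and tabulate
#' frequencies; run the exact and chi-squared 2x2 tests on same-origin
#' multi-specific shoaling; fit the log-scale shoal-size model with Tukey
#' letters; build the presence matrix and compute pairwise association
#' strengths; filter foraging records, fit the Tweedie bite- and bout-rate
#' models and derive slopes, ratios and rate summaries. All outputs plus a
#' manifest sufficient to re-run bit-identically are written under
#' `out_dir` (CSV for tables, JSON for tests/fits) when it is given.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or NULL to skip writing.
#' @return the report bundle (named list of all stage outputs), invisibly
#'   when writing, visibly otherwise.
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  catalog <- config$catalog
  seed <- config$seed
  # fixed per-stage seed offsets keep stages independent yet reproducible
  stage_seed <- function(k) if (is.null(seed)) NULL else seed + k

  if (config$simulate) {
    shoals <- simulate_shoals(assembly_params(catalog),
                              n_shoals = config$n_shoals,
                              seed = stage_seed(1L))
    foraging <- simulate_foraging(foraging_sim_params(catalog = catalog),
                                  n = config$n_foraging,
                                  seed = stage_seed(2L))
  } else {
    shoals <- read_shoal_table(config$shoal_table, catalog)
    foraging <- read_foraging_table(config$foraging_table, catalog)
  }

  cls <- classify_shoals(shoals, catalog)
  freqs <- configuration_frequencies(cls)
  tab2x2 <- multispecific_origin_table(cls)
  fisher <- fisher_exact_2x2(tab2x2)
  chisq <- tryCatch(chi_square_2x2(tab2x2),
                    error = function(e) list(statistic = NA_real_, df = 1L,
                                             p = NA_real_,
                                             note = conditionMessage(e)))
  size_fit <- fit_shoal_size_model(cls)

  pm <- build_presence_matrix(shoals, catalog)
  assoc <- association_strength(pm, n_null = config$n_null,
                                method = config$method,
                                seed = stage_seed(3L))

  filt <- filter_foraging_records(foraging)
  fdat <- prepare_foraging_data(filt$kept, catalog)
  bite_fit <- fit_tweedie_glm(fdat, foraging_formula("bite_rate"),
                              power = config$power)
  bout_fit <- fit_tweedie_glm(fdat, foraging_formula("bout_rate"),
                              power = config$power)
  contrasts <- group_slopes_and_contrasts(bite_fit,
                                          at_shoal_size = config$at_shoal_size)
  rates <- summarize_rates(fdat)

  manifest <- list(
    package = "mixshoal",
    version = as.character(utils::packageVersion("mixshoal")),
    r_version = R.version.string,
    seed = seed, stage_seeds = if (!is.null(seed)) seed + 1:3,
    simulate = config$simulate,
    n_shoals = nrow(shoals), n_foraging = nrow(foraging),
    n_null = config$n_null, method = config$method,
    power = config$power, at_shoal_size = config$at_shoal_size,
    filters = list(min_duration_s = 20, min_length_cm = 10,
                   max_shoal_size = 50),
    n_dropped = nrow(filt$dropped),
    dropped = filt$dropped
  )

  bundle <- list(shoals = shoals, foraging = foraging,
                 classification = cls, frequencies = freqs,
                 origin_2x2 = tab2x2, fisher = fisher, chisq = chisq,
                 shoal_size_fit = size_fit, association = assoc,
                 filtered = filt, bite_fit = bite_fit, bout_fit = bout_fit,
                 contrasts = contrasts, rate_summary = rates,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name)
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    w(shoals, "shoals.csv")
    w(foraging, "foraging.csv")
    w(cls, "classification.csv")
    w(freqs$by_origin, "frequencies_origin.csv")
    w(freqs$by_origin_type, "frequencies_origin_type.csv")
    w(assoc, "association.csv")
    w(contrasts$slopes, "bite_slopes.csv")
    w(contrasts$slope_contrasts, "bite_slope_contrasts.csv")
    w(contrasts$rate_ratios, "bite_rate_ratios.csv")
    w(rates, "rate_summary.csv")
    tests <- list(origin_2x2 = as.list(as.data.frame(tab2x2)),
                  fisher = fisher, chisq = chisq,
                  shoal_size = list(group_means = size_fit$group_means,
                                    contrasts = size_fit$contrasts,
                                    letters = as.list(size_fit$letters),
                                    aic = size_fit$aic))
    jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fit_json <- function(f) list(coefficients = as.list(coef(f)),
                                 power = f$power, dispersion = f$dispersion,
                                 deviance = f$deviance, n_iter = f$n_iter,
                                 converged = f$converged)
    jsonlite::write_json(list(bite = fit_json(bite_fit),
                              bout = fit_json(bout_fit)),
                         file.path(out_dir, "foraging_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}
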