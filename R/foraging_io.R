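#' Individual foraging-observation tables
#'
#' One row per focal-fish observation with columns `individual_id`,
#' `species`, `length_cm`, `shoal_size`, `shoal_type`
#' (`mono_specific` / `multi_specific`), `location_id`, `observer_id`,
#' `duration_s`, `n_bites`, `n_bouts`. Raw counts and durations are kept so
#' per-minute rates are always recomputable. A bout is a discrete feeding
#' event containing at least one bite, so `n_bouts <= n_bites` always.
#'
#' @name foraging_table
NULL

.foraging_cols <- c("individual_id", "species", "length_cm", "shoal_size",
                    "shoal_type", "location_id", "observer_id",
                    "duration_s", "n_bites", "n_bouts")

#' Validate a foraging table
#'
#' Checks required columns, positive durations and lengths, non-negative
#' counts and the bout-within-bite invariant (`n_bouts <= n_bites`).
#'
#' @param records a foraging table.
#' @param catalog optional [species_catalog()] to check species against.
#' @return the table, invisibly; errors describe the first violation.
#' @export
validate_foraging_table <- function(records, catalog = NULL) {
  miss <- setdiff(.foraging_cols, names(records))
  if (length(miss))
    stop("foraging table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) return(invisible(records))
  if (anyDuplicated(records$individual_id))
    stop("duplicated individual_id(s)", call. = FALSE)
  if (!is.null(catalog)) {
    unknown <- setdiff(unique(trimws(records$species)), names(catalog))
    if (length(unknown))
      stop("species not in catalog: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  bad_type <- setdiff(unique(records$shoal_type),
                      c("mono_specific", "multi_specific"))
  if (length(bad_type))
    stop("shoal_type must be mono_specific or multi_specific; got: ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  if (any(records$duration_s <= 0))
    stop("duration_s must be positive", call. = FALSE)
  if (any(records$length_cm <= 0))
    stop("length_cm must be positive", call. = FALSE)
  if (any(records$n_bites < 0) || any(records$n_bouts < 0))
    stop("bite/bout counts must be non-negative", call. = FALSE)
  over <- which(records$n_bouts > records$n_bites)
  if (length(over))
    stop("n_bouts exceeds n_bites at row(s): ",
         paste(utils::head(over, 5L), collapse = ", "), call. = FALSE)
  invisible(records)
}

#' Read / write a foraging-observation table (CSV/TSV)
#'
#' @param path file path; delimiter detected from the header line.
#' @param catalog optional [species_catalog()]; if supplied, species labels
#'   are checked against it.
#' @return a validated foraging table (`data.frame`).
#' @export
read_foraging_table <- function(path, catalog = NULL) {
  df <- .read_delim_auto(path)
  names(df) <- trimws(names(df))
  for (col in c("individual_id", "species", "shoal_type",
                "location_id", "observer_id"))
    if (col %in% names(df)) df[[col]] <- trimws(as.character(df[[col]]))
  validate_foraging_table(df, catalog)
  df
}

#' @rdname read_foraging_table
#' @param records a foraging table to write.
#' @export
write_foraging_table <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the study's record filters to foraging observations
#'
#' Keeps observations strictly longer than `min_duration_s` (observations of
#' 20 s or less are excluded), of fish strictly larger than `min_length_cm`,
#' and in shoals of at most `max_shoal_size` individuals (larger shoals are
#' dropped as unreliable size estimates). Each excluded record is logged with
#' exactly one primary reason, checked in the order duration, length,
#' shoal size.
#'
#' @param records a foraging table.
#' @param min_duration_s exclusive lower bound on observation time (s).
#' @param min_length_cm exclusive lower bound on body length (cm).
#' @param max_shoal_size inclusive upper bound on shoal size.
#' @return list with elements `kept` (foraging table) and `dropped`
#'   (`data.frame` with `individual_id`, `reason`).
#' @examples
#' tbl <- simulate_foraging(foraging_sim_params(seed = 1), n = 20)
#' filt <- filter_foraging_records(tbl)
#' nrow(filt$kept) + nrow(filt$dropped) == nrow(tbl)
#' @export
filter_foraging_records <- function(records, min_duration_s = 20,
                                    min_length_cm = 10, max_shoal_size = 50) {
  stopifnot(min_duration_s > 0, min_length_cm > 0, max_shoal_size > 0)
  if (nrow(records) == 0L) {
    return(list(kept = records,
                dropped = data.frame(individual_id = character(),
                                     reason = character(),
                                     stringsAsFactors = FALSE)))
  }
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$duration_s <= min_duration_s] <- "duration"
  reason[is.na(reason) & records$length_cm <= min_length_cm] <- "length"
  reason[is.na(reason) & records$shoal_size > max_shoal_size] <- "shoal_size"
  keep <- is.na(reason)
  list(
    kept = records[keep, , drop = FALSE],
    dropped = data.frame(individual_id = records$individual_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  )
}

#' Per-minute bite and bout rates
#'
#' Converts raw counts and observation durations into rates:
#' `bite_rate = n_bites / duration_s * 60`, likewise for bouts. Columns
#' `bite_rate` and `bout_rate` are appended to the table.
#'
#' @param records a foraging table.
#' @return `records` with `bite_rate` and `bout_rate` columns (bites/bouts
#'   per minute).
#' @export
compute_rates <- function(records) {
  if (any(records$duration_s <= 0))
    stop("duration_s must be positive to compute rates", call. = FALSE)
  records$bite_rate <- records$n_bites / records$duration_s * 60
  records$bout_rate <- records$n_bouts / records$duration_s * 60
  records
}
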