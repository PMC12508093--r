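#' Shoal-composition tables
#'
#' A shoal table is a plain `data.frame` with one row per observed shoal:
#' identifier columns `shoal_id`, `location_id`, `observer_id`, followed by
#' one non-negative integer count column per species. A zero count means
#' the species was absent from that shoal. Every shoal must hold at least
#' two individuals in total (a lone fish is not a shoal) and shoal ids must
#' be unique.
#'
#' @name shoal_table
NULL

.shoal_id_cols <- c("shoal_id", "location_id", "observer_id")

#' Species count columns of a shoal table
#' @param records a shoal table.
#' @return character vector of species column names.
#' @export
shoal_species <- function(records) setdiff(names(records), .shoal_id_cols)

#' Total individuals per shoal
#' @param records a shoal table.
#' @return integer vector of row sums over the species columns.
#' @export
shoal_sizes <- function(records) {
  sp <- shoal_species(records)
  as.integer(rowSums(records[, sp, drop = FALSE]))
}

#' Validate a shoal table
#'
#' Checks identifier columns, catalog membership of species columns,
#' integer non-negative counts, unique shoal ids and minimum shoal size 2.
#'
#' @param records a shoal table.
#' @param catalog optional [species_catalog()] to check species against.
#' @return the table, invisibly; errors describe the first violation.
#' @export
validate_shoal_table <- function(records, catalog = NULL) {
  miss <- setdiff(.shoal_id_cols, names(records))
  if (length(miss))
    stop("shoal table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sp <- shoal_species(records)
  if (length(sp) == 0L)
    stop("shoal table has no species columns", call. = FALSE)
  if (!is.null(catalog)) {
    unknown <- setdiff(sp, names(catalog))
    if (length(unknown))
      stop("species column(s) not in catalog: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$shoal_id))
    stop("duplicated shoal_id(s): ",
         paste(unique(records$shoal_id[duplicated(records$shoal_id)]),
               collapse = ", "), call. = FALSE)
  for (s in sp) {
    v <- records[[s]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("column '", s, "': non-integer or negative count at row ",
           bad[1L], call. = FALSE)
  }
  sz <- shoal_sizes(records)
  small <- which(sz < 2L)
  if (length(small))
    stop("shoal(s) with fewer than 2 individuals at row(s): ",
         paste(utils::head(small, 5L), collapse = ", "),
         " (a single fish is not a shoal)", call. = FALSE)
  invisible(records)
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, encoding = "UTF-8")
}

#' Read a shoal-composition table from CSV/TSV
#'
#' Expects a header row with `shoal_id`, `location_id`, `observer_id` and
#' one integer column per species; the delimiter (comma or tab) is detected
#' from the header. Every species column must be present in the catalog;
#' counts must be non-negative integers; each shoal must total at least two
#' individuals. Row order is preserved.
#'
#' @param path file path.
#' @param catalog a [species_catalog()] naming the permissible species.
#' @return a validated shoal table (`data.frame`).
#' @export
read_shoal_table <- function(path, catalog) {
  stopifnot(inherits(catalog, "species_catalog"))
  df <- .read_delim_auto(path)
  names(df) <- trimws(names(df))
  for (col in .shoal_id_cols)
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  validate_shoal_table(df, catalog)
  df
}

#' @rdname read_shoal_table
#' @param records a shoal table to write.
#' @export
write_shoal_table <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
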