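#' Species catalog: species labels and their biogeographic origin
#'
#' A species catalog maps each species label to its biogeographic origin,
#' either `"native"` or `"range_extending"`. Every species referenced by a
#' shoal or foraging table must appear exactly once in the catalog. The
#' catalog is the single source of the origin factor used throughout the
#' pipeline (shoal classification, foraging models).
#'
#' @param origins named character vector; names are species labels, values
#'   are `"native"` or `"range_extending"`. Labels are whitespace-trimmed
#'   and matched case-sensitively.
#' @return an object of class `species_catalog` (a named character vector).
#' @examples
#' cat4 <- species_catalog(c(
#'   Sarpa_salpa = "native", Sparisoma_cretense = "native",
#'   Siganus_luridus = "range_extending", Siganus_rivulatus = "range_extending"
#' ))
#' species_origin(cat4, "Sarpa_salpa")
#' @export
species_catalog <- function(origins) {
  if (is.list(origins)) origins <- unlist(origins)
  if (length(origins) == 0L || is.null(names(origins)))
    stop("catalog must be a non-empty named vector of origins", call. = FALSE)
  labels <- trimws(names(origins))
  origins <- trimws(as.character(origins))
  if (anyDuplicated(labels))
    stop("duplicated species label(s) in catalog: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(origins), c("native", "range_extending"))
  if (length(bad))
    stop("origin labels must be 'native' or 'range_extending'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(stats::setNames(origins, labels), class = "species_catalog")
}

#' @export
print.species_catalog <- function(x, ...) {
  cat("Species catalog (", length(x), " species)\n", sep = "")
  for (s in names(x)) cat("  ", format(s, width = 24), x[[s]], "\n", sep = "")
  invisible(x)
}

#' Read a species catalog from YAML or JSON
#'
#' The file must contain a flat mapping from species label to origin
#' (`native` / `range_extending`). Format is chosen by file extension
#' (`.json` is JSON, anything else is parsed as YAML, of which JSON is a
#' subset anyway).
#'
#' @param path file path.
#' @return a [species_catalog()].
#' @export
read_species_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  species_catalog(raw)
}

#' @rdname read_species_catalog
#' @param catalog a [species_catalog()].
#' @export
write_species_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "species_catalog"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(unclass(catalog)), path, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(as.list(unclass(catalog)), path)
  }
  invisible(path)
}

#' Look up the origin of one or more species
#'
#' @param catalog a [species_catalog()].
#' @param species character vector of species labels.
#' @return character vector of origins, same length as `species`.
#' @export
species_origin <- function(catalog, species) {
  stopifnot(inherits(catalog, "species_catalog"))
  species <- trimws(species)
  missing <- setdiff(unique(species), names(catalog))
  if (length(missing))
    stop("species not in catalog: ", paste(missing, collapse = ", "),
         call. = FALSE)
  unname(unclass(catalog)[species])
}

#' The four-species study catalog
#'
#' Convenience default: the two native Mediterranean herbivores
#' (*Sarpa salpa*, *Sparisoma cretense*) and the two range-extending
#' rabbitfishes (*Siganus luridus*, *Siganus rivulatus*).
#'
#' @return a [species_catalog()] with four entries.
#' @export
default_catalog <- function() {
  species_catalog(c(
    Sarpa_salpa        = "native",
    Sparisoma_cretense = "native",
    Siganus_luridus    = "range_extending",
    Siganus_rivulatus  = "range_extending"
  ))
}
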