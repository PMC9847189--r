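#' Write a city bundle to CSV files
#'
#' Writes `tracts.csv`, `neighborhoods.csv`, `adjacency.csv` (columns
#' `src,dst`, both directions of every edge), `establishments.csv` and
#' `schools.csv` into `dir`. Synthetic and real data share these schemas, so
#' a generated city can be re-read by [read_city()].
#'
#' @param city a `synthetic_city` or a bundle from [read_city()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_city <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(city$tracts, "tracts.csv")
  wr(city$neighborhoods, "neighborhoods.csv")
  wr(weights_to_edges(city$adjacency), "adjacency.csv")
  wr(city$establishments, "establishments.csv")
  wr(city$schools, "schools.csv")
  invisible(dir)
}

#' Read a city bundle from CSV files (or polygons)
#'
#' Reads the five-file schema written by [write_city()]. Adjacency can come
#' from `adjacency.csv` (symmetric edge list; an edge present in only one
#' direction is an error) or, when `geojson` is given, be derived from
#' polygons by rook contiguity ([rook_from_polygons()]).
#'
#' @param dir directory holding the CSV files.
#' @param geojson optional path to a GeoJSON polygon file used instead of
#'   `adjacency.csv`.
#' @return list of class `synthetic_city` (without a generator `config`):
#'   `tracts`, `neighborhoods`, `adjacency`, `establishments`, `schools`.
#' @export
read_city <- function(dir, geojson = NULL) {
  rd <- function(f, classes) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", f)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(names(classes), names(df))
    if (length(miss)) stop(f, " missing column(s): ", paste(miss, collapse = ", "))
    for (nm in names(classes)) {
      df[[nm]] <- switch(classes[[nm]],
                         character = as.character(df[[nm]]),
                         integer = as.integer(df[[nm]]),
                         numeric = as.numeric(df[[nm]]),
                         logical = as.logical(df[[nm]]))
    }
    df
  }
  tracts <- rd("tracts.csv", c(
    tract_id = "character", neighborhood_id = "character",
    population = "integer", total_income = "numeric",
    household_heads_total = "integer", household_heads_0_3_mw = "integer",
    households_below_half_mw = "integer", persons_7plus = "integer",
    illiterate_7plus = "integer", persons_inadequate_sanitation = "integer"))
  neighborhoods <- rd("neighborhoods.csv",
                      c(neighborhood_id = "character", population = "integer"))
  establishments <- rd("establishments.csv", c(
    establishment_id = "character", neighborhood_id = "character",
    activity_code = "character"))
  schools <- rd("schools.csv", c(
    school_id = "character", neighborhood_id = "character",
    sector = "character"))

  nb_ids <- neighborhoods$neighborhood_id
  if (!is.null(geojson)) {
    adjacency <- rook_from_polygons(geojson)
  } else {
    edges <- rd("adjacency.csv", c(src = "character", dst = "character"))
    adjacency <- weights_from_edges(edges, ids = nb_ids)
  }

  bad <- setdiff(unique(tracts$neighborhood_id), nb_ids)
  if (length(bad)) stop("tracts reference unknown neighborhood(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(establishments$neighborhood_id), nb_ids)
  if (length(bad)) stop("establishments reference unknown neighborhood(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(schools$neighborhood_id), nb_ids)
  if (length(bad)) stop("schools reference unknown neighborhood(s): ",
                        paste(bad, collapse = ", "))

  structure(list(config = NULL, tracts = tracts, neighborhoods = neighborhoods,
                 adjacency = adjacency, establishments = establishments,
                 schools = schools),
            class = "synthetic_city")
}

#' Filter the school roster with an audit trail
#'
#' Drops schools offering only professional education, only special education,
#' or lacking any inherited neighborhood index (missing segregation or other
#' category data), mirroring standard sample-construction practice for
#' school-level ecological studies. Exclusion counts per reason are returned
#' as an audit table; a school matching several reasons is counted once, under
#' the first matching reason.
#'
#' @param schools data frame; optional logical columns `professional_only`
#'   and `special_only`; any columns named in `index_columns` are checked for
#'   `NA`.
#' @param index_columns columns whose `NA` values mark missing index data.
#' @return list with `schools` (retained rows) and `audit` (data frame
#'   `reason`, `n`). Warns when nothing is retained.
#' @export
filter_schools <- function(schools,
                           index_columns = intersect(
                             c("tercile", "deprivation_cat", "segregation_cat",
                               "desert", "swamp"),
                             names(schools))) {
  n <- nrow(schools)
  prof <- if ("professional_only" %in% names(schools))
    isTRUE_v(schools$professional_only) else rep(FALSE, n)
  spec <- if ("special_only" %in% names(schools))
    isTRUE_v(schools$special_only) else rep(FALSE, n)
  missing_idx <- rep(FALSE, n)
  for (col in index_columns) missing_idx <- missing_idx | is.na(schools[[col]])

  reason <- rep(NA_character_, n)
  reason[missing_idx] <- "missing_index"
  reason[spec] <- "special_education_only"
  reason[prof] <- "professional_education_only"   # first reason wins

  keep <- is.na(reason)
  audit <- data.frame(
    reason = c("professional_education_only", "special_education_only",
               "missing_index", "retained"),
    n = c(sum(reason == "professional_education_only", na.rm = TRUE),
          sum(reason == "special_education_only", na.rm = TRUE),
          sum(reason == "missing_index", na.rm = TRUE),
          sum(keep)),
    stringsAsFactors = FALSE
  )
  if (!any(keep)) warning("no schools retained after filtering")
  list(schools = schools[keep, , drop = FALSE], audit = audit)
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)
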