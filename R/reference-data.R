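#' Published Rio de Janeiro school food-environment counts (2019)
#'
#' City-level contingency counts for the 3,159 public and private schools of
#' Rio de Janeiro: per stratum of each inequality measure (school sector,
#' per-capita income tercile, deprivation index, Gi* segregation index), the
#' number of schools and the number located in food-desert, food-swamp, and
#' simultaneous desert-and-swamp neighborhoods. These are aggregate counts
#' from the published city analysis (the underlying establishment registry is
#' not public), shipped so the tabulation and chi-square stages can be
#' exercised against real numbers.
#'
#' @return data frame with columns `stratum_var`, `level`, `n_schools`,
#'   `n_desert`, `n_swamp`, `n_both`.
#' @export
rio_reference_counts <- function() {
  path <- system.file("extdata", "rio_school_flags_2019.csv",
                      package = "foodscape", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Contingency tables from stratum-level counts
#'
#' Convenience wrapper turning one stratification of [rio_reference_counts()]
#' (or any counts in the same shape) into a [contingency_table] for a chosen
#' flag, ready for [chi_square()].
#'
#' @param counts data frame with columns `level`, `n_schools` and the chosen
#'   flag column.
#' @param flag one of `"n_desert"`, `"n_swamp"`, `"n_both"` (or any count
#'   column).
#' @return a [contingency_table].
#' @export
counts_to_table <- function(counts, flag = "n_desert") {
  if (!flag %in% names(counts)) stop("no column '", flag, "' in counts")
  contingency_table(counts$level, counts[[flag]], counts$n_schools)
}
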