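#' Establishment category map
#'
#' The CAISAN food-retail taxonomy used throughout the package: activity-code
#' prefixes (CNAE-style) map to 13 subcategories, each belonging to one macro
#' class — `in_natura` (fresh-food retail: butcheries, seafood shops, fruit and
#' vegetable markets), `ultraprocessed` (street vendors, bars, cafeterias /
#' snack bars, convenience stores, candy shops) or `mixed` (hypermarkets and
#' supermarkets, general food stores, mini markets, bakeries, restaurants).
#' `swamp_subcategories` names the subcategories whose summed count defines a
#' food swamp.
#'
#' Codes are matched by longest prefix; an establishment whose code matches no
#' prefix is counted as `non_food`.
#'
#' @param code_prefixes named character vector: prefix -> subcategory.
#' @param macro_class named character vector: subcategory -> macro class.
#' @param swamp_subcategories character vector of swamp-defining
#'   subcategories; must be ultraprocessed or mixed.
#' @return object of class `category_map`.
#' @export
category_map <- function(code_prefixes, macro_class, swamp_subcategories) {
  required <- c(butchery = "in_natura", seafood = "in_natura",
                fruits_vegetables = "in_natura",
                street_vendor = "ultraprocessed", bar = "ultraprocessed",
                cafeteria = "ultraprocessed", convenience = "ultraprocessed",
                candy = "ultraprocessed",
                hypermarket_supermarket = "mixed", food_store = "mixed",
                mini_market = "mixed", bakery = "mixed", restaurant = "mixed")
  if (!setequal(names(macro_class), names(required))) {
    stop("subcategories must cover exactly: ",
         paste(names(required), collapse = ", "))
  }
  if (!identical(unname(required[names(macro_class)]), unname(macro_class))) {
    stop("subcategory assigned to the wrong macro class")
  }
  bad <- setdiff(unique(code_prefixes), names(macro_class))
  if (length(bad)) stop("code prefix maps to unknown subcategory: ",
                        paste(bad, collapse = ", "))
  eligible <- names(macro_class)[macro_class %in% c("ultraprocessed", "mixed")]
  if (!all(swamp_subcategories %in% eligible)) {
    stop("swamp subcategories must be ultraprocessed or mixed")
  }
  structure(list(code_prefixes = code_prefixes,
                 macro_class = macro_class,
                 swamp_subcategories = swamp_subcategories),
            class = "category_map")
}

#' Default category map
#'
#' Ships a documented default mapping of CNAE-style code prefixes to the 13
#' subcategories. The codes follow the Brazilian CNAE retail/food-service
#' groups (47.x retail, 56.x food service); registries differ in formatting,
#' so the mapping is deliberately editable — load a custom one with
#' [read_category_map()]. The default swamp set is convenience stores,
#' cafeterias (snack bars / "lanchonetes"), mini markets (grocery stores) and
#' candy shops.
#'
#' @return a [category_map] object.
#' @export
default_category_map <- function() {
  category_map(
    code_prefixes = c(
      "4722-9/01" = "butchery",
      "4722-9/02" = "seafood",
      "4724-5"    = "fruits_vegetables",
      "5612-1"    = "street_vendor",
      "5611-2/02" = "bar",
      "5611-2/03" = "cafeteria",
      "4729-6/02" = "convenience",
      "4721-1/04" = "candy",
      "4711-3"    = "hypermarket_supermarket",
      "4729-6/99" = "food_store",
      "4712-1"    = "mini_market",
      "4721-1/02" = "bakery",
      "5611-2/01" = "restaurant"
    ),
    macro_class = c(
      butchery = "in_natura", seafood = "in_natura",
      fruits_vegetables = "in_natura",
      street_vendor = "ultraprocessed", bar = "ultraprocessed",
      cafeteria = "ultraprocessed", convenience = "ultraprocessed",
      candy = "ultraprocessed",
      hypermarket_supermarket = "mixed", food_store = "mixed",
      mini_market = "mixed", bakery = "mixed", restaurant = "mixed"
    ),
    swamp_subcategories = c("convenience", "cafeteria", "mini_market", "candy")
  )
}

#' Read a category map from YAML
#'
#' Expected structure: top-level keys `subcategories` (list: subcategory ->
#' list with `macro_class` and `code_prefixes`) and `swamp_subcategories`
#' (list of subcategory names). See
#' `system.file("extdata", "category_map.yaml", package = "foodscape")`.
#'
#' @param path path to the YAML file.
#' @return a [category_map] object.
#' @export
read_category_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$subcategories)) stop("YAML missing 'subcategories'")
  macro <- vapply(y$subcategories, function(s) s$macro_class, character(1))
  prefixes <- unlist(lapply(names(y$subcategories), function(nm) {
    p <- y$subcategories[[nm]]$code_prefixes
    stats::setNames(rep(nm, length(p)), unlist(p))
  }))
  category_map(prefixes, macro, unlist(y$swamp_subcategories))
}

#' @export
print.category_map <- function(x, ...) {
  cat("Category map:", length(x$macro_class), "subcategories,",
      length(x$code_prefixes), "code prefixes\n")
  for (cl in c("in_natura", "ultraprocessed", "mixed")) {
    cat(sprintf("  %-15s %s\n", cl,
                paste(names(x$macro_class)[x$macro_class == cl], collapse = ", ")))
  }
  cat("  swamp set:      ", paste(x$swamp_subcategories, collapse = ", "), "\n")
  invisible(x)
}

subcategories <- function(map) names(map$macro_class)

match_subcategory <- function(codes, map) {
  prefixes <- names(map$code_prefixes)
  ord <- order(nchar(prefixes), decreasing = TRUE)   # longest prefix wins
  prefixes <- prefixes[ord]
  subs <- unname(map$code_prefixes)[ord]
  out <- rep("non_food", length(codes))
  todo <- rep(TRUE, length(codes))
  for (k in seq_along(prefixes)) {
    hit <- todo & startsWith(codes, prefixes[k])
    out[hit] <- subs[k]
    todo[hit] <- FALSE
  }
  out
}
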