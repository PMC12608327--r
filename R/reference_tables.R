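#' Published summary tabulations from the Zbrzyca case study
#'
#' The package ships the class-level summary tables of the pine-dominated
#' Zbrzyca forest-range case study (northern Poland; two ALS epochs, 2013
#' and 2022, compared against State Forest Information System inventory
#' heights), transcribed as plain CSV. They serve as reference fixtures for
#' the tabulation and correlation routines: the unit-level data behind them
#' are not public, but every aggregate the study reports can be recomputed
#' from these tables.
#'
#' Available tables:
#' \describe{
#'   \item{`site_2013`, `site_2022`}{surface area (ha) of forest units per
#'     height-difference class, by forest site type.}
#'   \item{`species_2013`, `species_2022`}{the same by dominant species.}
#'   \item{`increments`}{counts of forest units by (inventory increment,
#'     LiDAR increment) over 2013-2022.}
#' }
#'
#' The 2013 comparison additionally excluded 11 gross-error units covering
#' [zbrzyca_excluded_area_2013()] ha; area shares that refer to "the
#' analysed area" of 2013 use the tabulated total plus that excluded area
#' as denominator.
#'
#' @param name one of `"site_2013"`, `"species_2013"`, `"site_2022"`,
#'   `"species_2022"`, `"increments"`.
#' @return a data.table (long format; difference classes as character
#'   labels, the pooled low class as `"[-8,-6]"`).
#' @export
zbrzyca_table <- function(name = c("site_2013", "species_2013",
                                   "site_2022", "species_2022",
                                   "increments")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("zbrzyca_", name, ".csv"),
                      package = "standgrowth", mustWork = TRUE)
  fread(path, colClasses = if (name == "increments") NULL else
    list(character = "diff_class"))
}

#' @rdname zbrzyca_table
#' @export
zbrzyca_excluded_area_2013 <- function() 19.01

#' Area share of a set of difference classes
#'
#' Sums the area over the given classes and divides by the tabulated total
#' plus `extra_area` (area of units excluded from the tabulation but still
#' counted as analysed, e.g. gross-error units).
#'
#' @param tab long table with columns `diff_class` and `area_ha`.
#' @param classes character vector of class labels to sum.
#' @param extra_area area (ha) added to the denominator only.
#' @return list with `area` (ha) and `share` (fraction of the analysed
#'   area).
#' @export
class_area_share <- function(tab, classes, extra_area = 0) {
  tab <- as.data.table(tab)
  area <- tab[diff_class %in% classes, sum(area_ha)]
  total <- tab[, sum(area_ha)] + extra_area
  list(area = area, share = area / total)
}
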