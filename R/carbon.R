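# Carbon accounting: the undesirable output is a coefficient-weighted sum over
# carbon sources, E = sum_k coef_k * quantity_k, reported in 10^4 t.

#' Load a carbon-coefficient table
#'
#' Columns: `source` (matches the panel's `cs_*` column suffixes), `factor`
#' (emission factor in kg C per source unit), `unit` (the source-quantity
#' unit), `to_1e4t` (explicit multiplicative conversion so that
#' `quantity * factor * to_1e4t` is in 10^4 t), `provenance` (free text).
#'
#' The shipped default table (`system.file("extdata",
#' "carbon_coefficients.csv", package = "ecoefnet")`) carries the six-source
#' convention of the agricultural-carbon accounting literature (fertilizer,
#' pesticide, plastic film, diesel, plowing, irrigation). Those defaults are
#' literature conventions, not measured ground truth, and are meant to be
#' replaced with study-specific factors where available.
#'
#' @param path CSV path; default is the shipped table.
#' @return data.frame of class `carbon_coefficients`.
#' @export
read_carbon_coefficients <- function(path = system.file("extdata",
    "carbon_coefficients.csv", package = "ecoefnet")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "factor", "unit", "to_1e4t", "provenance")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("coefficient table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(d$factor <= 0)) stop("all emission factors must be > 0")
  if (any(d$to_1e4t <= 0)) stop("all unit conversions must be > 0")
  if (anyDuplicated(d$source)) stop("duplicate source in coefficient table")
  class(d) <- c("carbon_coefficients", "data.frame")
  d
}

#' Carbon emissions of city-year records
#'
#' E = sum over sources of quantity x factor x unit conversion, in 10^4 t.
#' Linear in every quantity, additive over sources, invariant to source order.
#'
#' @param panel an `eep_panel` (or any data.frame with `cs_*` columns).
#' @param coef a `carbon_coefficients` table; every `cs_*` column of the panel
#'   must have a matching `source` row, else an error lists the missing ones.
#' @return numeric vector of emissions (10^4 t), one per record.
#' @export
carbon_emissions <- function(panel, coef = read_carbon_coefficients()) {
  cs <- grep("^cs_", names(panel), value = TRUE)
  src <- sub("^cs_", "", cs)
  missing_coef <- setdiff(src, coef$source)
  if (length(missing_coef))
    stop("no emission coefficient for source(s): ",
         paste(missing_coef, collapse = ", "))
  if (!length(cs)) return(rep(0, nrow(panel)))
  i <- match(src, coef$source)
  w <- coef$factor[i] * coef$to_1e4t[i]
  as.numeric(as.matrix(panel[, cs, drop = FALSE]) %*% w)
}
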