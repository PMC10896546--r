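# Panel data model: city-year input-output records, validation, file I/O,
# grade classification and provincial report aggregation.

# columns every panel must carry; carbon-source quantities are the columns
# prefixed "cs_" (one per source, source-specific units per coefficient table)
PANEL_NUMERIC <- c("sown_area", "labor", "machinery_power", "fertilizer",
                   "grain_output", "agri_output_value")
DEA_INPUTS  <- c("sown_area", "labor", "machinery_power", "fertilizer")
DEA_GOODS   <- c("grain_output", "agri_output_value")
GRADE_LABELS <- c("high", "relatively_high", "medium", "low", "lowest")

#' Construct and validate a city-year panel
#'
#' A panel is a rectangular set of city-year records of the cultivated-land
#' input-output system: four inputs (crop sown area in thousand hectares,
#' primary-industry labor in 10^4 persons, agricultural machinery power in
#' 10^4 kW, fertilizer applied in 10^4 t), two desirable outputs (grain output
#' in 10^4 t, gross agricultural output value in 10^8 yuan) and carbon-source
#' quantities in columns prefixed `cs_`.
#'
#' Validation enforces: exactly one record per (city, year); all numeric fields
#' finite and non-negative; DEA inputs and outputs strictly positive (zero
#' would make the ratio-form efficiency measure undefined, so it is rejected
#' rather than imputed); carbon-source quantities may be zero.
#'
#' @param records data.frame with columns `city_id`, `province`, `year`, the
#'   six indicator columns and zero or more `cs_*` columns.
#' @param years study window (integer vector); records outside it are an error.
#' @return the validated panel, a data.frame of class `eep_panel` with
#'   attributes `cities` (canonical city order, first-appearance order of the
#'   input) and `years`.
#' @export
as_panel <- function(records, years = sort(unique(records$year))) {
  records <- as.data.frame(records)
  need <- c("city_id", "province", "year", PANEL_NUMERIC)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("panel is missing required columns: ", paste(miss, collapse = ", "))
  cs <- grep("^cs_", names(records), value = TRUE)
  records$city_id <- as.character(records$city_id)
  records$province <- as.character(records$province)
  records$year <- as.integer(records$year)
  years <- as.integer(years)

  if (any(!records$year %in% years))
    stop("records outside the study window: years ",
         paste(sort(unique(records$year[!records$year %in% years])), collapse = ", "))

  cities <- unique(records$city_id)
  key <- paste(records$city_id, records$year)
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicate (city, year) records: ", paste(unique(dup), collapse = "; "))
  want <- as.vector(outer(cities, years, paste))
  gap <- setdiff(want, key)
  if (length(gap))
    stop("incomplete panel, missing (city, year): ", paste(gap, collapse = "; "))

  num <- c(PANEL_NUMERIC, cs)
  for (cl in num) {
    if (!is.numeric(records[[cl]]))
      stop("column ", cl, " has non-finite or non-numeric values")
    records[[cl]] <- as.double(records[[cl]])
    v <- records[[cl]]
    if (any(!is.finite(v)))
      stop("column ", cl, " has non-finite or non-numeric values")
    bad <- which(v < 0)
    if (length(bad))
      stop("negative value in column ", cl, " at row ", bad[1L],
           " (city ", records$city_id[bad[1L]], ", year ", records$year[bad[1L]], ")")
  }
  for (cl in c(DEA_INPUTS, DEA_GOODS)) {
    bad <- which(records[[cl]] == 0)
    if (length(bad))
      stop("zero value in DEA column ", cl, " at row ", bad[1L],
           " (city ", records$city_id[bad[1L]], ", year ", records$year[bad[1L]],
           "); zero inputs/outputs are rejected, not imputed")
  }
  # one province label per city
  pv <- tapply(records$province, records$city_id, function(p) length(unique(p)))
  if (any(pv > 1))
    stop("city with inconsistent province label: ",
         paste(names(pv)[pv > 1], collapse = ", "))

  records <- records[order(match(records$city_id, cities), records$year), , drop = FALSE]
  rownames(records) <- NULL
  structure(records, cities = cities, years = years,
            class = c("eep_panel", "data.frame"))
}

#' Read a panel from a delimited text file
#'
#' The file is comma-separated with a header row; the city order of the file is
#' canonical for every downstream matrix. `config$years` fixes the study
#' window; `config$column_map` (named character vector, `new = old`) renames
#' non-standard headers onto the panel fields before validation.
#'
#' @param path CSV file path.
#' @param config list with optional `years` and `column_map`.
#' @return validated panel (see [as_panel()]).
#' @export
read_panel <- function(path, config = list()) {
  if (!file.exists(path)) stop("panel file does not exist: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(config$column_map)) {
    cm <- config$column_map
    for (new in names(cm)) {
      if (!cm[[new]] %in% names(d))
        stop("column_map refers to absent column: ", cm[[new]])
      names(d)[names(d) == cm[[new]]] <- new
    }
  }
  years <- if (!is.null(config$years)) config$years else sort(unique(d$year))
  as_panel(d, years = years)
}

#' Write a panel (exact round trip)
#'
#' Numeric fields are formatted with 17 significant digits so that
#' `read_panel(write_panel(p))` reproduces every value exactly.
#'
#' @param panel an `eep_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  d <- as.data.frame(panel)
  num <- vapply(d, is.double, logical(1))
  d[num] <- lapply(d[num], function(x) sprintf("%.17g", x))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.eep_panel <- function(x, ...) {
  cat("City-year panel: ", length(attr(x, "cities")), " cities x ",
      length(attr(x, "years")), " years (", nrow(x), " records), ",
      length(grep("^cs_", names(x))), " carbon sources\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Efficiency grade bands
#'
#' The five-band classification of the final efficiency score P:
#' high (P >= 1), relatively_high (0.8 <= P < 1), medium (0.6 <= P < 0.8),
#' low (0.4 <= P < 0.6), lowest (P < 0.4). Band boundaries belong to the upper
#' band. The bands partition `[0, Inf)`.
#'
#' @return data.frame with columns `label`, `lower`, `upper` (upper exclusive,
#'   `Inf` for the top band).
#' @export
efficiency_grades <- function() {
  data.frame(label = GRADE_LABELS,
             lower = c(1, 0.8, 0.6, 0.4, 0),
             upper = c(Inf, 1, 0.8, 0.6, 0.4),
             stringsAsFactors = FALSE)
}

#' Classify efficiency scores into grade bands
#'
#' @param score numeric vector of non-negative efficiency scores.
#' @return character vector of band labels (see [efficiency_grades()]).
#' @export
classify_grade <- function(score) {
  if (any(!is.finite(score))) stop("scores must be finite")
  if (any(score < 0)) stop("negative efficiency score")
  out <- character(length(score))
  out[score >= 1] <- "high"
  out[score >= 0.8 & score < 1] <- "relatively_high"
  out[score >= 0.6 & score < 0.8] <- "medium"
  out[score >= 0.4 & score < 0.6] <- "low"
  out[score < 0.4] <- "lowest"
  out
}

#' Provincial report aggregation of efficiency scores
#'
#' Reproduces the provincial report layout: one cell per (year, province) with
#' the unweighted mean over that province's cities, a yearly `average` column
#' equal to the unweighted mean of the provincial cells, and an `Average` row
#' holding the mean over years of each column.
#'
#' @param scores data.frame with columns `province`, `year` and a score column.
#' @param score_col name of the score column (default `"P"`).
#' @param digits report rounding (default 3, the conventional print precision);
#'   `NULL` for exact values.
#' @return data.frame: one row per year plus the `Average` row; one column per
#'   province plus `average`.
#' @export
provincial_means <- function(scores, score_col = "P", digits = 3) {
  stopifnot(all(c("province", "year", score_col) %in% names(scores)))
  scores$province <- as.character(scores$province)
  if (any(is.na(scores$province)) || any(!nzchar(scores$province)))
    stop("every city needs a province label")
  provs <- unique(scores$province)
  years <- sort(unique(scores$year))
  M <- matrix(NA_real_, length(years), length(provs),
              dimnames = list(years, provs))
  for (p in provs) for (y in years) {
    v <- scores[[score_col]][scores$province == p & scores$year == y]
    if (!length(v)) stop("empty province group: ", p, " / ", y)
    M[as.character(y), p] <- mean(v)
  }
  avg_col <- rowMeans(M)
  M <- cbind(M, average = avg_col)
  M <- rbind(M, Average = colMeans(M))
  if (!is.null(digits)) M <- round(M, digits)
  out <- data.frame(year = c(as.character(years), "Average"), M,
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Share of cities falling in a set of grade bands
#'
#' @param scores numeric vector of per-city scores (one score per city).
#' @param bands subset of grade labels, e.g. `c("high", "relatively_high")`.
#' @param digits rounding for the reported percentage (default 1).
#' @return percentage in `[0, 100]`.
#' @export
grade_share <- function(scores, bands, digits = 1) {
  if (!length(scores)) stop("empty score list")
  bad <- setdiff(bands, GRADE_LABELS)
  if (length(bad)) stop("unknown grade labels: ", paste(bad, collapse = ", "))
  round(100 * mean(classify_grade(scores) %in% bands), digits)
}

#' Read the per-city attribute table
#'
#' One row per city: `city_id`, `agri_gdp_share` and `urbanization_rate`
#' (ratios in `[0,1]`), `rural_income` (yuan per capita), `fertilizer_intensity`
#' (t per sown ha), `mechanization_intensity` (kW per sown ha), `population`
#' (10^4 persons), `lon`, `lat` (degrees).
#'
#' @param path CSV file path.
#' @param cities canonical city order the table must cover (optional).
#' @return validated data.frame in canonical city order.
#' @export
read_attributes <- function(path, cities = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_attributes(d, cities)
}

#' Validate an attribute table
#' @param d attribute data.frame (see [read_attributes()]).
#' @param cities canonical city order, or NULL to take the table's order.
#' @return the table, reordered to `cities`.
#' @export
validate_attributes <- function(d, cities = NULL) {
  need <- c("city_id", "agri_gdp_share", "urbanization_rate", "rural_income",
            "fertilizer_intensity", "mechanization_intensity", "population",
            "lon", "lat")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("attribute table missing columns: ",
                         paste(miss, collapse = ", "))
  d$city_id <- as.character(d$city_id)
  if (anyDuplicated(d$city_id)) stop("duplicate city_id in attribute table")
  if (!is.null(cities)) {
    if (!setequal(d$city_id, cities))
      stop("attribute table cities do not match the panel")
    d <- d[match(cities, d$city_id), , drop = FALSE]
  }
  for (cl in c("agri_gdp_share", "urbanization_rate")) {
    if (any(d[[cl]] < 0 | d[[cl]] > 1))
      stop(cl, " must lie in [0, 1]")
  }
  if (any(abs(d$lat) > 90) || any(abs(d$lon) > 180))
    stop("invalid coordinates")
  rownames(d) <- NULL
  d
}

#' Read a spatial contiguity list
#'
#' Two columns of city ids; each row declares the pair adjacent, interpreted
#' symmetrically.
#'
#' @param path CSV file path (two columns, header row).
#' @return data.frame with columns `from`, `to`.
#' @export
read_contiguity <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("contiguity file needs two columns of city ids")
  data.frame(from = as.character(d[[1]]), to = as.character(d[[2]]),
             stringsAsFactors = FALSE)
}

#' Write a square matrix with city-id header row and column
#'
#' All gravity/tie/difference matrices are written in this aligned form so that
#' file order can never silently diverge from the canonical city order.
#'
#' @param M square matrix with dimnames set to city ids.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path) {
  stopifnot(nrow(M) == ncol(M), !is.null(rownames(M)))
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' Read a square city matrix written by [write_matrix()]
#' @param path CSV path.
#' @param cities expected city order (optional; reordered and checked if given).
#' @return numeric matrix with city dimnames.
#' @export
read_matrix <- function(path, cities = NULL) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(d)
  if (!is.null(cities)) {
    if (!setequal(rownames(M), cities) || !setequal(colnames(M), cities))
      stop("matrix cities do not match the canonical order")
    M <- M[cities, cities]
  }
  M
}
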