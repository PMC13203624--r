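#' Impact-category registry
#'
#' The life-cycle impact-assessment (LCIA) categories tracked by the package,
#' as defined by the Environmental Footprint (EF 3.0) method, with the two
#' climate-change subcategories (land use & land-use change; fossil fuel
#' combustion) reported separately. Machine ids are stable snake_case tokens;
#' labels carry the display punctuation.
#'
#' @return A data.frame with columns `id`, `label` and `unit`.
#' @examples
#' impact_registry()
#' @export
impact_registry <- function() {
  data.frame(
    id = c("acidification", "climate_change", "climate_change_land_use",
           "climate_change_fossil", "ecotoxicity_freshwater",
           "eutrophication_freshwater", "eutrophication_marine",
           "land_use", "resource_minerals", "resource_fossils", "water_use"),
    label = c("Acidification", "Climate change",
              "CC—Land use and change", "CC—Fossil resources",
              "Ecotoxicity, freshwater", "Eutrophication, freshwater",
              "Eutrophication, marine", "Land use",
              "Resource use—minerals", "Resource use—fossils",
              "Water use"),
    unit = c("mol H+ eq", "kg CO2 eq", "kg CO2 eq", "kg CO2 eq", "CTUe",
             "kg P eq", "kg N eq", "Pt", "kg Sb eq", "MJ", "m3 depriv."),
    stringsAsFactors = FALSE
  )
}

#' Construct a paired CON/DFM impact table
#'
#' An impact table holds one row per (impact category, nutritional scenario)
#' pair with the conventional phase-feeding (CON) and daily-fit-model (DFM)
#' impact magnitudes in the category's reference unit. Strict positivity is
#' required because downstream uncertainty propagation models each value as a
#' lognormal random variable.
#'
#' @param records A data.frame with columns `category`, `scenario`, `unit`,
#'   `con_value`, `dfm_value`.
#' @param registry Impact-category registry; every `category` must resolve in
#'   it. Defaults to [impact_registry()].
#' @return An object of class `impact_table` (a data.frame).
#' @examples
#' impact_table(data.frame(category = "climate_change", scenario = "BT-2017",
#'                         unit = "kg CO2 eq", con_value = 42177.46,
#'                         dfm_value = 41291.90))
#' @export
impact_table <- function(records, registry = impact_registry()) {
  required <- c("category", "scenario", "unit", "con_value", "dfm_value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("impact table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$category <- as.character(records$category)
  records$scenario <- as.character(records$scenario)
  records$unit <- as.character(records$unit)
  records$con_value <- as.numeric(records$con_value)
  records$dfm_value <- as.numeric(records$dfm_value)
  x <- structure(records, class = c("impact_table", "data.frame"),
                 registry = registry)
  validate_impact_table(x)
  x
}

validate_impact_table <- function(x) {
  if (nrow(x)) {
    bad <- which(!(x$con_value > 0) | !(x$dfm_value > 0) |
                   !is.finite(x$con_value) | !is.finite(x$dfm_value))
    if (length(bad)) {
      stop("impact table validation error: non-positive or non-finite value",
           " in row(s) ", paste(bad, collapse = ", "), call. = FALSE)
    }
    key <- paste(x$category, x$scenario, sep = "\r")
    if (anyDuplicated(key)) {
      stop("impact table validation error: duplicated (category, scenario) ",
           "pair(s): ",
           paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "),
           call. = FALSE)
    }
    registry <- attr(x, "registry")
    unknown <- setdiff(unique(x$category), registry$id)
    if (length(unknown)) {
      stop("impact table validation error: category not in registry: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(!nzchar(x$unit))) {
      stop("impact table validation error: empty unit", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.impact_table <- function(x, ...) {
  cat(sprintf("<impact_table> %d record(s), %d categor%s, %d scenario(s)\n",
              nrow(x), length(unique(x$category)),
              if (length(unique(x$category)) == 1L) "y" else "ies",
              length(unique(x$scenario))))
  print.data.frame(x, ...)
  invisible(x)
}

# parse "1,522,679.95" style numbers ("." decimal point, optional ","
# thousands separators accepted on input only)
parse_decimal <- function(x) {
  out <- suppressWarnings(as.numeric(gsub(",", "", trimws(as.character(x)))))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad)) {
    stop("impact table validation error: unparseable number in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a paired impact table from CSV or JSON
#'
#' CSV files must carry the header
#' `category,scenario,unit,con_value,dfm_value`; JSON files hold a list of
#' objects with the same five keys. Values use "." as the decimal point;
#' "," thousands separators are accepted on input.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @param registry Registry used for validation; `NULL` builds a permissive
#'   registry from the file's own (category, unit) pairs, for tables whose
#'   categories are not in [impact_registry()] (e.g. synthetic ones).
#' @return An [impact_table()].
#' @seealso [write_impact_table()], [pig_lcia_table()]
#' @export
read_impact_table <- function(path, format = c("csv", "json"),
                              registry = impact_registry()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format)
  if (format == "csv") {
    raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  } else {
    raw <- jsonlite::fromJSON(path)
    if (length(raw) == 0L) {
      raw <- data.frame(category = character(), scenario = character(),
                        unit = character(), con_value = numeric(),
                        dfm_value = numeric())
    }
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  }
  required <- c("category", "scenario", "unit", "con_value", "dfm_value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("impact table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$con_value <- parse_decimal(raw$con_value)
  raw$dfm_value <- parse_decimal(raw$dfm_value)
  if (is.null(registry)) {
    first <- !duplicated(raw$category)
    registry <- data.frame(id = as.character(raw$category[first]),
                           label = as.character(raw$category[first]),
                           unit = as.character(raw$unit[first]),
                           stringsAsFactors = FALSE)
  }
  impact_table(raw, registry = registry)
}

#' Write a paired impact table to CSV or JSON
#'
#' Values are written at full double precision so that
#' `read_impact_table(write_impact_table(x))` round-trips exactly; display
#' rounding belongs to reports only.
#'
#' @param table An [impact_table()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_impact_table <- function(table, path, format = c("csv", "json")) {
  validate_impact_table(table)
  if (missing(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format)
  df <- as.data.frame(table)
  if (format == "csv") {
    out <- df
    out$con_value <- format_full(df$con_value)
    out$dfm_value <- format_full(df$dfm_value)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

format_full <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                               trim = TRUE),
         character(1))
}

#' Published paired CON/DFM impact table for pig growing-finishing
#'
#' The paired CON/DFM LCIA results for one growing-finishing barrow batch
#' (about 20.6 kg to 138.9 kg over 120 days) under three nutrient-requirement
#' scenarios: the Brazilian tables (BT-2017), the NRC (NRC-2012) and the
#' Agroceres PIC guideline (AGPIC-2021). Ten impact categories carry paired
#' values: climate change plus its land-use and fossil subcategories,
#' freshwater and marine eutrophication, freshwater ecotoxicity, mineral and
#' fossil resource use, water use and land use. Acidification appears in the
#' registry but carries no published pair.
#'
#' Water-use rows are stored exactly as published (CON larger than DFM), so
#' their arithmetic reduction is positive even though the published summary
#' table prints those rows with a negative sign; the package reports the
#' arithmetic sign of the stored pair.
#'
#' @return An [impact_table()] with 30 records (10 categories x 3 scenarios).
#' @examples
#' tab <- pig_lcia_table()
#' subset(tab, category == "climate_change_land_use")
#' @export
pig_lcia_table <- function() {
  path <- system.file("extdata", "pig_lcia.csv", package = "herdfit",
                      mustWork = TRUE)
  read_impact_table(path, format = "csv")
}
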