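measurement_columns <- c("pile_id", "day", "distance_m", "side", "level",
                         "temp_C", "o2_pct", "co2_pct", "co_ppm")

valid_sides <- c("left", "right", "deep", "channel", "ambient")
valid_levels <- c("H1", "H2", "H3", "mid-deep", "n/a")

# Physical plausibility bounds for a probe reading; values outside are
# rejected row-wise, never silently clipped.
measurement_bounds <- list(
  o2_pct = c(0, 21), co2_pct = c(0, 100), co_ppm = c(0, Inf),
  temp_C = c(-30, 100)
)

#' Ambient conditions for a measurement day
#'
#' Ambient (atmospheric) gas composition and outside temperature used as the
#' boundary condition for field reconstruction. Gas defaults are atmospheric:
#' 20.9 % O2, 0.04 % CO2, 0 ppm CO.
#'
#' @param day Day of process (integer); `NA` for a day-independent default.
#' @param temp_C Outside temperature, degrees C.
#' @param o2_pct,co2_pct,co_ppm Ambient gas values.
#' @return A one-row tibble.
#' @export
ambient_conditions <- function(day = NA_integer_, temp_C = 18,
                               o2_pct = 20.9, co2_pct = 0.04, co_ppm = 0) {
  tibble(day = as.integer(day), temp_C = temp_C, o2_pct = o2_pct,
         co2_pct = co2_pct, co_ppm = co_ppm)
}

#' Read and validate probe measurement records
#'
#' Reads a comma-separated measurement file (UTF-8, `.` decimal separator,
#' one header line; missing values as empty cells). Each row either becomes a
#' valid record or is routed to a rejects table with a reason; units are
#' never auto-converted. Validation: O2 within 0–21 %, CO2 within 0–100 %,
#' CO >= 0 ppm, temperature within -30–100 degrees C; `side` and `level`
#' restricted to their controlled vocabularies.
#'
#' @param path Path to the measurement CSV.
#' @param rejects_path Optional path; when given, the rejects report
#'   (offending rows plus a `reject_reason` column) is written there as CSV.
#' @return A tibble of valid records (columns `pile_id`, `day`, `distance_m`,
#'   `side`, `level`, `temp_C`, `o2_pct`, `co2_pct`, `co_ppm`), with the
#'   rejects table in attribute `"rejects"`.
#' @export
read_measurements <- function(path, rejects_path = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           pile_id = readr::col_character(),
                           side = readr::col_character(),
                           level = readr::col_character(),
                           .default = readr::col_double()
                         ))
  missing_cols <- setdiff(measurement_columns, names(raw))
  if (length(missing_cols) > 0)
    abort(paste0("Measurement file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  raw <- raw[measurement_columns]
  raw$day <- as.integer(raw$day)
  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  for (var in names(measurement_bounds)) {
    b <- measurement_bounds[[var]]
    v <- raw[[var]]
    flag(!is.na(v) & (v < b[1] | v > b[2]),
         paste0(sub("_pct|_ppm|_C", "", var), " out of range"))
  }
  flag(!is.na(raw$side) & !raw$side %in% valid_sides, "unknown side")
  flag(!is.na(raw$level) & !raw$level %in% valid_levels, "unknown level")
  flag(is.na(raw$pile_id) | is.na(raw$day) | is.na(raw$distance_m) |
         is.na(raw$side) | is.na(raw$level), "missing location key")
  rejects <- dplyr::mutate(raw[!is.na(reason), ],
                           reject_reason = reason[!is.na(reason)])
  kept <- raw[is.na(reason), ]
  if (!is.null(rejects_path))
    readr::write_csv(rejects, rejects_path, progress = FALSE)
  attr(kept, "rejects") <- rejects
  kept
}

#' Write measurement records
#'
#' @param records A measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  readr::write_csv(as_tibble(records)[measurement_columns], path,
                   progress = FALSE)
  invisible(path)
}

#' Split records into complete and incomplete
#'
#' Incomplete and uncertain readings are rejected before modelling: a record
#' missing any of temperature, O2 or CO2 cannot be classified (the spot
#' criteria need all three simultaneously) and is routed to the rejected set.
#' A missing CO value alone does not reject a record for spot analysis, since
#' the hot/cold criteria do not use CO; set `require_co = TRUE` when CO fields
#' are to be reconstructed. Field values are never altered and input order is
#' preserved; `kept` and `rejected` partition the input.
#'
#' @param records A measurement tibble.
#' @param require_co Also require a CO value. Default `FALSE`.
#' @return A list with tibbles `kept` and `rejected`.
#' @export
reject_incomplete <- function(records, require_co = FALSE) {
  records <- as_tibble(records)
  bad <- is.na(records$temp_C) | is.na(records$o2_pct) | is.na(records$co2_pct)
  if (require_co) bad <- bad | is.na(records$co_ppm)
  list(kept = records[!bad, ], rejected = records[bad, ])
}

published_spots_md5 <- "1470e59c82e5f6f599625189948274ec"

#' Load the published hot/cold spot inventory
#'
#' Returns the campaign-level spot inventory reported for the six-pile
#' industrial study, packaged as a plain-text fixture: one record per
#' (pile, day, cross-section distance) occurrence, typed hot or cold, with
#' the reported localization phrase and its zone tags. Rows listing several
#' distances expand to one record each. The fixture is checksum-guarded.
#'
#' @return A spot inventory tibble (see [detect_spots()] for the schema) with
#'   provenance `"published-fixture"`.
#' @examples
#' inv <- load_published_inventory()
#' count_spots(inv, "A1", "hot")  # 6
#' @export
load_published_inventory <- function() {
  path <- system.file("extdata", "published_spots.csv", package = "pilespot",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, published_spots_md5))
    abort("Published spot fixture failed its checksum; refusing to load.")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = "cciccc")
  out <- raw |>
    dplyr::mutate(distance_m = purrr::map(.data$distances_m, function(s)
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))) |>
    tidyr::unnest("distance_m") |>
    dplyr::transmute(
      pile_id = .data$pile_id, day = as.integer(.data$day),
      distance_m = .data$distance_m, type = .data$type,
      zones = purrr::map(.data$zones, function(s)
        strsplit(s, ";", fixed = TRUE)[[1]]),
      probes = purrr::map(.data$pile_id, function(...) character()),
      localization = .data$localization
    )
  new_spot_inventory(out, provenance = "published-fixture")
}

new_spot_inventory <- function(x, provenance) {
  x <- as_tibble(x)
  key <- paste(x$pile_id, x$day, x$distance_m, x$type)
  if (anyDuplicated(key))
    abort("Spot inventory has duplicate (pile, day, distance, type) keys.")
  attr(x, "provenance") <- provenance
  class(x) <- c("spot_inventory", setdiff(class(x), "spot_inventory"))
  x
}

#' @export
print.spot_inventory <- function(x, ...) {
  cat("Spot inventory (", attr(x, "provenance"), "): ", nrow(x),
      " records\n", sep = "")
  NextMethod()
}

#' Write / read a spot inventory as CSV
#'
#' One row per spot record; multi-valued columns (`zones`, `probes`) are
#' semicolon-collapsed. Reading back a written inventory reproduces it.
#'
#' @param inventory A spot inventory tibble.
#' @param path CSV path.
#' @return `path` invisibly (write); the inventory (read).
#' @export
write_spot_inventory <- function(inventory, path) {
  flat <- as_tibble(inventory) |>
    dplyr::mutate(
      zones = purrr::map_chr(.data$zones, paste, collapse = ";"),
      probes = purrr::map_chr(.data$probes, paste, collapse = ";")
    )
  flat$localization <- flat$localization %||% NA_character_
  readr::write_csv(flat, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_spot_inventory
#' @param provenance Provenance tag to attach on read.
#' @export
read_spot_inventory <- function(path, provenance = "measured") {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           pile_id = readr::col_character(),
                           day = readr::col_integer(),
                           distance_m = readr::col_double(),
                           type = readr::col_character(),
                           zones = readr::col_character(),
                           probes = readr::col_character(),
                           .default = readr::col_character()
                         ))
  split_col <- function(s) {
    purrr::map(s, function(el) {
      if (is.na(el) || el == "") character()
      else strsplit(el, ";", fixed = TRUE)[[1]]
    })
  }
  raw$zones <- split_col(raw$zones)
  raw$probes <- split_col(raw$probes)
  new_spot_inventory(raw, provenance = provenance)
}

#' Write / read a field grid as an ESRI ASCII raster
#'
#' Standard 6-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows from the top of the grid
#' down; nodes outside the pile outline mask are NODATA.
#'
#' @param grid A `field_grid` object.
#' @param path Output path (conventionally `.asc`).
#' @return `path` invisibly (write); a `field_grid` (read; plane metadata is
#'   not representable in the format and is left unset).
#' @export
write_field_grid <- function(grid, path) {
  stopifnot(inherits(grid, "field_grid"))
  vals <- grid$values
  vals[!grid$mask] <- -9999
  hdr <- c(
    paste("ncols", ncol(vals)),
    paste("nrows", nrow(vals)),
    paste("xllcorner", format(grid$origin[1], digits = 12)),
    paste("yllcorner", format(grid$origin[2], digits = 12)),
    paste("cellsize", format(grid$cell_size_m, digits = 12)),
    "NODATA_value -9999"
  )
  # rows written top-down: matrix row 1 is the top (max v) row already
  body <- apply(vals, 1, function(r)
    paste(formatC(r, format = "g", digits = 9), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' @rdname write_field_grid
#' @export
read_field_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]])
  nrows <- as.integer(vals[["nrows"]])
  nodata <- vals[["nodata_value"]]
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  if (length(body) != nrows)
    abort("Corrupt ESRI ASCII grid: row count does not match header.")
  m <- do.call(rbind, lapply(body, as.numeric))
  if (ncol(m) != ncols)
    abort("Corrupt ESRI ASCII grid: column count does not match header.")
  mask <- m != nodata
  m[!mask] <- NA_real_
  new_field_grid(values = m, mask = mask,
                 origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
                 cell_size_m = vals[["cellsize"]],
                 plane = NA_character_, variable = NA_character_)
}
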