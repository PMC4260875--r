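#' @importFrom utils read.csv write.csv head
NULL

facility_categories <- c("mobile", "satellite", "phc", "cdc", "chc",
                         "district_hospital", "regional_hospital",
                         "tertiary_hospital", "parastatal")

facility_columns <- c("id", "name", "category", "district_id",
                      "latitude", "longitude", "annual_volume")

laboratory_columns <- c("id", "latitude", "longitude", "district_id", "tier",
                        "instrument_capacity_per_day",
                        "offers_general_pathology")

#' Validate a facility registry
#'
#' Checks the schema and invariants of a referring-facility table: required
#' columns present, ids unique, categories drawn from the recognised
#' facility types, WGS84 coordinates in range, and non-negative annual test
#' volumes. Missing volumes are set to 0 with a warning (registries are
#' often incomplete and zero is conservative for capacity planning).
#' Violations are reported with the offending row numbers.
#'
#' @param x A data.frame with columns
#'   `id,name,category,district_id,latitude,longitude,annual_volume`.
#' @return The validated data.frame, classed `facility_registry`.
#' @export
facility_registry <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(facility_columns, names(x))
  if (length(missing_cols)) {
    stop("facility registry is missing required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$id <- as.character(x$id)
  x$name <- as.character(x$name)
  x$category <- as.character(x$category)
  x$district_id <- as.character(x$district_id)
  dup <- duplicated(x$id)
  if (any(dup)) {
    stop("duplicate facility id(s): ",
         paste(unique(x$id[dup]), collapse = ", "), call. = FALSE)
  }
  bad_cat <- which(!x$category %in% facility_categories)
  if (length(bad_cat)) {
    stop("unknown facility category in row(s) ",
         paste(head(bad_cat, 5L), collapse = ", "), ": ",
         paste(unique(x$category[bad_cat]), collapse = ", "), call. = FALSE)
  }
  check_coordinates(x$latitude, x$longitude, what = "facility")
  if (anyNA(x$annual_volume)) {
    warning("annual_volume missing in ", sum(is.na(x$annual_volume)),
            " row(s); treated as 0", call. = FALSE)
    x$annual_volume[is.na(x$annual_volume)] <- 0
  }
  bad_vol <- which(x$annual_volume < 0)
  if (length(bad_vol)) {
    stop("negative annual_volume in row(s) ",
         paste(head(bad_vol, 5L), collapse = ", "), call. = FALSE)
  }
  x$annual_volume <- as.integer(round(x$annual_volume))
  rownames(x) <- NULL
  class(x) <- c("facility_registry", "data.frame")
  x
}

#' Validate a laboratory registry
#'
#' Same contract as [facility_registry()] for testing laboratories: unique
#' ids, coordinates in range, non-negative instrument capacity, tier either
#' `NA` (unassigned) or one of `T1..T6`.
#'
#' @param x A data.frame with columns `id,latitude,longitude,district_id,`
#'   `tier,instrument_capacity_per_day,offers_general_pathology`.
#' @return The validated data.frame, classed `laboratory_registry`.
#' @export
laboratory_registry <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(laboratory_columns, names(x))
  if (length(missing_cols)) {
    stop("laboratory registry is missing required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$id <- as.character(x$id)
  x$district_id <- as.character(x$district_id)
  dup <- duplicated(x$id)
  if (any(dup)) {
    stop("duplicate laboratory id(s): ",
         paste(unique(x$id[dup]), collapse = ", "), call. = FALSE)
  }
  check_coordinates(x$latitude, x$longitude, what = "laboratory")
  x$tier <- as.character(x$tier)
  x$tier[x$tier %in% c("", "NA", "unassigned")] <- NA_character_
  bad_tier <- which(!is.na(x$tier) & !x$tier %in% paste0("T", 1:6))
  if (length(bad_tier)) {
    stop("invalid tier in row(s) ", paste(head(bad_tier, 5L), collapse = ", "),
         " (expected T1..T6 or unassigned)", call. = FALSE)
  }
  if (anyNA(x$instrument_capacity_per_day) ||
      any(x$instrument_capacity_per_day < 0)) {
    stop("instrument_capacity_per_day must be non-negative and complete",
         call. = FALSE)
  }
  x$instrument_capacity_per_day <- as.integer(x$instrument_capacity_per_day)
  x$offers_general_pathology <- as.logical(x$offers_general_pathology)
  rownames(x) <- NULL
  class(x) <- c("laboratory_registry", "data.frame")
  x
}

check_coordinates <- function(lat, lon, what = "point") {
  bad <- which(is.na(lat) | is.na(lon) | lat < -90 | lat > 90 |
                 lon < -180 | lon > 180)
  if (length(bad)) {
    stop(what, " coordinates out of range (lat [-90,90], lon [-180,180]) ",
         "in row(s) ", paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a facility registry from CSV or GeoJSON
#'
#' @param path File path.
#' @param format `"csv"` or `"geojson"`; guessed from the file extension by
#'   default. GeoJSON files must be a `FeatureCollection` of `Point`
#'   features with the registry fields as properties (`[lon, lat]`
#'   coordinate order per the GeoJSON standard).
#' @return A `facility_registry`.
#' @export
read_facilities <- function(path, format = c("auto", "csv", "geojson")) {
  facility_registry(read_registry(path, match.arg(format), facility_columns))
}

#' Read a laboratory registry from CSV or GeoJSON
#' @inheritParams read_facilities
#' @return A `laboratory_registry`.
#' @export
read_laboratories <- function(path, format = c("auto", "csv", "geojson")) {
  laboratory_registry(read_registry(path, match.arg(format),
                                    laboratory_columns))
}

read_registry <- function(path, format, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "geojson" else "csv"
  }
  if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(gj$type) || gj$type != "FeatureCollection") {
      stop("GeoJSON root must be a FeatureCollection", call. = FALSE)
    }
    rows <- lapply(seq_along(gj$features), function(i) {
      f <- gj$features[[i]]
      if (is.null(f$geometry) || f$geometry$type != "Point") {
        stop("feature ", i, " is not a Point", call. = FALSE)
      }
      props <- f$properties
      props$longitude <- f$geometry$coordinates[[1L]]
      props$latitude <- f$geometry$coordinates[[2L]]
      props[lengths(props) == 0] <- NA
      as.data.frame(props, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df[, intersect(columns, names(df)), drop = FALSE]
  }
}

#' Write a registry to CSV or GeoJSON
#'
#' Writes a facility or laboratory registry so that reading it back with
#' [read_facilities()] / [read_laboratories()] reproduces the registry
#' field-for-field. GeoJSON output uses `[longitude, latitude]` coordinate
#' order.
#'
#' @param x A `facility_registry` or `laboratory_registry`.
#' @param path Output file path.
#' @param format `"csv"` or `"geojson"` (guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_registry <- function(x, path, format = c("auto", "csv", "geojson")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "geojson" else "csv"
  }
  df <- as.data.frame(x)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else {
    prop_cols <- setdiff(names(df), c("latitude", "longitude"))
    features <- lapply(seq_len(nrow(df)), function(i) {
      props <- as.list(df[i, prop_cols, drop = FALSE])
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(df$longitude[i], df$latitude[i])),
           properties = props)
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = FALSE)
  }
  invisible(path)
}
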