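#' Read occurrence records
#'
#' Reads species occurrence records from CSV (columns `species_id`,
#' `site_id`, `site_name` or `name`, `lat`, `lon`, `management_area_id`) or
#' from a GeoJSON FeatureCollection of Point features carrying the same
#' properties (coordinates in `[lon, lat]` order per the GeoJSON standard).
#' Records are validated row by row — coordinate bounds, duplicate
#' (species, site) pairs — with errors naming the offending row and field.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"geojson"`, or `"auto"` (by file extension).
#' @return A named list of [vent_fields()] tables, one per `species_id`.
#' @examples
#' occ <- read_occurrences(
#'   system.file("extdata", "occurrences.csv", package = "ventrisk"))
#' names(occ)
#' @export
read_occurrences <- function(path, format = c("auto", "csv", "geojson")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
      "geojson"
    } else {
      "csv"
    }
  }
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  } else {
    geojson_to_df(path)
  }
  if ("site_name" %in% names(df) && !"name" %in% names(df)) {
    df$name <- df$site_name
  }
  need <- c("species_id", "site_id", "lat", "lon", "management_area_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("occurrence file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"name" %in% names(df)) df$name <- df$site_id
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  key <- paste(df$species_id, df$site_id)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key))
    stop("duplicate (species_id, site_id) at row(s): ",
         paste(rows, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$species_id), function(g) {
    rownames(g) <- NULL
    validate_vent_fields(g[, c("site_id", "name", "lat", "lon",
                               "management_area_id", "species_id")])
  })
  out[order(names(out))]
}

# internal: flatten a GeoJSON FeatureCollection of points to a data.frame
geojson_to_df <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("GeoJSON root must be a FeatureCollection", call. = FALSE)
  }
  rows <- lapply(seq_along(gj$features), function(i) {
    ft <- gj$features[[i]]
    if (!identical(ft$geometry$type, "Point")) {
      stop("feature ", i, ": only Point geometries are supported",
           call. = FALSE)
    }
    cc <- unlist(ft$geometry$coordinates)
    props <- ft$properties
    props$lon <- cc[1]
    props$lat <- cc[2]
    as.data.frame(props, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write occurrence records
#'
#' Inverse of [read_occurrences()]: writes one CSV (or GeoJSON
#' FeatureCollection) covering all species, preserving every field so that
#' a read/write round trip is lossless.
#'
#' @param species_fields A named list of [vent_fields()] tables (as returned
#'   by [read_occurrences()]), or a single table.
#' @param path Output path.
#' @param format `"csv"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(species_fields, path,
                              format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (is.data.frame(species_fields)) species_fields <- list(species_fields)
  df <- do.call(rbind, lapply(species_fields, function(g) {
    as.data.frame(g)[, c("species_id", "site_id", "name", "lat", "lon",
                         "management_area_id")]
  }))
  rownames(df) <- NULL
  names(df)[names(df) == "name"] <- "site_name"
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    features <- lapply(seq_len(nrow(df)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(df$lon[i], df$lat[i])),
           properties = as.list(df[i, setdiff(names(df), c("lat", "lon"))]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a regime table from CSV
#'
#' Columns: `management_area_id`, `regime` (one of [REGIMES]), and optional
#' `jurisdiction`, `notes`.
#'
#' @param path Path to the CSV file.
#' @return A validated [regime_table()].
#' @export
read_regimes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_regime_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a scenario from JSON
#'
#' Format: `{"name": ..., "description": ..., "overrides": {"<area>":
#' "<REGIME>"}}`.
#'
#' @param path Path to the JSON file.
#' @return A [regime_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  regime_scenario(s$name %||% "scenario", unlist(s$overrides),
                  s$description %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise an assessment
#'
#' @param assessment A `redlist_assessment`.
#' @return A plain list ready for JSON serialisation (category, criteria
#'   string, per-criterion trace, metrics, threat flags, rationale).
#' @export
assessment_to_list <- function(assessment) {
  a <- assessment
  list(
    species_id = a$species_id,
    category = a$category,
    possibly_extinct = a$possibly_extinct,
    criteria_string = a$criteria_string,
    worst_case = a$worst_case,
    metrics = if (!is.null(a$metrics)) unclass(a$metrics),
    threat = if (!is.null(a$threat)) {
      t <- unclass(a$threat)
      t$location_regimes <- as.list(t$location_regimes)
      t
    },
    criteria = if (!is.null(a$criteria)) {
      lapply(a$criteria, function(r) {
        list(criterion = r$criterion, tier = r$tier,
             satisfied_conditions = r$satisfied_conditions)
      })
    },
    rationale = as.list(a$rationale)
  )
}

#' Write an assessment report
#'
#' Writes the machine-readable JSON form and, alongside it, a plain-text
#' rationale block mirroring the justification style of published
#' assessments.
#'
#' @param assessment A `redlist_assessment`.
#' @param path Output path for the JSON file; the text block goes to the
#'   same path with extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(assessment, path) {
  jsonlite::write_json(assessment_to_list(assessment), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(assessment)), con)
  invisible(path)
}
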