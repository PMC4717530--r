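#' Construct an occurrence table
#'
#' An occurrence table holds one row per georeferenced record: a species
#' identifier, decimal-degree coordinates (WGS84 assumed; geographic
#' distance is never used, all distances are environmental), and the 20
#' environmental values of [env_variable_set()].
#'
#' @param species character vector of species identifiers (non-empty).
#' @param lon,lat numeric coordinate vectors, decimal degrees.
#' @param env numeric matrix or data frame with the 20 environmental
#'   columns, names matching `env_set`.
#' @param env_set the environmental variable set (default the standard 20).
#' @return A data frame of class `occurrence_table` with columns
#'   `species`, `lon`, `lat` and the 20 environmental variables.
#' @export
occurrence_table <- function(species, lon, lat, env,
                             env_set = env_variable_set()) {
  env <- as.data.frame(env)
  check_env_columns(env, env_set)
  env <- env[, unclass(env_set), drop = FALSE]
  if (any(!nzchar(species)) || anyNA(species)) {
    stop("species identifiers must be non-empty", call. = FALSE)
  }
  n <- length(species)
  if (length(lon) != n || length(lat) != n || nrow(env) != n) {
    stop("species, lon, lat and env must have matching lengths", call. = FALSE)
  }
  if (anyNA(env)) stop("missing environmental values are not allowed",
                       call. = FALSE)
  out <- data.frame(species = as.character(species),
                    lon = as.numeric(lon), lat = as.numeric(lat),
                    env, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Read an occurrence table from CSV
#'
#' The file must be comma-delimited UTF-8 with a header containing
#' `species`, `lon`, `lat` and the 20 environmental variable names. Rows
#' with missing values are rejected.
#'
#' @param path path to the CSV file.
#' @param env_set environmental variable set defining required columns.
#' @return An [occurrence_table()].
#' @export
read_occurrences <- function(path, env_set = env_variable_set()) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", comment.char = "#")
  required <- c("species", "lon", "lat", unclass(env_set))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("occurrence file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("lon", "lat", unclass(env_set))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(df[[cn]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at data row %d", cn,
                   bad[1]), call. = FALSE)
    }
    if (anyNA(v) || any(!nzchar(df[[cn]]))) {
      stop(sprintf("missing value in column '%s' at data row %d", cn,
                   which(is.na(v) | !nzchar(df[[cn]]))[1]), call. = FALSE)
    }
    df[[cn]] <- v
  }
  occurrence_table(df$species, df$lon, df$lat,
                   df[, unclass(env_set), drop = FALSE], env_set)
}

#' Write an occurrence table to CSV
#'
#' @param occ an [occurrence_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  stopifnot(inherits(occ, "occurrence_table"))
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Environmental matrix of an occurrence table
#'
#' @param occ an [occurrence_table()].
#' @return Numeric matrix, one row per record, 20 environmental columns.
#' @export
env_matrix <- function(occ) {
  as.matrix(as.data.frame(occ)[, unclass(env_variable_set()), drop = FALSE])
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("Occurrence table: %d records, %d species\n",
              nrow(x), length(unique(x$species))))
  NextMethod()
}
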