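#' Construct an environmental grid
#'
#' A rectangular raster of environmental values. Indexing is 0-based and
#' row-major with the origin at the north-west corner (row 0 is the
#' northernmost row); all cell/coordinate conversions go through
#' [grid_cell_center()] so the convention lives in one place. Values are
#' defined exactly on masked (land) cells.
#'
#' @param env named list of numeric matrices (one per environmental
#'   variable, all the same dimension), names matching [env_variable_set()].
#' @param mask logical matrix of the same dimension; `TRUE` marks valid
#'   (land) cells.
#' @param cellsize cell edge length in decimal degrees.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(env, mask, cellsize = 0.05, xll = 0, yll = 0) {
  env_set <- env_variable_set()
  if (!setequal(names(env), unclass(env_set))) {
    stop("grid variables must be exactly the 20-variable set", call. = FALSE)
  }
  env <- env[unclass(env_set)]
  dims <- dim(env[[1]])
  ok <- vapply(env, function(m) identical(dim(m), dims), logical(1))
  if (!all(ok) || !identical(dim(mask), dims)) {
    stop("all grid layers and the mask must share one dimension",
         call. = FALSE)
  }
  for (nm in names(env)) env[[nm]][!mask] <- NA_real_
  structure(list(env = env, mask = mask, nrow = dims[1], ncol = dims[2],
                 cellsize = cellsize, xll = xll, yll = yll),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("Environmental grid: %d x %d cells (%d masked land cells), cellsize %g deg\n",
              x$nrow, x$ncol, sum(x$mask), x$cellsize))
  invisible(x)
}

#' Cell center coordinates
#'
#' The single place where grid indices are converted to geographic
#' coordinates: cell `(row, col)` is 0-based, row-major, row 0 at the
#' northern edge.
#'
#' @param grid an [env_grid()].
#' @param row,col 0-based cell indices (vectorized).
#' @return Data frame with `lon` and `lat` of the cell centers.
#' @export
grid_cell_center <- function(grid, row, col) {
  stopifnot(all(row >= 0), all(row < grid$nrow),
            all(col >= 0), all(col < grid$ncol))
  data.frame(lon = grid$xll + (col + 0.5) * grid$cellsize,
             lat = grid$yll + (grid$nrow - row - 0.5) * grid$cellsize)
}

#' Environmental values at cells
#'
#' @param grid an [env_grid()].
#' @param cells 2-column matrix of 0-based (row, col) indices.
#' @return Numeric matrix, one row per cell, 20 environmental columns.
#' @export
grid_env_at <- function(grid, cells) {
  cells <- matrix(as.integer(cells), ncol = 2)
  idx <- cbind(cells[, 1] + 1L, cells[, 2] + 1L)
  out <- vapply(grid$env, function(m) m[idx], numeric(nrow(cells)))
  if (nrow(cells) == 1L) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(grid$env)))
  out
}

#' Masked cells of a grid
#'
#' @param grid an [env_grid()].
#' @return 2-column integer matrix of 0-based (row, col) indices of land
#'   cells, in row-major order.
#' @export
grid_masked_cells <- function(grid) {
  w <- which(t(grid$mask))  # row-major order
  col <- (w - 1L) %% grid$ncol
  row <- (w - 1L) %/% grid$ncol
  cbind(row = row, col = col)
}

#' Write / read an environmental grid
#'
#' Plain-text multi-layer format: a six-line header in the ASCII-grid
#' convention (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`), then one block per variable introduced by a
#' `variable <name>` line followed by `nrows` rows of values, northernmost
#' row first. Masked-out cells carry the NODATA value. The round-trip is
#' lossless.
#'
#' @param grid an [env_grid()].
#' @param path file path.
#' @return `write_grid` returns `path` invisibly; `read_grid` an
#'   [env_grid()].
#' @export
write_grid <- function(grid, path) {
  nodata <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", grid$ncol), paste("nrows", grid$nrow),
               paste("xllcorner", format(grid$xll, digits = 17)),
               paste("yllcorner", format(grid$yll, digits = 17)),
               paste("cellsize", format(grid$cellsize, digits = 17)),
               paste("NODATA_value", nodata)), con)
  for (nm in names(grid$env)) {
    writeLines(paste("variable", nm), con)
    m <- grid$env[[nm]]
    m[!grid$mask] <- nodata
    writeLines(apply(m, 1, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[`, "", 1)
  if (!identical(keys, c("ncols", "nrows", "xllcorner", "yllcorner",
                         "cellsize", "NODATA_value"))) {
    stop("malformed grid header", call. = FALSE)
  }
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  ncol <- as.integer(vals[1]); nrow <- as.integer(vals[2])
  nodata <- vals[6]
  pos <- 7L
  env <- list()
  while (pos <= length(lines)) {
    vline <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (!identical(vline[1], "variable") || length(vline) != 2) {
      stop("malformed grid block header at line ", pos, call. = FALSE)
    }
    nm <- vline[2]
    block <- lines[pos + seq_len(nrow)]
    m <- t(vapply(strsplit(trimws(block), "\\s+"),
                  function(r) as.numeric(r), numeric(ncol)))
    if (any(dim(m) != c(nrow, ncol)) || anyNA(m)) {
      stop("grid block '", nm, "' has wrong dimensions", call. = FALSE)
    }
    env[[nm]] <- m
    pos <- pos + nrow + 1L
  }
  mask <- env[[1]] != nodata
  for (nm in names(env)) {
    if (!identical(unname(env[[nm]] == nodata), unname(!mask))) {
      stop("inconsistent NODATA mask across layers", call. = FALSE)
    }
    env[[nm]][!mask] <- NA_real_
  }
  env_grid(env, mask, cellsize = vals[5], xll = vals[3], yll = vals[4])
}
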