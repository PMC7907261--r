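#' Read a grid from an ESRI ASCII raster
#'
#' Parses the standard ESRI ASCII grid header (ncols, nrows,
#' xllcorner/yllcorner or xllcenter/yllcenter, cellsize, NODATA_value)
#' and the row-major value block. Nodata cells become NA.
#'
#' @param path file path.
#' @return an \code{agrisk_grid}.
#' @export
read_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
        grepl("^[A-Za-z_]", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path, ": need ",
         paste(req, collapse = ", "), call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  nodata <- hdr$nodata_value %||% -9999
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2
  if (is.null(xll) || is.null(yll))
    stop("malformed ESRI ASCII header in ", path,
         ": missing corner/center coordinates", call. = FALSE)
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ESRI ASCII body of ", path, " has ", length(vals),
         " values, expected ", nr * nc, call. = FALSE)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_layer(m, cs, origin = c(xll, yll + nr * cs), nodata = nodata)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Values are written at full double precision so a write-read round
#' trip is lossless; NA cells are written as the grid's nodata sentinel.
#'
#' @param grid an \code{agrisk_grid}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_grid <- function(grid, path) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10f", grid$origin[1]),
           sprintf("yllcorner %.10f", grid$origin[2] - nr * grid$cell_size),
           sprintf("cellsize %.10f", grid$cell_size),
           sprintf("NODATA_value %s", format(grid$nodata)))
  v[is.na(v)] <- grid$nodata
  body <- apply(v, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read several grids that must share one geometry
#'
#' @param paths named character vector of ESRI ASCII paths.
#' @return named list of grids; an error lists every layer whose
#'   geometry disagrees with the first.
#' @export
read_layers <- function(paths) {
  gs <- lapply(paths, read_grid)
  bad <- names(gs)[!vapply(gs, same_geometry, logical(1), b = gs[[1]])]
  if (length(bad))
    stop("layers with mismatching geometry: ",
         paste(bad, collapse = ", "), call. = FALSE)
  gs
}

#' Read a per-zone statistics table from CSV
#'
#' @param path CSV path; must contain a \code{zone} column.
#' @return data.frame.
#' @export
read_zone_table <- function(path) {
  tb <- utils::read.csv(path)
  if (!"zone" %in% names(tb))
    stop("zone table ", path, " lacks a `zone` column", call. = FALSE)
  tb
}
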