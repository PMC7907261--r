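#' Single-band raster grid
#'
#' The universal spatial carrier of the package: a numeric matrix with a
#' square-cell geometry. Cells are addressed row-major from the top-left
#' corner; the centre of cell \code{(r, c)} lies at
#' \code{origin + ((c - 0.5) * cell_size, -(r - 0.5) * cell_size)}.
#' Missing cells are stored as \code{NA} internally; the \code{nodata}
#' sentinel is only used when reading and writing files. Nodata cells are
#' excluded from every statistic and overlay.
#'
#' @param values numeric matrix (rows = grid rows, top row first).
#' @param cell_size cell edge length in metres (default 30, the common
#'   resolution of land-use products this model is applied to).
#' @param origin numeric length-2, (x, y) of the top-left corner.
#' @param nodata sentinel value used on disk for missing cells.
#' @return an object of class \code{agrisk_grid}.
#' @examples
#' g <- grid_layer(matrix(1:12, 3, 4), cell_size = 30)
#' summary(g)
#' @export
grid_layer <- function(values, cell_size = 30, origin = c(0, 0),
                       nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be a numeric (x, y) pair", call. = FALSE)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "agrisk_grid")
}

#' Categorical raster grid
#'
#' A grid whose cells hold integer class codes, with a code-to-label
#' lookup. Every non-nodata code must appear in the class table.
#'
#' @param values integer matrix of class codes.
#' @param class_table named integer vector or data.frame with columns
#'   \code{code} and \code{label}.
#' @inheritParams grid_layer
#' @return an object of class \code{agrisk_catgrid} (also
#'   \code{agrisk_grid}).
#' @export
categorical_grid <- function(values, class_table, cell_size = 30,
                             origin = c(0, 0), nodata = -9999) {
  g <- grid_layer(values, cell_size, origin, nodata)
  tab <- as_class_table(class_table)
  present <- unique(g$values[!is.na(g$values)])
  if (length(setdiff(present, tab$code)))
    stop("grid contains codes absent from `class_table`: ",
         paste(setdiff(present, tab$code), collapse = ", "), call. = FALSE)
  g$class_table <- tab
  class(g) <- c("agrisk_catgrid", class(g))
  g
}

as_class_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("code", "label") %in% names(x)))
    data.frame(code = as.integer(x$code), label = as.character(x$label))
  } else {
    data.frame(code = as.integer(x), label = names(x))
  }
}

#' Zone partition with attribute table
#'
#' A categorical grid of zone identifiers (administrative counties in the
#' intended application) paired with a per-zone attribute table. Zone ids
#' in the grid and rows of the table are bijective; each cell belongs to
#' exactly one zone.
#'
#' @param grid \code{agrisk_catgrid} (or integer matrix) of zone ids.
#' @param zone_table data.frame with a \code{zone} column of ids plus any
#'   per-zone statistics columns.
#' @inheritParams grid_layer
#' @return an object of class \code{agrisk_zonemap}.
#' @export
zone_map <- function(grid, zone_table, cell_size = 30, origin = c(0, 0)) {
  if (is.matrix(grid)) {
    ids <- sort(unique(as.vector(grid[!is.na(grid)])))
    labs <- if ("name" %in% names(zone_table))
      as.character(zone_table$name[match(ids, zone_table$zone)])
    else paste0("zone_", ids)
    grid <- categorical_grid(grid, data.frame(code = ids, label = labs),
                             cell_size = cell_size, origin = origin)
  }
  stopifnot(inherits(grid, "agrisk_catgrid"), is.data.frame(zone_table),
            "zone" %in% names(zone_table))
  ids_grid <- sort(unique(grid$values[!is.na(grid$values)]))
  ids_tab <- sort(unique(as.integer(zone_table$zone)))
  if (anyDuplicated(zone_table$zone))
    stop("duplicated zone ids in `zone_table`", call. = FALSE)
  if (!setequal(ids_grid, ids_tab))
    stop("zone ids in grid and table must be bijective; grid-only: ",
         paste(setdiff(ids_grid, ids_tab), collapse = ","), "; table-only: ",
         paste(setdiff(ids_tab, ids_grid), collapse = ","), call. = FALSE)
  structure(list(grid = grid, table = zone_table), class = "agrisk_zonemap")
}

#' @export
dim.agrisk_grid <- function(x) dim(x$values)

#' @export
as.matrix.agrisk_grid <- function(x, ...) x$values

#' Test that two grids share the same geometry
#'
#' All layers entering one analysis must share shape, cell size and origin
#' exactly; the package never resamples implicitly.
#' @param a,b grids (an \code{agrisk_zonemap} is compared via its grid).
#' @return logical.
#' @export
same_geometry <- function(a, b) {
  a <- layer_of(a); b <- layer_of(b)
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

layer_of <- function(x) if (inherits(x, "agrisk_zonemap")) x$grid else x

check_same_geometry <- function(...) {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!same_geometry(gs[[1]], gs[[i]]))
      stop("layers do not share geometry (shape/cell size/origin); ",
           "resample inputs explicitly before analysis", call. = FALSE)
  invisible(TRUE)
}

#' Cell-centre coordinates
#' @param grid an \code{agrisk_grid}.
#' @return list with matrices \code{x} and \code{y} of cell-centre
#'   coordinates in map units (metres).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xs <- grid$origin[1] + (seq_len(nc) - 0.5) * grid$cell_size
  ys <- grid$origin[2] - (seq_len(nr) - 0.5) * grid$cell_size
  list(x = matrix(xs, nr, nc, byrow = TRUE), y = matrix(ys, nr, nc))
}

# area of one cell in hectares (1 ha = 1e4 m^2)
cell_area_ha <- function(grid) grid$cell_size^2 / 1e4

#' @export
print.agrisk_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<agrisk_grid> %d x %d cells, %g m resolution\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (x, y): (%g, %g); nodata cells: %d\n",
              x$origin[1], x$origin[2], sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range: [%g, %g]\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.agrisk_catgrid <- function(x, ...) {
  cat(sprintf("<agrisk_catgrid> %d x %d cells, %g m resolution\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cnt <- table(factor(x$values[!is.na(x$values)], levels = x$class_table$code,
                      labels = x$class_table$label))
  print(cnt)
  invisible(x)
}

#' @export
print.agrisk_zonemap <- function(x, ...) {
  cat(sprintf("<agrisk_zonemap> %d zones over a %d x %d grid\n",
              nrow(x$table), nrow(x$grid$values), ncol(x$grid$values)))
  invisible(x)
}

#' @export
summary.agrisk_grid <- function(object, ...) {
  v <- object$values[!is.na(object$values)]
  out <- c(summary(v), n = length(v), nodata = sum(is.na(object$values)))
  out
}

#' Image plot of a grid
#'
#' @param x grid to plot.
#' @param main plot title.
#' @param col colour ramp.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.agrisk_grid <- function(x, main = NULL,
                             col = grDevices::hcl.colors(64, "YlOrRd",
                                                         rev = TRUE), ...) {
  v <- x$values
  # image() draws column-major from bottom-left; transpose + flip rows
  z <- t(v[rev(seq_len(nrow(v))), , drop = FALSE])
  xs <- x$origin[1] + c(0, ncol(v)) * x$cell_size
  ys <- x$origin[2] - c(nrow(v), 0) * x$cell_size
  graphics::image(seq(xs[1], xs[2], length.out = ncol(v)),
                  seq(ys[1], ys[2], length.out = nrow(v)),
                  z, col = col, xlab = "x (m)", ylab = "y (m)",
                  main = main, asp = 1, ...)
  invisible(x)
}
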