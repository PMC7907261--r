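#' Select at-risk cell centres as points
#'
#' Cells at or above a minimum risk grade become unit-weight points at
#' their centres — the input of the kernel density analysis. The default
#' minimum grade is 3 (medium): when no cell exceeds the high-risk cut
#' the medium-grade pattern spots are the ones worth mapping; raise it to
#' 4 to analyse high/extremely-high cells only.
#'
#' @param grade grade grid (or an \code{ito3de_risk}).
#' @param min_grade minimum grade included (default 3).
#' @return data.frame with columns \code{x}, \code{y}, \code{row},
#'   \code{col}; zero rows when no cell qualifies.
#' @export
select_at_risk_cells <- function(grade, min_grade = 3) {
  if (inherits(grade, "ito3de_risk")) grade <- grade$grade
  v <- grade$values
  sel <- which(!is.na(v) & v >= min_grade)
  cc <- cell_centers(grade)
  data.frame(x = cc$x[sel], y = cc$y[sel],
             row = (sel - 1L) %% nrow(v) + 1L,
             col = (sel - 1L) %/% nrow(v) + 1L)
}

#' Quartic-kernel density surface
#'
#' Planar kernel density with the quartic (biweight) kernel used by the
#' standard GIS tool: each point contributes
#' \eqn{(3 / (\pi h^2)) (1 - d^2/h^2)^2} for distances \eqn{d < h} and 0
#' beyond the bandwidth. Densities are reported per square kilometre.
#'
#' @param points data.frame with \code{x}, \code{y} columns (map metres).
#' @param bandwidth kernel radius h in metres.
#' @param geometry an \code{agrisk_grid} supplying the output geometry.
#' @return an \code{agrisk_grid} of densities (points per km^2).
#' @export
kernel_density_surface <- function(points, bandwidth, geometry) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("`bandwidth` must be a single positive number", call. = FALSE)
  nr <- nrow(geometry$values); nc <- ncol(geometry$values)
  out <- matrix(0, nr, nc)
  if (nrow(points)) {
    cs <- geometry$cell_size
    h2 <- bandwidth^2
    xs <- geometry$origin[1] + (seq_len(nc) - 0.5) * cs
    ys <- geometry$origin[2] - (seq_len(nr) - 0.5) * cs
    kcells <- ceiling(bandwidth / cs)
    norm <- 3 / (pi * h2)
    for (i in seq_len(nrow(points))) {
      px <- points$x[i]; py <- points$y[i]
      c0 <- floor((px - geometry$origin[1]) / cs) + 1
      r0 <- floor((geometry$origin[2] - py) / cs) + 1
      if (r0 + kcells < 1 || r0 - kcells > nr ||
          c0 + kcells < 1 || c0 - kcells > nc) next
      rs <- max(1, r0 - kcells):min(nr, r0 + kcells)
      cls <- max(1, c0 - kcells):min(nc, c0 + kcells)
      d2 <- outer((ys[rs] - py)^2, (xs[cls] - px)^2, "+")
      w <- 1 - d2 / h2
      w[w < 0] <- 0
      out[rs, cls] <- out[rs, cls] + norm * w^2
    }
  }
  # per m^2 -> per km^2
  grid_layer(out * 1e6, geometry$cell_size, geometry$origin, geometry$nodata)
}

#' Equal-interval 10-grade zoning of a density surface
#'
#' The density range [0, max] is split into 10 equal intervals; class k
#' covers ((k-1)w, kw] with w = max/10, class 1 including 0. The 10th
#' (top) class is the "gathering" mask — the high-risk gathering zones.
#'
#' @param density density grid.
#' @param n number of classes (default 10).
#' @return list with \code{grade10} (\code{agrisk_catgrid} of 1..n) and
#'   \code{gathering_mask} (0/1 grid of the top class).
#' @export
equal_interval_grades <- function(density, n = 10) {
  v <- density$values
  mx <- suppressWarnings(max(v, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0)
    stop("density surface is all zero (or nodata); nothing to zone",
         call. = FALSE)
  w <- mx / n
  k <- ceiling(v / w)
  k[!is.na(v) & v == 0] <- 1L
  k[k > n] <- n  # numerical guard at the exact maximum
  tab <- data.frame(code = seq_len(n), label = paste0("grade_", seq_len(n)))
  grade10 <- categorical_grid(k, tab, density$cell_size, density$origin,
                              density$nodata)
  mask <- grid_layer((!is.na(k) & k == n) * 1, density$cell_size,
                     density$origin, density$nodata)
  mask$values[is.na(v)] <- NA_real_
  list(grade10 = grade10, gathering_mask = mask)
}

#' Connected gathering zones of a density surface
#'
#' Labels 8-connected components of the gathering mask and reports their
#' centroids and areas.
#'
#' @param mask 0/1 gathering mask grid.
#' @return data.frame with \code{zone}, \code{cells}, \code{area_ha},
#'   \code{x}, \code{y} (centroid of cell centres).
#' @export
gathering_zones <- function(mask) {
  v <- mask$values
  sel <- which(!is.na(v) & v == 1)
  if (!length(sel))
    return(data.frame(zone = integer(), cells = integer(),
                      area_ha = numeric(), x = numeric(), y = numeric()))
  nr <- nrow(v)
  r <- (sel - 1L) %% nr + 1L
  c_ <- (sel - 1L) %/% nr + 1L
  key <- function(rr, cc) (cc - 1L) * nr + rr
  idx <- stats::setNames(seq_along(sel), key(r, c_))
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb <- key(r + off[1], c_ + off[2])
    hit <- !is.na(idx[as.character(nb)])
    if (any(hit))
      edges <- c(edges, rbind(seq_along(sel)[hit],
                              idx[as.character(nb[hit])]))
  }
  g <- igraph::make_graph(edges = edges, n = length(sel), directed = FALSE)
  comp <- igraph::components(g)$membership
  cc <- cell_centers(mask)
  agg <- data.frame(zone = sort(unique(comp)))
  agg$cells <- as.integer(table(comp)[as.character(agg$zone)])
  agg$area_ha <- agg$cells * cell_area_ha(mask)
  agg$x <- tapply(cc$x[sel], comp, mean)[as.character(agg$zone)]
  agg$y <- tapply(cc$y[sel], comp, mean)[as.character(agg$zone)]
  agg[order(-agg$cells), ]
}

#' Kernel density analysis of a risk surface
#'
#' Full kernel-density stage: select at-risk cells, estimate the quartic
#' kernel density, zone it into 10 equal-interval grades and extract the
#' gathering zones (top class).
#'
#' @param x grade grid or \code{ito3de_risk}.
#' @param bandwidth kernel radius in metres; default 30 cell widths.
#' @param min_grade minimum grade treated as at-risk (default 3).
#' @return object of class \code{risk_kde}: list with \code{points},
#'   \code{density}, \code{grade10}, \code{gathering_mask},
#'   \code{zones}, \code{bandwidth}, \code{min_grade}.
#' @export
risk_kde <- function(x, bandwidth = NULL, min_grade = 3) {
  grade <- if (inherits(x, "ito3de_risk")) x$grade else x
  if (is.null(bandwidth)) bandwidth <- 30 * grade$cell_size
  pts <- select_at_risk_cells(grade, min_grade)
  dens <- kernel_density_surface(pts, bandwidth, grade)
  if (any(dens$values > 0, na.rm = TRUE)) {
    zoning <- equal_interval_grades(dens, 10)
    zones <- gathering_zones(zoning$gathering_mask)
  } else {
    zoning <- list(grade10 = NULL, gathering_mask = NULL)
    zones <- gathering_zones(grid_layer(matrix(0, nrow(dens$values),
                                               ncol(dens$values)),
                                        dens$cell_size, dens$origin))
  }
  structure(list(points = pts, density = dens, grade10 = zoning$grade10,
                 gathering_mask = zoning$gathering_mask, zones = zones,
                 bandwidth = bandwidth, min_grade = min_grade),
            class = "risk_kde")
}

#' @export
print.risk_kde <- function(x, ...) {
  cat(sprintf(
    "Kernel density of %d at-risk cells (grade >= %d), h = %g m\n",
    nrow(x$points), x$min_grade, x$bandwidth))
  mx <- suppressWarnings(max(x$density$values, na.rm = TRUE))
  cat(sprintf("Peak density: %.1f points/km^2; gathering zones: %d\n",
              mx, nrow(x$zones)))
  invisible(x)
}
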