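#' Focal (neighbourhood) statistic
#'
#' Moving-window statistic over a square window, the GIS
#' "neighbourhood statistics" operation. Nodata cells are ignored within
#' each window; a cell is nodata only when its whole window is nodata.
#' Windows are truncated at the grid edge (no padding).
#'
#' @param grid an \code{agrisk_grid}.
#' @param window odd positive window edge length in cells (e.g. 7 for the
#'   7 x 7 window used for relief amplitude).
#' @param stat one of \code{"range"}, \code{"mean"}, \code{"min"},
#'   \code{"max"}.
#' @return an \code{agrisk_grid} with the same geometry.
#' @export
focal_statistic <- function(grid, window,
                            stat = c("range", "mean", "min", "max")) {
  stat <- match.arg(stat)
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0)
    stop("`window` must be a positive odd integer", call. = FALSE)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr == 0L || nc == 0L) stop("empty grid", call. = FALSE)
  k <- (window - 1L) / 2L
  # running accumulators over the window offsets; NA never wins
  mn <- matrix(Inf, nr, nc); mx <- matrix(-Inf, nr, nc)
  sm <- matrix(0, nr, nc); cnt <- matrix(0L, nr, nc)
  for (dr in -k:k) {
    rs <- seq_len(nr) + dr
    ok_r <- rs >= 1L & rs <= nr
    for (dc in -k:k) {
      cs <- seq_len(nc) + dc
      ok_c <- cs >= 1L & cs <= nc
      if (!any(ok_r) || !any(ok_c)) next
      src <- v[rs[ok_r], cs[ok_c], drop = FALSE]
      tgt_r <- which(ok_r); tgt_c <- which(ok_c)
      has <- !is.na(src)
      if (stat %in% c("min", "range")) {
        cur <- mn[tgt_r, tgt_c, drop = FALSE]
        cur[has] <- pmin(cur[has], src[has])
        mn[tgt_r, tgt_c] <- cur
      }
      if (stat %in% c("max", "range")) {
        cur <- mx[tgt_r, tgt_c, drop = FALSE]
        cur[has] <- pmax(cur[has], src[has])
        mx[tgt_r, tgt_c] <- cur
      }
      if (stat == "mean") {
        cur <- sm[tgt_r, tgt_c, drop = FALSE]
        cur[has] <- cur[has] + src[has]
        sm[tgt_r, tgt_c] <- cur
      }
      cc <- cnt[tgt_r, tgt_c, drop = FALSE]
      cc[has] <- cc[has] + 1L
      cnt[tgt_r, tgt_c] <- cc
    }
  }
  out <- switch(stat,
                range = mx - mn,
                min   = mn,
                max   = mx,
                mean  = sm / cnt)
  out[cnt == 0L] <- NA_real_
  grid_layer(out, grid$cell_size, grid$origin, grid$nodata)
}

#' Euclidean distance to the nearest source cell
#'
#' Distance-to-feature transform: each cell receives the straight-line
#' distance in metres from its centre to the nearest centre of a source
#' (mask = 1) cell. Source cells receive 0.
#'
#' @param mask an \code{agrisk_grid} of 0/1 values (NA allowed; NA cells
#'   still receive a distance).
#' @return an \code{agrisk_grid} of distances in metres.
#' @export
euclidean_distance <- function(mask) {
  v <- mask$values
  nr <- nrow(v); nc <- ncol(v)
  src <- which(!is.na(v) & v == 1)
  if (!length(src)) stop("mask contains no source (1) cells", call. = FALSE)
  sr <- (src - 1L) %% nr + 1L
  sc <- (src - 1L) %/% nr + 1L
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc)
  chunk <- 64L
  for (s in seq(1L, length(src), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(src))
    d2 <- outer(as.vector(rows), sr[idx], "-")^2 +
          outer(as.vector(cols), sc[idx], "-")^2
    best <- pmin(best, matrix(do.call(pmin, asplit(d2, 2L)), nr, nc))
  }
  grid_layer(sqrt(best) * mask$cell_size, mask$cell_size, mask$origin,
             mask$nodata)
}

#' Spread per-zone totals uniformly over a mask
#'
#' Implements the "evenly dispersed" spatialization assumption: a zone's
#' total amount (e.g. kg of fertilizer) is distributed uniformly over the
#' zone's mask cells (e.g. farmland) as an intensity per hectare.
#' Non-mask cells receive 0. A zone with a positive total but no mask
#' cells is reported in a warning and its cells stay 0 (the total is
#' dropped, keeping the dispersal semantics literal).
#'
#' @param zones an \code{agrisk_zonemap}.
#' @param totals named numeric vector of per-zone amounts (names = zone
#'   ids) or a numeric vector aligned with \code{zones$table$zone}.
#' @param mask 0/1 \code{agrisk_grid} of cells eligible to receive mass.
#' @return an \code{agrisk_grid} of intensities (amount per hectare).
#' @export
zonal_spread <- function(zones, totals, mask) {
  check_same_geometry(zones, mask)
  zid <- zones$grid$values
  m <- !is.na(mask$values) & mask$values == 1 & !is.na(zid)
  if (is.null(names(totals))) {
    stopifnot(length(totals) == nrow(zones$table))
    names(totals) <- as.character(zones$table$zone)
  }
  counts <- table(zid[m])
  out <- matrix(0, nrow(zid), ncol(zid))
  dropped <- character()
  for (z in names(totals)) {
    tz <- totals[[z]]
    if (is.na(tz) || tz == 0) next
    n <- if (z %in% names(counts)) as.integer(counts[[z]]) else 0L
    if (n == 0L) { dropped <- c(dropped, z); next }
    out[m & zid == as.numeric(z)] <- tz / (n * cell_area_ha(zones$grid))
  }
  if (length(dropped))
    warning("zones with positive totals but no mask cells (totals dropped): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out[is.na(zid)] <- NA_real_
  grid_layer(out, zones$grid$cell_size, zones$grid$origin, zones$grid$nodata)
}

#' Per-zone mean of a grid
#'
#' @param zones an \code{agrisk_zonemap}.
#' @param grid grid to summarise.
#' @return data.frame with columns \code{zone} and \code{mean}; a zone
#'   that is entirely nodata in \code{grid} gets \code{NA}.
#' @export
zonal_mean <- function(zones, grid) {
  check_same_geometry(zones, grid)
  zid <- zones$grid$values
  ok <- !is.na(zid) & !is.na(grid$values)
  means <- tapply(grid$values[ok], zid[ok], mean)
  zs <- zones$table$zone
  data.frame(zone = zs,
             mean = as.numeric(means[match(as.character(zs), names(means))]))
}

#' Class area proportions of a categorical grid
#'
#' @param categorical an \code{agrisk_catgrid}.
#' @return data.frame with columns \code{code}, \code{label},
#'   \code{percent}; percentages of the non-nodata area, summing to 100.
#' @export
area_proportions <- function(categorical) {
  v <- categorical$values[!is.na(categorical$values)]
  if (!length(v)) stop("grid is entirely nodata", call. = FALSE)
  tab <- categorical$class_table
  cnt <- table(factor(v, levels = tab$code))
  data.frame(code = tab$code, label = tab$label,
             percent = 100 * as.numeric(cnt) / length(v))
}
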