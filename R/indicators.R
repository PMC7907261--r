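#' Default indicator specifications
#'
#' Static description of the twelve indicators of the three-dimensional
#' ("Input-Translate-Output") risk model: dimension membership, direction,
#' reference value and weight. Directions: risk rises with the raw value
#' for positive indices (index = C/E) and falls for negative indices
#' (index = E/C). The distance-to-water, water-capacity, water-network
#' and paddy-retention indicators (I8, I10, I11, I12) are negative; all
#' others positive. I3 and I9 have no scalar reference: they are Nemerow
#' composites of ratio sub-indices that are already reference-scaled.
#'
#' Reference values: fertilizer 250 kg/ha (national ecological-county
#' construction standard), pesticide 2.5 kg/ha (internationally
#' recognised safe usage), rainfall erosivity 100 J cm/(ha h), relief
#' amplitude 50 m over a 7 x 7 window, field slope 15 degrees, distance
#' to water 1500 m, runoff modulus 61.95, lake/reservoir density
#' 0.025 km^2/km^2 and river density 0.404 km/km^2, paddy share of
#' farmland 0.3339 (long-term regional averages).
#'
#' @return data.frame with one row per indicator: \code{id},
#'   \code{dimension}, \code{direction}, \code{reference}, \code{weight},
#'   \code{description}.
#' @export
indicator_specs <- function() {
  data.frame(
    id = paste0("I", 1:12),
    dimension = c(rep("Input", 3), rep("Translate", 5), rep("Output", 4)),
    direction = c("positive", "positive", "positive", "positive", "positive",
                  "positive", "positive", "negative", "positive", "negative",
                  "negative", "negative"),
    reference = c(250, 2.5, NA, 100, 50, NA, 15, 1500, NA, 61.95, 1, 0.3339),
    weight = c(0.547, 0.339, 0.114,
               0.290, 0.098, 0.182, 0.267, 0.163,
               0.347, 0.293, 0.153, 0.207),
    description = c(
      "chemical fertilizer use intensity per unit farmland area",
      "pesticide use intensity per unit farmland area",
      "livestock breeding intensity (Nemerow composite of ratios)",
      "rainfall erosivity",
      "relief amplitude (7x7 neighbourhood elevation range)",
      "soil erodibility by land-use class",
      "sloping-field ratio against the 15 degree reference",
      "distance from water area",
      "water quality (Nemerow composite of COD, NH3-N, TP indices)",
      "water capacity (runoff generation modulus ratio)",
      "water network density (river + lake/reservoir density)",
      "paddy field retention (paddy share of farmland)"))
}

# normalized indices are capped so composites stay finite near zero
# denominators while lying safely above the extremely-high-risk cut (5.0)
CAP_VALUE <- 10

#' Normalize a positive-direction indicator
#'
#' Risk rises with the raw value: index = C / E, capped at the package
#' cap (10).
#'
#' @param C raw-value grid (or numeric); values must be >= 0.
#' @param E positive scalar reference value.
#' @param cap upper cap applied after division.
#' @return grid (or numeric) of dimensionless index values.
#' @export
normalize_positive <- function(C, E, cap = CAP_VALUE) {
  if (!is.numeric(E) || length(E) != 1L || is.na(E) || E <= 0)
    stop("reference value `E` must be a single positive number",
         call. = FALSE)
  f <- function(v) pmin(v / E, cap)
  if (inherits(C, "agrisk_grid"))
    grid_layer(f(C$values), C$cell_size, C$origin, C$nodata)
  else f(C)
}

#' Normalize a negative-direction indicator
#'
#' Risk falls with the raw value: index = E / C. Raw values below
#' \code{E / cap} are clamped to that floor before division, which
#' realises the cap exactly (a zero distance to water maps to the cap).
#'
#' @inheritParams normalize_positive
#' @return grid (or numeric) of dimensionless index values.
#' @export
normalize_negative <- function(C, E, cap = CAP_VALUE) {
  if (!is.numeric(E) || length(E) != 1L || is.na(E) || E <= 0)
    stop("reference value `E` must be a single positive number",
         call. = FALSE)
  floor_c <- E / cap
  f <- function(v) E / pmax(v, floor_c)
  if (inherits(C, "agrisk_grid"))
    grid_layer(f(C$values), C$cell_size, C$origin, C$nodata)
  else f(C)
}

#' Nemerow composite index
#'
#' Combines sub-indices by the Nemerow environmental-quality form
#' \eqn{P = \sqrt{(\bar P^2 + P_{max}^2)/2}}, which up-weights the worst
#' sub-index relative to a plain mean. Used for the livestock (I3) and
#' water-quality (I9) indicators.
#'
#' @param sub_indices list of grids sharing one geometry, or a numeric
#'   vector/matrix of sub-index values (combined along the list / vector).
#' @return grid (or numeric scalar) of composite values.
#' @export
nemerow_index <- function(sub_indices) {
  if (is.numeric(sub_indices)) {
    p <- sub_indices
    if (!length(p)) stop("no sub-indices supplied", call. = FALSE)
    if (any(p < 0, na.rm = TRUE))
      stop("sub-indices must be >= 0", call. = FALSE)
    return(sqrt((mean(p)^2 + max(p)^2) / 2))
  }
  if (!length(sub_indices)) stop("no sub-indices supplied", call. = FALSE)
  do.call(check_same_geometry, sub_indices)
  arr <- vapply(sub_indices, function(g) g$values,
                sub_indices[[1]]$values)
  if (any(arr < 0, na.rm = TRUE))
    stop("sub-indices must be >= 0", call. = FALSE)
  dims <- dim(sub_indices[[1]]$values)
  arr <- array(arr, c(dims, length(sub_indices)))
  pbar <- apply(arr, c(1, 2), mean)
  pmax_ <- apply(arr, c(1, 2), max)
  g1 <- sub_indices[[1]]
  grid_layer(sqrt((pbar^2 + pmax_^2) / 2), g1$cell_size, g1$origin, g1$nodata)
}

# assign a per-zone value uniformly to cells of a mask (or zone-wide when
# mask is NULL); cells outside get `fill`
zonal_assign <- function(zones, values, mask = NULL, fill = 0) {
  zid <- zones$grid$values
  if (is.null(names(values))) {
    stopifnot(length(values) == nrow(zones$table))
    names(values) <- as.character(zones$table$zone)
  }
  out <- matrix(fill, nrow(zid), ncol(zid))
  sel_all <- !is.na(zid)
  if (!is.null(mask)) sel_all <- sel_all & !is.na(mask$values) & mask$values == 1
  vz <- values[as.character(zid[sel_all])]
  out[sel_all] <- as.numeric(vz)
  out[is.na(zid)] <- NA_real_
  grid_layer(out, zones$grid$cell_size, zones$grid$origin, zones$grid$nodata)
}

#' Build one normalized indicator layer
#'
#' Dispatches the recipe for one of the twelve indicators. The
#' \code{inputs} list supplies what each recipe needs (see Details);
#' missing pieces raise an error naming the indicator.
#'
#' @details Recipes (E = reference from \code{\link{indicator_specs}}):
#' \describe{
#'   \item{I1/I2}{per-zone fertilizer/pesticide totals (kg) spread evenly
#'     over the farmland mask, plus an optional local intensity surcharge
#'     grid (\code{fert_extra}/\code{pest_extra}, kg/ha), then C/E.}
#'   \item{I3}{per-zone Nemerow composite of three livestock ratio
#'     sub-indices (pollution-load ratio, facility-deficiency ratio,
#'     scale ratio; columns \code{lv_load}, \code{lv_facility},
#'     \code{lv_scale}), assigned on the suitable-breeding mask.}
#'   \item{I4}{erosivity layer (plus optional \code{erosivity_extra}) / 100.}
#'   \item{I5}{7 x 7 focal range of the DEM / 50.}
#'   \item{I6}{land-use class -> soil erodibility K lookup, / reference K.}
#'   \item{I7}{slope(deg)/15 on farmland cells, 0 elsewhere.}
#'   \item{I8}{1500 / distance-to-water.}
#'   \item{I9}{per-zone Nemerow composite of COD, NH3-N and TP pollution
#'     indices (columns \code{cod}, \code{nh3n}, \code{tp}), zone-wide.}
#'   \item{I10}{61.95 / per-zone runoff modulus (column \code{runoff}),
#'     zone-wide.}
#'   \item{I11}{per-zone C = mean(river_density/0.404,
#'     lake_density/0.025); index = 1/C (columns \code{river_density},
#'     \code{lake_density}).}
#'   \item{I12}{per-zone paddy share p of farmland; 0.3339/p on paddy
#'     cells; non-paddy farmland receives the capped value (low paddy
#'     retention reads as risk); zone-wide assignment available via
#'     \code{paddy_mode = "zone"}.}
#' }
#'
#' @param id indicator id, \code{"I1"} .. \code{"I12"}.
#' @param inputs named list of input layers/tables; see Details.
#' @param spec one row of \code{\link{indicator_specs}} (defaults looked
#'   up by id).
#' @param config list of tunables: \code{cap} (default 10), \code{k_table}
#'   (named K lookup by land-use label), \code{k_reference},
#'   \code{focal_window} (default 7), \code{focal_stat} (default
#'   \code{"range"}), \code{paddy_mode} (\code{"paddy"} or \code{"zone"}).
#' @return an \code{agrisk_grid} of index values in [0, cap].
#' @export
build_indicator <- function(id, inputs, spec = NULL, config = list()) {
  specs <- indicator_specs()
  if (!id %in% specs$id) stop("unknown indicator id: ", id, call. = FALSE)
  if (is.null(spec)) spec <- specs[specs$id == id, ]
  cap <- config$cap %||% CAP_VALUE
  need <- function(what) {
    if (is.null(inputs[[what]]))
      stop(sprintf("indicator %s requires input `%s`", id, what),
           call. = FALSE)
    inputs[[what]]
  }
  zcol <- function(tbl, col) {
    if (!col %in% names(tbl))
      stop(sprintf("indicator %s requires zone-table column `%s`", id, col),
           call. = FALSE)
    stats::setNames(tbl[[col]], as.character(tbl$zone))
  }
  switch(id,
    I1 = , I2 = {
      zones <- need("zones"); farm <- need("farmland_mask")
      col <- if (id == "I1") "fert_total" else "pest_total"
      extra <- inputs[[if (id == "I1") "fert_extra" else "pest_extra"]]
      intensity <- zonal_spread(zones, zcol(zones$table, col), farm)
      if (!is.null(extra)) {
        check_same_geometry(intensity, extra)
        intensity$values <- intensity$values + extra$values
      }
      normalize_positive(intensity, spec$reference, cap)
    },
    I3 = {
      zones <- need("zones"); mask <- need("breeding_mask")
      tb <- zones$table
      p <- mapply(function(a, b, c) nemerow_index(c(a, b, c)),
                  zcol(tb, "lv_load"), zcol(tb, "lv_facility"),
                  zcol(tb, "lv_scale"))
      g <- zonal_assign(zones, pmin(p, cap), mask)
      g
    },
    I4 = {
      ero <- need("erosivity")
      extra <- inputs[["erosivity_extra"]]
      if (!is.null(extra)) {
        check_same_geometry(ero, extra)
        ero <- grid_layer(ero$values + extra$values, ero$cell_size,
                          ero$origin, ero$nodata)
      }
      normalize_positive(ero, spec$reference, cap)
    },
    I5 = {
      dem <- need("dem")
      w <- config$focal_window %||% 7L
      st <- config$focal_stat %||% "range"
      normalize_positive(focal_statistic(dem, w, st), spec$reference, cap)
    },
    I6 = {
      lu <- need("land_use")
      ktab <- config$k_table %||% need("k_table")
      kref <- config$k_reference %||% need("k_reference")
      lab <- lu$class_table$label[match(lu$values, lu$class_table$code)]
      kv <- matrix(unname(ktab[lab]), nrow(lu$values), ncol(lu$values))
      kv[is.na(lu$values)] <- NA_real_
      normalize_positive(grid_layer(kv, lu$cell_size, lu$origin, lu$nodata),
                         kref, cap)
    },
    I7 = {
      slope <- need("slope"); farm <- need("farmland_mask")
      check_same_geometry(slope, farm)
      idx <- normalize_positive(slope, spec$reference, cap)
      idx$values[!is.na(farm$values) & farm$values != 1] <- 0
      idx
    },
    I8 = {
      water <- need("water_mask")
      normalize_negative(euclidean_distance(water), spec$reference, cap)
    },
    I9 = {
      zones <- need("zones"); tb <- zones$table
      p <- mapply(function(a, b, c) nemerow_index(c(a, b, c)),
                  zcol(tb, "cod"), zcol(tb, "nh3n"), zcol(tb, "tp"))
      zonal_assign(zones, pmin(p, cap))
    },
    I10 = {
      zones <- need("zones")
      C <- zonal_assign(zones, zcol(zones$table, "runoff"))
      normalize_negative(C, spec$reference, cap)
    },
    I11 = {
      zones <- need("zones"); tb <- zones$table
      C <- (zcol(tb, "river_density") / 0.404 +
            zcol(tb, "lake_density") / 0.025) / 2
      normalize_negative(zonal_assign(zones, C), 1, cap)
    },
    I12 = {
      zones <- need("zones"); farm <- need("farmland_mask")
      paddy <- need("paddy_mask")
      zid <- zones$grid$values
      okf <- !is.na(farm$values) & farm$values == 1
      okp <- !is.na(paddy$values) & paddy$values == 1
      nf <- table(zid[okf]); np <- table(zid[okp])
      zs <- as.character(zones$table$zone)
      p <- as.numeric(np[zs]); p[is.na(p)] <- 0
      f <- as.numeric(nf[zs]); share <- ifelse(f > 0, p / f, 0)
      idx_z <- normalize_negative(share, spec$reference, cap)
      names(idx_z) <- zs
      mode <- config$paddy_mode %||% "paddy"
      if (mode == "zone") {
        zonal_assign(zones, idx_z)
      } else {
        g <- zonal_assign(zones, idx_z, mask = grid_layer(
          paddy$values, paddy$cell_size, paddy$origin, paddy$nodata))
        # non-paddy farmland: worst (capped) value so low retention reads
        # as risk; non-farmland stays 0
        g$values[okf & !okp] <- cap
        g
      }
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
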