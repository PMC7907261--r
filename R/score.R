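#' Default weight configuration
#'
#' Expert (Delphi-elicited) weights of the three-dimensional evaluation:
#' dimension weights A = 0.430 A1 + 0.231 A2 + 0.339 A3 and per-dimension
#' indicator weights A1 = 0.547 I1 + 0.339 I2 + 0.114 I3,
#' A2 = 0.290 I4 + 0.098 I5 + 0.182 I6 + 0.267 I7 + 0.163 I8,
#' A3 = 0.347 I9 + 0.293 I10 + 0.153 I11 + 0.207 I12.
#' Each weight set sums to 1.
#'
#' @return list with elements \code{dimensions} (named numeric) and
#'   \code{indicators} (named list of named numerics).
#' @export
ito3de_weights <- function() {
  w <- list(
    dimensions = c(A1 = 0.430, A2 = 0.231, A3 = 0.339),
    indicators = list(
      A1 = c(I1 = 0.547, I2 = 0.339, I3 = 0.114),
      A2 = c(I4 = 0.290, I5 = 0.098, I6 = 0.182, I7 = 0.267, I8 = 0.163),
      A3 = c(I9 = 0.347, I10 = 0.293, I11 = 0.153, I12 = 0.207)))
  validate_weights(w)
  w
}

validate_weights <- function(w) {
  sets <- c(list(dimensions = w$dimensions), w$indicators)
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (any(s <= 0)) stop("weights in ", nm, " must be > 0", call. = FALSE)
    if (abs(sum(s) - 1) > 1e-6)
      stop("weights in ", nm, " must sum to 1 (got ", sum(s), ")",
           call. = FALSE)
  }
  invisible(w)
}

#' Five-class risk grading scale
#'
#' Grade cuts at 0.7, 1.0, 3.0 and 5.0 delimit the classes no risk
#' (<= 0.7), low (0.7-1.0], medium (1.0-3.0], high (3.0-5.0) and
#' extremely high (>= 5.0). Intervals are left-open/right-closed except
#' the explicit "<= 0.7" and ">= 5.0" endpoints.
#'
#' @param thresholds strictly increasing numeric of length 4.
#' @param labels five class labels.
#' @return list of class \code{grade_scale}.
#' @export
grade_scale <- function(thresholds = c(0.7, 1.0, 3.0, 5.0),
                        labels = c("no", "low", "medium", "high",
                                   "extremely_high")) {
  stopifnot(length(thresholds) == 4, all(diff(thresholds) > 0),
            length(labels) == 5)
  structure(list(thresholds = thresholds, labels = labels),
            class = "grade_scale")
}

#' Weighted aggregation of indicator layers into a dimension score
#'
#' Cellwise convex combination of the supplied layers. A cell that is
#' nodata in any layer is nodata in the result (weights are never
#' silently renormalized over missing indicators, which would change the
#' model).
#'
#' @param layers named list of \code{agrisk_grid}s (names = indicator or
#'   dimension ids).
#' @param weights named numeric covering exactly the supplied names and
#'   summing to 1.
#' @return an \code{agrisk_grid}.
#' @export
aggregate_dimension <- function(layers, weights) {
  if (!setequal(names(layers), names(weights)))
    stop("layer names and weight names must match exactly", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1", call. = FALSE)
  do.call(check_same_geometry, unname(layers))
  g1 <- layers[[1]]
  acc <- matrix(0, nrow(g1$values), ncol(g1$values))
  for (nm in names(layers)) acc <- acc + weights[[nm]] * layers[[nm]]$values
  grid_layer(acc, g1$cell_size, g1$origin, g1$nodata)
}

#' Composite risk score from the three dimension scores
#'
#' @param A1,A2,A3 dimension score grids (Input, Translate, Output).
#' @param weights dimension weights (named A1, A2, A3, summing to 1).
#' @return an \code{agrisk_grid} of composite scores A.
#' @export
composite_score <- function(A1, A2, A3,
                            weights = ito3de_weights()$dimensions) {
  aggregate_dimension(list(A1 = A1, A2 = A2, A3 = A3), weights)
}

#' Classify a composite score into the five risk grades
#'
#' @param A score grid (or numeric); values must be >= 0.
#' @param scale a \code{\link{grade_scale}}.
#' @return grid (or integer vector) of grades 1..5.
#' @export
risk_grade <- function(A, scale = grade_scale()) {
  f <- function(v) {
    if (any(v < 0, na.rm = TRUE))
      stop("composite scores must be >= 0", call. = FALSE)
    t <- scale$thresholds
    g <- 1L + (v > t[1]) + (v > t[2]) + (v > t[3]) + (v >= t[4])
    g
  }
  if (inherits(A, "agrisk_grid")) {
    out <- grid_layer(f(A$values), A$cell_size, A$origin, A$nodata)
    out
  } else as.integer(f(A))
}

#' Evaluate the three-dimensional pollution risk model
#'
#' Central evaluator: builds the twelve normalized indicator layers from
#' a scene (synthetic or assembled inputs), aggregates them into the
#' Input/Translate/Output dimension scores and the composite risk score
#' A, and grades A on the five-class scale.
#'
#' @param scene a \code{synthetic_scene} (see
#'   \code{\link{generate_scene}}) or a named list of raw inputs:
#'   \code{land_use}, \code{dem}, \code{slope}, \code{erosivity},
#'   \code{zones}, optional \code{fert_extra}, \code{pest_extra},
#'   \code{erosivity_extra} surcharge grids, optional precomputed masks.
#' @param weights a weight configuration (\code{\link{ito3de_weights}}).
#' @param scale a \code{\link{grade_scale}}.
#' @param config indicator tunables passed to
#'   \code{\link{build_indicator}} (cap, K lookup, focal window, paddy
#'   spatialization mode).
#' @param epoch optional epoch label carried into outputs.
#' @return object of class \code{ito3de_risk}: list with
#'   \code{indicators} (named list of 12 grids), \code{dimensions}
#'   (grids A1, A2, A3), \code{score} (grid A), \code{grade} (grid of
#'   1..5), plus the weights, scale and epoch used.
#' @examples
#' sc <- generate_scene(scene_config(nrows = 40, ncols = 40, n_zones = 4,
#'                                   seed = 1))
#' fit <- ito3de(sc)
#' print(fit)
#' summary(fit)
#' @export
ito3de <- function(scene, weights = ito3de_weights(), scale = grade_scale(),
                   config = list(), epoch = NULL) {
  validate_weights(weights)
  inputs <- assemble_inputs(scene, config)
  specs <- indicator_specs()
  inds <- lapply(specs$id, function(id)
    build_indicator(id, inputs, config = config))
  names(inds) <- specs$id
  dims <- lapply(c("A1", "A2", "A3"), function(d) {
    ids <- names(weights$indicators[[d]])
    aggregate_dimension(inds[ids], weights$indicators[[d]])
  })
  names(dims) <- c("A1", "A2", "A3")
  A <- composite_score(dims$A1, dims$A2, dims$A3, weights$dimensions)
  structure(
    list(indicators = inds, dimensions = dims, score = A,
         grade = risk_grade(A, scale), weights = weights, scale = scale,
         epoch = epoch %||% attr(scene, "epoch"), call = match.call()),
    class = "ito3de_risk")
}

# derive the masks and input list the indicator recipes need
assemble_inputs <- function(scene, config = list()) {
  if (inherits(scene, "synthetic_scene")) scene <- unclass(scene)
  stopifnot(is.list(scene))
  for (nm in c("land_use", "dem", "slope", "erosivity", "zones"))
    if (is.null(scene[[nm]]))
      stop("scene is missing required input `", nm, "`", call. = FALSE)
  lu <- scene$land_use
  code_of <- function(lab) lu$class_table$code[lu$class_table$label == lab]
  mk_mask <- function(codes) {
    m <- matrix(0, nrow(lu$values), ncol(lu$values))
    m[lu$values %in% codes] <- 1
    m[is.na(lu$values)] <- NA_real_
    grid_layer(m, lu$cell_size, lu$origin, lu$nodata)
  }
  farmland <- scene$farmland_mask %||%
    mk_mask(c(code_of("paddy"), code_of("dry_land")))
  inputs <- list(
    land_use = lu, dem = scene$dem, slope = scene$slope,
    erosivity = scene$erosivity, zones = scene$zones,
    farmland_mask = farmland,
    paddy_mask = scene$paddy_mask %||% mk_mask(code_of("paddy")),
    water_mask = scene$water_mask %||% mk_mask(code_of("water")),
    breeding_mask = scene$breeding_mask %||% farmland,
    fert_extra = scene$fert_extra, pest_extra = scene$pest_extra,
    erosivity_extra = scene$erosivity_extra,
    k_table = scene$k_table %||% default_k_table(),
    k_reference = scene$k_reference %||% default_k_reference())
  inputs
}

#' Default soil-erodibility lookup by land-use class
#'
#' Typical K factors (t ha h / (ha MJ mm)) for the six land-use classes,
#' standing in for a regional soil survey; tunable per study area.
#' @return named numeric vector.
#' @export
default_k_table <- function() {
  c(paddy = 0.24, dry_land = 0.30, forest = 0.18, water = 0,
    artificial = 0.10, other = 0.26)
}

#' @rdname default_k_table
#' @export
default_k_reference <- function() 0.25

#' @export
print.ito3de_risk <- function(x, ...) {
  cat("Three-dimensional agricultural pollution risk evaluation\n")
  if (!is.null(x$epoch)) cat("Epoch:", x$epoch, "\n")
  v <- x$score$values
  cat(sprintf("Composite risk A over %d cells: range %.2f-%.2f\n",
              sum(!is.na(v)), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  gp <- grade_proportions(x)
  cat("Grade shares (%):",
      paste(sprintf("%s %.1f", gp$label, gp$percent), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ito3de_risk <- function(object, ...) {
  rng <- function(g) {
    v <- g$values
    c(min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
  }
  dims <- t(vapply(object$dimensions, rng, numeric(2)))
  comp <- rng(object$score)
  out <- list(dimension_ranges = dims, composite_range = comp,
              grade_percent = grade_proportions(object),
              epoch = object$epoch)
  class(out) <- "summary.ito3de_risk"
  out
}

#' @export
print.summary.ito3de_risk <- function(x, ...) {
  cat("Dimension score ranges (Input A1, Translate A2, Output A3):\n")
  print(round(x$dimension_ranges, 3))
  cat(sprintf("Composite A: %.3f-%.3f\n", x$composite_range[1],
              x$composite_range[2]))
  cat("Risk grade shares:\n")
  print(x$grade_percent, row.names = FALSE)
  invisible(x)
}

#' Grade area shares of a risk surface
#' @param x an \code{ito3de_risk}.
#' @return data.frame of grade, label and percent of non-nodata area.
#' @export
grade_proportions <- function(x) {
  g <- x$grade$values[!is.na(x$grade$values)]
  cnt <- table(factor(g, levels = 1:5))
  data.frame(grade = 1:5, label = x$scale$labels,
             percent = 100 * as.numeric(cnt) / length(g))
}

#' Effective indicator weights of the composite
#'
#' Products of the dimension weight and the within-dimension indicator
#' weight; the composite equals the 12-term weighted sum of indicators
#' with these coefficients.
#' @param object an \code{ito3de_risk}.
#' @param ... unused.
#' @return named numeric of length 12 (sums to 1).
#' @export
coef.ito3de_risk <- function(object, ...) {
  w <- object$weights
  out <- unlist(lapply(names(w$indicators), function(d)
    w$dimensions[[d]] * w$indicators[[d]]))
  names(out) <- unlist(lapply(w$indicators, names))
  out
}

#' @export
plot.ito3de_risk <- function(x, what = c("grade", "score"), ...) {
  what <- match.arg(what)
  if (what == "score") {
    plot(x$score, main = "Composite risk score A", ...)
  } else {
    cols <- c("#2c7bb6", "#abd9e9", "#ffffbf", "#fdae61", "#d7191c")
    plot(x$grade, main = "Risk grade", col = cols, ...)
  }
  invisible(x)
}
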