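#' Encode a three-epoch grade trajectory into a transition code
#'
#' The spatiotemporal transition matrix encodes each cell's grade
#' trajectory across three epochs as a three-digit integer
#' \code{B = g1*100 + g2*10 + g3}, so e.g. code 123 reads "no risk in the
#' first epoch, low risk in the second, medium risk in the third".
#'
#' @param g1,g2,g3 grade grids (values 1..5) for the three epochs, or
#'   plain numeric vectors/matrices.
#' @return grid (or numeric) of three-digit codes; nodata propagates.
#' @export
encode_transition <- function(g1, g2, g3) {
  is_grid <- inherits(g1, "agrisk_grid")
  if (is_grid) {
    check_same_geometry(g1, g2, g3)
    v1 <- g1$values; v2 <- g2$values; v3 <- g3$values
  } else {
    v1 <- g1; v2 <- g2; v3 <- g3
  }
  for (v in list(v1, v2, v3)) {
    bad <- !is.na(v) & (v < 1 | v > 5 | v != round(v))
    if (any(bad))
      stop("grades must be integers in 1..5", call. = FALSE)
  }
  code <- v1 * 100 + v2 * 10 + v3
  if (is_grid) grid_layer(code, g1$cell_size, g1$origin, g1$nodata) else code
}

#' Classify transition codes into trajectory categories
#'
#' A trajectory with all three grades equal is "no change" at that grade;
#' a non-decreasing trajectory with at least one strict rise is
#' \code{increase}; a non-increasing one with at least one strict fall is
#' \code{decline}; anything else (a rise and a fall) is
#' \code{fluctuation}. The six reported groups (three no-change classes
#' observed in practice plus increase/decline/fluctuation) partition all
#' cells.
#'
#' @param code grid (or numeric) of three-digit transition codes.
#' @return an \code{agrisk_catgrid} of category codes (or, for numeric
#'   input, a character vector of category labels). Category codes 1..5
#'   are \code{no_change_<grade label>}; 6 = increase, 7 = decline,
#'   8 = fluctuation.
#' @export
classify_transition <- function(code) {
  is_grid <- inherits(code, "agrisk_grid")
  v <- if (is_grid) code$values else code
  d1 <- v %/% 100
  d2 <- (v %/% 10) %% 10
  d3 <- v %% 10
  ok <- !is.na(v)
  if (any(ok & (d1 < 1 | d1 > 5 | d2 < 1 | d2 > 5 | d3 < 1 | d3 > 5)))
    stop("invalid transition code: digits must be grades 1..5",
         call. = FALSE)
  cat_ <- ifelse(d1 == d2 & d2 == d3, d1,
          ifelse(d1 <= d2 & d2 <= d3, 6L,
          ifelse(d1 >= d2 & d2 >= d3, 7L, 8L)))
  labs <- transition_categories()
  if (!is_grid) return(labs$label[match(cat_, labs$code)])
  categorical_grid(cat_, labs, code$cell_size, code$origin, code$nodata)
}

#' Transition category legend
#' @return data.frame of category \code{code} and \code{label}.
#' @export
transition_categories <- function() {
  gl <- grade_scale()$labels
  data.frame(code = 1:8,
             label = c(paste0("no_change_", gl, "_risk"),
                       "increase", "decline", "fluctuation"))
}

#' Area shares of transition categories
#'
#' @param category an \code{agrisk_catgrid} from
#'   \code{\link{classify_transition}}.
#' @return data.frame of code, label and percent of non-nodata area
#'   (sums to 100).
#' @export
category_proportions <- function(category) area_proportions(category)

#' Full three-epoch transition analysis
#'
#' Convenience wrapper: encodes the grade trajectory, classifies it and
#' tabulates category shares.
#'
#' @param g1,g2,g3 grade grids for the three epochs, or \code{ito3de_risk}
#'   objects (their grade grids are used).
#' @param epochs optional labels for the three epochs.
#' @return object of class \code{risk_transition}: list with \code{code}
#'   grid, \code{category} grid and \code{proportions} table.
#' @export
risk_transition <- function(g1, g2, g3, epochs = NULL) {
  as_grade <- function(x) if (inherits(x, "ito3de_risk")) x$grade else x
  g1 <- as_grade(g1); g2 <- as_grade(g2); g3 <- as_grade(g3)
  code <- encode_transition(g1, g2, g3)
  category <- classify_transition(code)
  structure(list(code = code, category = category,
                 proportions = category_proportions(category),
                 epochs = epochs),
            class = "risk_transition")
}

#' @export
print.risk_transition <- function(x, ...) {
  cat("Three-epoch risk-grade transition\n")
  if (!is.null(x$epochs)) cat("Epochs:", paste(x$epochs, collapse = ", "),
                              "\n")
  pr <- x$proportions[x$proportions$percent > 0, ]
  print(transform(pr, percent = round(percent, 2)), row.names = FALSE)
  nc <- sum(x$proportions$percent[1:5])
  cat(sprintf("Total no-change share: %.2f%%\n", nc))
  invisible(x)
}

#' Code-to-category table over all 125 grade triplets
#'
#' Documentation artefact: the complete mapping from every possible
#' three-digit transition code to its trajectory category.
#' @return data.frame with columns \code{code}, \code{g1}, \code{g2},
#'   \code{g3}, \code{category}.
#' @export
transition_codebook <- function() {
  g <- expand.grid(g3 = 1:5, g2 = 1:5, g1 = 1:5)[, 3:1]
  code <- g$g1 * 100 + g$g2 * 10 + g$g3
  out <- data.frame(code = code, g, category = classify_transition(code))
  out[order(out$code), ]
}
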