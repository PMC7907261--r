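#' Build spatial weights for the Gi* statistic
#'
#' Binary contiguity or fixed-distance-band weights over grid cells or
#' zones, stored as a sparse matrix. The Gi* convention includes each
#' unit in its own neighbourhood (\code{include_self = TRUE},
#' w_ii = 1).
#'
#' @param units an \code{agrisk_grid} (cells are units, ordered
#'   column-major as \code{as.vector(values)}) or an
#'   \code{agrisk_zonemap} (zones are units, adjacency from shared cell
#'   edges, centroids used for distance bands).
#' @param scheme \code{"queen"} (8 neighbours), \code{"rook"} (4) or
#'   \code{"fixed_distance"} (all units within \code{d} metres).
#' @param d band radius in metres, required for
#'   \code{"fixed_distance"}.
#' @param include_self logical; include w_ii = 1 (Gi* convention).
#' @return object of class \code{spatial_weights}: list with sparse
#'   matrix \code{W}, unit \code{ids}, \code{scheme},
#'   \code{include_self}.
#' @export
build_weights <- function(units, scheme = c("queen", "rook",
                                            "fixed_distance"),
                          d = NULL, include_self = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "fixed_distance" &&
      (is.null(d) || !is.numeric(d) || d <= 0))
    stop("`d` must be a positive distance for the fixed-distance band",
         call. = FALSE)
  if (inherits(units, "agrisk_zonemap")) {
    W_ids <- zone_weights(units, scheme, d, include_self)
  } else if (inherits(units, "agrisk_grid")) {
    W_ids <- grid_weights(units, scheme, d, include_self)
  } else stop("`units` must be a grid or a zone map", call. = FALSE)
  isolated <- Matrix::rowSums(W_ids$W != 0) == 0
  if (any(isolated))
    warning(sum(isolated), " unit(s) have no neighbours; their z scores ",
            "will be undefined and flagged not significant", call. = FALSE)
  structure(list(W = W_ids$W, ids = W_ids$ids, scheme = scheme, d = d,
                 include_self = include_self),
            class = "spatial_weights")
}

grid_weights <- function(grid, scheme, d, include_self) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  offsets <- switch(scheme,
    rook  = list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)),
    queen = {
      o <- expand.grid(dr = -1:1, dc = -1:1)
      o <- o[!(o$dr == 0 & o$dc == 0), ]
      lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
    },
    fixed_distance = {
      k <- floor(d / grid$cell_size)
      o <- expand.grid(dr = -k:k, dc = -k:k)
      o <- o[(o$dr^2 + o$dc^2) * grid$cell_size^2 <= d^2 &
               !(o$dr == 0 & o$dc == 0), ]
      lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
    })
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ii <- integer(0); jj <- integer(0)
  for (off in offsets) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ii <- c(ii, which(ok))
    jj <- c(jj, (c2[ok] - 1L) * nr + r2[ok])
  }
  n <- nr * nc
  if (include_self) { ii <- c(ii, seq_len(n)); jj <- c(jj, seq_len(n)) }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  list(W = W, ids = seq_len(n))
}

zone_weights <- function(zones, scheme, d, include_self) {
  zid <- zones$grid$values
  ids <- sort(zones$table$zone)
  n <- length(ids)
  pos <- function(z) match(z, ids)
  if (scheme == "fixed_distance") {
    cc <- cell_centers(zones$grid)
    cx <- tapply(cc$x[!is.na(zid)], zid[!is.na(zid)], mean)[as.character(ids)]
    cy <- tapply(cc$y[!is.na(zid)], zid[!is.na(zid)], mean)[as.character(ids)]
    dm <- as.matrix(stats::dist(cbind(cx, cy)))
    adj <- dm <= d & row(dm) != col(dm)
  } else {
    # adjacency: zones sharing at least one cell edge (rook) or also a
    # corner (queen)
    pairs <- rbind(
      cbind(as.vector(zid[-nrow(zid), ]), as.vector(zid[-1, ])),
      cbind(as.vector(zid[, -ncol(zid)]), as.vector(zid[, -1])))
    if (scheme == "queen")
      pairs <- rbind(pairs,
        cbind(as.vector(zid[-nrow(zid), -ncol(zid)]),
              as.vector(zid[-1, -1])),
        cbind(as.vector(zid[-nrow(zid), -1]),
              as.vector(zid[-1, -ncol(zid)])))
    pairs <- pairs[!is.na(pairs[, 1]) & !is.na(pairs[, 2]) &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    adj <- matrix(FALSE, n, n)
    if (nrow(pairs)) {
      adj[cbind(pos(pairs[, 1]), pos(pairs[, 2]))] <- TRUE
      adj <- adj | t(adj)
    }
  }
  if (include_self) diag(adj) <- TRUE
  list(W = Matrix::Matrix(adj * 1, sparse = TRUE), ids = ids)
}

#' Local Getis-Ord Gi* statistic
#'
#' For each unit i with weights w_ij,
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar X \sum_j w_{ij}}
#'   {S \sqrt{[n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2] / (n - 1)}}}
#' with \eqn{\bar X} the global mean and S the global population
#' standard deviation (unit i included, the self-inclusive Gi*
#' convention). Positive z flags clusters of high values (hot spots),
#' negative z clusters of low values (cold spots); p is the two-sided
#' normal tail.
#'
#' @param x numeric vector of unit values (NA units are excluded from
#'   the global statistics and get NA scores).
#' @param W a \code{spatial_weights} object (its matrix must match
#'   \code{length(x)}).
#' @return data.frame with columns \code{z} and \code{p}.
#' @export
gi_star <- function(x, W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (length(x) != nrow(W$W))
    stop("`x` length does not match the weights matrix", call. = FALSE)
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 non-missing units", call. = FALSE)
  xb <- mean(x[ok])
  S <- sqrt(mean(x[ok]^2) - xb^2)
  if (S == 0)
    stop("constant field: global variance is zero, Gi* is undefined",
         call. = FALSE)
  Wok <- W$W[, ok, drop = FALSE]
  sw <- as.numeric(Matrix::rowSums(Wok))
  sw2 <- as.numeric(Matrix::rowSums(Wok^2))
  num <- as.numeric(Wok %*% x[ok]) - xb * sw
  den <- S * sqrt(pmax(n * sw2 - sw^2, 0) / (n - 1))
  z <- ifelse(den > 0, num / den, NA_real_)
  z[!ok] <- NA_real_
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Confidence bins from Gi* z scores
#'
#' Standard hot/cold-spot binning: |z| at or above the two-sided normal
#' critical values 1.644854, 1.959964 and 2.575829 maps to confidence
#' levels 90, 95 and 99% (bins of magnitude 1, 2, 3, signed by z); bin 0
#' is not significant. With \code{correction = "fdr"} the thresholds are
#' applied through Benjamini-Hochberg-adjusted p values instead.
#'
#' @param z numeric z scores.
#' @param alpha significance levels for bins 1..3.
#' @param correction \code{"none"} (plain confidence classes) or
#'   \code{"fdr"}.
#' @return integer bins in -3..3 (NA z gives 0).
#' @export
gi_bin <- function(z, alpha = c(0.10, 0.05, 0.01),
                   correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  stopifnot(length(alpha) == 3, all(diff(alpha) < 0))
  if (correction == "none") {
    # conventional 7-significant-digit critical values (1.644854,
    # 1.959964, 2.575829 at the default levels)
    crit <- signif(stats::qnorm(1 - alpha / 2), 7)
    mag <- (abs(z) >= crit[1]) + (abs(z) >= crit[2]) + (abs(z) >= crit[3])
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    padj <- stats::p.adjust(p, method = "BH")
    mag <- (padj <= alpha[1]) + (padj <= alpha[2]) + (padj <= alpha[3])
  }
  bin <- as.integer(sign(z) * mag)
  bin[is.na(z)] <- 0L
  bin
}

#' Hot/cold-spot class labels from confidence bins
#' @param bins integer bins in -3..3.
#' @return character labels ("Hot Spot - 99% Confidence", ...,
#'   "Not Significant").
#' @export
classify_hotspots <- function(bins) {
  lab <- function(b) {
    if (is.na(b) || b == 0) return("Not Significant")
    side <- if (b > 0) "Hot Spot" else "Cold Spot"
    conf <- c("90", "95", "99")[abs(b)]
    sprintf("%s - %s%% Confidence", side, conf)
  }
  vapply(bins, lab, character(1))
}

#' Hot-spot analysis of a risk surface
#'
#' Runs the Gi* statistic over zones (county means of the composite
#' score, the default analysis unit) or over grid cells.
#'
#' @param x an \code{ito3de_risk}, or a numeric vector of unit values
#'   when \code{weights} is supplied.
#' @param zones an \code{agrisk_zonemap}; when supplied (or found in
#'   \code{x}), zonal means of the composite score are analysed.
#' @param unit \code{"zone"} or \code{"cell"}.
#' @param scheme,d,include_self weight options, see
#'   \code{\link{build_weights}}.
#' @param correction p-value correction for binning.
#' @param weights optional prebuilt \code{spatial_weights} (with
#'   \code{x} a plain numeric vector).
#' @return data.frame of class \code{hotspot_surface}: unit \code{id},
#'   value \code{x}, \code{z}, \code{p}, \code{gi_bin}, \code{class}.
#' @export
hotspot_analysis <- function(x, zones = NULL, unit = c("zone", "cell"),
                             scheme = "queen", d = NULL,
                             include_self = TRUE,
                             correction = "none", weights = NULL) {
  unit <- match.arg(unit)
  if (is.null(weights)) {
    if (inherits(x, "ito3de_risk")) {
      score <- x$score
      if (unit == "zone") {
        if (is.null(zones)) stop("zone-level analysis needs `zones`",
                                 call. = FALSE)
        vals <- zonal_mean(zones, score)$mean
        weights <- build_weights(zones, scheme, d, include_self)
      } else {
        vals <- as.vector(score$values)
        weights <- build_weights(score, scheme, d, include_self)
      }
    } else stop("supply either an ito3de_risk or `weights` + values",
                call. = FALSE)
  } else vals <- x
  zp <- gi_star(vals, weights)
  bins <- gi_bin(zp$z, correction = correction)
  out <- data.frame(id = weights$ids, x = vals, z = zp$z, p = zp$p,
                    gi_bin = bins, class = classify_hotspots(bins))
  class(out) <- c("hotspot_surface", class(out))
  attr(out, "weights") <- weights
  out
}

#' @export
print.hotspot_surface <- function(x, ...) {
  cat(sprintf("Getis-Ord Gi* hot-spot analysis over %d units\n", nrow(x)))
  print(table(x$class))
  NextMethod()
}
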