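#' Slope from a DEM (Horn 3x3 method)
#'
#' Gradient by Horn's third-order finite differences on the 3x3
#' neighbourhood, converted to degrees. Border cells are handled by linear
#' extrapolation of the DEM one cell outward, which reduces to one-sided
#' differences and keeps planar surfaces exact to the edge. Nodata
#' propagates to any cell whose 3x3 window touches it.
#'
#' @param dem A `raster_grid` of elevations in metres.
#' @return A `raster_grid` of slope in degrees, in `[0, 90]`.
#' @export
compute_slope <- function(dem) {
  g <- horn_gradient(dem)
  deg <- atan(sqrt(g$dzdx^2 + g$dzdy^2)) * 180 / pi
  raster_like(dem, deg)
}

#' Aspect from a DEM
#'
#' Azimuth of steepest descent in degrees, 0 = north, clockwise, in
#' `[0, 360)`. Cells whose gradient magnitude falls below `flat_threshold`
#' (m/m) receive the flat sentinel `-1`.
#'
#' @inheritParams compute_slope
#' @param flat_threshold Gradient magnitude below which a cell is flat.
#' @return A `raster_grid` of azimuths (degrees) with `-1` on flat cells.
#' @export
compute_aspect <- function(dem, flat_threshold = 1e-6) {
  g <- horn_gradient(dem)
  mag <- sqrt(g$dzdx^2 + g$dzdy^2)
  az <- (atan2(-g$dzdx, -g$dzdy) * 180 / pi) %% 360
  az[mag < flat_threshold] <- -1
  az[is.na(mag)] <- NA_real_
  raster_like(dem, az)
}

# Horn 3x3 gradients; dzdx is the eastward, dzdy the northward derivative.
horn_gradient <- function(dem) {
  stopifnot(is_raster_grid(dem))
  v <- dem$values
  if (sum(is.finite(v)) < 9) stop("DEM needs at least a 3x3 block of valid cells")
  cs <- dem$cell_size
  # pad one cell by linear extrapolation so borders get one-sided differences
  p <- rbind(2 * v[1, ] - v[2, ], v, 2 * v[nrow(v), ] - v[nrow(v) - 1, ])
  p <- cbind(2 * p[, 1] - p[, 2], p, 2 * p[, ncol(p)] - p[, ncol(p) - 1])
  ri <- 2:(nrow(p) - 1); ci <- 2:(ncol(p) - 1)
  a <- p[ri - 1, ci - 1]; b <- p[ri - 1, ci]; cc <- p[ri - 1, ci + 1]
  d <- p[ri, ci - 1];                          f <- p[ri, ci + 1]
  g <- p[ri + 1, ci - 1]; h <- p[ri + 1, ci]; i <- p[ri + 1, ci + 1]
  list(dzdx = ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs),
       dzdy = ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs))
}

#' Local relief (neighbourhood elevation range)
#'
#' Per-cell maximum minus minimum elevation over an odd square window;
#' windows are clipped at the grid edge and nodata cells are ignored within
#' the window (a nodata centre stays nodata).
#'
#' @inheritParams compute_slope
#' @param window Odd window side length in cells, `>= 3`.
#' @return A `raster_grid` of relief in metres, `>= 0`.
#' @export
compute_relief <- function(dem, window = 3L) {
  stopifnot(is_raster_grid(dem))
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3")
  v <- dem$values
  r <- (window - 1L) %/% 2L
  mx <- matrix(-Inf, nrow(v), ncol(v))
  mn <- matrix(Inf, nrow(v), ncol(v))
  for (dr in -r:r) for (dc in -r:r) {
    s <- shift_mat(v, dr, dc)
    upd <- is.finite(s)
    mx[upd] <- pmax(mx[upd], s[upd])
    mn[upd] <- pmin(mn[upd], s[upd])
  }
  out <- mx - mn
  out[!is.finite(v) | !is.finite(out)] <- NA_real_
  raster_like(dem, out)
}

# D8 neighbour offsets in the deterministic tie-break order E, SE, S, SW,
# W, NW, N, NE (row/col offsets; row +1 is south).
d8_offsets <- function() {
  data.frame(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
             dc = c(1, 1, 0, -1, -1, -1, 0, 1))
}

#' Fill DEM depressions
#'
#' Raises every interior pit to its lowest pour point (plus a tiny epsilon
#' gradient so that drainage across former pits and flats is resolvable),
#' leaving all other cells untouched. Cells on the grid border, or adjacent
#' to nodata, can drain off-grid and are never raised.
#'
#' @inheritParams compute_slope
#' @param eps Small elevation increment enforcing monotone drainage.
#' @return A `raster_grid` of hydrologically conditioned elevations.
#' @export
fill_depressions <- function(dem, eps = 1e-6) {
  stopifnot(is_raster_grid(dem))
  z <- dem$values
  valid <- is.finite(z)
  if (!any(valid)) stop("DEM is entirely nodata")
  nr <- nrow(z); nc <- ncol(z)
  off <- d8_offsets()
  # boundary: border cells and cells next to nodata drain off-grid
  boundary <- matrix(FALSE, nr, nc)
  boundary[1, ] <- boundary[nr, ] <- TRUE
  boundary[, 1] <- boundary[, nc] <- TRUE
  for (k in seq_len(8)) {
    nb <- shift_mat(z, off$dr[k], off$dc[k])
    boundary <- boundary | !is.finite(nb)
  }
  w <- matrix(Inf, nr, nc)
  w[boundary & valid] <- z[boundary & valid]
  w[!valid] <- NA_real_
  repeat {
    nmin <- matrix(Inf, nr, nc)
    for (k in seq_len(8)) {
      s <- shift_mat(w, off$dr[k], off$dc[k])
      s[!is.finite(s)] <- Inf
      nmin <- pmin(nmin, s)
    }
    cand <- pmax(z, nmin + eps)
    new_w <- pmin(w, cand)
    new_w[!valid] <- NA_real_
    new_w[boundary & valid] <- z[boundary & valid]
    if (identical(new_w, w)) break
    w <- new_w
  }
  raster_like(dem, w)
}

#' D8 flow accumulation
#'
#' Each cell routes all of its flow to the single steepest-descent D8
#' neighbour (distance-weighted drop; ties broken by the fixed neighbour
#' order E, SE, S, SW, W, NW, N, NE). Depressions are filled first with
#' [fill_depressions()]. Accumulation counts the cell itself, so the result
#' is the upslope contributing area in square metres including the cell.
#' Cells with no lower valid neighbour drain off-grid.
#'
#' @inheritParams compute_slope
#' @param fill Logical; condition the DEM with [fill_depressions()] first.
#' @return A `raster_grid` of contributing area (m^2).
#' @export
flow_accumulation_d8 <- function(dem, fill = TRUE) {
  stopifnot(is_raster_grid(dem))
  z0 <- if (fill) fill_depressions(dem)$values else dem$values
  valid <- is.finite(z0)
  if (!any(valid)) stop("DEM is entirely nodata")
  nr <- nrow(z0); nc <- ncol(z0); cs <- dem$cell_size
  off <- d8_offsets()
  dist <- cs * sqrt(off$dr^2 + off$dc^2)
  best_drop <- matrix(0, nr, nc)
  receiver <- matrix(0L, nr, nc)  # 0 = off-grid outlet
  for (k in seq_len(8)) {
    nb <- shift_mat(z0, off$dr[k], off$dc[k])
    drop <- (z0 - nb) / dist[k]
    upd <- is.finite(drop) & drop > best_drop   # strict > keeps first-in-order tie
    best_drop[upd] <- drop[upd]
    # linear index of the receiving neighbour
    ridx <- matrix(rep(seq_len(nr) + off$dr[k], nc), nr, nc)
    cidx <- matrix(rep(seq_len(nc) + off$dc[k], each = nr), nr, nc)
    receiver[upd] <- (cidx[upd] - 1L) * nr + ridx[upd]
  }
  acc <- ifelse(valid, 1, NA_real_)
  ord <- order(z0, decreasing = TRUE, na.last = NA)
  for (i in ord) {
    r <- receiver[i]
    if (r > 0L) acc[r] <- acc[r] + acc[i]
  }
  raster_like(dem, matrix(acc * cs * cs, nr, nc))
}

#' Specific catchment area
#'
#' Contributing area per unit contour width: D8 accumulation (m^2) divided
#' by the cell width.
#'
#' @param accumulation `raster_grid` from [flow_accumulation_d8()] (m^2).
#' @return A `raster_grid` of specific catchment area (m).
#' @export
specific_catchment <- function(accumulation) {
  stopifnot(is_raster_grid(accumulation))
  raster_like(accumulation, accumulation$values / accumulation$cell_size)
}

#' Topographic wetness index
#'
#' `TWI = ln(alpha / tan(beta))` with `alpha` the specific catchment area
#' and `beta` the local slope; `tan(beta)` is floored at `eps` so flat cells
#' stay finite.
#'
#' @param alpha `raster_grid` of specific catchment area (m), `> 0`.
#' @param slope_deg `raster_grid` of slope in degrees.
#' @param eps Floor on `tan(beta)` for flat cells.
#' @return A `raster_grid` of TWI (dimensionless).
#' @export
compute_twi <- function(alpha, slope_deg, eps = 0.001) {
  stopifnot_aligned(alpha, slope_deg)
  a <- alpha$values
  if (any(a <= 0, na.rm = TRUE)) stop("specific catchment area must be > 0")
  tb <- pmax(tan(slope_deg$values * pi / 180), eps)
  out <- log(a / tb)
  out[!is.finite(a) | !is.finite(slope_deg$values)] <- NA_real_
  raster_like(alpha, out)
}

#' Slope classes
#'
#' Seven-class geomorphological slope taxonomy applied in degrees:
#' plain `[0, 2)`, gentle ramp `[2, 5)`, ramp `[5, 15)`, steep `[15, 25)`,
#' very steep `[25, 35)`, scarp `[35, 55)`, vertical `>= 55` (the published
#' taxonomy leaves 45-55 unassigned; the scarp class is extended so the
#' classes are contiguous). Intervals are left-closed, right-open.
#'
#' @param slope_deg `raster_grid` of slope in degrees, `[0, 90]`.
#' @return Integer-valued `raster_grid` of classes 1-7, with a
#'   `legend` attribute naming the classes.
#' @export
classify_slope <- function(slope_deg) {
  stopifnot(is_raster_grid(slope_deg))
  v <- slope_deg$values
  if (any(v < 0, na.rm = TRUE)) stop("slope must be non-negative")
  cls <- findInterval(v, c(2, 5, 15, 25, 35, 55)) + 1
  cls[!is.finite(v)] <- NA_real_
  out <- raster_like(slope_deg, matrix(cls, nrow(v), ncol(v)))
  attr(out, "legend") <- c("plain", "gentle ramp", "ramp", "steep",
                           "very steep", "scarp", "vertical")
  out
}

#' Default aspect-sector boundaries
#'
#' Azimuth intervals (degrees, from north, clockwise) per sector; the
#' northern sector wraps through 0.
#' @return Named list of `c(from, to)` azimuth pairs.
#' @export
default_sectors <- function() {
  list(northern = c(315, 45), eastern = c(45, 135),
       southern = c(135, 225), western = c(225, 315))
}

#' Mountain aspect sectors from the summit
#'
#' Labels every cell by the azimuth from the summit to the cell centre
#' using configurable sector boundaries. The eastern sector can be masked
#' out (study-area exclusion).
#'
#' @param grid A `raster_grid` supplying the geometry.
#' @param summit `c(x, y)` summit coordinates, inside the grid extent.
#' @param sectors Named list of azimuth intervals as in
#'   [default_sectors()].
#' @param mask Character vector of sector names to set to nodata.
#' @return Integer-valued `raster_grid` of sector codes (in the order of
#'   `sectors`), with a `legend` attribute.
#' @export
assign_aspect_sector <- function(grid, summit, sectors = default_sectors(),
                                 mask = character()) {
  stopifnot(is_raster_grid(grid), length(summit) == 2L)
  cc <- cell_centers(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  xr <- grid$origin[1] + c(0, nc * cs)
  yr <- grid$origin[2] - c(nr * cs, 0)
  if (summit[1] < xr[1] || summit[1] > xr[2] ||
      summit[2] < yr[1] || summit[2] > yr[2])
    stop("summit lies outside the grid extent")
  az <- (atan2(cc$x - summit[1], cc$y - summit[2]) * 180 / pi) %% 360
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_along(sectors)) {
    b <- sectors[[i]]
    inside <- if (b[1] <= b[2]) az >= b[1] & az < b[2]
              else az >= b[1] | az < b[2]   # wraps through north
    out[inside] <- i
  }
  out[!is.finite(grid$values)] <- NA_real_
  for (nm in mask) out[out == match(nm, names(sectors))] <- NA_real_
  res <- raster_like(grid, out)
  attr(res, "legend") <- names(sectors)
  res
}

#' Full terrain stack from a DEM
#'
#' Convenience wrapper deriving slope, aspect, relief, D8 specific
#' catchment, TWI and slope classes on one grid.
#'
#' @inheritParams compute_slope
#' @param relief_window Odd window (cells) for [compute_relief()].
#' @param flat_threshold Passed to [compute_aspect()].
#' @param twi_eps Passed to [compute_twi()].
#' @return List of class `terrain_stack` with elements `elevation`,
#'   `slope_deg`, `aspect_deg`, `relief`, `twi`, `slope_class`.
#' @export
terrain_stack <- function(dem, relief_window = 3L, flat_threshold = 1e-6,
                          twi_eps = 0.001) {
  slope <- compute_slope(dem)
  aspect <- compute_aspect(dem, flat_threshold)
  relief <- compute_relief(dem, relief_window)
  alpha <- specific_catchment(flow_accumulation_d8(dem))
  twi <- compute_twi(alpha, slope, twi_eps)
  structure(list(elevation = dem, slope_deg = slope, aspect_deg = aspect,
                 relief = relief, twi = twi,
                 slope_class = classify_slope(slope),
                 window_relief = as.integer(relief_window)),
            class = "terrain_stack")
}
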