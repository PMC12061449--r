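#' Parameter ledger for the synthetic landscape
#'
#' Collects every parameter of the synthetic scene: a volcano-shaped DEM,
#' elevation-lapsed monthly climate with spatially correlated noise, and a
#' multi-year expansion series whose colonization probability is a known
#' logistic function of chosen (z-scored) factors including optional
#' pairwise interactions. The defaults describe a 200 x 200 cell scene at
#' 50 m resolution (10 x 10 km) observed in 2002/2010/2017/2021.
#'
#' @param seed Integer seed; every generator call derives its RNG stream
#'   from it.
#' @param nrow,ncol,cell_size Grid shape (cells) and resolution (m).
#' @param summit_height Cone apex elevation (m).
#' @param cone_slope Cone gradient (m per m).
#' @param roughness_amplitude SD (m) of the smoothed random field added to
#'   the cone; 0 gives a pure cone.
#' @param correlation_length Gaussian smoothing length (cells) of the DEM
#'   roughness.
#' @param sea_level_tmean Twelve monthly sea-level mean temperatures
#'   (deg C, January first).
#' @param lapse_rate Temperature lapse (deg C per m, negative).
#' @param temp_aspect_amp Amplitude (deg C) of the south-facing warming
#'   modulation.
#' @param temp_noise_sd SD (deg C) of the spatially correlated temperature
#'   noise.
#' @param precip_base Twelve monthly baseline precipitation totals (mm) at
#'   the reference elevation.
#' @param precip_ref_elev Reference elevation (m) for the precipitation
#'   gradient.
#' @param precip_elev_gradient Precipitation increase (mm per m of
#'   elevation, per month).
#' @param precip_noise_sd SD (mm) of the spatially correlated
#'   precipitation noise.
#' @param climate_noise_corr Gaussian smoothing length (cells) of the
#'   climate noise fields.
#' @param beta0 Suitability intercept (logit scale).
#' @param beta Named numeric vector of linear effects on z-scored factors.
#' @param beta_int Named list of pairwise interaction effects; names are
#'   `"A:B"` with A and B factor names.
#' @param colonization_scale Multiplier in `[0, 1]` on the logistic
#'   colonization probability per year.
#' @param neighborhood_radius Chebyshev radius (cells) within which an
#'   occupied neighbour enables colonization.
#' @param init_quantile Elevation quantile below which cells start
#'   occupied in the first year.
#' @param years Observation years (maps are recorded at these years;
#'   colonization updates run annually between them).
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(
    seed = 1L, nrow = 200L, ncol = 200L, cell_size = 50,
    summit_height = 2600, cone_slope = 0.10,
    roughness_amplitude = 15, correlation_length = 8,
    sea_level_tmean = c(-10, -6, 0, 8, 14, 18, 21, 20, 14, 7, -2, -8),
    lapse_rate = -0.0065, temp_aspect_amp = 0.5, temp_noise_sd = 0.3,
    precip_base = c(15, 20, 30, 45, 80, 110, 180, 160, 90, 45, 25, 15),
    precip_ref_elev = 1800, precip_elev_gradient = 0.03,
    precip_noise_sd = 8, climate_noise_corr = 10,
    beta0 = -1.5, beta = c(TWI = 1.2, elevation = -0.8, Pre_1 = 0.4),
    beta_int = NULL,
    colonization_scale = 0.35, neighborhood_radius = 1L,
    init_quantile = 0.35,
    years = c(2002L, 2010L, 2017L, 2021L)) {
  stopifnot(lapse_rate < 0, length(sea_level_tmean) == 12L,
            length(precip_base) == 12L,
            colonization_scale >= 0, colonization_scale <= 1,
            init_quantile > 0, init_quantile < 1,
            nrow >= 32L, ncol >= 32L)
  structure(as.list(environment()), class = "synthetic_truth")
}

# local RNG stream: run expr with a seed derived from (seed, offset)
# without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# smoothed standard-normal field rescaled to unit sd (then caller scales)
correlated_noise <- function(nr, nc, corr_len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len > 0) {
    z <- gaussian_smooth(z, corr_len)
    z <- (z - mean(z)) / stats::sd(z)
  }
  z
}

#' Generate the synthetic volcano DEM
#'
#' Cone centred on the grid plus a smoothed Gaussian random field;
#' bit-identical for identical truth (seed included). With zero roughness
#' the surface is an exact cone, so slope equals the cone gradient and
#' aspect equals the azimuth from the summit everywhere off-centre.
#'
#' @param truth A `synthetic_truth`.
#' @return A `raster_grid`; the summit (x, y) is attached as attribute
#'   `"summit"`.
#' @export
generate_dem <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  nr <- truth$nrow; nc <- truth$ncol; cs <- truth$cell_size
  g <- raster_grid(matrix(0, nr, nc), cs, origin = c(0, nr * cs))
  cc <- cell_centers(g)
  summit <- c(nc * cs / 2, nr * cs / 2)
  d <- sqrt((cc$x - summit[1])^2 + (cc$y - summit[2])^2)
  z <- truth$summit_height - truth$cone_slope * d
  if (truth$roughness_amplitude > 0) {
    noise <- with_seed(truth$seed, correlated_noise(nr, nc,
                                                    truth$correlation_length))
    z <- z + truth$roughness_amplitude * noise
  }
  out <- raster_like(g, z)
  attr(out, "summit") <- summit
  out
}

#' Generate the synthetic monthly climate stack
#'
#' Monthly mean temperature follows the elevation lapse plus a
#' south-facing aspect modulation and spatially correlated noise; maximum
#' and minimum temperatures are fixed offsets of the mean. Precipitation
#' follows an elevation gradient around the reference elevation plus
#' correlated noise, floored at zero.
#'
#' @param dem A `raster_grid` (from [generate_dem()]).
#' @param truth A `synthetic_truth`.
#' @return A `climate_stack`.
#' @export
generate_climate <- function(dem, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  elev <- dem$values
  asp <- compute_aspect(dem)$values
  mod <- truth$temp_aspect_amp * cos((asp - 180) * pi / 180)
  mod[asp < 0] <- 0
  nr <- nrow(elev); nc <- ncol(elev)
  with_seed(truth$seed + 1L, {
    precip <- vector("list", 12L); tmean <- vector("list", 12L)
    tmax <- vector("list", 12L); tmin <- vector("list", 12L)
    for (m in 1:12) {
      tn <- truth$temp_noise_sd *
        correlated_noise(nr, nc, truth$climate_noise_corr)
      tv <- truth$sea_level_tmean[m] + truth$lapse_rate * elev + mod + tn
      tmean[[m]] <- raster_like(dem, tv)
      tmax[[m]] <- raster_like(dem, tv + 5)
      tmin[[m]] <- raster_like(dem, tv - 5)
      pn <- truth$precip_noise_sd *
        correlated_noise(nr, nc, truth$climate_noise_corr)
      pv <- truth$precip_base[m] +
        truth$precip_elev_gradient * (elev - truth$precip_ref_elev) + pn
      precip[[m]] <- raster_like(dem, pmax(pv, 0))
    }
    climate_stack(precip, tmean, tmax, tmin, resolution_m = dem$cell_size)
  })
}

# z-score a matrix over its finite cells
zscore_mat <- function(m) {
  mu <- mean(m[is.finite(m)])
  s <- stats::sd(m[is.finite(m)])
  if (s == 0) m * 0 else (m - mu) / s
}

# parse "A:B" interaction names against available factors
parse_interactions <- function(beta_int, factor_names) {
  if (is.null(beta_int) || !length(beta_int)) return(NULL)
  out <- lapply(names(beta_int), function(nm) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% factor_names))
      stop("interaction name must be 'A:B' over known factors: ", nm)
    list(a = pair[1], b = pair[2], beta = beta_int[[nm]])
  })
  out
}

#' Generate the multi-year presence series
#'
#' Starting from presence on all cells below the `init_quantile` elevation
#' quantile, each year every absent cell with at least one occupied
#' neighbour within the Chebyshev radius colonizes with probability
#' `plogis(beta0 + sum(beta * z) + sum(beta_int * z_i * z_j)) * scale`,
#' where `z` are the z-scored factor values. Presence never reverts, so
#' the series is nested (expansion-only). Maps are recorded at the truth's
#' observation years.
#'
#' @param factors Named list of aligned factor `raster_grid`s; must
#'   contain `elevation` plus every factor named in the truth's `beta` /
#'   `beta_int`.
#' @param truth A `synthetic_truth`.
#' @return A `cover_series`; `truth` is attached as attribute `"truth"`.
#' @export
generate_presence_series <- function(factors, truth) {
  stopifnot(inherits(truth, "synthetic_truth"),
            "elevation" %in% names(factors))
  do.call(stopifnot_aligned, unname(factors))
  need <- union(names(truth$beta),
                unlist(lapply(parse_interactions(truth$beta_int,
                                                 names(factors)),
                              function(p) c(p$a, p$b))))
  miss <- setdiff(need, names(factors))
  if (length(miss)) stop("factors missing from the set: ",
                         paste(miss, collapse = ", "))
  elev <- factors$elevation$values
  valid <- Reduce(`&`, lapply(factors, function(g) is.finite(g$values)))
  z <- lapply(factors, function(g) zscore_mat(g$values))
  logit <- matrix(truth$beta0, nrow(elev), ncol(elev))
  for (nm in names(truth$beta)) logit <- logit + truth$beta[[nm]] * z[[nm]]
  for (p in parse_interactions(truth$beta_int, names(factors)))
    logit <- logit + p$beta * z[[p$a]] * z[[p$b]]
  pcol <- stats::plogis(logit) * truth$colonization_scale
  pcol[!valid] <- 0
  init_thresh <- stats::quantile(elev[is.finite(elev)], truth$init_quantile)
  pres <- matrix(0, nrow(elev), ncol(elev))
  pres[valid & elev <= init_thresh] <- 1
  if (!any(pres == 1)) stop("initial presence is empty")
  r <- truth$neighborhood_radius
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  yrs <- truth$years
  maps <- vector("list", length(yrs))
  maps[[1]] <- pres
  with_seed(truth$seed + 2L, {
    for (i in 2:length(yrs)) {
      for (step in seq_len(yrs[i] - yrs[i - 1])) {
        nb <- matrix(0, nrow(pres), ncol(pres))
        for (k in seq_len(nrow(offs))) {
          s <- shift_mat(pres, offs$dr[k], offs$dc[k])
          s[is.na(s)] <- 0
          nb <- nb + s
        }
        frontier <- valid & pres == 0 & nb > 0
        u <- matrix(stats::runif(length(pres)), nrow(pres))
        pres[frontier & u < pcol] <- 1
      }
      maps[[i]] <- pres
    }
  })
  mk <- function(m) {
    m[!valid] <- NA_real_
    raster_like(factors$elevation, m)
  }
  out <- cover_series(yrs, lapply(maps, mk))
  attr(out, "truth") <- truth
  out
}

#' Full synthetic scene
#'
#' Convenience wrapper: DEM, terrain stack, climate, the standard factor
#' set (growing-season/monthly climate factors plus elevation, slope,
#' relief, TWI), and the presence series, all from one truth ledger.
#'
#' @param truth A `synthetic_truth`.
#' @param season Growing-season months for [derive_climate_variables()].
#' @return List with `truth`, `dem`, `summit`, `terrain`, `climate`,
#'   `factors` (a `factor_set`), `series`.
#' @export
simulate_scene <- function(truth = synthetic_truth(), season = 6:9) {
  dem <- generate_dem(truth)
  terr <- terrain_stack(dem)
  clim <- generate_climate(dem, truth)
  cvars <- derive_climate_variables(clim, season)
  fs <- factor_set(cvars,
                   list(elevation = dem, slope = terr$slope_deg,
                        relief = terr$relief, TWI = terr$twi))
  series <- generate_presence_series(fs, truth)
  list(truth = truth, dem = dem, summit = attr(dem, "summit"),
       terrain = terr, climate = clim, factors = fs, series = series)
}
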