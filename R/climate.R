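#' Monthly climate stack
#'
#' Bundles twelve monthly rasters per climate variable on one grid.
#'
#' @param precip,tmean,tmax,tmin Lists of 12 `raster_grid`s (calendar
#'   order, January first).
#' @param resolution_m Nominal resolution in metres (defaults to the grid
#'   cell size).
#' @return List of class `climate_stack`.
#' @export
climate_stack <- function(precip, tmean, tmax = NULL, tmin = NULL,
                          resolution_m = NULL) {
  for (v in list(precip, tmean)) {
    if (length(v) != 12L) stop("each climate variable needs 12 monthly layers")
  }
  do.call(stopifnot_aligned, c(precip, tmean, tmax, tmin))
  if (any(vapply(precip, function(g) any(g$values < 0, na.rm = TRUE),
                 logical(1))))
    stop("precipitation must be non-negative")
  if (is.null(resolution_m)) resolution_m <- precip[[1]]$cell_size
  structure(list(precip = precip, tmean = tmean, tmax = tmax, tmin = tmin,
                 resolution_m = resolution_m),
            class = "climate_stack")
}

# Design matrix for the downscaling regression: elevation, slope and the
# circular aspect encoded as a sin/cos pair (flat cells contribute 0, 0).
mlr_design <- function(topo) {
  asp <- topo$aspect_deg$values
  flat <- asp < 0
  rad <- asp * pi / 180
  s <- sin(rad); cc <- cos(rad)
  s[flat] <- 0; cc[flat] <- 0
  data.frame(elev = as.vector(topo$elevation$values),
             slope = as.vector(topo$slope_deg$values),
             asp_sin = as.vector(s), asp_cos = as.vector(cc))
}

#' Downscale a coarse climate raster by terrain regression
#'
#' Fits ordinary least squares of the coarse climate field on elevation,
#' slope and the sin/cos pair of aspect over the coarse cells, then predicts
#' at the fine cells. A rank-deficient design falls back to an
#' elevation-only regression with a warning.
#'
#' @param coarse `raster_grid` of the coarse climate field.
#' @param coarse_topo,fine_topo `terrain_stack`s on the coarse and fine
#'   grids (from [terrain_stack()]).
#' @return A fine-grid `raster_grid`; the fitted `lm` is attached as the
#'   `"model"` attribute.
#' @export
downscale_mlr <- function(coarse, coarse_topo, fine_topo) {
  stopifnot_aligned(coarse, coarse_topo$elevation)
  df <- mlr_design(coarse_topo)
  df$y <- as.vector(coarse$values)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10L) stop("need at least 10 valid coarse cells")
  fit <- stats::lm(y ~ elev + slope + asp_sin + asp_cos, data = df)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient downscaling design; falling back to elevation-only")
    fit <- stats::lm(y ~ elev, data = df)
  }
  newdf <- mlr_design(fine_topo)
  pred <- rep(NA_real_, nrow(newdf))
  ok <- stats::complete.cases(newdf)
  pred[ok] <- stats::predict(fit, newdf[ok, , drop = FALSE])
  out <- raster_like(fine_topo$elevation,
                     matrix(pred, nrow(fine_topo$elevation$values)))
  attr(out, "model") <- fit
  out
}

#' Downscaling skill against station observations
#'
#' @param pred,obs Paired finite numeric vectors (predicted and observed
#'   values at validation stations).
#' @return List with `rmse` and `r2` (`1 - SSE/SST` of the observations).
#' @export
validate_downscaling <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]
  if (length(obs) < 2L) stop("need at least 2 paired observations")
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("observations have zero variance; R^2 undefined")
  sse <- sum((obs - pred)^2)
  list(rmse = sqrt(mean((obs - pred)^2)), r2 = 1 - sse / sst)
}

#' Derive the climate factor rasters
#'
#' Seasonal and monthly aggregates used as explanatory factors:
#' growing-season precipitation (`Pre_g`, sum over the season months),
#' coldest-month precipitation (`Pre_1`, January), warmest-month
#' precipitation (`Pre_8`, August), warmest-month mean temperature
#' (`T_MEAN8`) and growing-season mean temperature (`T_MEANg`).
#'
#' @param stack A `climate_stack`.
#' @param season Integer months of the growing season (default June to
#'   September).
#' @return Named list of `raster_grid`s (a climate `factor_set` fragment).
#' @export
derive_climate_variables <- function(stack, season = 6:9) {
  stopifnot(inherits(stack, "climate_stack"))
  season <- as.integer(season)
  if (any(season < 1L | season > 12L)) stop("season months must be in 1..12")
  tmpl <- stack$precip[[1]]
  msum <- function(layers, months) {
    out <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
    for (m in months) out <- out + layers[[m]]$values
    out
  }
  list(
    Pre_g = raster_like(tmpl, msum(stack$precip, season)),
    Pre_1 = stack$precip[[1]],
    Pre_8 = stack$precip[[8]],
    T_MEAN8 = stack$tmean[[8]],
    T_MEANg = raster_like(tmpl, msum(stack$tmean, season) / length(season))
  )
}

#' Assemble a named factor set
#'
#' @param ... Named `raster_grid`s or named lists of them (e.g. the output
#'   of [derive_climate_variables()] together with terrain layers).
#' @return Named list of aligned `raster_grid`s, class `factor_set`.
#' @export
factor_set <- function(...) {
  parts <- list(...)
  out <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (is_raster_grid(p)) {
      nm <- names(parts)[i]
      out[[nm]] <- p
    } else {
      out <- c(out, p)
    }
  }
  if (is.null(names(out)) || any(names(out) == "") || anyDuplicated(names(out)))
    stop("factor names must be unique and non-empty")
  do.call(stopifnot_aligned, unname(out))
  structure(out, class = "factor_set")
}

#' Drop highly correlated factors
#'
#' Pairwise Pearson correlation over the cells valid in every factor; while
#' any pair exceeds the threshold in absolute value, the lower-priority
#' member of the currently worst pair is dropped.
#'
#' @param candidates Named list of aligned `raster_grid`s (or a
#'   `factor_set`).
#' @param threshold Absolute correlation above which a pair is pruned
#'   (in `(0, 1]`).
#' @param priority Character vector ordering factors from most to least
#'   preferred (default: input order).
#' @return List with `kept` (surviving named list) and `dropped`
#'   (data.frame log with columns `dropped`, `kept`, `r`).
#' @export
prune_correlated <- function(candidates, threshold = 0.90,
                             priority = names(candidates)) {
  if (length(candidates) < 2L) stop("need at least 2 candidate factors")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]")
  vals <- vapply(candidates, function(g) as.vector(g$values),
                 numeric(length(candidates[[1]]$values)))
  ok <- stats::complete.cases(vals)
  if (sum(ok) < 3L) stop("need at least 3 shared valid cells")
  vals <- vals[ok, , drop = FALSE]
  alive <- names(candidates)
  rank_of <- function(nm) match(nm, priority)
  log <- data.frame(dropped = character(), kept = character(), r = numeric())
  repeat {
    if (length(alive) < 2L) break
    cm <- suppressWarnings(stats::cor(vals[, alive, drop = FALSE]))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    worst <- max(abs(cm))
    if (worst <= threshold) break
    idx <- which(abs(cm) == worst, arr.ind = TRUE)[1, ]
    pair <- alive[idx]
    drop <- pair[which.max(rank_of(pair))]
    keep <- setdiff(pair, drop)
    log <- rbind(log, data.frame(dropped = drop, kept = keep,
                                 r = cm[idx[1], idx[2]]))
    alive <- setdiff(alive, drop)
  }
  list(kept = candidates[alive], dropped = log)
}
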