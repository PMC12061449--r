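#' Year-keyed binary cover series
#'
#' @param years Ordered integer vector of map years.
#' @param maps List of aligned binary `raster_grid`s (values 0/1/NA), one
#'   per year.
#' @return List of class `cover_series` with `years`, `maps` (named by
#'   year) and `cell_area` (m^2).
#' @export
cover_series <- function(years, maps) {
  if (length(years) != length(maps)) stop("one map per year required")
  if (is.unsorted(years)) stop("`years` must be increasing")
  do.call(stopifnot_aligned, unname(maps))
  for (m in maps) {
    v <- m$values
    if (any(!(v %in% c(0, 1)) & is.finite(v)))
      stop("cover maps must be binary (0/1/NA)")
  }
  names(maps) <- as.character(years)
  structure(list(years = as.integer(years), maps = maps,
                 cell_area = maps[[1]]$cell_size^2),
            class = "cover_series")
}

# hm^2 (hectares): 1 hm^2 = 1e4 m^2
cells_to_hm2 <- function(n_cells, cell_area) n_cells * cell_area / 1e4

#' Two-date change map
#'
#' Cell-wise four-way categorisation between two years:
#' 0 absent-stable, 1 present-stable (unchanged), 2 expanded (0 to 1),
#' 3 reduced (1 to 0).
#'
#' @param series A `cover_series`.
#' @param y1,y2 Years present in the series.
#' @return A `raster_grid` of category codes with attributes `from_year`,
#'   `to_year`, `counts` (named cell counts) and `areas_hm2`.
#' @export
change_map <- function(series, y1, y2) {
  stopifnot(inherits(series, "cover_series"))
  k1 <- as.character(y1); k2 <- as.character(y2)
  if (!k1 %in% names(series$maps) || !k2 %in% names(series$maps))
    stop("both years must be present in the series")
  a <- series$maps[[k1]]$values
  b <- series$maps[[k2]]$values
  cat <- matrix(NA_real_, nrow(a), ncol(a))
  cat[a == 0 & b == 0] <- 0
  cat[a == 1 & b == 1] <- 1
  cat[a == 0 & b == 1] <- 2
  cat[a == 1 & b == 0] <- 3
  out <- raster_like(series$maps[[k1]], cat)
  counts <- vapply(0:3, function(k) sum(cat == k, na.rm = TRUE), numeric(1))
  names(counts) <- c("absent_stable", "unchanged", "expanded", "reduced")
  attr(out, "from_year") <- y1
  attr(out, "to_year") <- y2
  attr(out, "counts") <- counts
  attr(out, "areas_hm2") <- cells_to_hm2(counts, series$cell_area)
  attr(out, "legend") <- names(counts)
  out
}

#' Year span under a chosen convention
#'
#' `"difference"` gives the calendar difference `y2 - y1`; `"inclusive"`
#' counts both endpoint years (`y2 - y1 + 1`), the convention under which
#' a 2002-2021 window spans 20 years.
#'
#' @param y1,y2 Years, `y2 > y1`.
#' @param convention `"difference"` or `"inclusive"`.
#' @return Numeric span in years.
#' @export
year_span <- function(y1, y2, convention = c("difference", "inclusive")) {
  convention <- match.arg(convention)
  if (y2 <= y1) stop("y2 must exceed y1")
  switch(convention, difference = y2 - y1, inclusive = y2 - y1 + 1)
}

#' Annual expansion rate
#'
#' Simple (non-compounded) annual rate:
#' `((area2 - area1) / area1) * 100 / span_years`, in percent per year.
#'
#' @param area1,area2 Areas (any common unit, e.g. hm^2); `area1 > 0`.
#' @param span_years Positive span in years (see [year_span()]).
#' @return Percent per year.
#' @export
annual_rate <- function(area1, area2, span_years) {
  if (!is.finite(area1) || area1 <= 0)
    stop("`area1` must be positive (rate undefined otherwise)")
  if (!is.finite(span_years) || span_years <= 0)
    stop("`span_years` must be positive")
  ((area2 - area1) / area1) * 100 / span_years
}

#' Per-sector areas, expansion rates and maximum elevations
#'
#' For every aspect sector: presence area per year (hm^2), annual rates
#' between consecutive years and over the whole series, and the maximum
#' elevation over presence cells per year.
#'
#' @param series A `cover_series`.
#' @param sectors Integer sector `raster_grid` from
#'   [assign_aspect_sector()].
#' @param dem Elevation `raster_grid`.
#' @param span_convention Passed to [year_span()]; the replication profile
#'   uses `"inclusive"` for the full-period rate.
#' @return List of data frames `areas` (sector, year, area_hm2,
#'   max_elevation_m) and `rates` (sector, from, to, rate_pct_yr).
#' @export
sector_summary <- function(series, sectors, dem,
                           span_convention = "difference") {
  stopifnot(inherits(series, "cover_series"))
  stopifnot_aligned(series$maps[[1]], sectors, dem)
  legend <- attr(sectors, "legend")
  codes <- sort(unique(as.vector(sectors$values)))
  codes <- codes[is.finite(codes)]
  sector_name <- function(k) if (!is.null(legend)) legend[k] else as.character(k)
  areas <- data.frame(); rates <- data.frame()
  yrs <- series$years
  for (k in codes) {
    in_sec <- sectors$values == k & is.finite(sectors$values)
    a_by_year <- numeric(length(yrs)); e_by_year <- numeric(length(yrs))
    for (i in seq_along(yrs)) {
      pres <- series$maps[[i]]$values == 1 & in_sec
      n <- sum(pres, na.rm = TRUE)
      a_by_year[i] <- cells_to_hm2(n, series$cell_area)
      e_by_year[i] <- if (n > 0)
        max(dem$values[which(pres)], na.rm = TRUE) else NA_real_
    }
    if (all(a_by_year == 0)) warning("sector ", sector_name(k), " is empty")
    areas <- rbind(areas, data.frame(
      sector = sector_name(k), year = yrs, area_hm2 = a_by_year,
      max_elevation_m = e_by_year))
    pairs <- cbind(seq_len(length(yrs) - 1), seq(2, length(yrs)))
    if (length(yrs) > 2) pairs <- rbind(pairs, c(1, length(yrs)))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      r <- if (a_by_year[i] > 0)
        annual_rate(a_by_year[i], a_by_year[j],
                    year_span(yrs[i], yrs[j], span_convention))
      else NA_real_
      rates <- rbind(rates, data.frame(
        sector = sector_name(k), from = yrs[i], to = yrs[j],
        rate_pct_yr = r))
    }
  }
  list(areas = areas, rates = rates)
}

#' Presence distribution across slope classes
#'
#' Per year, the percentage of presence cells falling in each slope class
#' (percentages sum to 100 within rounding).
#'
#' @param series A `cover_series`.
#' @param slope_class Integer class `raster_grid` from [classify_slope()].
#' @return Data frame with `year`, `class`, `class_name`, `percent`;
#'   empty when no presence cells exist.
#' @export
slope_distribution <- function(series, slope_class) {
  stopifnot(inherits(series, "cover_series"))
  stopifnot_aligned(series$maps[[1]], slope_class)
  legend <- attr(slope_class, "legend")
  out <- data.frame()
  for (i in seq_along(series$years)) {
    pres <- series$maps[[i]]$values == 1
    cls <- slope_class$values[which(pres)]
    cls <- cls[is.finite(cls)]
    if (!length(cls)) next
    for (k in 1:7) {
      out <- rbind(out, data.frame(
        year = series$years[i], class = k,
        class_name = if (!is.null(legend)) legend[k] else as.character(k),
        percent = 100 * sum(cls == k) / length(cls)))
    }
  }
  out
}

#' Density-increase response surface
#'
#' Aggregates the expanded category of a change map onto coarser analysis
#' cells: per block of `aggregation` x `aggregation` fine cells (partial
#' blocks at the edges included), the percentage of valid fine cells that
#' switched from absent to present.
#'
#' @param change A change-map `raster_grid` from [change_map()].
#' @param aggregation Fine cells per analysis-cell side, `>= 1`.
#' @return A `raster_grid` of percentages in `[0, 100]` at the aggregated
#'   cell size.
#' @export
density_increase <- function(change, aggregation = 10L) {
  stopifnot(is_raster_grid(change))
  aggregation <- as.integer(aggregation)
  if (is.na(aggregation) || aggregation < 1L)
    stop("`aggregation` must be a positive integer")
  expanded <- raster_like(change,
                          ifelse(is.finite(change$values),
                                 as.numeric(change$values == 2), NA_real_))
  agg <- aggregate_raster(expanded, aggregation, mean)
  raster_like(agg, agg$values * 100)
}

#' Flatten a response raster for the detectors
#'
#' @param response A `raster_grid` (e.g. from [density_increase()]).
#' @return Data frame with `cell`, `x`, `y`, `response` (valid cells only).
#' @export
as_response_table <- function(response) {
  stopifnot(is_raster_grid(response))
  cc <- cell_centers(response)
  v <- as.vector(response$values)
  ok <- is.finite(v)
  data.frame(cell = which(ok), x = as.vector(cc$x)[ok],
             y = as.vector(cc$y)[ok], response = v[ok])
}
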