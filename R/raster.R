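#' Regular planar raster grid
#'
#' A light container for a single-band raster: a numeric matrix plus the
#' grid geometry. Row 1 is the northernmost row; `origin` is the (x, y)
#' coordinate of the outer (north-west) corner of cell `[1, 1]`. Missing
#' cells are stored as `NA`; a `nodata` sentinel is only used on disk.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2, (x, y) of the north-west grid corner.
#' @param nodata Sentinel written to / read from ASCII grid files.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 1, origin = c(0, 0),
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be two finite coordinates")
  if (any(is.infinite(values)))
    stop("raster values must be finite or NA")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, cell %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  values: [%g, %g], NA cells: %d\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  else cat("  all cells NA\n")
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Build a raster on the same grid as a template
#'
#' @param template A `raster_grid` supplying the geometry.
#' @param values Matrix of the same dimension (default all `NA`).
#' @return A `raster_grid`.
#' @export
raster_like <- function(template, values = NULL) {
  stopifnot(is_raster_grid(template))
  if (is.null(values))
    values <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  if (!identical(dim(values), dim(template$values)))
    stop("`values` does not match the template dimensions")
  raster_grid(values, template$cell_size, template$origin, template$nodata)
}

#' Check that rasters share grid geometry
#' @param ... `raster_grid` objects.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
stopifnot_aligned <- function(...) {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        !isTRUE(all.equal(g$cell_size, ref$cell_size)) ||
        !isTRUE(all.equal(g$origin, ref$origin)))
      stop("rasters are not aligned on the same grid")
  }
  invisible(TRUE)
}

#' Coordinates of cell centres
#'
#' @param grid A `raster_grid`.
#' @return List with matrices `x` and `y` of cell-centre coordinates.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  x <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  y <- grid$origin[2] - (seq_len(nr) - 0.5) * cs   # row 1 is north
  list(x = matrix(x, nr, nc, byrow = TRUE),
       y = matrix(y, nr, nc))
}

#' Look up raster values at point coordinates
#'
#' Each point takes the value of the cell containing it (no interpolation),
#' matching centre-of-cell fishnet extraction.
#'
#' @param grid A `raster_grid`.
#' @param x,y Point coordinates (same CRS/units as the grid).
#' @return Numeric vector; `NA` outside the grid or on nodata cells.
#' @export
extract_at_points <- function(grid, x, y) {
  stopifnot(is_raster_grid(grid), length(x) == length(y))
  cs <- grid$cell_size
  col <- floor((x - grid$origin[1]) / cs) + 1L
  row <- floor((grid$origin[2] - y) / cs) + 1L
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  ok <- row >= 1L & row <= nr & col >= 1L & col <= nc &
    !is.na(row) & !is.na(col)
  out <- rep(NA_real_, length(x))
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Aggregate a raster by block mean (or other function)
#'
#' Blocks of `fact` x `fact` fine cells become one coarse cell; partial
#' blocks at the south/east edges are kept and summarised over the cells
#' they do contain. `NA` cells are ignored unless a whole block is `NA`.
#'
#' @param grid A `raster_grid`.
#' @param fact Positive integer aggregation factor (fine cells per side).
#' @param fun Summary function taking a numeric vector, applied with
#'   `NA` removed.
#' @return A `raster_grid` with cell size `fact * cell_size`.
#' @export
aggregate_raster <- function(grid, fact, fun = mean) {
  stopifnot(is_raster_grid(grid))
  fact <- as.integer(fact)
  if (is.na(fact) || fact < 1L) stop("`fact` must be a positive integer")
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  br <- ceiling(nr / fact); bc <- ceiling(nc / fact)
  ri <- rep(seq_len(br), each = fact)[seq_len(nr)]
  ci <- rep(seq_len(bc), each = fact)[seq_len(nc)]
  out <- matrix(NA_real_, br, bc)
  for (i in seq_len(br)) {
    rows <- which(ri == i)
    sub <- v[rows, , drop = FALSE]
    for (j in seq_len(bc)) {
      vals <- sub[, which(ci == j)]
      vals <- vals[is.finite(vals)]
      if (length(vals)) out[i, j] <- fun(vals)
    }
  }
  raster_grid(out, grid$cell_size * fact, grid$origin, grid$nodata)
}

#' Read / write ESRI ASCII grid files
#'
#' Plain-text single-band raster interchange (`.asc`): a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`)
#' followed by rows north to south.
#'
#' @param path File path.
#' @return `read_ascii_grid()` returns a `raster_grid`.
#' @export
read_ascii_grid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, 1L)), "\\s+")[[1]]
    hdr[[tolower(ln[1])]] <- as.numeric(ln[2])
  }
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  raster_grid(m, hdr$cellsize, origin, nodata)
}

#' @rdname read_ascii_grid
#' @param grid A `raster_grid` to write.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- grid$origin[2] - nr * grid$cell_size
  hdr <- c(
    sprintf("ncols %d", nc), sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("nodata_value %.10g", grid$nodata)
  )
  v[!is.finite(v)] <- grid$nodata
  rows <- apply(v, 1L, function(r) paste(format(r, trim = TRUE,
                                                digits = 10), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Shift a matrix by (dr, dc): result[i, j] = m[i + dr, j + dc], NA outside.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  rok <- rs >= 1L & rs <= nr
  cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Separable Gaussian smoothing of a matrix via row/column band matrices,
# with edge renormalisation (kernel rows re-sum to 1 near borders).
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    B <- matrix(0, n, n)
    for (d in seq(-r, r)) {
      idx <- which(seq_len(n) + d >= 1 & seq_len(n) + d <= n)
      B[cbind(idx, idx + d)] <- k[d + r + 1]
    }
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}
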