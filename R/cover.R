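#' Spectral indices from reflectance bands
#'
#' Normalised-difference indices used in the nine-band feature space:
#' `NDVI = (NIR - Red) / (NIR + Red)`,
#' `NDWI = (Green - NIR) / (Green + NIR)` and the soil index
#' `NDSI = (SWIR1 - NIR) / (SWIR1 + NIR)`. A zero denominator yields
#' nodata.
#'
#' @param bands Named list of aligned reflectance `raster_grid`s; needs
#'   `Green`, `Red`, `NIR`, `SWIR1` (values `>= 0`).
#' @return Named list of `raster_grid`s `NDVI`, `NDWI`, `NDSI`.
#' @export
compute_indices <- function(bands) {
  need <- c("Green", "Red", "NIR", "SWIR1")
  miss <- setdiff(need, names(bands))
  if (length(miss)) stop("missing band(s): ", paste(miss, collapse = ", "))
  do.call(stopifnot_aligned, unname(bands[need]))
  for (nm in need)
    if (any(bands[[nm]]$values < 0, na.rm = TRUE))
      stop("reflectance must be non-negative (band ", nm, ")")
  nd <- function(a, b) {
    den <- a$values + b$values
    out <- (a$values - b$values) / den
    out[den == 0] <- NA_real_
    raster_like(a, out)
  }
  list(NDVI = nd(bands$NIR, bands$Red),
       NDWI = nd(bands$Green, bands$NIR),
       NDSI = nd(bands$SWIR1, bands$NIR))
}

#' Filter raw field samples
#'
#' Removes points outside the study boundary, then points rejected by
#' visual interpretation, and keeps a count ledger.
#'
#' @param samples Data frame with logical columns `inside_boundary` and
#'   `visual_class` (`TRUE` = confirmed target stand).
#' @return The retained data frame; the ledger
#'   (`raw`, `removed_boundary`, `removed_visual`, `retained`) is attached
#'   as attribute `"ledger"`.
#' @export
filter_samples <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("inside_boundary", "visual_class") %in% names(samples)))
  raw <- nrow(samples)
  inb <- samples[samples$inside_boundary, , drop = FALSE]
  removed_boundary <- raw - nrow(inb)
  kept <- inb[inb$visual_class, , drop = FALSE]
  removed_visual <- nrow(inb) - nrow(kept)
  if (nrow(kept) == 0L) warning("no samples retained after filtering")
  attr(kept, "ledger") <- list(raw = raw, removed_boundary = removed_boundary,
                               removed_visual = removed_visual,
                               retained = nrow(kept))
  kept
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/validation split
#'
#' Random split stratified by `class`; the total training size is
#' `round(n * train_fraction)` with half-up rounding, allocated across
#' classes by largest remainder so the per-class proportions are as even
#' as possible.
#'
#' @param samples Data frame with a `class` column.
#' @param train_fraction Fraction for training, in `(0, 1)`.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return List with data frames `train` and `validation` (disjoint,
#'   exhaustive).
#' @export
split_samples <- function(samples, train_fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(samples), "class" %in% names(samples))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  n <- nrow(samples)
  if (n < 2L) stop("need at least 2 samples to split")
  n_train <- round_half_up(n * train_fraction)
  cls <- as.character(samples$class)
  classes <- unique(cls)
  target <- table(cls)[classes] * train_fraction
  base <- floor(target)
  rem <- n_train - sum(base)
  if (rem > 0) {
    frac_order <- order(target - base, decreasing = TRUE)
    base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  } else if (rem < 0) {
    frac_order <- order(target - base)
    base[frac_order[seq_len(-rem)]] <- base[frac_order[seq_len(-rem)]] - 1
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  train_idx <- integer()
  for (k in classes) {
    idx <- which(cls == k)
    take <- min(base[[k]], length(idx))
    train_idx <- c(train_idx, sort(sample(idx, take)))
  }
  list(train = samples[sort(train_idx), , drop = FALSE],
       validation = samples[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

#' Soft-margin kernel SVM classifier contract
#'
#' The default pluggable binary classifier for [classify_cover()]: a
#' radial-kernel support vector machine. Any list with `fit(x, y)`
#' returning a model and `predict(model, x)` returning labels satisfies
#' the contract.
#'
#' @param ... Passed to [e1071::svm()] (e.g. `cost`, `gamma`).
#' @return List of class `cover_classifier` with `fit` and `predict`.
#' @export
svm_classifier <- function(...) {
  structure(list(
    fit = function(x, y) e1071::svm(x, factor(y), kernel = "radial", ...),
    predict = function(model, x) as.character(stats::predict(model, x))
  ), class = "cover_classifier")
}

#' Classify cover from a feature stack
#'
#' Trains the supplied classifier on per-point feature vectors extracted
#' from the feature rasters at the training coordinates, then labels every
#' valid cell. Degenerate training features (all rows identical) yield a
#' majority-class map with a warning.
#'
#' @param features Named list of aligned feature `raster_grid`s (the
#'   nine-band stack: reflectances plus indices).
#' @param train Data frame with `x`, `y` and `class` columns; both classes
#'   must be present.
#' @param classifier A classifier contract, e.g. [svm_classifier()].
#' @param target_class Label treated as presence (map value 1).
#' @return Binary `raster_grid` (1 = target stand, 0 = other).
#' @export
classify_cover <- function(features, train, classifier = svm_classifier(),
                           target_class = "target") {
  do.call(stopifnot_aligned, unname(features))
  stopifnot(all(c("x", "y", "class") %in% names(train)))
  X <- vapply(features, extract_at_points, numeric(nrow(train)),
              x = train$x, y = train$y)
  X <- matrix(X, nrow = nrow(train),
              dimnames = list(NULL, names(features)))
  y <- as.character(train$class)
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (length(unique(y)) < 2L)
    stop("training set contains a single class")
  tmpl <- features[[1]]
  cells <- vapply(features, function(g) as.vector(g$values),
                  numeric(length(tmpl$values)))
  valid <- stats::complete.cases(cells)
  out <- rep(NA_real_, length(tmpl$values))
  if (all(duplicated(X)[-1])) {
    warning("all training feature vectors identical; returning majority class")
    maj <- names(sort(table(y), decreasing = TRUE))[1]
    out[valid] <- as.numeric(maj == target_class)
  } else {
    model <- classifier$fit(X, y)
    pred <- classifier$predict(model, cells[valid, , drop = FALSE])
    out[valid] <- as.numeric(pred == target_class)
  }
  raster_like(tmpl, matrix(out, nrow(tmpl$values)))
}

#' Overall classification accuracy
#'
#' @param pred,truth Paired label vectors at the validation points.
#' @return List with `n`, `correct`, `misclassified` and
#'   `overall_accuracy` (percent, one decimal).
#' @export
assess_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  n <- length(pred)
  if (n < 1L) stop("need at least one validation point")
  correct <- sum(pred == truth)
  list(n = n, correct = correct, misclassified = n - correct,
       overall_accuracy = round(100 * correct / n, 1))
}
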