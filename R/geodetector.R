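#' Discretize a continuous factor into strata
#'
#' Stratification for the factor detector. Methods:
#' \describe{
#'   \item{quantile}{equal-frequency bins at sample quantiles (default).}
#'   \item{equal}{equal-width intervals over the data range.}
#'   \item{natural}{variance-minimising 1-D partition (Fisher-Jenks,
#'     exact dynamic programme over the sorted unique values).}
#'   \item{categorical}{passes integer codes through unchanged.}
#' }
#' If fewer than `k` distinct bins are achievable the stratum count is
#' reduced with a warning.
#'
#' @param values Numeric vector (NAs allowed; they stay unlabelled).
#' @param method One of `"quantile"`, `"equal"`, `"natural"`,
#'   `"categorical"`.
#' @param k Requested stratum count, `>= 2` (ignored for categorical).
#' @param factor_name Optional name carried into results.
#' @return List of class `strata_assignment`: `labels` (integer 1..L or
#'   NA), `L`, `method`, `breaks`, `factor_name`.
#' @export
discretize <- function(values, method = c("quantile", "equal", "natural",
                                          "categorical"),
                       k = 5L, factor_name = NULL) {
  method <- match.arg(method)
  labels <- rep(NA_integer_, length(values))
  ok <- is.finite(values)
  v <- values[ok]
  breaks <- NULL
  if (method == "categorical") {
    lev <- sort(unique(v))
    labels[ok] <- match(v, lev)
    L <- length(lev)
  } else {
    k <- as.integer(k)
    if (is.na(k) || k < 2L) stop("`k` must be at least 2")
    nu <- length(unique(v))
    if (nu <= 1L) {
      warning("constant factor: single stratum")
      labels[ok] <- 1L
      L <- 1L
    } else {
      if (nu < k) {
        warning("fewer distinct values than strata; reducing k to ", nu)
        k <- nu
      }
      breaks <- switch(method,
        quantile = unique(stats::quantile(v, probs = seq(0, 1, length.out = k + 1),
                                          names = FALSE)),
        equal = seq(min(v), max(v), length.out = k + 1),
        natural = jenks_breaks(v, k))
      if (length(breaks) - 1L < k && method == "quantile")
        warning("duplicated quantiles; reducing k to ", length(breaks) - 1L)
      labels[ok] <- as.integer(cut(v, breaks, include.lowest = TRUE))
      L <- length(breaks) - 1L
    }
  }
  structure(list(labels = labels, L = L, method = method, breaks = breaks,
                 factor_name = factor_name),
            class = "strata_assignment")
}

# Exact 1-D variance-minimising partition (Fisher-Jenks) by dynamic
# programming over sorted unique values weighted by multiplicity. For more
# than `max_unique` distinct values the data are first condensed onto
# quantile micro-bins to bound the DP cost.
jenks_breaks <- function(v, k, max_unique = 2000L) {
  u <- sort(unique(v))
  w <- as.numeric(table(factor(v, levels = u)))
  if (length(u) > max_unique) {
    q <- unique(stats::quantile(v, probs = seq(0, 1, length.out = max_unique),
                                names = FALSE))
    idx <- findInterval(v, q, all.inside = TRUE)
    u <- as.numeric(tapply(v, idx, mean))
    w <- as.numeric(table(idx))
  }
  m <- length(u)
  cw <- cumsum(w); cwx <- cumsum(w * u); cwx2 <- cumsum(w * u^2)
  # within-class weighted SS for classes spanning u[i..j]
  seg_cost <- function(i, j) {
    W <- cw[j] - if (i > 1) cw[i - 1] else 0
    S <- cwx[j] - if (i > 1) cwx[i - 1] else 0
    S2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
    S2 - S^2 / W
  }
  D <- matrix(Inf, k, m)
  B <- matrix(0L, k, m)
  D[1, ] <- vapply(seq_len(m), function(j) seg_cost(1L, j), numeric(1))
  if (k > 1) for (c in 2:k) {
    for (j in c:m) {
      is <- c:j
      costs <- D[c - 1, is - 1L] +
        vapply(is, function(i) seg_cost(i, j), numeric(1))
      best <- which.min(costs)
      D[c, j] <- costs[best]
      B[c, j] <- is[best]
    }
  }
  cuts <- integer(0)
  j <- m
  for (c in k:2) {
    i <- B[c, j]
    cuts <- c(i, cuts)
    j <- i - 1L
  }
  # breaks halfway between adjacent class-boundary values
  c(u[1], (u[cuts - 1L] + u[cuts]) / 2, u[m])
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Factor detector q statistic
#'
#' The stratified-heterogeneity statistic `q = 1 - SSW/SST`, where
#' `SSW = sum_h N_h * sigma_h^2` and `SST = N * sigma^2` with population
#' variances. Strata with fewer than `min_stratum_n` observations are
#' dropped (and logged) before computing; observations with missing
#' response or label are excluded listwise.
#'
#' @param y Numeric response vector.
#' @param strata A `strata_assignment`, or an integer/label vector.
#' @param min_stratum_n Minimum observations per retained stratum.
#' @return List of class `q_result`: `q`, `SSW`, `SST`, `N`, `strata`
#'   (per-stratum data frame `label`, `N_h`, `mean_h`, `var_h`),
#'   `dropped_strata`, `factor_name`.
#' @export
factor_q <- function(y, strata, min_stratum_n = 2L) {
  if (inherits(strata, "strata_assignment")) {
    labels <- strata$labels
    fname <- strata$factor_name
  } else {
    labels <- strata
    fname <- NULL
  }
  if (length(y) != length(labels)) stop("y and strata labels differ in length")
  ok <- is.finite(y) & !is.na(labels)
  y <- y[ok]; labels <- labels[ok]
  tab <- table(labels)
  small <- names(tab)[tab < min_stratum_n]
  keep <- !(labels %in% small)
  y <- y[keep]; labels <- labels[keep]
  N <- length(y)
  if (N < 2L) stop("fewer than 2 observations after dropping small strata")
  sst <- N * pop_var(y)
  if (sst == 0) stop("response is constant (SST = 0); q undefined")
  groups <- split(y, labels)
  N_h <- vapply(groups, length, numeric(1))
  mean_h <- vapply(groups, mean, numeric(1))
  var_h <- vapply(groups, pop_var, numeric(1))
  ssw <- sum(N_h * var_h)
  q <- 1 - ssw / sst
  stopifnot(q >= -1e-12, q <= 1 + 1e-12)
  structure(list(
    q = min(max(q, 0), 1), SSW = ssw, SST = sst, N = N,
    strata = data.frame(label = names(groups), N_h = N_h, mean_h = mean_h,
                        var_h = var_h, row.names = NULL),
    dropped_strata = small, factor_name = fname
  ), class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("q = %.5f (N = %d, %d strata%s)\n", x$q, x$N, nrow(x$strata),
              if (length(x$dropped_strata))
                paste0(", ", length(x$dropped_strata), " dropped") else ""))
  invisible(x)
}

#' Interaction detector
#'
#' Overlays two stratifications (distinct label pairs become overlay
#' strata), computes `q` on the overlay, recomputes each single-factor `q`
#' on exactly the overlay-retained observations (so the three values share
#' one sample and refinement monotonicity holds), and classifies the
#' interaction.
#'
#' @param y Numeric response vector.
#' @param strata_a,strata_b `strata_assignment`s or label vectors.
#' @param min_stratum_n Minimum observations per retained overlay stratum.
#' @param tol Tie tolerance for [classify_interaction()].
#' @return List of class `interaction_result`: `qA`, `qB`, `qAB`,
#'   `category`, `pair`, `N`.
#' @export
interaction_q <- function(y, strata_a, strata_b, min_stratum_n = 2L,
                          tol = 1e-9) {
  la <- if (inherits(strata_a, "strata_assignment")) strata_a$labels else strata_a
  lb <- if (inherits(strata_b, "strata_assignment")) strata_b$labels else strata_b
  na <- if (inherits(strata_a, "strata_assignment")) strata_a$factor_name else NULL
  nb <- if (inherits(strata_b, "strata_assignment")) strata_b$factor_name else NULL
  if (length(y) != length(la) || length(y) != length(lb))
    stop("y and strata labels differ in length")
  ok <- is.finite(y) & !is.na(la) & !is.na(lb)
  y <- y[ok]; la <- la[ok]; lb <- lb[ok]
  overlay <- paste(la, lb, sep = ":")
  tab <- table(overlay)
  keep <- !(overlay %in% names(tab)[tab < min_stratum_n])
  y <- y[keep]; la <- la[keep]; lb <- lb[keep]; overlay <- overlay[keep]
  qab <- factor_q(y, overlay, min_stratum_n = 1L)
  qa <- factor_q(y, la, min_stratum_n = 1L)
  qb <- factor_q(y, lb, min_stratum_n = 1L)
  structure(list(
    qA = qa$q, qB = qb$q, qAB = qab$q,
    category = classify_interaction(qa$q, qb$q, qab$q, tol),
    pair = c(na %||% "A", nb %||% "B"), N = qab$N
  ), class = "interaction_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interaction category from the three q values
#'
#' Five-way taxonomy comparing the overlay `qAB` against the single-factor
#' values: nonlinear enhancement (`qAB > qA + qB`), independence
#' (`qAB = qA + qB`), dual-factor (bi-) enhancement
#' (`qAB > max(qA, qB)`), single-factor weakening
#' (`min <= qAB < max`), nonlinear weakening (`qAB < min`). Sum
#' comparisons take precedence over max comparisons; equality with the max
#' (within `tol`) is resolved to bi-enhance, since on a shared sample the
#' overlay can never fall below the better single factor.
#'
#' @param qA,qB,qAB q values in `[0, 1]`.
#' @param tol Absolute tie tolerance.
#' @return One of `"nonlinear-enhance"`, `"independent"`, `"bi-enhance"`,
#'   `"single-weaken"`, `"nonlinear-weaken"`.
#' @export
classify_interaction <- function(qA, qB, qAB, tol = 1e-9) {
  stopifnot(all(is.finite(c(qA, qB, qAB))))
  s <- qA + qB; mx <- max(qA, qB); mn <- min(qA, qB)
  if (qAB > s + tol) return("nonlinear-enhance")
  if (abs(qAB - s) <= tol) return("independent")
  if (qAB > mx + tol || abs(qAB - mx) <= tol) return("bi-enhance")
  if (qAB >= mn - tol) return("single-weaken")
  "nonlinear-weaken"
}

#' Run factor and interaction detectors over a response table
#'
#' For each aspect sector (or the whole area when `sectors` is `NULL`):
#' discretizes every factor at the response locations, computes the factor
#' detector q for each factor and the interaction detector for every
#' factor pair, and returns ranked tables.
#'
#' @param response Data frame with `x`, `y`, `response` columns (e.g. from
#'   [as_response_table()]).
#' @param factors Named list of aligned factor `raster_grid`s (a
#'   `factor_set`).
#' @param sectors Optional sector `raster_grid`; response points are
#'   assigned to the sector of the cell that contains them.
#' @param k,method Stratification settings passed to [discretize()].
#' @param min_stratum_n Passed to [factor_q()] / [interaction_q()].
#' @param min_cells Sectors with fewer response cells are skipped with a
#'   warning.
#' @return List with data frames `factor_q` (sector, factor, q, N, ranked
#'   within sector) and `interaction_q` (sector, factor_a, factor_b, qA,
#'   qB, qAB, category, N).
#' @export
run_detectors <- function(response, factors, sectors = NULL, k = 5L,
                          method = "quantile", min_stratum_n = 2L,
                          min_cells = 30L) {
  stopifnot(all(c("x", "y", "response") %in% names(response)),
            length(factors) >= 2L)
  fvals <- lapply(factors, extract_at_points, x = response$x, y = response$y)
  sec <- if (is.null(sectors)) rep(1, nrow(response))
         else extract_at_points(sectors, response$x, response$y)
  legend <- if (is.null(sectors)) "all" else attr(sectors, "legend")
  fq <- data.frame(); iq <- data.frame()
  for (s in sort(unique(sec[is.finite(sec)]))) {
    idx <- which(sec == s)
    sname <- if (!is.null(legend) && s <= length(legend)) legend[s]
             else as.character(s)
    if (length(idx) < min_cells) {
      warning("sector ", sname, " has fewer than ", min_cells,
              " cells; skipped")
      next
    }
    y <- response$response[idx]
    strata <- lapply(names(factors), function(nm)
      discretize(fvals[[nm]][idx], method = method, k = k, factor_name = nm))
    names(strata) <- names(factors)
    for (nm in names(factors)) {
      qr <- factor_q(y, strata[[nm]], min_stratum_n)
      fq <- rbind(fq, data.frame(sector = sname, factor = nm, q = qr$q,
                                 N = qr$N))
    }
    nms <- names(factors)
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      ir <- interaction_q(y, strata[[nms[i]]], strata[[nms[j]]],
                          min_stratum_n)
      iq <- rbind(iq, data.frame(sector = sname, factor_a = nms[i],
                                 factor_b = nms[j], qA = ir$qA, qB = ir$qB,
                                 qAB = ir$qAB, category = ir$category,
                                 N = ir$N))
    }
  }
  if (nrow(fq)) fq <- fq[order(fq$sector, -fq$q), ]
  if (nrow(iq)) iq <- iq[order(iq$sector, -iq$qAB), ]
  rownames(fq) <- NULL; rownames(iq) <- NULL
  list(factor_q = fq, interaction_q = iq)
}

#' Strata-count sensitivity sweep
#'
#' Recomputes the factor detector q for each factor over a range of
#' stratum counts, as a robustness report for the (unstated) choice of k.
#'
#' @inheritParams run_detectors
#' @param ks Integer vector of stratum counts to sweep.
#' @return Data frame with `factor`, `k`, `q`.
#' @export
sweep_strata <- function(response, factors, ks = 3:8, method = "quantile",
                         min_stratum_n = 2L) {
  fvals <- lapply(factors, extract_at_points, x = response$x, y = response$y)
  out <- data.frame()
  for (k in ks) for (nm in names(factors)) {
    s <- discretize(fvals[[nm]], method = method, k = k, factor_name = nm)
    qr <- factor_q(response$response, s, min_stratum_n)
    out <- rbind(out, data.frame(factor = nm, k = k, q = qr$q))
  }
  out
}
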