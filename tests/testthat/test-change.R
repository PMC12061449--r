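two_maps <- function(m1, m2, years = c(2002, 2021), cs = 50) {
  cover_series(years, list(raster_grid(m1, cs, c(0, nrow(m1) * cs)),
                           raster_grid(m2, cs, c(0, nrow(m1) * cs))))
}

test_that("change categories match cell-wise enumeration", {
  m <- matrix(rep(c(0, 1), 8), 4, 4)
  s <- two_maps(m, m)
  ch <- change_map(s, 2002, 2021)
  cnt <- attr(ch, "counts")
  expect_equal(cnt[["expanded"]], 0)
  expect_equal(cnt[["reduced"]], 0)
  m2 <- m; m2[1, 1] <- 1   # m[1,1] was 0
  ch2 <- change_map(two_maps(m, m2), 2002, 2021)
  expect_equal(attr(ch2, "counts")[["expanded"]], 1)
  expect_equal(ch2$values[1, 1], 2)
  expect_error(change_map(s, 2002, 2015), "present")

  set.seed(14)
  a <- matrix(rbinom(400, 1, 0.4), 20, 20)
  b <- matrix(rbinom(400, 1, 0.5), 20, 20)
  cnt3 <- attr(change_map(two_maps(a, b), 2002, 2021), "counts")
  # brute-force loop oracle
  want <- c(absent_stable = 0, unchanged = 0, expanded = 0, reduced = 0)
  for (i in 1:20) for (j in 1:20) {
    k <- if (a[i, j] == 0 && b[i, j] == 0) 1 else if (a[i, j] == 1 && b[i, j] == 1) 2
         else if (a[i, j] == 0) 3 else 4
    want[k] <- want[k] + 1
  }
  expect_equal(unname(cnt3), unname(want))
})

test_that("annual rates follow the simple convention and span choices", {
  expect_equal(annual_rate(100, 100, 10), 0)
  expect_equal(annual_rate(100, 200, 10), 10)
  # headline replication: +24.26 % over an inclusive 2002-2021 span
  r <- annual_rate(100, 124.26, year_span(2002, 2021, "inclusive"))
  expect_equal(round(r, 2), 1.21)
  expect_equal(year_span(2002, 2021, "difference"), 19)
  expect_equal(year_span(2002, 2021, "inclusive"), 20)
  expect_error(annual_rate(0, 10, 5), "positive")
  expect_error(annual_rate(10, 20, 0), "positive")
  expect_error(year_span(2021, 2021), "exceed")
})

test_that("rate sign asymmetry holds only for equal spans", {
  up <- annual_rate(100, 150, 10)
  down <- annual_rate(150, 100, 10)
  expect_gt(up, 0); expect_lt(down, 0)
  expect_false(isTRUE(all.equal(up, -down)))  # relative base differs
  expect_equal(annual_rate(100, 120, 5), -annual_rate(100, 80, 5))
})

test_that("sector summaries report areas, rates and maximum elevations", {
  dem <- raster_grid(matrix(seq(2300, 1900, length.out = 20), 20, 20),
                     50, c(0, 1000))
  sec <- assign_aspect_sector(dem, c(500, 500))
  m1 <- matrix(0, 20, 20); m1[10, 2] <- 1   # single presence cell, west
  s <- two_maps(m1, m1)
  out <- suppressWarnings(sector_summary(s, sec, dem))
  west <- out$areas[out$areas$sector == "western", ]
  expect_equal(west$max_elevation_m, rep(dem$values[10, 2], 2))
  expect_equal(out$rates$rate_pct_yr[is.finite(out$rates$rate_pct_yr)],
               rep(0, sum(is.finite(out$rates$rate_pct_yr))))
})

test_that("scripted per-sector growth reproduces the hand ledger", {
  dem <- raster_grid(matrix(2000, 12, 12), 50, c(0, 600))
  dem$values[] <- 2000 + matrix(runif(144), 12, 12)
  sec <- assign_aspect_sector(dem, c(300, 300))
  m1 <- matrix(0, 12, 12); m2 <- m1
  north <- which(sec$values == 1); west <- which(sec$values == 4)
  m1[north[1:10]] <- 1; m2[north[1:15]] <- 1   # +50 % in the north
  m1[west[1:8]] <- 1; m2[west[1:8]] <- 1       # unchanged in the west
  s <- two_maps(m1, m2, years = c(2010, 2020))
  out <- suppressWarnings(sector_summary(s, sec, dem,
                                         span_convention = "difference"))
  rn <- out$rates[out$rates$sector == "northern", "rate_pct_yr"]
  expect_equal(rn, 50 / 10)
  rw <- out$rates[out$rates$sector == "western", "rate_pct_yr"]
  expect_equal(rw, 0)
  an <- out$areas[out$areas$sector == "northern", "area_hm2"]
  expect_equal(an, c(10, 15) * 2500 / 1e4)   # 50 m cells -> 0.25 hm2 each
})

test_that("slope distributions tally presence per class and sum to 100", {
  slope <- rg(matrix(c(rep(1, 8), rep(10, 8)), 4, 4))
  cls <- classify_slope(slope)
  m <- matrix(1, 4, 4)
  s <- two_maps(m, m, cs = 1)
  cls$cell_size <- 1; cls$origin <- c(0, 4)
  d <- slope_distribution(s, cls)
  expect_equal(d$percent[d$year == 2002 & d$class == 1], 50)
  expect_equal(d$percent[d$year == 2002 & d$class == 3], 50)
  expect_equal(sum(d$percent[d$year == 2002]), 100)
  # all presence on one class
  m2 <- matrix(0, 4, 4); m2[, 1:2] <- 1    # columns 1-2: slope 1 deg -> class 1
  d2 <- slope_distribution(two_maps(m2, m2, cs = 1), cls)
  expect_equal(d2$percent[d2$class == 1], c(100, 100))
  # random map equals exhaustive tally
  set.seed(6)
  m3 <- matrix(rbinom(16, 1, 0.6), 4, 4)
  d3 <- slope_distribution(two_maps(m3, m3, cs = 1), cls)
  pres <- which(m3 == 1)
  for (k in unique(cls$values[pres]))
    expect_equal(d3$percent[d3$year == 2002 & d3$class == k],
                 100 * sum(cls$values[pres] == k) / length(pres))
})

test_that("density increase is the block percentage of expanded cells", {
  a <- matrix(0, 10, 10); b <- a
  b[1:10, 1:10] <- 1
  ch_full <- change_map(two_maps(a, b), 2002, 2021)
  expect_equal(density_increase(ch_full, 10)$values[1, 1], 100)
  ch_none <- change_map(two_maps(a, a), 2002, 2021)
  expect_true(all(density_increase(ch_none, 5)$values == 0))
  set.seed(17)
  b2 <- a; b2[sample(100, 37)] <- 1
  ch37 <- change_map(two_maps(a, b2), 2002, 2021)
  expect_equal(density_increase(ch37, 10)$values[1, 1], 37)
  # aggregation 1 reproduces the expansion indicator x 100
  d1 <- density_increase(ch37, 1)
  expect_equal(d1$values, 100 * (ch37$values == 2))
  expect_true(all(d1$values >= 0 & d1$values <= 100))
  expect_error(density_increase(ch37, 0), "positive")
})

test_that("nested series have no reduction and nondecreasing areas", {
  set.seed(20)
  m1 <- matrix(rbinom(225, 1, 0.3), 15, 15)
  m2 <- pmin(m1 + matrix(rbinom(225, 1, 0.2), 15, 15), 1)
  m3 <- pmin(m2 + matrix(rbinom(225, 1, 0.2), 15, 15), 1)
  s <- cover_series(c(2002, 2010, 2021),
                    lapply(list(m1, m2, m3), function(m)
                      raster_grid(m, 50, c(0, 750))))
  ch <- change_map(s, 2002, 2021)
  expect_equal(attr(ch, "counts")[["reduced"]], 0)
  areas <- sapply(s$maps, function(g) sum(g$values == 1))
  expect_true(all(diff(areas) >= 0))
})

test_that("response tables carry cell-centre coordinates of valid cells", {
  g <- rg(matrix(c(1, NA, 3, 4), 2, 2), cs = 10)
  tab <- as_response_table(g)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("cell", "x", "y", "response") %in% names(tab)))
  expect_equal(tab$response, c(1, 3, 4))
})
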