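band <- function(v, n = 3) rg(matrix(v, n, n))

test_that("normalised-difference indices follow their formulas and bounds", {
  b <- list(Green = band(0.2), Red = band(0.1), NIR = band(0.5),
            SWIR1 = band(0.3))
  idx <- compute_indices(b)
  expect_equal(idx$NDVI$values[1, 1], 0.4 / 0.6)
  expect_equal(idx$NDWI$values[1, 1], (0.2 - 0.5) / 0.7)
  expect_equal(idx$NDSI$values[1, 1], (0.3 - 0.5) / 0.8)
  # symmetry and boundary cases
  idx2 <- compute_indices(list(Green = band(0), Red = band(0.3),
                               NIR = band(0.3), SWIR1 = band(0.3)))
  expect_equal(idx2$NDVI$values[1, 1], 0)
  expect_equal(idx2$NDWI$values[1, 1], -1)
  # 0/0 -> nodata
  idx3 <- compute_indices(list(Green = band(0), Red = band(0), NIR = band(0),
                               SWIR1 = band(0)))
  expect_true(all(is.na(idx3$NDVI$values)))
  expect_error(compute_indices(list(Red = band(1), NIR = band(1))), "missing")
  expect_error(compute_indices(list(Green = band(-0.1), Red = band(0.1),
                                    NIR = band(0.1), SWIR1 = band(0.1))),
               "non-negative")
  # indices stay in [-1, 1] wherever denominators are positive
  set.seed(8)
  bb <- list(Green = rg(matrix(runif(25), 5, 5)),
             Red = rg(matrix(runif(25), 5, 5)),
             NIR = rg(matrix(runif(25), 5, 5)),
             SWIR1 = rg(matrix(runif(25), 5, 5)))
  ii <- compute_indices(bb)
  for (g in ii) expect_true(all(abs(g$values) <= 1, na.rm = TRUE))
})

test_that("sample filtering reproduces the field-survey ledger", {
  set.seed(2)
  s <- data.frame(id = 1:480,
                  class = rep(c("target", "non-target"), 240),
                  inside_boundary = TRUE, visual_class = TRUE)
  s$inside_boundary[sample(480, 39)] <- FALSE
  inside <- which(s$inside_boundary)
  s$visual_class[sample(inside, 30)] <- FALSE
  kept <- filter_samples(s)
  led <- attr(kept, "ledger")
  expect_equal(led, list(raw = 480, removed_boundary = 39,
                         removed_visual = 30, retained = 411))
  expect_equal(nrow(kept), 411)
  # ledger conservation
  expect_equal(led$raw,
               led$removed_boundary + led$removed_visual + led$retained)
  # no flags set: identity
  s2 <- data.frame(id = 1:10, inside_boundary = TRUE, visual_class = TRUE)
  expect_equal(nrow(filter_samples(s2)), 10)
  # degenerate: everything outside
  s3 <- data.frame(id = 1:5, inside_boundary = FALSE, visual_class = TRUE)
  expect_warning(k3 <- filter_samples(s3), "no samples")
  expect_equal(nrow(k3), 0)
})

test_that("the stratified split rounds half-up and partitions exactly", {
  s <- data.frame(id = 1:411,
                  class = rep(c("target", "non-target"), c(250, 161)))
  sp <- split_samples(s, 0.7, seed = 4)
  expect_equal(nrow(sp$train), 288)
  expect_equal(nrow(sp$validation), 123)
  expect_length(intersect(sp$train$id, sp$validation$id), 0)
  expect_setequal(c(sp$train$id, sp$validation$id), s$id)
  # class proportions preserved within one sample
  expect_equal(sum(sp$train$class == "target"), 175)  # floor/remainder of 250*.7
  s2 <- data.frame(id = 1:10, class = rep(c("a", "b"), 5))
  sp2 <- split_samples(s2, 0.5, seed = 1)
  expect_equal(nrow(sp2$train), 5)
  # determinism
  sp3 <- split_samples(s, 0.7, seed = 4)
  expect_identical(sp$train$id, sp3$train$id)
  expect_error(split_samples(s, 1.2), "train_fraction")
})

feature_scene <- function(n = 40, m = 50, seed = 31, sep = 2) {
  # two-class scene: class field drawn per cell, one informative band
  set.seed(seed)
  truthm <- matrix(rbinom(n * m, 1, 0.5), n, m)
  f1 <- truthm * sep + matrix(rnorm(n * m), n, m)
  f2 <- matrix(rnorm(n * m), n, m)
  feats <- list(B1 = rg(f1), B2 = rg(f2))
  pts <- data.frame(x = runif(300, 0, m), y = runif(300, 0, n))
  cc <- extract_at_points(rg(truthm), pts$x, pts$y)
  pts$class <- ifelse(cc == 1, "target", "non-target")
  list(features = feats, truth = truthm, train = pts)
}

test_that("a separable scene is classified perfectly at the training points", {
  sc <- feature_scene(sep = 50)   # classes far apart: separable
  map <- classify_cover(sc$features, sc$train)
  pred <- extract_at_points(map, sc$train$x, sc$train$y)
  expect_equal(mean(pred == (sc$train$class == "target")), 1)
})

test_that("classifier accuracy approaches the Bayes rate on a Gaussian mixture", {
  # band B1 ~ N(0,1) vs N(2,1): Bayes accuracy pnorm(1) ~ 0.841
  sc <- feature_scene(n = 40, m = 50, sep = 2)
  map <- classify_cover(sc$features, sc$train)
  acc <- mean((map$values == 1) == (sc$truth == 1))
  expect_lt(abs(acc - pnorm(1)), 0.03)
})

test_that("degenerate and single-class training sets are handled", {
  feats <- list(B1 = rg(matrix(1, 5, 5)), B2 = rg(matrix(2, 5, 5)))
  tr <- data.frame(x = runif(10, 0, 5), y = runif(10, 0, 5),
                   class = rep(c("target", "non-target"), 5))
  expect_warning(map <- classify_cover(feats, tr), "identical")
  expect_true(all(map$values %in% c(0, 1)))
  expect_true(length(unique(as.vector(map$values))) == 1)
  tr2 <- tr; tr2$class <- "target"
  expect_error(classify_cover(feats, tr2), "single class")
})

test_that("overall accuracy is correct/n in percent, order-invariant", {
  pred <- c(rep(1, 106), rep(0, 41))
  truth <- rep(1, 147)
  a <- assess_accuracy(pred, truth)
  expect_equal(a$overall_accuracy, 72.1)
  expect_equal(a$correct, 106)
  expect_equal(a$misclassified, 41)
  o <- sample(147)
  expect_equal(assess_accuracy(pred[o], truth[o])$overall_accuracy, 72.1)
  expect_equal(assess_accuracy(1:5, 1:5)$overall_accuracy, 100)
  expect_equal(assess_accuracy(rep(0, 5), rep(1, 5))$overall_accuracy, 0)
  expect_error(assess_accuracy(1:3, 1:4), "differ")
})
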