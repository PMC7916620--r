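test_that("generation is a pure function of the spec", {
  sp <- synth_spec(channels = 3, bands = 4, n_classes = 3, n_train = 5,
                   n_val = 4, n_test = 6, effects = c(0, 1, 2, 0), seed = 77)
  a <- synth_bands(sp)
  b <- synth_bands(sp)
  expect_identical(a$train$x, b$train$x)
  expect_identical(a$val$x, b$val$x)
  expect_identical(a$test$x, b$test$x)
  expect_identical(a$means, b$means)
  # a different seed changes the draw
  c <- synth_bands(synth_spec(channels = 3, bands = 4, n_classes = 3,
                              n_train = 5, n_val = 4, n_test = 6,
                              effects = c(0, 1, 2, 0), seed = 78))
  expect_false(identical(a$train$x, c$train$x))
  # empty splits are NULL
  expect_null(synth_bands(synth_spec(channels = 2, bands = 2, n_classes = 2,
                                     n_train = 3, n_val = 0, n_test = 0,
                                     effects = c(1, 1)))$val)
})

test_that("class-mean geometry matches the documented recipe", {
  sp <- synth_spec(channels = 6, bands = 3, n_classes = 4, n_train = 2,
                   effects = c(0, 2, 4), noise_sd = 1.5, seed = 10)
  means <- synth_bands(sp)$means
  expect_equal(means[[1]], matrix(0, 4, 6))   # e = 0: no class information
  for (f in 2:3) {
    M <- means[[f]]
    dists <- as.numeric(dist(M))
    target <- sp$effects[f] * sp$noise_sd * sqrt(sp$channels)
    expect_equal(dists, rep(target, 6), tolerance = 1e-10)
    # equidistant but never antipodal: all means share one norm and no pair
    # is a sign flip of another
    nrms <- sqrt(rowSums(M^2))
    expect_equal(nrms, rep(target / sqrt(2), 4), tolerance = 1e-10)
    for (a in 1:3) for (b in (a + 1):4) {
      expect_gt(sum((M[a, ] + M[b, ])^2), 1e-6)
    }
  }
})

test_that("a zero-effect generator yields chance-level classification", {
  sim <- synth_bands(synth_spec(channels = 4, bands = 3, n_classes = 4,
                                n_train = 40, n_val = 0, n_test = 100,
                                effects = c(0, 0, 0), seed = 55))
  sp <- make_scales(3)[[3]]
  model <- fit_scale(sim$train, sp)
  acc <- mean(ssfbel_predict(model, sim$test)$labels == sim$test$labels)
  n <- nrow(sim$test$x)
  expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("increasing a band's effect size increases its patch accuracy", {
  accs <- vapply(c(0.5, 2, 5), function(e) {
    sim <- synth_bands(synth_spec(channels = 4, bands = 2, n_classes = 2,
                                  n_train = 30, n_val = 0, n_test = 100,
                                  effects = c(e, 0), seed = 60))
    m <- fit_scale(sim$train, make_scales(2)[[1]])
    mean(ssfbel_predict(m, sim$test)$patch_labels[, 1] == sim$test$labels)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.95)
})

test_that("decision fixtures hit the prescribed column accuracies", {
  expect_equal(make_decision_fixture(10, c(1, 1), seed = 1),
               matrix(1, 10, 2))
  expect_equal(make_decision_fixture(10, 0, seed = 1), matrix(-1, 10, 1))
  D <- make_decision_fixture(1000, c(0.9, 0.5), seed = 3)
  expect_true(all(D %in% c(-1, 1)))
  for (j in 1:2) {
    a <- c(0.9, 0.5)[j]
    expect_lt(abs(mean(D[, j]) - (2 * a - 1)),
              3 * 2 * sqrt(a * (1 - a) / 1000))
  }
  expect_identical(make_decision_fixture(50, c(0.7, 0.2), seed = 9),
                   make_decision_fixture(50, c(0.7, 0.2), seed = 9))
  expect_error(make_decision_fixture(5, 1.2), "\\[0, 1\\]")
})

test_that("feature tables round-trip through CSV bit-exactly", {
  sim <- synth_bands(synth_spec(channels = 3, bands = 2, n_classes = 2,
                                n_train = 6, n_val = 0, n_test = 0,
                                effects = c(1, 0), seed = 5,
                                band_names = c("Theta", "Alpha")))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp, paste0(tmp, ".json"))))
  write_band_csv(sim$train, tmp)
  back <- read_band_csv(tmp)
  expect_identical(back$x, sim$train$x)
  expect_identical(back$labels, sim$train$labels)
  expect_identical(back$band_names, c("Theta", "Alpha"))
  expect_equal(back$channels, 3)
  expect_equal(back$n_classes, 2)
})
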