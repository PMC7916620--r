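test_that("coding solves the regularized normal equations", {
  # identity dictionary, no penalty: coefficients reproduce y
  d <- patch_dictionary(diag(4), class_of = c(1, 1, 2, 2))
  y <- c(1, -2, 3, 0.5)
  expect_equal(crc_code(d, y, 0), y)

  # huge penalty drives the code to zero at the known rate
  lam <- 1e12
  a <- crc_code(d, y, lam)
  expect_lte(sqrt(sum(a^2)), sqrt(sum(crossprod(d$X, y)^2)) / lam * (1 + 1e-10))

  # random instances agree with an independent dense solve
  set.seed(101)
  for (r in 1:25) {
    dj <- sample(2:20, 1)
    n <- sample(2:30, 1)
    X <- matrix(rnorm(dj * n), dj, n)
    dict <- patch_dictionary(X, sample(1:2, n, replace = TRUE))
    y <- rnorm(dj)
    lam <- 10^runif(1, -4, 0)
    a <- crc_code(dict, y, lam)
    expect_equal(a, oracle_crc_code(dict$X, y, lam), tolerance = 1e-8)
    # linear-system residual bound
    lhs <- crossprod(dict$X) %*% a + lam * a
    rhs <- crossprod(dict$X, y)
    expect_lt(sqrt(sum((lhs - rhs)^2)) / max(1, sqrt(sum(rhs^2))), 1e-10)
  }

  # rank-deficient dictionary at lambda = 0 is an error
  Xdef <- cbind(c(1, 0), c(1, 0), c(0, 1))
  expect_error(crc_code(patch_dictionary(Xdef, c(1, 1, 2)), c(1, 1), 0),
               "rank deficient")
})

test_that("the code is the unique minimizer of the ridge objective", {
  set.seed(7)
  X <- matrix(rnorm(18), 6, 3)
  dict <- patch_dictionary(X, c(1, 2, 1))
  y <- rnorm(6)
  lam <- 0.05
  obj <- function(a) sum((dict$X %*% a - y)^2) + lam * sum(a^2)
  a <- crc_code(dict, y, lam)
  for (i in seq_along(a)) {
    for (eps in c(-1e-4, 1e-4)) {
      ap <- a
      ap[i] <- ap[i] + eps
      expect_gt(obj(ap), obj(a))
    }
  }
})

test_that("classification matches a from-scratch re-implementation", {
  set.seed(202)
  cfg <- crc_config(lambda = 0.01)
  for (r in 1:30) {
    c <- sample(2:4, 1)
    dj <- sample(3:8, 1)
    nk <- sample(2:5, c, replace = TRUE)
    X <- matrix(rnorm(dj * sum(nk)), dj)
    cls <- rep(seq_len(c), times = nk)
    dict <- patch_dictionary(X, cls)
    y <- rnorm(dj)
    got <- crc_classify(dict, y, cfg)
    want <- oracle_crc_classify(dict$X, dict$class_of, y, cfg$lambda)
    expect_identical(got$label, as.integer(want$label))
    expect_equal(unname(got$scores), unname(want$scores), tolerance = 1e-8)
  }
})

test_that("membership, tie-breaking and invariances behave as specified", {
  # y equals a class-1 column; class 2 orthogonal -> class 1 wins
  y <- c(1, 0, 0, 0)
  X <- cbind(y, c(0, 1, 0, 0), c(0, 0, 1, 0))
  dict <- patch_dictionary(X, c(1, 2, 2))
  out <- crc_classify(dict, y, crc_config(lambda = 1e-6))
  expect_equal(out$label, 1L)
  expect_lt(out$scores[1], 1e-3)

  # two classes with identical columns: identical scores, tie -> class 1
  Xs <- matrix(rnorm(8), 4, 2)
  dict2 <- patch_dictionary(cbind(Xs, Xs), c(1, 1, 2, 2))
  out2 <- crc_classify(dict2, rnorm(4), crc_config(lambda = 0.1))
  expect_equal(out2$scores[1], out2$scores[2], tolerance = 1e-12)
  expect_equal(out2$label, 1L)

  # permuting columns within a class leaves the scores unchanged
  set.seed(9)
  X3 <- matrix(rnorm(24), 4, 6)
  cls3 <- c(1, 1, 1, 2, 2, 2)
  y3 <- rnorm(4)
  s1 <- crc_classify(patch_dictionary(X3, cls3), y3)$scores
  perm <- c(3, 1, 2, 4, 6, 5)  # permutes within each class block
  s2 <- crc_classify(patch_dictionary(X3[, perm], cls3[perm]), y3)$scores
  expect_equal(s1, s2, tolerance = 1e-10)

  # without residual normalization, scaling y scales every residual by t
  cfg_raw <- crc_config(lambda = 0.05, normalize_residual = FALSE)
  d4 <- patch_dictionary(X3, cls3)
  r1 <- crc_classify(d4, y3, cfg_raw)
  r2 <- crc_classify(d4, 3 * y3, cfg_raw)
  expect_equal(r2$scores, 3 * r1$scores, tolerance = 1e-10)
  expect_identical(r1$label, r2$label)
})
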