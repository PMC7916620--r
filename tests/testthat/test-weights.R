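test_that("decision matrix encodes correctness as +/-1", {
  expect_equal(decision_matrix(matrix(1, 3, 2), rep(1, 3)), matrix(1, 3, 2))
  expect_equal(decision_matrix(matrix(2, 3, 2), rep(1, 3)), matrix(-1, 3, 2))
  expect_equal(decision_matrix(matrix(c(1, 2), 1), 1), matrix(c(1, -1), 1))
  expect_error(decision_matrix(matrix(1, 3, 2), rep(1, 4)), "nrow")
})

test_that("ensemble loss equals the per-sample margin summation", {
  m <- 6
  D <- matrix(1, m, 3)
  expect_equal(ensemble_loss(D, c(1, 0, 0)), 0)          # zero-loss vertex
  expect_equal(ensemble_loss(-D, rep(1 / 3, 3)), 4 * m)  # all wrong: 4m
  set.seed(17)
  for (r in 1:10) {
    D <- matrix(sample(c(-1, 1), m * 3, replace = TRUE), m)
    w <- oracle_proj_simplex(rnorm(3))
    direct <- sum(vapply(seq_len(m), function(p) (1 - sum(w * D[p, ]))^2,
                         numeric(1)))
    expect_equal(ensemble_loss(D, w), direct, tolerance = 1e-12)
  }
})

test_that("the auxiliary update minimizes the augmented Lagrangian in v", {
  set.seed(23)
  s <- 4
  D <- matrix(sample(c(-1, 1), 10 * s, replace = TRUE), 10)
  M <- crossprod(D)
  b <- 2 * colSums(D)
  w <- oracle_proj_simplex(rnorm(s))
  beta <- rnorm(s)
  mu <- 0.7
  v <- update_v(w, beta, mu, M, b)
  lagr <- function(v) sum(v * (M %*% w)) - sum(v * b) +
    mu / 2 * sum((w - v + beta / mu)^2)
  # gradient at the returned point vanishes
  grad <- drop(M %*% w) - b - mu * (w - v + beta / mu)
  expect_lt(sqrt(sum(grad^2)), 1e-8)
  # beats random perturbations
  for (r in 1:20) {
    expect_gte(lagr(v + rnorm(s, 0, 1e-3)), lagr(v))
  }
  # M = 0, beta = 0 closed form
  expect_equal(update_v(w, rep(0, s), 2, matrix(0, s, s), b), w + b / 2)
  # penalty-dominated limit: v -> w
  vbig <- update_v(w, beta, 1e12, M, b)
  expect_lt(max(abs(vbig - w)), sqrt(sum((beta + b - M %*% w)^2)) / 1e12 + 1e-15)
})

test_that("the Newton threshold root matches the sort-based exact root", {
  expect_equal(simplex_root(c(0.6, 0.4)), 0, tolerance = 1e-10)
  expect_equal(simplex_root(c(1.5, 0.5)), 0.5, tolerance = 1e-10)
  expect_equal(simplex_root(c(2, -1)), 1, tolerance = 1e-10)
  expect_equal(simplex_root(5), 4, tolerance = 1e-10)   # s = 1
  expect_error(simplex_root(c(1, NA)), "finite")
  set.seed(29)
  for (r in 1:200) {
    h <- rnorm(sample(1:8, 1), sd = sample(c(0.1, 1, 10), 1))
    eta <- simplex_root(h)
    expect_equal(sum(pmax(h - eta, 0)), 1, tolerance = 1e-9)
    expect_equal(eta, oracle_simplex_root(h), tolerance = 1e-9)
  }
})

test_that("the weight update is the Euclidean simplex projection", {
  s <- 3
  I0 <- matrix(0, s, s)
  # with M = 0, beta = 0, mu = 1: g = v, so a simplex point is a fixed point
  g <- c(0.5, 0.3, 0.2)
  expect_equal(solve_w(g, rep(0, s), 1, I0), g, tolerance = 1e-10)
  # far exterior point projects to a vertex
  expect_equal(solve_w(c(10, 0, 0), rep(0, s), 1, I0), c(1, 0, 0),
               tolerance = 1e-10)
  # randomized equivalence with the sort-based oracle
  set.seed(37)
  for (r in 1:300) {
    sdim <- sample(2:8, 1)
    g <- rnorm(sdim, sd = sample(c(0.5, 2, 20), 1))
    w <- solve_w(g, rep(0, sdim), 1, matrix(0, sdim, sdim))
    expect_equal(w, oracle_proj_simplex(g), tolerance = 1e-8)
    expect_true(all(w >= -1e-12))
    expect_equal(sum(w), 1, tolerance = 1e-8)
  }
})

test_that("learned weights solve the simplex-constrained least squares", {
  # a column that is always right and others always wrong: vertex optimum
  D <- matrix(-1, 20, 4)
  D[, 2] <- 1
  res <- learn_weights(D)
  expect_equal(res$w, c(0, 1, 0, 0), tolerance = 1e-6)
  expect_lt(ensemble_loss(D, res$w), 1e-10)
  expect_true(res$converged)

  # s = 1: the constraint forces w = 1
  expect_equal(learn_weights(matrix(c(1, -1, 1), 3, 1))$w, 1, tolerance = 1e-9)

  # random instances against the long-run projected-gradient oracle
  set.seed(41)
  for (r in 1:12) {
    m <- sample(5:40, 1)
    s <- sample(2:6, 1)
    D <- matrix(sample(c(-1, 1), m * s, replace = TRUE), m)
    res <- learn_weights(D)
    wpg <- oracle_pg_weights(D, iters = 5000)
    expect_lt(ensemble_loss(D, res$w) - ensemble_loss(D, wpg), 1e-5)
    # vertex dominance
    for (j in seq_len(s)) {
      ej <- replace(rep(0, s), j, 1)
      expect_lte(ensemble_loss(D, res$w), ensemble_loss(D, ej) + 1e-6)
    }
    # simplex membership
    expect_true(all(res$w >= -1e-12))
    expect_equal(sum(res$w), 1, tolerance = 1e-8)
  }
})

test_that("weight learning is equivariant under column permutation", {
  set.seed(43)
  D <- matrix(sample(c(-1, 1), 30 * 5, replace = TRUE), 30)
  perm <- sample(5)
  w1 <- learn_weights(D)$w
  w2 <- learn_weights(D[, perm])$w
  expect_equal(w2, w1[perm], tolerance = 1e-6)
})

test_that("hitting the iteration cap warns and still returns a simplex point", {
  set.seed(47)
  D <- matrix(sample(c(-1, 1), 40 * 4, replace = TRUE), 40)
  expect_warning(res <- learn_weights(D, solver_config(max_iter = 3)),
                 "did not converge")
  expect_false(res$converged)
  expect_equal(sum(res$w), 1, tolerance = 1e-8)
  expect_length(res$trace, 3)
})

test_that("invalid decision matrices are rejected", {
  expect_error(learn_weights(matrix(c(1, 0), 1)), "\\+1 or -1")
})
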