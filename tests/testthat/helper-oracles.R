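# Independent oracles. These deliberately avoid the package's own code paths:
# direct linear solves instead of Cholesky coding, a sort-based simplex
# projection instead of the Newton-root construction, and a long-run projected
# gradient method instead of the augmented-Lagrangian alternation.

# Ridge coding by a general dense linear solve of the normal equations.
oracle_crc_code <- function(X, y, lambda) {
  solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, y))[, 1]
}

# From-scratch collaborative-representation classification: code over the
# whole dictionary, reconstruct per class, pick the minimum (optionally
# normalized) residual, lowest class index on ties.
oracle_crc_classify <- function(X, class_of, y, lambda,
                                normalize_columns = TRUE,
                                normalize_residual = TRUE) {
  if (normalize_columns) {
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  }
  a <- oracle_crc_code(X, y, lambda)
  cls <- sort(unique(class_of))
  scores <- vapply(cls, function(k) {
    idx <- class_of == k
    r <- sqrt(sum((X[, idx, drop = FALSE] %*% a[idx] - y)^2))
    if (normalize_residual) r <- r / sqrt(sum(a[idx]^2))
    r
  }, numeric(1))
  list(label = cls[which.min(scores)], scores = scores)
}

# Exact Euclidean projection onto the probability simplex (sort and
# threshold).
oracle_proj_simplex <- function(g) {
  u <- sort(g, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(g - tau, 0)
}

# Long-run projected gradient descent for min ||1 - D w||^2 over the simplex.
oracle_pg_weights <- function(D, iters = 20000) {
  m <- nrow(D)
  s <- ncol(D)
  w <- rep(1 / s, s)
  L <- 2 * norm(crossprod(D), "2")
  for (i in seq_len(iters)) {
    gr <- 2 * crossprod(D, D %*% w - rep(1, m))[, 1]
    w <- oracle_proj_simplex(w - gr / L)
  }
  w
}

# Exact piecewise-linear root of sum((h - eta)+) = 1 via the same sort-based
# threshold (eta equals the projection's tau for the shifted vector).
oracle_simplex_root <- function(h) {
  u <- sort(h, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  (css[rho] - 1) / rho
}

# Small labelled band_data fixture; band 2 informative by default.
make_fixture <- function(seed = 1, channels = 3, bands = 4, n_classes = 2,
                         n_train = 10, n_test = 10,
                         effects = replace(rep(0, bands), min(2, bands), 3)) {
  synth_bands(synth_spec(channels = channels, bands = bands,
                         n_classes = n_classes, n_train = n_train,
                         n_val = 0, n_test = n_test, effects = effects,
                         seed = seed))
}
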