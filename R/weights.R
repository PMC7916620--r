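#' Decision matrix of per-scale correctness
#'
#' For `m` validation samples and `s` scales, entry `(p, j)` is `+1` when
#' scale `j` predicted sample `p` correctly and `-1` otherwise. Column means
#' of `(D + 1) / 2` are therefore the per-scale validation accuracies.
#'
#' @param pred `m x s` integer matrix of per-scale predicted labels.
#' @param truth length-`m` integer vector of true labels.
#'
#' @return An `m x s` matrix with entries in `{-1, +1}`.
#'
#' @examples
#' decision_matrix(cbind(c(1, 2), c(1, 1)), truth = c(1, 1))
#' @export
decision_matrix <- function(pred, truth) {
  pred <- as.matrix(pred)
  truth <- as.integer(truth)
  if (nrow(pred) != length(truth)) {
    stop("nrow(pred) must equal length(truth)", call. = FALSE)
  }
  D <- ifelse(pred == truth, 1, -1)
  storage.mode(D) <- "double"
  dimnames(D) <- NULL
  D
}

#' Ensemble loss of a weight vector
#'
#' The margin of validation sample `p` under weights `w` is
#' `sum_j w_j d_pj`; maximizing margins is cast as minimizing the squared
#' deviation of every margin from its ideal value 1:
#' `loss(w) = || 1_m - D w ||^2`.
#'
#' @param D decision matrix (`m x s`, entries ±1).
#' @param w weight vector on the probability simplex.
#'
#' @return Nonnegative scalar.
#' @export
ensemble_loss <- function(D, w) {
  D <- as.matrix(D)
  w <- as.numeric(w)
  if (ncol(D) != length(w)) stop("ncol(D) must equal length(w)", call. = FALSE)
  sum((1 - drop(D %*% w))^2)
}

#' Solver settings for ensemble-weight learning
#'
#' Controls the augmented-Lagrangian alternation of [learn_weights()]. The
#' defaults follow the standard initialization for this scheme: multiplier
#' `beta` of all ones, growth factor `rho = 1.1`, and an initial penalty
#' `mu0 = 1e-3` from the usual `10^(-5:-1)` tuning grid.
#'
#' @param mu0 initial quadratic penalty, `> 0`.
#' @param rho penalty growth factor, `> 1`.
#' @param mu_max penalty ceiling; `NULL` (default) caps the penalty at twice
#'   the largest diagonal entry of `D'D`, i.e. at the scale of the problem's
#'   curvature. An unbounded penalty freezes the iterate wherever the
#'   geometric growth outruns the optimization, so the cap is what lets the
#'   multiplier updates finish the job on hard instances.
#' @param max_iter maximum number of outer iterations.
#' @param tol convergence tolerance, applied to both the constraint gap
#'   `||w - v||_inf` and the relative change in `w`.
#' @param newton_tol,newton_max_iter tolerance and iteration cap for the inner
#'   Newton root-finding of the simplex projection.
#'
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(mu0 = 1e-3, rho = 1.1, max_iter = 5000L,
                          tol = 1e-8, mu_max = NULL, newton_tol = 1e-12,
                          newton_max_iter = 100L) {
  stopifnot(mu0 > 0, rho > 1, max_iter >= 1, tol > 0, newton_tol > 0,
            newton_max_iter >= 1, is.null(mu_max) || mu_max >= mu0)
  structure(list(mu0 = mu0, rho = rho, max_iter = as.integer(max_iter),
                 tol = tol, mu_max = mu_max, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter)),
            class = "solver_config")
}

#' Auxiliary-variable update of the augmented-Lagrangian scheme
#'
#' With the weight block held fixed, the augmented Lagrangian
#' `v'Mw - v'b + (mu/2) ||w - v + beta/mu||^2` is an unconstrained quadratic
#' in `v`; its stationary point is `v = w + (beta + b - M w) / mu`.
#'
#' @param w current weight vector.
#' @param beta Lagrange multiplier vector.
#' @param mu penalty parameter, `> 0`.
#' @param M `s x s` matrix `D'D`.
#' @param b length-`s` vector `2 D' 1_m`.
#'
#' @return The minimizing auxiliary vector `v`.
#' @export
update_v <- function(w, beta, mu, M, b) {
  stopifnot(mu > 0)
  w + (beta + b - drop(M %*% w)) / mu
}

#' Newton root of the simplex-projection threshold equation
#'
#' Finds the threshold `eta` solving `sum_j (h_j - eta)_+ = 1`, the KKT
#' condition of the Euclidean projection onto the probability simplex. The
#' function `f(eta) = sum_j (h_j - eta)_+ - 1` is convex, piecewise linear and
#' nonincreasing; Newton steps use the one-sided slope
#' `-#({j : h_j > eta})` starting from `eta0 = max(h) - 1` (where `f >= 0`),
#' with a bisection fallback should the active set ever cycle.
#'
#' @param h numeric vector.
#' @param tol absolute tolerance on `f(eta)` at the returned root.
#' @param max_iter iteration cap.
#'
#' @return The root `eta`.
#'
#' @examples
#' simplex_root(c(0.6, 0.4))   # 0: h already on the simplex
#' simplex_root(c(1.5, 0.5))   # 0.5 -> weights (1, 0)
#' @export
simplex_root <- function(h, tol = 1e-12, max_iter = 100L) {
  h <- as.numeric(h)
  if (length(h) == 0L || !all(is.finite(h))) {
    stop("'h' must be a non-empty finite vector", call. = FALSE)
  }
  f <- function(eta) sum(pmax(h - eta, 0)) - 1
  eta <- max(h) - 1          # f(eta0) >= 0 by construction
  lo <- eta
  hi <- max(h)               # f(hi) = -1 < 0
  for (it in seq_len(max_iter)) {
    fe <- f(eta)
    if (abs(fe) <= tol) return(eta)
    if (fe > 0) lo <- max(lo, eta) else hi <- min(hi, eta)
    k <- sum(h > eta)
    step_ok <- k > 0
    if (step_ok) {
      eta_new <- eta + fe / k
      step_ok <- eta_new > lo && eta_new < hi + tol
    }
    eta <- if (step_ok) eta_new else (lo + hi) / 2   # bisection fallback
  }
  eta
}

#' Weight update: Euclidean projection onto the probability simplex
#'
#' With the auxiliary block fixed, minimizing the augmented Lagrangian over
#' `{w : w >= 0, sum(w) = 1}` reduces to projecting
#' `g = v - (beta + M'v) / mu` onto the simplex. Following the shift-and-
#' threshold construction, `h = g - mean(g) + 1/s` is thresholded at the
#' root of [simplex_root()]: `w_j = (h_j - eta)_+`. (The linear term `-v'b`
#' of the augmented Lagrangian is constant in `w` and correctly plays no
#' role here.)
#'
#' @param v auxiliary vector.
#' @param beta Lagrange multiplier.
#' @param mu penalty parameter, `> 0`.
#' @param M `s x s` matrix `D'D`.
#' @param newton_tol,newton_max_iter passed to [simplex_root()].
#'
#' @return Weight vector on the simplex (nonnegative, summing to 1).
#' @export
solve_w <- function(v, beta, mu, M, newton_tol = 1e-12, newton_max_iter = 100L) {
  stopifnot(mu > 0)
  s <- length(v)
  g <- v - (beta + drop(crossprod(M, v))) / mu
  h <- g - mean(g) + 1 / s
  eta <- simplex_root(h, tol = newton_tol, max_iter = newton_max_iter)
  w <- pmax(h - eta, 0)
  w / sum(w)     # tidy the root-finder's residual so sum(w) is exactly 1
}

#' Learn ensemble weights from a decision matrix
#'
#' Minimizes the margin loss `||1_m - D w||^2` over the probability simplex
#' by an augmented-Lagrangian alternation: an auxiliary variable `v` splits
#' the quadratic, `v` and `w` are updated in closed form ([update_v()],
#' [solve_w()]), then the multiplier and the penalty are advanced
#' (`beta <- beta + mu (w - v)`, with `mu` growing by the factor `rho` up to
#' the `mu_max` ceiling — see [solver_config()]). Convergence is declared
#' only when the constraint gap and the change in `w` are below `tol` *and*
#' the iterate passes a projected-gradient stationarity check for the
#' constrained problem. Scales that were right on
#' more validation samples receive more mass; the learned loss can never
#' exceed the loss of the best single scale, because every one-hot vector
#' lies in the feasible set.
#'
#' @param D decision matrix (`m x s`, entries ±1) from [decision_matrix()].
#' @param cfg a [solver_config].
#'
#' @return A list of class `ensemble_weights`: `w` (length-`s` weights on the
#'   simplex), `trace` (objective value per outer iteration), `iterations`,
#'   `converged` (logical; `FALSE` raises a warning and returns the last
#'   iterate).
#'
#' @examples
#' D <- cbind(rep(1, 8), rep(-1, 8))   # scale 1 always right, scale 2 never
#' learn_weights(D)$w                  # ~ (1, 0)
#' @export
learn_weights <- function(D, cfg = solver_config()) {
  D <- as.matrix(D)
  storage.mode(D) <- "double"
  if (!all(D %in% c(-1, 1))) stop("D entries must be +1 or -1", call. = FALSE)
  stopifnot(inherits(cfg, "solver_config"))
  s <- ncol(D)
  M <- crossprod(D)
  b <- 2 * colSums(D)
  mu_max <- if (is.null(cfg$mu_max)) 2 * max(diag(M)) else cfg$mu_max
  v <- rep(1 / s, s)
  beta <- rep(1, s)
  mu <- cfg$mu0
  w <- solve_w(v, beta, mu, M, cfg$newton_tol, cfg$newton_max_iter)
  # stationarity of the constrained QP: w is optimal iff projecting one
  # gradient step (any positive step size) returns w itself
  kkt_resid <- function(w) {
    step <- 1 / max(1, 2 * max(diag(M)))
    g2 <- w - step * (2 * drop(M %*% w) - b)
    h2 <- g2 - mean(g2) + 1 / s
    max(abs(pmax(h2 - simplex_root(h2, cfg$newton_tol, cfg$newton_max_iter), 0) - w))
  }
  trace <- numeric(cfg$max_iter)
  best_w <- w
  best_loss <- ensemble_loss(D, w)
  converged <- FALSE
  it <- 0L
  while (it < cfg$max_iter) {
    it <- it + 1L
    v <- update_v(w, beta, mu, M, b)
    w_new <- solve_w(v, beta, mu, M, cfg$newton_tol, cfg$newton_max_iter)
    beta <- beta + mu * (w_new - v)
    mu <- min(cfg$rho * mu, mu_max)
    trace[it] <- ensemble_loss(D, w_new)
    if (trace[it] < best_loss) {
      best_loss <- trace[it]
      best_w <- w_new
    }
    gap <- max(abs(w_new - v))
    dw <- max(abs(w_new - w)) / max(1, max(abs(w)))
    w <- w_new
    if (gap < cfg$tol && dw < cfg$tol && kkt_resid(w) < sqrt(cfg$tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    w <- best_w
    warning("weight learning did not converge in ", cfg$max_iter,
            " iterations; returning the best iterate", call. = FALSE)
  }
  structure(list(w = w, trace = trace[seq_len(it)], iterations = it,
                 converged = converged),
            class = "ensemble_weights")
}

#' @export
print.ensemble_weights <- function(x, digits = 4, ...) {
  cat("ensemble weights (", length(x$w), " scales):\n", sep = "")
  print(round(x$w, digits))
  cat(sprintf("loss %.6g after %d iterations%s\n",
              x$trace[length(x$trace)], x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
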