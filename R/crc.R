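#' Collaborative-representation classifier settings
#'
#' The base classifier codes a test patch over the whole training dictionary
#' with ridge (l2) regularization and assigns the class whose columns
#' reconstruct the patch with the smallest residual.
#'
#' @param lambda nonnegative ridge penalty on the representation coefficients.
#'   The classical tuning grid is `10^(-5:-1)`.
#' @param normalize_columns if `TRUE` (default), dictionary columns are scaled
#'   to unit l2 norm before coding — standard practice for collaborative
#'   representation so that every training patch contributes on the same scale.
#' @param normalize_residual if `TRUE` (default), each class residual
#'   `||X_k a_k - y||` is divided by `||a_k||`, which sharpens discrimination:
#'   a class that explains `y` with large coefficients is favoured over one
#'   that barely uses its columns.
#'
#' @return A list of class `crc_config`.
#' @export
crc_config <- function(lambda = 1e-3, normalize_columns = TRUE,
                       normalize_residual = TRUE) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("'lambda' must be a single finite value >= 0", call. = FALSE)
  }
  structure(list(lambda = as.numeric(lambda),
                 normalize_columns = isTRUE(normalize_columns),
                 normalize_residual = isTRUE(normalize_residual)),
            class = "crc_config")
}

#' Patch dictionary of training samples
#'
#' Builds the codebook for one patch: a `d_j x n` matrix whose columns are
#' training patches, grouped by class (class 1 first, then class 2, ...),
#' input order preserved within a class.
#'
#' @param X numeric matrix with training patches as columns (`d_j x n`).
#' @param class_of integer class label (in `1..c`) of each column.
#' @param n_classes number of classes `c`; defaults to `max(class_of)`.
#'
#' @return An object of class `patch_dictionary` with elements `X` (columns
#'   reordered into class blocks), `class_of`, `n_classes`, `n_k` (per-class
#'   counts).
#' @export
patch_dictionary <- function(X, class_of, n_classes = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  class_of <- as.integer(class_of)
  if (length(class_of) != ncol(X)) {
    stop("length(class_of) must equal ncol(X)", call. = FALSE)
  }
  if (any(class_of < 1L)) stop("class labels must be >= 1", call. = FALSE)
  if (is.null(n_classes)) n_classes <- max(class_of)
  n_classes <- as.integer(n_classes)
  ord <- order(class_of)          # stable: preserves input order within class
  X <- X[, ord, drop = FALSE]
  class_of <- class_of[ord]
  structure(list(X = X, class_of = class_of, n_classes = n_classes,
                 n_k = tabulate(class_of, n_classes)),
            class = "patch_dictionary")
}

# Scale columns to unit l2 norm; zero columns are left untouched.
normalize_cols <- function(X) {
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  sweep(X, 2, nrm, "/")
}

# Ridge-regularized coding of many patches at once: solves
# (X'X + lambda I) A = X'Y column-by-column via one Cholesky factorization.
# lambda = 0 is routed through a QR least-squares solve; a rank-deficient
# dictionary at lambda = 0 is an error (the normal equations are singular).
crc_code_matrix <- function(X, Y, lambda) {
  n <- ncol(X)
  if (lambda > 0) {
    G <- crossprod(X)
    diag(G) <- diag(G) + lambda
    R <- chol(G)
    backsolve(R, forwardsolve(t(R), crossprod(X, Y)))
  } else {
    qx <- qr(X)
    if (qx$rank < n) {
      stop("dictionary is rank deficient; coding with lambda = 0 requires ",
           "X'X to be invertible", call. = FALSE)
    }
    A <- qr.coef(qx, Y)
    if (is.null(dim(A))) A <- matrix(A, ncol = 1)
    A
  }
}

#' Ridge-regularized collaborative coding of a patch
#'
#' Computes the representation coefficients `a` minimizing
#' `||X a - y||^2 + lambda ||a||^2`, i.e. the solution of the normal equations
#' `(X'X + lambda I) a = X'y`, through a symmetric positive-definite
#' factorization (never an explicit matrix inverse).
#'
#' @param dict a [patch_dictionary].
#' @param y numeric vector of length `nrow(dict$X)`.
#' @param lambda nonnegative ridge penalty; `lambda = 0` requires `X'X` to be
#'   invertible and is solved as a least-squares problem.
#'
#' @return Numeric coefficient vector of length `ncol(dict$X)`, in the
#'   dictionary's column order.
#'
#' @examples
#' d <- patch_dictionary(diag(3), class_of = c(1, 1, 2))
#' crc_code(d, c(1, 2, 3), lambda = 0)  # identity dictionary reproduces y
#' @export
crc_code <- function(dict, y, lambda) {
  stopifnot(inherits(dict, "patch_dictionary"))
  y <- as.numeric(y)
  if (length(y) != nrow(dict$X)) {
    stop("length(y) must equal the dictionary's patch dimension", call. = FALSE)
  }
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("'lambda' must be a single finite value >= 0", call. = FALSE)
  }
  drop(crc_code_matrix(dict$X, matrix(y, ncol = 1), lambda))
}

# Batch classification: Y has one test patch per column. Returns a list with
# integer labels and the c x q score matrix of (optionally normalized)
# class-wise reconstruction residuals. Ties go to the lowest class index
# (which.min's convention).
crc_classify_matrix <- function(dict, Y, cfg) {
  X <- dict$X
  if (cfg$normalize_columns) X <- normalize_cols(X)
  A <- crc_code_matrix(X, Y, cfg$lambda)
  c <- dict$n_classes
  q <- ncol(Y)
  scores <- matrix(Inf, c, q)
  for (k in seq_len(c)) {
    idx <- which(dict$class_of == k)
    if (length(idx) == 0L) next      # class absent: score stays +Inf
    Ak <- A[idx, , drop = FALSE]
    E <- X[, idx, drop = FALSE] %*% Ak - Y
    res <- sqrt(colSums(E^2))
    if (cfg$normalize_residual) {
      an <- sqrt(colSums(Ak^2))
      res <- ifelse(an == 0, Inf, res / an)
    }
    scores[k, ] <- res
  }
  if (any(apply(scores, 2, function(s) all(!is.finite(s))))) {
    stop("degenerate input: every class residual is infinite for some patch",
         call. = FALSE)
  }
  list(labels = apply(scores, 2, which.min), scores = scores)
}

#' Classify a patch by class-wise reconstruction error
#'
#' Codes `y` over the full dictionary with [crc_code()], then reconstructs it
#' from each class's columns separately and assigns the class with the
#' smallest residual `||X_k a_k - y||` (divided by `||a_k||` when
#' `normalize_residual` is on). Ties are broken by the lowest class index.
#'
#' @param dict a [patch_dictionary]; every class should contribute at least
#'   one column.
#' @param y numeric test patch.
#' @param cfg a [crc_config].
#'
#' @return A list with `label` (integer class) and `scores` (per-class
#'   residuals; `Inf` marks a class that cannot represent `y` at all).
#'
#' @examples
#' d <- patch_dictionary(cbind(c(1, 0), c(0, 1)), class_of = c(1, 2))
#' crc_classify(d, c(1, 0.1), crc_config(lambda = 1e-6))$label
#' @export
crc_classify <- function(dict, y, cfg = crc_config()) {
  stopifnot(inherits(dict, "patch_dictionary"), inherits(cfg, "crc_config"))
  y <- as.numeric(y)
  if (length(y) != nrow(dict$X)) {
    stop("length(y) must equal the dictionary's patch dimension", call. = FALSE)
  }
  out <- crc_classify_matrix(dict, matrix(y, ncol = 1), cfg)
  list(label = out$labels[1L], scores = drop(out$scores))
}
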