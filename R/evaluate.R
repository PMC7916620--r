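#' Evaluate a fitted model on labelled test data
#'
#' @param model a fitted [msfbel] model (or any object with a compatible
#'   `predict` method returning integer labels).
#' @param test labelled [band_data].
#' @param normalize if `TRUE`, confusion-matrix rows are normalized to sum
#'   to 1 (per-class recognition rates) instead of raw counts.
#'
#' @return A list of class `eval_report`: `accuracy`, `per_class` (per-class
#'   accuracy), `confusion` (`c x c` matrix, rows = true class, columns =
#'   predicted), `n`.
#' @export
evaluate <- function(model, test, normalize = FALSE) {
  stopifnot(inherits(test, "band_data"))
  if (is.null(test$labels) || nrow(test$x) == 0L) {
    stop("'test' must be non-empty and labelled", call. = FALSE)
  }
  pred <- predict(model, test)
  c <- test$n_classes
  confusion <- matrix(0, c, c,
                      dimnames = list(true = seq_len(c), pred = seq_len(c)))
  for (i in seq_along(pred)) {
    confusion[test$labels[i], pred[i]] <- confusion[test$labels[i], pred[i]] + 1
  }
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  acc <- sum(diag(confusion)) / length(pred)
  if (normalize) confusion <- confusion / pmax(rowSums(confusion), 1)
  structure(list(accuracy = acc, per_class = per_class,
                 confusion = confusion, n = length(pred)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("accuracy: %.*g on %d samples\n", digits, x$accuracy, x$n))
  cat("per-class:", paste(round(x$per_class, digits), collapse = " "), "\n")
  cat("confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Nemenyi critical distance
#'
#' After a Friedman rank test over `k` methods compared on `N` independent
#' result groups (use [stats::friedman.test()] for the omnibus test), two
#' methods differ significantly when their average ranks differ by more than
#' the critical distance `CD = q_alpha * sqrt(k (k + 1) / (6 N))`, where
#' `q_alpha` is the Studentized-range-based critical value from the standard
#' Nemenyi table (for example 2.569 at alpha = 0.05 with k = 4).
#'
#' @param k number of methods, `>= 2`.
#' @param N number of result groups, `>= 1`.
#' @param q_alpha critical value from the Nemenyi table, `> 0`.
#'
#' @return The critical distance (scalar).
#'
#' @examples
#' nemenyi_cd(k = 4, N = 45, q_alpha = 2.569)
#' @export
nemenyi_cd <- function(k, N, q_alpha) {
  if (length(k) != 1L || !is.finite(k) || k < 2) {
    stop("'k' must be a single integer >= 2", call. = FALSE)
  }
  if (length(N) != 1L || !is.finite(N) || N < 1) {
    stop("'N' must be a single integer >= 1", call. = FALSE)
  }
  if (length(q_alpha) != 1L || !is.finite(q_alpha) || q_alpha <= 0) {
    stop("'q_alpha' must be a single positive value", call. = FALSE)
  }
  q_alpha * sqrt(k * (k + 1) / (6 * N))
}

#' Baseline-deviation correction of trial samples
#'
#' Standard pre-stimulus baseline removal: the first `n_baseline` samples of
#' a trial are averaged and that average is subtracted from every remaining
#' sample of the trial (e.g. 3 baseline + 60 trial samples per one-minute
#' clip yields 60 corrected samples).
#'
#' @param data ordered [band_data] holding the samples of one trial, baseline
#'   samples first.
#' @param n_baseline number of leading baseline samples, `>= 1`.
#'
#' @return [band_data] with `nrow(data$x) - n_baseline` corrected samples.
#' @export
baseline_correct <- function(data, n_baseline) {
  stopifnot(inherits(data, "band_data"))
  n_baseline <- as.integer(n_baseline)
  n <- nrow(data$x)
  if (n_baseline < 1L || n < n_baseline + 1L) {
    stop("need at least n_baseline + 1 samples", call. = FALSE)
  }
  base <- colMeans(data$x[seq_len(n_baseline), , drop = FALSE])
  rest <- data$x[-seq_len(n_baseline), , drop = FALSE]
  band_data(sweep(rest, 2, base),
            labels = if (is.null(data$labels)) NULL else data$labels[-seq_len(n_baseline)],
            channels = data$channels, bands = data$bands,
            band_names = data$band_names, n_classes = data$n_classes)
}

#' Grid search for the CRC regularization parameter
#'
#' Evaluates each candidate `lambda` by the validation accuracy of the
#' global-scale single-scale ensemble (all bands concatenated, one patch) on
#' a stratified split of the training data, and returns the best; ties are
#' resolved toward the smallest `lambda`.
#'
#' @param train labelled [band_data].
#' @param grid candidate penalties; default the classical `10^(-5:-1)`.
#' @param split fraction of each class in the dictionary part.
#' @param seed optional seed for the split.
#' @param cfg a [crc_config] supplying the normalization flags.
#'
#' @return A list with `lambda` (the selected value) and `accuracy` (named
#'   vector of validation accuracies over the deduplicated, sorted grid).
#' @export
tune_lambda <- function(train, grid = 10^(-5:-1), split = 0.5, seed = NULL,
                        cfg = crc_config()) {
  stopifnot(inherits(train, "band_data"))
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) == 0L) stop("'grid' must be non-empty", call. = FALSE)
  parts <- split_band_data(train, fraction = split, seed = seed)
  spec <- make_scales(train$bands)[[train$bands]]  # global scale
  acc <- vapply(grid, function(lam) {
    cfg_l <- crc_config(lam, cfg$normalize_columns, cfg$normalize_residual)
    model <- fit_scale(parts$fit, spec, cfg_l)
    mean(ssfbel_predict(model, parts$val)$labels == parts$val$labels)
  }, numeric(1))
  names(acc) <- format(grid, scientific = TRUE)
  list(lambda = grid[which.max(acc)], accuracy = acc)
}
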