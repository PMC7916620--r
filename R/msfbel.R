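#' Split labelled data into a fit part and a validation part
#'
#' Stratified split used to calibrate the ensemble weights: the fit part
#' trains the per-scale dictionaries and the validation part supplies the
#' decision matrix. When a `trials` vector is given the split is by trial
#' (whole trials go to one side, stratified by class); otherwise it is a
#' stratified random split by class.
#'
#' @param data labelled [band_data].
#' @param fraction fraction of each class (or of each class's trials)
#'   assigned to the fit part; default 0.5, i.e. each part holds half the
#'   samples of every class.
#' @param trials optional vector of trial identifiers, one per sample.
#' @param seed optional integer seed making the split reproducible.
#'
#' @return A list with `fit` and `val`, both [band_data], plus the index
#'   vectors `fit_idx` and `val_idx`.
#' @export
split_band_data <- function(data, fraction = 0.5, trials = NULL, seed = NULL) {
  stopifnot(inherits(data, "band_data"))
  if (is.null(data$labels)) stop("'data' must be labelled", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- nrow(data$x)
  fit_idx <- integer(0)
  if (is.null(trials)) {
    for (k in seq_len(data$n_classes)) {
      idx <- which(data$labels == k)
      n_fit <- floor(length(idx) * fraction)
      if (n_fit < 1L || n_fit >= length(idx)) {
        stop("class ", k, " cannot be split: too few samples", call. = FALSE)
      }
      fit_idx <- c(fit_idx, sort(sample(idx, n_fit)))
    }
  } else {
    if (length(trials) != n) stop("length(trials) must equal sample count", call. = FALSE)
    for (k in seq_len(data$n_classes)) {
      idx <- which(data$labels == k)
      tr_k <- unique(trials[idx])
      n_fit <- floor(length(tr_k) * fraction)
      if (n_fit < 1L || n_fit >= length(tr_k)) {
        stop("class ", k, " cannot be split by trial: too few trials", call. = FALSE)
      }
      fit_tr <- sample(tr_k, n_fit)
      fit_idx <- c(fit_idx, idx[trials[idx] %in% fit_tr])
    }
  }
  fit_idx <- sort(fit_idx)
  val_idx <- setdiff(seq_len(n), fit_idx)
  counts <- tabulate(data$labels[val_idx], data$n_classes)
  if (any(counts == 0L)) {
    stop("validation part lost class ", which(counts == 0L)[1], call. = FALSE)
  }
  list(fit = data[fit_idx], val = data[val_idx],
       fit_idx = fit_idx, val_idx = val_idx)
}

#' Fit a multi-scale frequency-band ensemble
#'
#' Trains the full multi-scale classifier on labelled band-structured
#' features. The `s` bands yield `s` scales (windows of 1, 2, ..., `s`
#' adjacent bands); each scale is a single-scale ensemble of collaborative
#' representation classifiers fused by majority voting ([fit_scale()],
#' [ssfbel_predict()]). The training data are split into a fit part (which
#' builds the patch dictionaries) and a validation part; per-scale
#' correctness on the validation part forms the decision matrix from which
#' [learn_weights()] learns a weight for every scale on the probability
#' simplex. Prediction fuses the per-scale labels by a weighted vote.
#'
#' By default the dictionaries presented at test time remain those of the fit
#' part, against which the weights were calibrated; set `refit = TRUE` to
#' rebuild them from the full training set after weight learning.
#'
#' @param data labelled [band_data] (or a numeric matrix, in which case
#'   `labels`, `channels` and `bands` must be supplied).
#' @param labels,channels,bands used only when `data` is a bare matrix.
#' @param cfg a [crc_config] shared by all scales.
#' @param solver a [solver_config] for the weight learner.
#' @param split fraction of each class used for the dictionary-fit part;
#'   see [split_band_data()].
#' @param trials optional trial identifiers for a by-trial split.
#' @param refit rebuild dictionaries on the full training set after weight
#'   learning (default `FALSE`).
#' @param seed optional integer seed for the split.
#'
#' @return An object of class `msfbel`: list with `scale_models`, `weights`
#'   (an `ensemble_weights` object), `D` (the validation decision matrix),
#'   `scale_val_accuracy` (per-scale validation accuracies, the column means
#'   of `(D + 1) / 2`), `channels`, `bands`, `band_names`, `n_classes`,
#'   `cfg`, `solver`, `split`, `seed`, `call`.
#'
#' @examples
#' sim <- synth_bands(synth_spec(channels = 4, bands = 3, n_classes = 2,
#'                               n_train = 20, n_val = 0, n_test = 0,
#'                               effects = c(0, 2, 0), seed = 1))
#' fit <- msfbel(sim$train, seed = 1)
#' coef(fit)
#' @export
msfbel <- function(data, labels = NULL, channels = NULL, bands = NULL,
                   cfg = crc_config(), solver = solver_config(),
                   split = 0.5, trials = NULL, refit = FALSE, seed = NULL) {
  cl <- match.call()
  if (!inherits(data, "band_data")) {
    data <- band_data(data, labels = labels, channels = channels, bands = bands)
  }
  if (is.null(data$labels)) stop("training data must be labelled", call. = FALSE)
  scales <- make_scales(data$bands)
  parts <- split_band_data(data, fraction = split, trials = trials, seed = seed)
  counts <- tabulate(parts$fit$labels, data$n_classes)
  if (any(counts == 0L)) {
    stop("fit part lost class ", which(counts == 0L)[1], call. = FALSE)
  }
  scale_models <- lapply(scales, function(sp) fit_scale(parts$fit, sp, cfg))
  pred_val <- vapply(scale_models,
                     function(m) ssfbel_predict_matrix(m, parts$val)$labels,
                     integer(nrow(parts$val$x)))
  D <- decision_matrix(pred_val, parts$val$labels)
  weights <- learn_weights(D, solver)
  if (refit) {
    scale_models <- lapply(scales, function(sp) fit_scale(data, sp, cfg))
  }
  structure(
    list(scale_models = scale_models, weights = weights, D = D,
         scale_val_accuracy = colMeans((D + 1) / 2),
         channels = data$channels, bands = data$bands,
         band_names = data$band_names, n_classes = data$n_classes,
         cfg = cfg, solver = solver, split = split, refit = refit,
         seed = seed, call = cl),
    class = "msfbel"
  )
}

#' Predict from a fitted multi-scale ensemble
#'
#' Each scale produces its own label by patch-wise collaborative
#' representation plus majority voting; the final label is the weighted vote
#' `argmax_k sum_j w_j I(r_j = k)` with the learned scale weights, ties going
#' to the lowest class index.
#'
#' @param object a fitted [msfbel] model.
#' @param newdata [band_data] or a numeric matrix of flattened samples.
#' @param type `"class"` (default) returns the integer label vector;
#'   `"scales"` additionally returns the per-scale labels.
#' @param ... unused.
#'
#' @return For `type = "class"`, an integer vector of predicted labels. For
#'   `type = "scales"`, a list with `class` and the `n x s` matrix
#'   `per_scale`.
#' @export
predict.msfbel <- function(object, newdata, type = c("class", "scales"), ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "band_data")) {
    newdata <- band_data(newdata, channels = object$channels,
                         bands = object$bands, n_classes = object$n_classes)
  }
  if (newdata$channels != object$channels || newdata$bands != object$bands) {
    stop("'newdata' shape does not match the fitted model", call. = FALSE)
  }
  per_scale <- vapply(object$scale_models,
                      function(m) ssfbel_predict_matrix(m, newdata)$labels,
                      integer(nrow(newdata$x)))
  if (nrow(newdata$x) == 1L) per_scale <- matrix(per_scale, nrow = 1)
  w <- object$weights$w
  cls <- apply(per_scale, 1, function(r) {
    which.max(vapply(seq_len(object$n_classes),
                     function(k) sum(w[r == k]), numeric(1)))
  })
  if (type == "class") cls else list(class = cls, per_scale = per_scale)
}

#' @export
print.msfbel <- function(x, digits = 4, ...) {
  cat("Multi-scale frequency-band ensemble\n")
  cat(sprintf("  %d channels x %d bands, %d classes, %d scales\n",
              x$channels, x$bands, x$n_classes, x$bands))
  cat(sprintf("  lambda = %g, split = %g%s\n", x$cfg$lambda, x$split,
              if (x$refit) ", dictionaries refit on full training set" else ""))
  cat("  scale weights:", paste(round(x$weights$w, digits), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.msfbel <- function(object, ...) {
  tab <- data.frame(
    scale = seq_len(object$bands),
    patches = vapply(object$scale_models, function(m) m$spec$p, integer(1)),
    val_accuracy = object$scale_val_accuracy,
    weight = object$weights$w
  )
  structure(list(table = tab, n_val = nrow(object$D),
                 loss = ensemble_loss(object$D, object$weights$w),
                 converged = object$weights$converged,
                 iterations = object$weights$iterations,
                 call = object$call),
            class = "summary.msfbel")
}

#' @export
print.summary.msfbel <- function(x, digits = 4, ...) {
  cat("Multi-scale frequency-band ensemble\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\nPer-scale validation performance (m = %d samples):\n", x$n_val))
  print(x$table, digits = digits, row.names = FALSE)
  cat(sprintf("\nEnsemble loss on validation decision matrix: %.*g\n",
              digits, x$loss))
  cat(sprintf("Weight solver: %d iterations, %sconverged\n",
              x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
coef.msfbel <- function(object, ...) {
  w <- object$weights$w
  names(w) <- paste0("scale", seq_along(w))
  w
}

#' Plot learned scale weights against validation accuracy
#'
#' Barplot of the learned ensemble weight per scale, with the per-scale
#' validation accuracy overlaid as points on a secondary axis.
#'
#' @param x a fitted [msfbel] model.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.msfbel <- function(x, ...) {
  w <- x$weights$w
  bp <- graphics::barplot(w, names.arg = paste0("j=", seq_along(w)),
                          ylab = "ensemble weight", xlab = "scale",
                          ylim = c(0, max(1, max(w))), ...)
  graphics::points(bp, x$scale_val_accuracy, pch = 19)
  graphics::legend("topright", legend = c("weight", "validation accuracy"),
                   fill = c("grey", NA), border = c("black", NA),
                   pch = c(NA, 19), bty = "n")
  invisible(x)
}
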