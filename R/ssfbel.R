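#' Majority vote over patch labels
#'
#' Returns the class receiving the most votes; ties are broken by the lowest
#' class index, so the result is invariant to the order of the votes.
#'
#' @param labels integer class labels in `1..c`, one per voter.
#' @param c number of classes.
#'
#' @return The winning class (integer).
#'
#' @examples
#' majority_vote(c(1, 1, 2), 2)  # 1
#' majority_vote(c(1, 2), 2)     # 1 (tie -> lowest index)
#' @export
majority_vote <- function(labels, c) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("'labels' must be non-empty", call. = FALSE)
  if (any(labels < 1L | labels > c)) {
    stop("labels must lie in 1..c", call. = FALSE)
  }
  which.max(tabulate(labels, as.integer(c)))
}

#' Fit the single-scale ensemble (SSFBEL) for one scale
#'
#' Builds one patch dictionary per adjacent-band window of the scale from the
#' labelled training samples. All dictionaries of a scale share one CRC
#' configuration, and the band composition and order of each dictionary match
#' the test patches it will classify.
#'
#' @param train labelled [band_data].
#' @param spec a `scale_spec` from [make_scales()]; its `s` must equal
#'   `train$bands`.
#' @param cfg a [crc_config], shared by all patches of the scale.
#'
#' @return An object of class `scale_model`: list with `spec`, `dictionaries`
#'   (one [patch_dictionary] per patch), `cfg`, `channels`, `n_classes`.
#' @export
fit_scale <- function(train, spec, cfg = crc_config()) {
  stopifnot(inherits(train, "band_data"), inherits(spec, "scale_spec"),
            inherits(cfg, "crc_config"))
  if (is.null(train$labels)) stop("'train' must be labelled", call. = FALSE)
  if (train$bands != spec$s) stop("band count mismatch", call. = FALSE)
  counts <- tabulate(train$labels, train$n_classes)
  if (any(counts == 0L)) {
    stop("every class in 1..n_classes needs at least one training sample; ",
         "missing: ", paste(which(counts == 0L), collapse = ", "),
         call. = FALSE)
  }
  dictionaries <- lapply(seq_len(spec$p), function(i) {
    patch_dictionary(t(extract_patch(train, spec, i)), train$labels,
                     train$n_classes)
  })
  structure(list(spec = spec, dictionaries = dictionaries, cfg = cfg,
                 channels = train$channels, n_classes = train$n_classes),
            class = "scale_model")
}

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf("scale_model: scale j = %d (%d patch dictionaries of %d columns), lambda = %g\n",
              x$spec$j, x$spec$p, ncol(x$dictionaries[[1]]$X), x$cfg$lambda))
  invisible(x)
}

# All per-scale predictions for a batch of samples: returns n x p matrix of
# patch labels and length-n vector of scale labels.
ssfbel_predict_matrix <- function(model, data) {
  spec <- model$spec
  n <- nrow(data$x)
  patch_labels <- matrix(NA_integer_, n, spec$p)
  for (i in seq_len(spec$p)) {
    Y <- t(extract_patch(data, spec, i))
    patch_labels[, i] <- crc_classify_matrix(model$dictionaries[[i]], Y,
                                             model$cfg)$labels
  }
  scale_labels <- apply(patch_labels, 1, majority_vote, c = model$n_classes)
  list(labels = scale_labels, patch_labels = patch_labels)
}

#' Predict with a single-scale ensemble
#'
#' Classifies every adjacent-band patch of each sample with the collaborative
#' representation classifier, then fuses the `p_j` patch labels by simple
#' majority voting to obtain the scale-level label `r_j`.
#'
#' @param model a `scale_model` from [fit_scale()].
#' @param data [band_data] with matching channel and band counts.
#'
#' @return A list with `labels` (integer vector, one scale-level label per
#'   sample) and `patch_labels` (`n x p_j` integer matrix of per-patch votes).
#' @export
ssfbel_predict <- function(model, data) {
  stopifnot(inherits(model, "scale_model"))
  if (inherits(data, "band_data")) {
    if (data$channels != model$channels || data$bands != model$spec$s) {
      stop("'data' shape does not match the fitted model", call. = FALSE)
    }
  } else {
    data <- band_data(data, channels = model$channels, bands = model$spec$s,
                      n_classes = model$n_classes)
  }
  ssfbel_predict_matrix(model, data)
}
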