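#' Band-structured feature data
#'
#' Container for a set of samples whose features have a channels-by-bands
#' structure, such as per-channel differential-entropy (DE) features extracted
#' from a handful of EEG frequency bands (Delta, Theta, Alpha, Beta, Gamma).
#' Each sample is conceptually a `channels x bands` matrix; samples are stored
#' flattened in *band-major* order: the feature vector is the concatenation of
#' the per-band channel blocks, so feature `(f - 1) * channels + ch` is channel
#' `ch` of band `f`. With 62 channels and 5 bands this yields the familiar
#' 310-dimensional layout.
#'
#' @param x numeric matrix, one row per sample, `channels * bands` columns in
#'   band-major order; a single sample may be given as a vector.
#' @param labels optional integer class labels in `1..n_classes`; `NA` entries
#'   are not allowed.
#' @param channels number of channels (rows of the per-sample matrix).
#' @param bands number of frequency bands (columns of the per-sample matrix).
#' @param band_names optional character vector of band names, length `bands`.
#' @param n_classes number of classes; defaults to `max(labels)`.
#'
#' @return An object of class `band_data`: a list with elements `x` (the
#'   sample-by-feature matrix), `labels` (or `NULL`), `channels`, `bands`,
#'   `band_names`, `n_classes`.
#'
#' @examples
#' x <- matrix(rnorm(4 * 6), 4, 6)
#' d <- band_data(x, labels = c(1, 1, 2, 2), channels = 2, bands = 3)
#' d$bands
#' @export
band_data <- function(x, labels = NULL, channels, bands,
                      band_names = NULL, n_classes = NULL) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (channels < 1 || bands < 1) {
    stop("'channels' and 'bands' must be positive integers", call. = FALSE)
  }
  channels <- as.integer(channels)
  bands <- as.integer(bands)
  if (ncol(x) != channels * bands) {
    stop(sprintf("ncol(x) = %d but channels * bands = %d",
                 ncol(x), channels * bands), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("all feature values must be finite", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(x)) {
      stop("length(labels) must equal nrow(x)", call. = FALSE)
    }
    if (anyNA(labels) || any(labels < 1L)) {
      stop("labels must be integers >= 1 with no NA", call. = FALSE)
    }
  }
  if (is.null(n_classes)) {
    n_classes <- if (is.null(labels)) NA_integer_ else max(labels)
  }
  if (is.null(band_names)) {
    band_names <- paste0("band", seq_len(bands))
  } else if (length(band_names) != bands) {
    stop("length(band_names) must equal 'bands'", call. = FALSE)
  }
  structure(
    list(x = x, labels = labels, channels = channels, bands = bands,
         band_names = as.character(band_names),
         n_classes = as.integer(n_classes)),
    class = "band_data"
  )
}

#' @export
print.band_data <- function(x, ...) {
  cat(sprintf("band_data: %d samples, %d channels x %d bands (d = %d)\n",
              nrow(x$x), x$channels, x$bands, ncol(x$x)))
  if (!is.null(x$labels)) {
    cat("classes:", paste(sprintf("%d (n=%d)", seq_len(x$n_classes),
                                  tabulate(x$labels, x$n_classes)),
                          collapse = ", "), "\n")
  } else {
    cat("unlabelled\n")
  }
  invisible(x)
}

#' @export
`[.band_data` <- function(x, i, ...) {
  band_data(x$x[i, , drop = FALSE],
            labels = if (is.null(x$labels)) NULL else x$labels[i],
            channels = x$channels, bands = x$bands,
            band_names = x$band_names, n_classes = x$n_classes)
}

#' Multi-scale decomposition into adjacent-band patches
#'
#' At scale `j` (for `j = 1..s`) every window of `j` adjacent frequency bands
#' forms one patch, giving `p_j = s - j + 1` patches per scale. Scale `s` has
#' one patch covering all bands (the "global scale", i.e. plain feature
#' concatenation); smaller scales are "local scales". Only contiguous band
#' windows exist: neighbouring bands reflect a continuum of oscillatory
#' activity, so non-adjacent groupings are deliberately excluded.
#'
#' @param s number of frequency bands (and hence of scales), `s >= 1`.
#'
#' @return A list of `s` objects of class `scale_spec`, one per scale `j`.
#'   Each has fields `s`, `j`, `p` (the patch count `s - j + 1`) and
#'   `windows`, an ordered list of integer vectors of the 1-based band indices
#'   covered by each patch.
#'
#' @examples
#' sc <- make_scales(5)
#' sc[[2]]$p        # 4 patches at scale 2
#' sc[[5]]$windows  # one window covering bands 1..5
#' @export
make_scales <- function(s) {
  if (length(s) != 1L || !is.finite(s) || s < 1) {
    stop("'s' must be a single integer >= 1", call. = FALSE)
  }
  s <- as.integer(s)
  lapply(seq_len(s), function(j) {
    p <- s - j + 1L
    windows <- lapply(seq_len(p), function(i) seq.int(i, i + j - 1L))
    structure(list(s = s, j = j, p = p, windows = windows),
              class = "scale_spec")
  })
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("scale_spec: scale j = %d of s = %d bands, %d patch(es)\n",
              x$j, x$s, x$p))
  for (i in seq_len(x$p)) {
    w <- x$windows[[i]]
    cat(sprintf("  patch %d: bands %d..%d\n", i, w[1], w[length(w)]))
  }
  invisible(x)
}

# Column indices (into the band-major flattened layout) of patch i of a scale.
patch_columns <- function(spec, i, channels) {
  w <- spec$windows[[i]]
  unlist(lapply(w, function(f) seq.int((f - 1L) * channels + 1L, f * channels)))
}

#' Extract one patch from band-structured samples
#'
#' Pure selection of the feature columns belonging to one adjacent-band window:
#' the returned values are the concatenated channel blocks of the window's
#' bands, in band order with channel order preserved (no arithmetic is
#' performed). The patch dimension is `d_j = channels * j`.
#'
#' @param data a [band_data] object, or a numeric vector holding one flattened
#'   sample (in which case `channels` must be supplied).
#' @param spec a `scale_spec` from [make_scales()].
#' @param i patch index, `1 <= i <= spec$p`.
#' @param channels number of channels; taken from `data` when it is a
#'   `band_data` object.
#'
#' @return For `band_data` input, a numeric matrix with one row per sample and
#'   `d_j` columns; for a single flattened sample, a numeric vector of length
#'   `d_j`.
#'
#' @examples
#' sc <- make_scales(3)
#' y <- c(1, 2, 10, 20, 100, 200)        # 2 channels x 3 bands, band-major
#' extract_patch(y, sc[[1]], 2, channels = 2)  # band 2 -> c(10, 20)
#' @export
extract_patch <- function(data, spec, i, channels = NULL) {
  if (!inherits(spec, "scale_spec")) stop("'spec' must be a scale_spec", call. = FALSE)
  if (length(i) != 1L || i < 1 || i > spec$p) {
    stop(sprintf("patch index i = %s out of range 1..%d", as.character(i), spec$p),
         call. = FALSE)
  }
  if (inherits(data, "band_data")) {
    if (data$bands != spec$s) {
      stop("band count of 'data' does not match spec$s", call. = FALSE)
    }
    cols <- patch_columns(spec, i, data$channels)
    data$x[, cols, drop = FALSE]
  } else {
    if (is.null(channels)) stop("'channels' required for vector input", call. = FALSE)
    y <- as.numeric(data)
    if (length(y) != channels * spec$s) {
      stop("sample length does not equal channels * s", call. = FALSE)
    }
    y[patch_columns(spec, i, channels)]
  }
}
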