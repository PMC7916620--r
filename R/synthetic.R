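#' Specification for the synthetic band-feature generator
#'
#' Describes a class-conditional Gaussian model for band-structured features
#' with per-band controllable discriminability. For band `f` the `c` class
#' means form a regular simplex in channel space whose pairwise Euclidean
#' distance is `effects[f] * noise_sd * sqrt(channels)` — i.e. `effects[f]`
#' is the per-channel standardized separation (a Cohen's-d-like effect size)
#' between any two classes in that band. The simplex is realized along
#' random orthonormal channel directions (class mean `k` is
#' `effects[f] * noise_sd * sqrt(channels / 2) * q_k` with orthonormal
#' `q_k`), so class means are mutually equidistant but never antipodal.
#' `effects[f] = 0` makes band `f` carry no class information at all.
#' Channel noise is i.i.d. Gaussian with standard deviation `noise_sd`.
#'
#' @param channels,bands,n_classes dimensions of the generated samples.
#' @param n_train,n_val,n_test samples *per class* in each split (any may
#'   be 0).
#' @param effects nonnegative per-band effect sizes, length `bands`.
#' @param noise_sd channel noise standard deviation, `> 0`.
#' @param seed integer seed; the class means and all noise draws are fully
#'   determined by it.
#' @param band_names optional band names.
#'
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(channels = 8, bands = 5, n_classes = 4,
                       n_train = 100, n_val = 100, n_test = 200,
                       effects = rep(1, bands), noise_sd = 1, seed = 1,
                       band_names = NULL) {
  stopifnot(channels >= 1, bands >= 1, n_classes >= 1,
            n_train >= 0, n_val >= 0, n_test >= 0, noise_sd > 0)
  effects <- as.numeric(effects)
  if (length(effects) != bands || !all(is.finite(effects)) || any(effects < 0)) {
    stop("'effects' must be a finite nonnegative vector of length 'bands'",
         call. = FALSE)
  }
  structure(list(channels = as.integer(channels), bands = as.integer(bands),
                 n_classes = as.integer(n_classes),
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), effects = effects,
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed),
                 band_names = band_names),
            class = "synth_spec")
}

# Class means for one band: vertices of a regular simplex with pairwise
# distance `dist`, embedded along random orthonormal directions in channel
# space (uncentred, so no two class means are ever antipodal — antipodal
# means are indistinguishable to a representation that is sign-invariant
# after column normalization, and real band features have a common positive
# offset anyway). Uses the current RNG stream.
simplex_means <- function(n_classes, channels, dist) {
  if (dist == 0 || n_classes == 1L) {
    return(matrix(0, n_classes, channels))
  }
  V <- diag(n_classes) * dist / sqrt(2)  # pairwise distance exactly `dist`
  if (channels >= n_classes) {
    Q <- qr.Q(qr(matrix(stats::rnorm(channels * n_classes), channels, n_classes)))
    t(Q %*% t(V))                        # isometric embedding: distances exact
  } else {
    # fewer channels than classes: project; distances shrink but stay
    # proportional to `dist`
    Q <- qr.Q(qr(matrix(stats::rnorm(n_classes * channels), n_classes, channels)))
    V %*% Q
  }
}

#' Generate synthetic band-structured class-conditional features
#'
#' Draws train/validation/test splits from the Gaussian model of
#' [synth_spec()]. The class means are drawn once per seed and shared by the
#' three splits; the splits are disjoint draws. The whole output is a pure
#' function of the spec (same spec, same data).
#'
#' @param spec a [synth_spec].
#'
#' @return A list with labelled [band_data] elements `train`, `val`, `test`
#'   (empty splits are `NULL`), plus `means` (per-band class-mean matrices,
#'   `c x channels`) for use by oracles and audits.
#'
#' @examples
#' sim <- synth_bands(synth_spec(channels = 2, bands = 3, n_classes = 2,
#'                               n_train = 10, effects = c(0, 3, 0), seed = 42))
#' sim$train
#' @export
synth_bands <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  means <- lapply(seq_len(spec$bands), function(f) {
    simplex_means(spec$n_classes, spec$channels,
                  spec$effects[f] * spec$noise_sd * sqrt(spec$channels))
  })
  draw <- function(n_per_class) {
    if (n_per_class == 0L) return(NULL)
    lab <- rep(seq_len(spec$n_classes), each = n_per_class)
    n <- length(lab)
    x <- matrix(0, n, spec$channels * spec$bands)
    for (f in seq_len(spec$bands)) {
      cols <- seq.int((f - 1L) * spec$channels + 1L, f * spec$channels)
      x[, cols] <- means[[f]][lab, , drop = FALSE] +
        matrix(stats::rnorm(n * spec$channels, 0, spec$noise_sd), n)
    }
    band_data(x, labels = lab, channels = spec$channels, bands = spec$bands,
              band_names = spec$band_names, n_classes = spec$n_classes)
  }
  list(train = draw(spec$n_train), val = draw(spec$n_val),
       test = draw(spec$n_test), means = means)
}

#' Sample a synthetic decision matrix with prescribed column accuracies
#'
#' Entry `(p, j)` is `+1` with probability `a[j]`, independently — a direct
#' simulation of per-scale correctness indicators at known accuracies, handy
#' for exercising the weight learner in isolation.
#'
#' @param m number of validation samples (rows).
#' @param a per-scale accuracies in `[0, 1]`; its length sets the scale
#'   count.
#' @param seed integer seed.
#'
#' @return An `m x length(a)` matrix with entries in `{-1, +1}`.
#' @export
make_decision_fixture <- function(m, a, seed = 1) {
  a <- as.numeric(a)
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1)) {
    stop("'a' must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(m >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  D <- vapply(a, function(aj) ifelse(stats::runif(m) < aj, 1, -1), numeric(m))
  if (m == 1L) D <- matrix(D, nrow = 1)
  D
}
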