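#' Write band-structured features to CSV with a JSON shape descriptor
#'
#' One row per sample; feature columns are named `<band>_<channel>` in
#' band-major order, followed by a `label` column when labels are present.
#' The shape descriptor (channels, bands, band_names, n_classes) goes to a
#' JSON sidecar so the table can be re-read without guessing the layout.
#'
#' @param data a [band_data] object.
#' @param file path of the CSV to write.
#' @param descriptor path of the JSON sidecar; default `<file>.json` next to
#'   the CSV, `NULL` to skip.
#' @return `file`, invisibly.
#' @export
write_band_csv <- function(data, file, descriptor = paste0(file, ".json")) {
  stopifnot(inherits(data, "band_data"))
  # %.17g guarantees doubles survive the text round trip bit-exactly
  df <- as.data.frame(lapply(seq_len(ncol(data$x)),
                             function(j) sprintf("%.17g", data$x[, j])))
  names(df) <- paste(rep(data$band_names, each = data$channels),
                     rep(seq_len(data$channels), data$bands), sep = "_")
  if (!is.null(data$labels)) df$label <- data$labels
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  if (!is.null(descriptor)) {
    jsonlite::write_json(
      list(channels = data$channels, bands = data$bands,
           band_names = data$band_names, n_classes = data$n_classes),
      descriptor, auto_unbox = TRUE)
  }
  invisible(file)
}

#' Read band-structured features from CSV
#'
#' @param file CSV written by [write_band_csv()] (or any delimited table
#'   with `channels * bands` feature columns in band-major order and an
#'   optional `label` column).
#' @param descriptor path of the JSON shape descriptor; default
#'   `<file>.json`. Alternatively pass `channels`/`bands` directly.
#' @param channels,bands shape, used when no descriptor file exists.
#' @return A [band_data] object.
#' @export
read_band_csv <- function(file, descriptor = paste0(file, ".json"),
                          channels = NULL, bands = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  band_names <- NULL
  n_classes <- NULL
  if (!is.null(descriptor) && file.exists(descriptor)) {
    d <- jsonlite::read_json(descriptor, simplifyVector = TRUE)
    channels <- d$channels
    bands <- d$bands
    band_names <- d$band_names
    n_classes <- d$n_classes
  }
  if (is.null(channels) || is.null(bands)) {
    stop("no shape descriptor found; supply 'channels' and 'bands'",
         call. = FALSE)
  }
  band_data(as.matrix(df), labels = labels, channels = channels,
            bands = bands, band_names = band_names, n_classes = n_classes)
}

#' Save a fitted multi-scale ensemble as plain-text files
#'
#' Writes a JSON manifest (shape, configuration, learned weights) and one
#' CSV per patch dictionary under `dir`, so a model round-trips through
#' version-controllable text.
#'
#' @param model a fitted [msfbel] model.
#' @param dir directory to create/fill.
#' @return `dir`, invisibly.
#' @export
write_msfbel <- function(model, dir) {
  stopifnot(inherits(model, "msfbel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    channels = model$channels, bands = model$bands,
    band_names = model$band_names, n_classes = model$n_classes,
    cfg = unclass(model$cfg), solver = unclass(model$solver),
    split = model$split, refit = model$refit, seed = model$seed,
    weights = model$weights$w,
    weights_converged = model$weights$converged,
    scale_val_accuracy = as.numeric(model$scale_val_accuracy)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(model$D), file.path(dir, "decision_matrix.csv"),
                   row.names = FALSE)
  for (m in model$scale_models) {
    j <- m$spec$j
    for (i in seq_len(m$spec$p)) {
      d <- m$dictionaries[[i]]
      df <- as.data.frame(lapply(seq_len(nrow(d$X)),
                                 function(r) sprintf("%.17g", d$X[r, ])))
      names(df) <- paste0("f", seq_len(nrow(d$X)))
      df$class <- d$class_of
      utils::write.csv(df, file.path(dir, sprintf("dict_s%d_p%d.csv", j, i)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Load a multi-scale ensemble saved by [write_msfbel()]
#'
#' @param dir model directory.
#' @return An object of class `msfbel`.
#' @export
read_msfbel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- crc_config(manifest$cfg$lambda, manifest$cfg$normalize_columns,
                    manifest$cfg$normalize_residual)
  solver_args <- Filter(function(x) length(x) > 0, manifest$solver)  # JSON null -> list()
  solver <- do.call(solver_config, solver_args)
  scales <- make_scales(manifest$bands)
  scale_models <- lapply(scales, function(sp) {
    dictionaries <- lapply(seq_len(sp$p), function(i) {
      df <- utils::read.csv(file.path(dir, sprintf("dict_s%d_p%d.csv", sp$j, i)))
      cls <- df$class
      df$class <- NULL
      patch_dictionary(t(as.matrix(df)), cls, manifest$n_classes)
    })
    structure(list(spec = sp, dictionaries = dictionaries, cfg = cfg,
                   channels = manifest$channels,
                   n_classes = manifest$n_classes),
              class = "scale_model")
  })
  D <- as.matrix(utils::read.csv(file.path(dir, "decision_matrix.csv")))
  dimnames(D) <- NULL
  weights <- structure(list(w = manifest$weights, trace = numeric(0),
                            iterations = NA_integer_,
                            converged = manifest$weights_converged),
                       class = "ensemble_weights")
  structure(
    list(scale_models = scale_models, weights = weights, D = D,
         scale_val_accuracy = manifest$scale_val_accuracy,
         channels = manifest$channels, bands = manifest$bands,
         band_names = manifest$band_names, n_classes = manifest$n_classes,
         cfg = cfg, solver = solver, split = manifest$split,
         refit = manifest$refit, seed = manifest$seed,
         call = quote(read_msfbel(dir))),
    class = "msfbel"
  )
}
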