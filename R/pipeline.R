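# End-to-end pipeline fit on a fixed training set (no cross-validation):
# multiview selection, network training, and a text archive so a fitted
# pipeline can be reloaded for prediction.

#' Fit the full multiview pipeline on a training dataset
#'
#' Runs per-view selection, reduces the views, and trains the fusion network
#' on all supplied rows (optionally holding out a validation fraction for
#' checkpointing).
#'
#' @param data An `mv_dataset` (training rows).
#' @param config Run configuration (see [default_config()]).
#' @param seed Master seed; overrides `config$cv$seed` when given.
#' @param val_fraction Fraction of rows held out for validation
#'   checkpointing (default 0: train on everything, keep the final state).
#' @return List of class `mv_pipeline`: `selection`, `fit`, `config`.
#' @export
fit_pipeline <- function(data, config = default_config(), seed = NULL,
                         val_fraction = 0) {
  stopifnot(inherits(data, "mv_dataset"))
  config <- merge_config(default_config(), config)
  if (!is.null(seed)) config$cv$seed <- as.integer(seed)
  master <- config$cv$seed
  N <- length(data$subject_ids)
  set.seed(master + 7L)
  val_rows <- integer(0)
  if (val_fraction > 0) {
    val_rows <- sample.int(N, max(1L, round(val_fraction * N)))
  }
  train_rows <- setdiff(seq_len(N), val_rows)
  train <- subset_mv(data, train_rows)
  sel <- run_per_view_selection(train, a1 = config$selection$a1,
                                lam = config$selection$lambda,
                                standardize = config$selection$standardize,
                                max_iter = config$selection$max_iter,
                                tol = config$selection$tol)
  tr <- apply_selection(sel, train)
  va <- if (length(val_rows) > 0L) apply_selection(sel, subset_mv(data, val_rows))
  spec <- encoder_spec(layer_widths = config$encoder$widths,
                       activation = config$encoder$activation,
                       pretrain = config$encoder$pretrain,
                       pretrain_epochs = config$encoder$pretrain_epochs,
                       pretrain_lr = config$encoder$pretrain_lr)
  widths <- vapply(tr$views, ncol, integer(1L))
  net <- mvnet_init(widths, spec, K = config$fusion$K,
                    position = config$fusion$position,
                    mode = config$fusion$mode, seed = master,
                    pretrain_data = tr$views)
  fit <- mvnet_train(net, tr$views, tr$labels,
                     train_config(epochs = config$train$epochs,
                                  batch_size = config$train$batch_size,
                                  learning_rate = config$train$learning_rate,
                                  seed = master),
                     loss_config(gamma = config$loss$gamma,
                                 margin = config$loss$margin,
                                 lambda1 = config$loss$lambda1,
                                 lambda2 = config$loss$lambda2),
                     val_views = if (is.null(va)) NULL else va$views,
                     val_labels = if (is.null(va)) NULL else va$labels)
  structure(list(selection = sel, fit = fit, config = config),
            class = "mv_pipeline")
}

#' Predict with a fitted pipeline
#'
#' @param pipeline An `mv_pipeline`.
#' @param data An `mv_dataset` with the same views (full-width features; the
#'   stored selection is applied internally).
#' @return Data frame from [mvnet_predict()] with a `subject_id` column.
#' @export
predict_pipeline <- function(pipeline, data) {
  stopifnot(inherits(pipeline, "mv_pipeline"))
  reduced <- apply_selection(pipeline$selection, data)
  out <- mvnet_predict(pipeline$fit, reduced$views)
  cbind(data.frame(subject_id = data$subject_ids), out)
}

#' Save a fitted pipeline as a text archive
#'
#' The archive is R source text (deparsed object with full double precision)
#' wrapped with a format-version field.
#'
#' @param pipeline An `mv_pipeline`.
#' @param path Output path.
#' @export
save_pipeline <- function(pipeline, path) {
  stopifnot(inherits(pipeline, "mv_pipeline"))
  obj <- list(format_version = 1L, pipeline = pipeline)
  dput(obj, file = path, control = c("all", "digits17"))
  invisible(path)
}

#' Load a pipeline archive written by [save_pipeline()]
#'
#' @param path Input path.
#' @return An `mv_pipeline`.
#' @export
load_pipeline <- function(path) {
  obj <- dget(path)
  if (!identical(obj$format_version, 1L)) {
    stop("unsupported pipeline archive version")
  }
  obj$pipeline
}
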