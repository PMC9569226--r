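# Per-view stacked autoencoder: tanh MLP encoder whose layers can be
# pretrained greedily to reconstruct their inputs before the supervised
# fine-tuning performed by the full training loop.

#' Encoder architecture specification
#'
#' @param layer_widths Integer vector of hidden-layer widths, outermost first.
#'   Default `c(1000, 100, 100)`: a wide first hidden layer followed by two
#'   100-unit layers.
#' @param activation Nonlinearity, currently `"tanh"` (bounded activations
#'   suit the correlation-based fusion regularizer) or `"linear"`.
#' @param pretrain Whether layers are pretrained by reconstruction
#'   (default `TRUE`).
#' @param pretrain_epochs Epochs of per-layer reconstruction training
#'   (default 50).
#' @param pretrain_lr Learning rate for pretraining (default 1e-3).
#' @return List of class `encoder_spec`.
#' @export
encoder_spec <- function(layer_widths = c(1000L, 100L, 100L),
                         activation = c("tanh", "linear"),
                         pretrain = TRUE, pretrain_epochs = 50L,
                         pretrain_lr = 1e-3) {
  activation <- match.arg(activation)
  layer_widths <- as.integer(layer_widths)
  if (length(layer_widths) < 1L || any(layer_widths < 1L)) {
    stop("need at least one hidden layer with positive width")
  }
  structure(list(layer_widths = layer_widths, activation = activation,
                 pretrain = pretrain, pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_lr = pretrain_lr),
            class = "encoder_spec")
}

act_fun <- function(name) {
  switch(name,
         tanh = tanh,
         linear = identity,
         stop("unknown activation: ", name))
}

act_deriv_from_out <- function(name, a) {
  # derivative expressed through the activation output (cheap for tanh)
  switch(name,
         tanh = 1 - a^2,
         linear = array(1, dim = dim(a)),
         stop("unknown activation: ", name))
}

# fan-in-scaled uniform init, seeded by the caller's RNG state
init_layer <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in),
       b = numeric(n_out))
}

#' Initialize an encoder stack for one view
#'
#' Fan-in-scaled uniform initialization, reproducible from `seed`.
#'
#' @param n_in Input feature count of the view.
#' @param spec An [encoder_spec()].
#' @param seed Integer RNG seed.
#' @return List of class `encoder_state` with per-layer `W` (out x in) and
#'   `b`, plus the spec and seed.
#' @export
init_encoder <- function(n_in, spec, seed = 0L) {
  stopifnot(inherits(spec, "encoder_spec"))
  set.seed(seed)
  widths <- c(n_in, spec$layer_widths)
  layers <- lapply(seq_along(spec$layer_widths), function(l) {
    init_layer(widths[l], widths[l + 1L])
  })
  structure(list(layers = layers, spec = spec, seed = as.integer(seed)),
            class = "encoder_state")
}

# one affine+activation forward step; X is batch x in, returns batch x out
layer_forward <- function(X, layer, activation) {
  act_fun(activation)(X %*% t(layer$W) + rep(layer$b, each = nrow(X)))
}

#' Greedy layer-wise reconstruction pretraining
#'
#' Each hidden layer is trained as a single-layer autoencoder on the output
#' of the previous layer: encoder `a = act(W x + b)`, linear decoder
#' `x_hat = W' a + b'`, mean-squared reconstruction error minimized by Adam
#' for `pretrain_epochs` full-batch steps. With `spec$pretrain = FALSE` the
#' seeded random initialization is returned untouched.
#'
#' @param X_view Training feature matrix of the view (subjects x features).
#' @param spec An [encoder_spec()].
#' @param seed Integer RNG seed (controls initialization).
#' @return An `encoder_state` with a `pretrain_trace` attribute (per-layer
#'   reconstruction-error traces) when pretraining ran.
#' @export
pretrain_layerwise <- function(X_view, spec, seed = 0L) {
  state <- init_encoder(ncol(X_view), spec, seed)
  if (!spec$pretrain) return(state)
  A <- as.matrix(X_view)
  traces <- list()
  for (l in seq_along(state$layers)) {
    enc <- state$layers[[l]]
    dec <- init_layer(nrow(enc$W), ncol(enc$W))
    opt_enc <- adam_init(enc)
    opt_dec <- adam_init(dec)
    trace <- numeric(spec$pretrain_epochs + 1L)
    B <- nrow(A)
    for (ep in seq_len(spec$pretrain_epochs + 1L)) {
      H <- layer_forward(A, enc, spec$activation)
      Xhat <- H %*% t(dec$W) + rep(dec$b, each = B)
      R <- Xhat - A
      loss <- mean(R^2)
      if (!is.finite(loss)) {
        stop("pretraining diverged at layer ", l, " (non-finite loss)")
      }
      trace[ep] <- loss
      if (ep > spec$pretrain_epochs) break
      dXhat <- 2 * R / length(R)
      g_dec <- list(W = crossprod(dXhat, H), b = colSums(dXhat))
      dH <- dXhat %*% dec$W
      dZ <- dH * act_deriv_from_out(spec$activation, H)
      g_enc <- list(W = crossprod(dZ, A), b = colSums(dZ))
      upd <- adam_update(enc, g_enc, opt_enc, spec$pretrain_lr)
      enc <- upd$par; opt_enc <- upd$opt
      upd <- adam_update(dec, g_dec, opt_dec, spec$pretrain_lr)
      dec <- upd$par; opt_dec <- upd$opt
    }
    state$layers[[l]] <- enc
    traces[[l]] <- trace
    A <- layer_forward(A, enc, spec$activation)
  }
  attr(state, "pretrain_trace") <- traces
  state
}

#' Forward pass through the first layers of an encoder
#'
#' Deterministic given `(state, X)`.
#'
#' @param state An `encoder_state`.
#' @param X Feature matrix (batch x view width).
#' @param upto_layer Number of hidden layers to apply (default: full depth).
#' @return Matrix of encoded features, `batch x layer_widths[upto_layer]`.
#' @export
encode_features <- function(state, X, upto_layer = length(state$layers)) {
  stopifnot(inherits(state, "encoder_state"))
  if (upto_layer < 1L || upto_layer > length(state$layers)) {
    stop("upto_layer must be in 1..", length(state$layers))
  }
  X <- as.matrix(X)
  if (ncol(X) != ncol(state$layers[[1L]]$W)) {
    stop("input width ", ncol(X), " != encoder input width ",
         ncol(state$layers[[1L]]$W))
  }
  A <- X
  for (l in seq_len(upto_layer)) {
    A <- layer_forward(A, state$layers[[l]], state$spec$activation)
  }
  A
}

# ---- Adam optimizer on a named list of arrays (W, b, ...) -----------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(par, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(par, grad, opt, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (k in names(par)) {
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * grad[[k]]
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * grad[[k]]^2
    mhat <- opt$m[[k]] / (1 - beta1^opt$t)
    vhat <- opt$v[[k]] / (1 - beta2^opt$t)
    step <- lr * mhat / (sqrt(vhat) + eps)
    par[[k]] <- par[[k]] - array(step, dim = dim(par[[k]]) %||% length(par[[k]]))
  }
  list(par = par, opt = opt)
}

#' Save encoder parameters to a versioned text archive
#'
#' One JSON file per view holding layer shapes and flattened parameters.
#'
#' @param state An `encoder_state`.
#' @param path Output path.
#' @export
save_encoder <- function(state, path) {
  obj <- list(
    format_version = 1L,
    activation = state$spec$activation,
    layer_widths = state$spec$layer_widths,
    seed = state$seed,
    layers = lapply(state$layers, function(l) {
      list(dim = dim(l$W), W = as.numeric(l$W), b = as.numeric(l$b))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an encoder archive written by [save_encoder()]
#'
#' @param path Input path.
#' @return An `encoder_state`.
#' @export
load_encoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported encoder archive version")
  }
  spec <- encoder_spec(layer_widths = obj$layer_widths,
                       activation = obj$activation, pretrain = FALSE)
  layers <- lapply(seq_along(obj$layers$dim), function(i) {
    d <- obj$layers$dim[[i]]
    list(W = matrix(obj$layers$W[[i]], d[1L], d[2L]),
         b = as.numeric(obj$layers$b[[i]]))
  })
  structure(list(layers = layers, spec = spec, seed = as.integer(obj$seed)),
            class = "encoder_state")
}
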