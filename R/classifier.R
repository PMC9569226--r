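# Prototype-based classification head and the full multiview network:
# per-view tanh encoders -> linear per-view transforms + additive fusion
# (optionally followed by shared layers) -> prototype space. Training
# minimizes  L = L_DCE + lambda1 * L_MP - lambda2 * L_MV  by Adam, with
# analytically derived gradients (verified against finite differences in the
# test suite).

#' Class prototypes as feature-space class means
#'
#' `p_c = (1/N_c) sum over class-c instances of g(x_i)`.
#'
#' @param G Matrix of extracted features (instances x width).
#' @param labels Factor of class labels aligned with the rows of `G`.
#' @return `C x width` matrix of prototypes, rownames = class levels.
#' @export
init_prototypes <- function(G, labels) {
  labels <- as.factor(labels)
  G <- as.matrix(G)
  counts <- table(labels)
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0L) {
    stop("class(es) with no training instances: ", paste(empty, collapse = ", "))
  }
  P <- t(vapply(levels(labels), function(cl) {
    colMeans(G[labels == cl, , drop = FALSE])
  }, numeric(ncol(G))))
  rownames(P) <- levels(labels)
  P
}

#' Squared Euclidean distances to the prototypes
#'
#' `d_c = || g(x) - p_c ||^2` for every class c, for every row of `G`.
#'
#' @param G Feature matrix (instances x width).
#' @param prototypes `C x width` prototype matrix.
#' @return `instances x C` matrix of nonnegative squared distances.
#' @export
proto_distances <- function(G, prototypes) {
  G <- as.matrix(G)
  if (ncol(G) != ncol(prototypes)) stop("feature width != prototype width")
  g2 <- rowSums(G^2)
  p2 <- rowSums(prototypes^2)
  d <- outer(g2, p2, "+") - 2 * G %*% t(prototypes)
  d[d < 0] <- 0
  colnames(d) <- rownames(prototypes)
  d
}

#' Class probabilities from prototype distances
#'
#' `P(c | x) = exp(-gamma d_c) / sum_c' exp(-gamma d_c')`, computed with a
#' max-shift for numerical stability. `gamma = 0` gives the uniform 1/C.
#'
#' @param d Distance matrix (instances x C) or vector (one instance).
#' @param gamma Nonnegative scale.
#' @return Probability matrix of the same shape; rows sum to 1.
#' @export
class_prob <- function(d, gamma) {
  if (gamma < 0) stop("gamma must be >= 0")
  vec <- is.null(dim(d))
  d <- if (vec) matrix(d, nrow = 1L) else as.matrix(d)
  s <- -gamma * d
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  p <- e / rowSums(e)
  if (vec) drop(p) else p
}

#' Distance-based cross-entropy loss
#'
#' `-log P(y | x)`, averaged over instances; probabilities are clamped at
#' 1e-12 before the log.
#'
#' @param p_true Probabilities of the true class, in (0, 1].
#' @return Mean negative log probability.
#' @export
dce_loss <- function(p_true) {
  if (any(p_true <= 0)) {
    warning("probability <= 0 clamped at 1e-12")
  }
  mean(-log(pmax(p_true, 1e-12)))
}

#' Margin-based prototype loss
#'
#' `max(0, d_y - d_r + m)` where `d_y` is the distance to the true-class
#' prototype and `d_r` the minimum distance over the other classes; zero when
#' the true class wins by at least the margin.
#'
#' @param d_y,d_r Nonnegative distances (vectorized).
#' @param m Margin, `m >= 0`.
#' @return Elementwise hinge values.
#' @export
mp_loss <- function(d_y, d_r, m) {
  if (m < 0) stop("margin must be >= 0")
  pmax(0, d_y - d_r + m)
}

#' Loss configuration
#'
#' @param gamma Distance-to-probability scale (default 1).
#' @param margin Prototype margin m (default 1).
#' @param lambda1 Weight of the margin-prototype loss (default 0.5).
#' @param lambda2 Weight of the multiview alignment reward (default 0.1).
#' @return List of class `loss_config`.
#' @export
loss_config <- function(gamma = 1.0, margin = 1.0, lambda1 = 0.5,
                        lambda2 = 0.1) {
  if (gamma < 0 || margin < 0 || lambda1 < 0 || lambda2 < 0) {
    stop("loss_config parameters must be nonnegative")
  }
  structure(list(gamma = gamma, margin = margin, lambda1 = lambda1,
                 lambda2 = lambda2), class = "loss_config")
}

# ---- network container ----------------------------------------------------

#' Initialize the multiview network
#'
#' Per-view encoder stacks up to `position` hidden layers, per-view linear
#' fusion transforms into a K-dimensional space (or concatenation in
#' `"concat"` mode), and shared tanh layers after the fusion point when
#' `position < depth`. Widths after the fusion point follow the encoder spec.
#'
#' @param input_widths Named integer vector: selected-feature count per view.
#' @param spec An [encoder_spec()] (depth = `length(spec$layer_widths)`).
#' @param K Fused feature count (default 100). Ignored in concat mode.
#' @param position Hidden-layer index at which fusion occurs
#'   (default: full depth).
#' @param mode `"fuse"` (additive, NCC-regularized) or `"concat"` baseline.
#' @param seed Integer seed for all parameter initialization.
#' @param pretrain_data Optional named list of per-view training matrices;
#'   when given and `spec$pretrain` is `TRUE`, encoder stacks are pretrained
#'   layer-wise on it.
#' @return List of class `mvnet`.
#' @export
mvnet_init <- function(input_widths, spec, K = 100L,
                       position = length(spec$layer_widths),
                       mode = c("fuse", "concat"), seed = 0L,
                       pretrain_data = NULL) {
  mode <- match.arg(mode)
  depth <- length(spec$layer_widths)
  if (position < 1L || position > depth) stop("position must be in 1..", depth)
  V <- length(input_widths)
  if (is.null(names(input_widths))) {
    names(input_widths) <- paste0("view", seq_len(V))
  }
  pre_spec <- encoder_spec(spec$layer_widths[seq_len(position)],
                           activation = spec$activation,
                           pretrain = spec$pretrain,
                           pretrain_epochs = spec$pretrain_epochs,
                           pretrain_lr = spec$pretrain_lr)
  encoders <- list()
  for (v in seq_len(V)) {
    vn <- names(input_widths)[v]
    sd_v <- seed + 1000L * v
    if (!is.null(pretrain_data) && spec$pretrain) {
      encoders[[vn]] <- pretrain_layerwise(pretrain_data[[vn]], pre_spec, sd_v)
    } else {
      encoders[[vn]] <- init_encoder(input_widths[[v]], pre_spec, sd_v)
    }
  }
  d_pos <- spec$layer_widths[position]
  set.seed(seed + 777L)
  if (mode == "fuse") {
    fusion_W <- stats::setNames(lapply(seq_len(V), function(v) {
      init_layer(d_pos, K)$W
    }), names(input_widths))
    post_in <- K
  } else {
    fusion_W <- NULL
    post_in <- d_pos * V
  }
  shared <- list()
  if (position < depth) {
    widths <- c(post_in, spec$layer_widths[(position + 1L):depth])
    shared <- lapply(seq_len(depth - position), function(l) {
      init_layer(widths[l], widths[l + 1L])
    })
  }
  structure(
    list(encoders = encoders, fusion_W = fusion_W, shared = shared,
         mode = mode, position = position, K = as.integer(K), spec = spec,
         input_widths = input_widths, seed = as.integer(seed)),
    class = "mvnet")
}

#' Forward pass of the multiview network
#'
#' @param net An `mvnet`.
#' @param X_views Named list of per-view batch matrices.
#' @param keep_intermediate Return layer activations for backprop.
#' @return List with `g` (final features, batch x width), `u_per_view`
#'   (fuse mode), `z`, and with `keep_intermediate` the per-layer
#'   activations.
#' @export
mvnet_forward <- function(net, X_views, keep_intermediate = FALSE) {
  act <- net$spec$activation
  acts <- list()
  v_out <- list()
  for (vn in names(net$encoders)) {
    A <- as.matrix(X_views[[vn]])
    layer_acts <- vector("list", length(net$encoders[[vn]]$layers) + 1L)
    layer_acts[[1L]] <- A
    for (l in seq_along(net$encoders[[vn]]$layers)) {
      A <- layer_forward(A, net$encoders[[vn]]$layers[[l]], act)
      layer_acts[[l + 1L]] <- A
    }
    acts[[vn]] <- layer_acts
    v_out[[vn]] <- A
  }
  if (net$mode == "fuse") {
    u_per_view <- stats::setNames(lapply(names(v_out), function(vn) {
      view_transform(v_out[[vn]], net$fusion_W[[vn]])
    }), names(v_out))
    z <- fuse_views(u_per_view)
  } else {
    u_per_view <- NULL
    z <- concat_views(v_out)
  }
  shared_acts <- list(z)
  G <- z
  for (l in seq_along(net$shared)) {
    G <- layer_forward(G, net$shared[[l]], act)
    shared_acts[[l + 1L]] <- G
  }
  out <- list(g = G, u_per_view = u_per_view, z = z)
  if (keep_intermediate) {
    out$acts <- acts
    out$shared_acts <- shared_acts
  }
  out
}

# ---- loss + gradients -----------------------------------------------------

#' Total training loss and parameter gradients on a batch
#'
#' Computes `L = L_DCE + lambda1 * L_MP - lambda2 * L_MV` (each component
#' averaged over the batch) and its gradients with respect to every encoder,
#' fusion and shared-layer parameter. Prototypes are treated as constants.
#'
#' @param net An `mvnet`.
#' @param X_views Named list of per-view batch matrices.
#' @param y Integer class indices (1..C) for the batch.
#' @param prototypes `C x width` prototype matrix.
#' @param cfg A [loss_config()].
#' @return List: `loss`, `components` (dce, mp, mv), `grads` (mirroring the
#'   net's parameter structure).
#' @export
mvnet_loss <- function(net, X_views, y, prototypes, cfg) {
  fwd <- mvnet_forward(net, X_views, keep_intermediate = TRUE)
  G <- fwd$g
  B <- nrow(G)
  C <- nrow(prototypes)
  d <- proto_distances(G, prototypes)
  P <- class_prob(d, cfg$gamma)
  idx <- cbind(seq_len(B), y)
  p_true <- P[idx]
  l_dce <- dce_loss(p_true)

  d_y <- d[idx]
  d_other <- d
  d_other[idx] <- Inf
  r_idx <- max.col(-d_other, ties.method = "first")
  d_r <- d_other[cbind(seq_len(B), r_idx)]
  hinge <- mp_loss(d_y, d_r, cfg$margin)
  l_mp <- mean(hinge)

  # dL/dd (batch x C), both loss components, already including the 1/B mean
  dLdd <- cfg$gamma * ((idx_matrix(B, C, y)) - P) / B       # DCE
  active <- hinge > 0
  if (any(active)) {
    mp_dd <- matrix(0, B, C)
    mp_dd[cbind(which(active), y[active])] <- 1
    mp_dd[cbind(which(active), r_idx[active])] <-
      mp_dd[cbind(which(active), r_idx[active])] - 1
    dLdd <- dLdd + cfg$lambda1 * mp_dd / B
  }
  # d d_c / d g = 2 (g - p_c)  =>  dL/dG = 2 (G * rowSums(dLdd) - dLdd P)
  dG <- 2 * (G * rowSums(dLdd) - dLdd %*% prototypes)

  grads <- list(encoders = list(), fusion_W = NULL, shared = list())
  act <- net$spec$activation

  # back through shared layers
  delta_in <- dG
  if (length(net$shared) > 0L) {
    grads$shared <- vector("list", length(net$shared))
    for (l in rev(seq_along(net$shared))) {
      a_out <- fwd$shared_acts[[l + 1L]]
      a_in <- fwd$shared_acts[[l]]
      dZ <- delta_in * act_deriv_from_out(act, a_out)
      grads$shared[[l]] <- list(W = crossprod(dZ, a_in), b = colSums(dZ))
      delta_in <- dZ %*% net$shared[[l]]$W
    }
  }
  dz <- delta_in  # gradient at the fusion output z

  l_mv <- 0
  if (net$mode == "fuse") {
    u <- fwd$u_per_view
    V <- length(u)
    du <- lapply(u, function(m) matrix(0, nrow(m), ncol(m)))
    if (cfg$lambda2 > 0 && V >= 2L && net$K >= 2L) {
      for (v in seq_len(V - 1L)) {
        for (i in seq_len(B)) {
          ng <- ncc_with_grad(u[[v]][i, ], u[[v + 1L]][i, ])
          l_mv <- l_mv + ng$value / B
          # loss carries -lambda2 * L_MV
          du[[v]][i, ] <- du[[v]][i, ] - cfg$lambda2 * ng$g1 / B
          du[[v + 1L]][i, ] <- du[[v + 1L]][i, ] - cfg$lambda2 * ng$g2 / B
        }
      }
    } else if (V >= 2L && net$K >= 2L) {
      l_mv <- mv_regularizer(u)
    }
    vns <- names(net$encoders)
    grads$fusion_W <- stats::setNames(vector("list", V), vns)
    delta_v <- list()
    for (v in seq_len(V)) {
      vn <- vns[v]
      dUv <- dz + du[[v]]
      v_feat <- fwd$acts[[vn]][[length(fwd$acts[[vn]])]]
      grads$fusion_W[[vn]] <- crossprod(dUv, v_feat)
      delta_v[[vn]] <- dUv %*% net$fusion_W[[vn]]
    }
  } else {
    # concat: split dz by view widths
    vns <- names(net$encoders)
    widths <- vapply(vns, function(vn) {
      ncol(fwd$acts[[vn]][[length(fwd$acts[[vn]])]])
    }, integer(1L))
    ends <- cumsum(widths)
    starts <- ends - widths + 1L
    delta_v <- stats::setNames(lapply(seq_along(vns), function(v) {
      dz[, starts[v]:ends[v], drop = FALSE]
    }), vns)
  }

  # back through per-view encoders
  for (vn in names(net$encoders)) {
    layers <- net$encoders[[vn]]$layers
    gl <- vector("list", length(layers))
    delta <- delta_v[[vn]]
    for (l in rev(seq_along(layers))) {
      a_out <- fwd$acts[[vn]][[l + 1L]]
      a_in <- fwd$acts[[vn]][[l]]
      dZ <- delta * act_deriv_from_out(act, a_out)
      gl[[l]] <- list(W = crossprod(dZ, a_in), b = colSums(dZ))
      delta <- dZ %*% layers[[l]]$W
    }
    grads$encoders[[vn]] <- gl
  }

  loss <- l_dce + cfg$lambda1 * l_mp - cfg$lambda2 * l_mv
  if (!is.finite(loss)) {
    stop("non-finite loss (dce=", l_dce, ", mp=", l_mp, ", mv=", l_mv, ")")
  }
  list(loss = loss,
       components = c(dce = l_dce, mp = l_mp, mv = l_mv),
       grads = grads)
}

idx_matrix <- function(B, C, y) {
  m <- matrix(0, B, C)
  m[cbind(seq_len(B), y)] <- 1
  m
}

#' Training configuration
#'
#' @param epochs Number of epochs (default 300).
#' @param batch_size Minibatch size (default 96).
#' @param learning_rate Adam step size (default 1e-4).
#' @param seed Master seed for initialization and shuffling (default 0).
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 96L,
                         learning_rate = 1e-4, seed = 0L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

# flatten/unflatten all trainable parameters; used by Adam and by the
# finite-difference checks in the tests
mvnet_get_params <- function(net) {
  pars <- list()
  for (vn in names(net$encoders)) {
    for (l in seq_along(net$encoders[[vn]]$layers)) {
      pars[[paste0("enc.", vn, ".", l, ".W")]] <- net$encoders[[vn]]$layers[[l]]$W
      pars[[paste0("enc.", vn, ".", l, ".b")]] <- net$encoders[[vn]]$layers[[l]]$b
    }
  }
  if (net$mode == "fuse") {
    for (vn in names(net$fusion_W)) {
      pars[[paste0("fus.", vn)]] <- net$fusion_W[[vn]]
    }
  }
  for (l in seq_along(net$shared)) {
    pars[[paste0("shared.", l, ".W")]] <- net$shared[[l]]$W
    pars[[paste0("shared.", l, ".b")]] <- net$shared[[l]]$b
  }
  pars
}

mvnet_set_params <- function(net, pars) {
  for (vn in names(net$encoders)) {
    for (l in seq_along(net$encoders[[vn]]$layers)) {
      net$encoders[[vn]]$layers[[l]]$W <- pars[[paste0("enc.", vn, ".", l, ".W")]]
      net$encoders[[vn]]$layers[[l]]$b <- pars[[paste0("enc.", vn, ".", l, ".b")]]
    }
  }
  if (net$mode == "fuse") {
    for (vn in names(net$fusion_W)) {
      net$fusion_W[[vn]] <- pars[[paste0("fus.", vn)]]
    }
  }
  for (l in seq_along(net$shared)) {
    net$shared[[l]]$W <- pars[[paste0("shared.", l, ".W")]]
    net$shared[[l]]$b <- pars[[paste0("shared.", l, ".b")]]
  }
  net
}

mvnet_grads_flat <- function(net, grads) {
  pars <- list()
  for (vn in names(net$encoders)) {
    for (l in seq_along(net$encoders[[vn]]$layers)) {
      pars[[paste0("enc.", vn, ".", l, ".W")]] <- grads$encoders[[vn]][[l]]$W
      pars[[paste0("enc.", vn, ".", l, ".b")]] <- grads$encoders[[vn]][[l]]$b
    }
  }
  if (net$mode == "fuse") {
    for (vn in names(net$fusion_W)) {
      pars[[paste0("fus.", vn)]] <- grads$fusion_W[[vn]]
    }
  }
  for (l in seq_along(net$shared)) {
    pars[[paste0("shared.", l, ".W")]] <- grads$shared[[l]]$W
    pars[[paste0("shared.", l, ".b")]] <- grads$shared[[l]]$b
  }
  pars
}

#' Train the multiview network
#'
#' Adam minimization of the total loss. Prototypes are recomputed as class
#' means of the current features over the full training set at the start of
#' every epoch and held constant within the epoch. When validation data is
#' supplied, the state with the best validation accuracy is retained.
#' Deterministic given the seed.
#'
#' @param net An `mvnet` (fresh from [mvnet_init()] or pre-trained).
#' @param X_views Named list of per-view training matrices.
#' @param labels Training labels (factor).
#' @param cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param val_views,val_labels Optional validation split for checkpointing.
#' @return List of class `mvnet_fit`: `net` (best state), `prototypes`,
#'   `class_levels`, `history` (data frame with per-epoch losses and
#'   accuracies), `loss_cfg`.
#' @export
mvnet_train <- function(net, X_views, labels, cfg = train_config(),
                        loss_cfg = loss_config(),
                        val_views = NULL, val_labels = NULL) {
  labels <- as.factor(labels)
  lv <- levels(labels)
  y <- as.integer(labels)
  N <- length(y)
  pars <- mvnet_get_params(net)
  opt <- adam_init(pars)
  set.seed(cfg$seed + 31L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0))
  prototypes <- init_prototypes(mvnet_forward(net, X_views)$g, labels)
  best <- list(net = net, prototypes = prototypes, val_acc = -Inf, epoch = 0L)
  if (!is.null(val_views)) {
    best$val_acc <- proto_accuracy(net, prototypes, val_views,
                                   as.integer(factor(val_labels, levels = lv)))
  }
  if (cfg$epochs == 0L) {
    return(structure(list(net = net, prototypes = prototypes,
                          class_levels = lv, history = history,
                          loss_cfg = loss_cfg, train_cfg = cfg),
                     class = "mvnet_fit"))
  }
  for (ep in seq_len(cfg$epochs)) {
    prototypes <- init_prototypes(mvnet_forward(net, X_views)$g, labels)
    ord <- sample.int(N)
    epoch_loss <- 0
    nb <- 0L
    for (start in seq(1L, N, by = cfg$batch_size)) {
      rows <- ord[start:min(start + cfg$batch_size - 1L, N)]
      bx <- lapply(X_views, function(m) m[rows, , drop = FALSE])
      res <- mvnet_loss(net, bx, y[rows], prototypes, loss_cfg)
      g <- mvnet_grads_flat(net, res$grads)
      upd <- adam_update(pars, g, opt, cfg$learning_rate)
      pars <- upd$par
      opt <- upd$opt
      net <- mvnet_set_params(net, pars)
      epoch_loss <- epoch_loss + res$loss
      nb <- nb + 1L
    }
    prototypes_eval <- init_prototypes(mvnet_forward(net, X_views)$g, labels)
    tr_acc <- proto_accuracy(net, prototypes_eval, X_views, y)
    va_acc <- NA_real_
    if (!is.null(val_views)) {
      va_acc <- proto_accuracy(net, prototypes_eval, val_views,
                               as.integer(factor(val_labels, levels = lv)))
      if (va_acc > best$val_acc) {
        best <- list(net = net, prototypes = prototypes_eval,
                     val_acc = va_acc, epoch = ep)
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = epoch_loss / nb, train_acc = tr_acc,
      val_acc = va_acc))
  }
  if (is.null(val_views)) {
    best <- list(net = net,
                 prototypes = init_prototypes(mvnet_forward(net, X_views)$g,
                                              labels),
                 val_acc = NA_real_, epoch = cfg$epochs)
  }
  structure(list(net = best$net, prototypes = best$prototypes,
                 class_levels = lv, history = history, loss_cfg = loss_cfg,
                 train_cfg = cfg, best_epoch = best$epoch),
            class = "mvnet_fit")
}

proto_accuracy <- function(net, prototypes, X_views, y) {
  d <- proto_distances(mvnet_forward(net, X_views)$g, prototypes)
  pred <- apply(d, 1L, which.min)
  mean(pred == y)
}

#' Predict class labels and probabilities
#'
#' The predicted label is the class with the nearest prototype (equivalently
#' the highest probability); ties break toward the lower class index.
#'
#' @param fit An `mvnet_fit`.
#' @param X_views Named list of per-view feature matrices.
#' @return Data frame with `label` (factor in the training levels), the
#'   per-class probability columns, and `d_min`.
#' @export
mvnet_predict <- function(fit, X_views) {
  G <- mvnet_forward(fit$net, X_views)$g
  d <- proto_distances(G, fit$prototypes)
  P <- class_prob(d, fit$loss_cfg$gamma)
  pred <- apply(d, 1L, which.min)  # which.min takes the first (lowest) index
  out <- data.frame(label = factor(fit$class_levels[pred],
                                   levels = fit$class_levels))
  probs <- as.data.frame(P)
  names(probs) <- paste0("p_", fit$class_levels)
  cbind(out, probs, d_min = d[cbind(seq_len(nrow(d)), pred)])
}
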