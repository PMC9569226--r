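test_that("prototypes are per-class feature means", {
  G <- rbind(c(0, 0), c(2, 4))
  y <- factor(c("a", "b"))
  P <- init_prototypes(G, y)
  expect_equal(P["a", ], c(0, 0), ignore_attr = TRUE)
  expect_equal(P["b", ], c(2, 4), ignore_attr = TRUE)
  G2 <- rbind(c(0, 0), c(2, 4))
  expect_equal(init_prototypes(G2, factor(c("a", "a")))["a", ], c(1, 2),
               ignore_attr = TRUE)

  set.seed(12)
  G3 <- matrix(rnorm(60), 30, 2)
  y3 <- factor(sample(c("x", "y"), 30, replace = TRUE))
  P3 <- init_prototypes(G3, y3)
  for (cl in levels(y3)) {
    rows <- which(y3 == cl)
    manual <- c(sum(G3[rows, 1]) / length(rows), sum(G3[rows, 2]) / length(rows))
    expect_equal(P3[cl, ], manual, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(init_prototypes(G3, factor(rep("x", 30), levels = c("x", "y"))),
               "no training instances.*y")
})

test_that("proto_distances is the squared Euclidean distance", {
  P <- rbind(p1 = c(3, 4), p2 = c(0, 0))
  d <- proto_distances(matrix(c(0, 0), 1, 2), P)
  expect_equal(unname(d[1, "p1"]), 25)
  expect_equal(unname(d[1, "p2"]), 0)
  set.seed(14)
  G <- matrix(rnorm(10), 5, 2)
  d2 <- proto_distances(G, P)
  for (i in 1:5) for (c in 1:2) {
    expect_equal(unname(d2[i, c]), sum((G[i, ] - P[c, ])^2),
                 tolerance = 1e-12)
  }
  expect_error(proto_distances(matrix(0, 1, 3), P), "width")
})

test_that("class probabilities are a stable softmax over negative scaled distances", {
  expect_equal(class_prob(c(1, 1), 2), c(0.5, 0.5))
  expect_equal(class_prob(c(0.3, 5, 7), 0), rep(1 / 3, 3))
  # frozen from a high-precision evaluation of 1/(1+exp(-1))
  expect_equal(class_prob(c(0, 1), 1),
               c(0.7310585786300049, 0.2689414213699951), tolerance = 1e-12)
  # max-shift keeps huge distances finite
  p <- class_prob(c(0, 2000), 1)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1)
  set.seed(16)
  for (i in 1:50) {
    d <- runif(4, 0, 10)
    expect_equal(sum(class_prob(d, runif(1, 0.1, 5))), 1, tolerance = 1e-12)
  }
  expect_error(class_prob(c(1, 2), -1), "gamma")
})

test_that("dce_loss is the clamped negative log probability", {
  expect_equal(dce_loss(1), 0)
  expect_equal(dce_loss(0.5), log(2))
  expect_lt(dce_loss(0.9), dce_loss(0.1))
  expect_warning(v <- dce_loss(0), "clamped")
  expect_equal(v, -log(1e-12))
  expect_equal(dce_loss(c(1, 0.5)), log(2) / 2)  # batch mean
})

test_that("mp_loss reproduces the hinge branches", {
  expect_equal(mp_loss(0.2, 0.5, 0.1), 0)
  expect_equal(mp_loss(0.5, 0.2, 0.1), 0.4)
  expect_equal(mp_loss(0.3, 0.3, 0), 0)
  expect_equal(mp_loss(c(0.2, 0.5), c(0.5, 0.2), 0.1), c(0, 0.4))
  expect_error(mp_loss(1, 1, -0.1), "margin")
})

test_that("total loss reduces to DCE at lambda1 = lambda2 = 0 and matches components", {
  gen <- make_tiny_mv()
  net <- make_tiny_net(gen)
  rows <- mixed_rows(gen)
  Xv <- lapply(gen$data$views, function(m) m[rows, , drop = FALSE])
  y <- as.integer(gen$data$labels[rows])
  protos <- init_prototypes(mvnet_forward(net, Xv)$g, gen$data$labels[rows])

  res0 <- mvnet_loss(net, Xv, y, protos, loss_config(lambda1 = 0, lambda2 = 0))
  G <- mvnet_forward(net, Xv)$g
  d <- proto_distances(G, protos)
  P <- class_prob(d, 1)
  expect_equal(res0$loss, dce_loss(P[cbind(seq_along(y), y)]),
               tolerance = 1e-12)

  cfg <- loss_config(gamma = 1, margin = 1, lambda1 = 0.5, lambda2 = 0.1)
  res <- mvnet_loss(net, Xv, y, protos, cfg)
  # component-wise reconstruction from independent single-component calls
  d_y <- d[cbind(seq_along(y), y)]
  d_o <- d; d_o[cbind(seq_along(y), y)] <- Inf
  d_r <- apply(d_o, 1, min)
  l_mp <- mean(mp_loss(d_y, d_r, 1))
  u <- mvnet_forward(net, Xv)$u_per_view
  l_mv <- mv_regularizer(u)
  expect_equal(unname(res$components["mp"]), l_mp, tolerance = 1e-12)
  expect_equal(unname(res$components["mv"]), l_mv, tolerance = 1e-12)
  expect_equal(res$loss,
               unname(res$components["dce"]) + 0.5 * l_mp - 0.1 * l_mv,
               tolerance = 1e-12)
})

test_that("analytic gradients match central differences on a tiny network", {
  gen <- make_tiny_mv()
  net <- make_tiny_net(gen, widths = c(4L, 3L), K = 3L)
  rows <- mixed_rows(gen)
  Xv <- lapply(gen$data$views, function(m) m[rows, , drop = FALSE])
  y <- as.integer(gen$data$labels[rows])
  protos <- init_prototypes(mvnet_forward(net, Xv)$g, gen$data$labels[rows])
  cfg <- loss_config(gamma = 1, margin = 1, lambda1 = 0.5, lambda2 = 0.1)
  res <- mvnet_loss(net, Xv, y, protos, cfg)
  analytic <- mvfcc:::mvnet_grads_flat(net, res$grads)
  pars <- mvfcc:::mvnet_get_params(net)
  f <- function(p) {
    mvnet_loss(mvfcc:::mvnet_set_params(net, p), Xv, y, protos, cfg)$loss
  }
  numeric <- numeric_grad(f, pars)
  for (k in names(pars)) {
    checked <- which(!is.na(numeric[[k]]))
    expect_equal(unname(analytic[[k]][checked]),
                 unname(numeric[[k]][checked]), tolerance = 1e-4)
  }
})

test_that("gradients also match central differences with shared post-fusion layers and in concat mode", {
  gen <- make_tiny_mv()
  rows <- mixed_rows(gen)
  Xv <- lapply(gen$data$views, function(m) m[rows, , drop = FALSE])
  y <- as.integer(gen$data$labels[rows])
  spec <- encoder_spec(c(4L, 3L), pretrain = FALSE)
  w <- vapply(gen$data$views, ncol, integer(1L))
  cfg <- loss_config()
  for (mode in c("fuse", "concat")) {
    net <- mvnet_init(w, spec, K = 3L, position = 1L, mode = mode, seed = 5L)
    protos <- init_prototypes(mvnet_forward(net, Xv)$g, gen$data$labels[rows])
    res <- mvnet_loss(net, Xv, y, protos, cfg)
    analytic <- mvfcc:::mvnet_grads_flat(net, res$grads)
    pars <- mvfcc:::mvnet_get_params(net)
    f <- function(p) {
      mvnet_loss(mvfcc:::mvnet_set_params(net, p), Xv, y, protos, cfg)$loss
    }
    numeric <- numeric_grad(f, pars, max_per_block = 4L)
    for (k in names(pars)) {
      checked <- which(!is.na(numeric[[k]]))
      expect_equal(unname(analytic[[k]][checked]),
                   unname(numeric[[k]][checked]), tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic, returns unchanged state at 0 epochs, and separates an easy toy", {
  gen <- generate_multiview(synth_config(N = 120L, region_counts = c(6L, 5L),
                                         s = 4L, effect = 5, seed = 0L))
  spec <- encoder_spec(c(6L, 4L), pretrain = FALSE)
  widths <- vapply(gen$data$views, ncol, integer(1L))
  net <- mvnet_init(widths, spec, K = 4L, position = 2L, seed = 0L)

  fit0 <- mvnet_train(net, gen$data$views, gen$data$labels,
                      train_config(epochs = 0L), loss_config())
  expect_identical(fit0$net, net)
  expect_equal(nrow(fit0$history), 0L)

  tcfg <- train_config(epochs = 30L, batch_size = 96L, learning_rate = 0.01,
                       seed = 0L)
  fit1 <- mvnet_train(net, gen$data$views, gen$data$labels, tcfg, loss_config())
  fit2 <- mvnet_train(net, gen$data$views, gen$data$labels, tcfg, loss_config())
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$history$train_acc[nrow(fit1$history)], 1)
})

test_that("prototype recomputation is idempotent without parameter updates", {
  gen <- make_tiny_mv()
  net <- make_tiny_net(gen)
  G <- mvnet_forward(net, gen$data$views)$g
  p1 <- init_prototypes(G, gen$data$labels)
  p2 <- init_prototypes(mvnet_forward(net, gen$data$views)$g, gen$data$labels)
  expect_identical(p1, p2)
})

test_that("prediction takes the nearest prototype with lower-index tie-break", {
  gen <- make_tiny_mv()
  net <- make_tiny_net(gen)
  fit <- mvnet_train(net, gen$data$views, gen$data$labels,
                     train_config(epochs = 0L), loss_config())
  # instance whose features equal prototype 1 exactly: distance 0
  pred <- mvnet_predict(fit, gen$data$views)
  d <- proto_distances(mvnet_forward(fit$net, gen$data$views)$g, fit$prototypes)
  manual <- apply(d, 1, which.min)
  expect_equal(as.integer(pred$label), manual, ignore_attr = TRUE)
  p1 <- pred[, paste0("p_", fit$class_levels[1])]
  p2 <- pred[, paste0("p_", fit$class_levels[2])]
  expect_true(all(abs(p1 + p2 - 1) < 1e-12))
  # equidistant instance goes to the first class
  fitX <- fit
  fitX$prototypes <- rbind(c(1, 0, 0), c(-1, 0, 0))
  rownames(fitX$prototypes) <- fit$class_levels
  G0 <- matrix(0, 1, 3)
  d0 <- proto_distances(G0, fitX$prototypes)
  expect_equal(unname(d0[1, 1]), unname(d0[1, 2]))
  expect_equal(unname(which.min(d0[1, ])), 1L)
})
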