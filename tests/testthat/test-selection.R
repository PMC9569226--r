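test_that("the data term and its gradient match definitional oracles", {
  set.seed(31)
  N <- 10L; D <- 6L
  X <- matrix(rnorm(N * D), N, D)
  w <- rnorm(D)
  y <- rnorm(N)
  # explicit loop oracle
  acc <- 0
  for (i in seq_len(N)) acc <- acc + (y[i] - sum(w * X[i, ]))^2
  expect_equal(sel_objective_f(w, X, y), acc / (2 * N), tolerance = 1e-12)
  expect_identical(sel_objective_f(numeric(D), X, numeric(N)), 0)
  w_fit <- qr.solve(X, y)
  expect_equal(sel_objective_f(w_fit, X, drop(X %*% w_fit)), 0)

  # gradient: finite differences, zero point, stationarity
  g <- sel_gradient(w, X, y)
  h <- 1e-6
  for (j in seq_len(D)) {
    wp <- w; wp[j] <- w[j] + h
    wm <- w; wm[j] <- w[j] - h
    num <- (sel_objective_f(wp, X, y) - sel_objective_f(wm, X, y)) / (2 * h)
    expect_equal(g[j], num, tolerance = 1e-4)
  }
  expect_equal(sel_gradient(numeric(D), X, y), -drop(crossprod(X, y)) / N)
  N2 <- 20L
  X2 <- matrix(rnorm(N2 * D), N2, D)
  y2 <- rnorm(N2)
  w_ls <- qr.solve(crossprod(X2), crossprod(X2, y2))
  expect_lt(max(abs(sel_gradient(drop(w_ls), X2, y2))), 1e-9)
  expect_error(sel_gradient(w, X, y[-1]), "length")
})

test_that("lipschitz_estimate equals the squared top singular value over N", {
  expect_equal(lipschitz_estimate(diag(4)), 1 / 4, tolerance = 1e-8)
  cvec <- c(1, -2, 3)
  X1 <- cbind(cvec, 0, 0)
  expect_equal(lipschitz_estimate(X1), sum(cvec^2) / 3, tolerance = 1e-8)
  set.seed(41)
  X <- matrix(rnorm(600), 20, 30)
  expect_equal(lipschitz_estimate(X), max(svd(X)$d)^2 / 20, tolerance = 1e-6)
  expect_error(lipschitz_estimate(matrix(0, 3, 3)), "zero")
})

test_that("prox_step reproduces the three soft-threshold branches", {
  # theta = lam * a / L = 0.2
  expect_equal(prox_step(0.5, 1, 0.2, 1), 0.3)
  expect_equal(prox_step(0.1, 1, 0.2, 1), 0)
  expect_equal(prox_step(-0.5, 1, 0.2, 1), -0.3)
  # vectorized with per-position weights
  expect_equal(prox_step(c(1, 1), c(0.2, 0.8), 1, 2), c(0.9, 0.6))
  expect_error(prox_step(1, 1, 0.1, 0), "positive")
})

test_that("soft-threshold magnitude never increases with the threshold", {
  xi <- seq(-1.5, 1.5, by = 0.25)
  prev <- abs(prox_step(xi, 1, 0, 1))
  for (theta in seq(0.1, 1, by = 0.1)) {
    cur <- abs(prox_step(xi, 1, theta, 1))
    expect_true(all(cur <= prev + 1e-15))
    prev <- cur
  }
})

test_that("ista_solve fully shrinks to zero when lambda dominates the gradient", {
  inst <- make_standardized_instance(30, 12, seed = 51)
  lam_max <- max(abs(crossprod(inst$X, inst$y)) / nrow(inst$X)) / 0.4
  m <- ista_solve(inst$X, inst$y, primary_idx = 1:6, a1 = 0.4,
                  lam = lam_max * 1.01)
  expect_identical(m$omega, numeric(12))
  expect_true(m$converged)
})

test_that("ista at a1 = a2 = 0.5 matches a coordinate-descent lasso oracle", {
  inst <- make_standardized_instance(50, 100, seed = 61)
  lam <- 0.2
  m <- ista_solve(inst$X, inst$y, primary_idx = 1:50, a1 = 0.5, lam = lam,
                  max_iter = 50000L, tol = 1e-12)
  w_oracle <- cd_lasso_oracle(inst$X, inst$y, lam / 2)
  expect_lt(max(abs(m$omega - w_oracle)), 1e-6)
  expect_true(all(diff(m$objective_trace) <= 1e-10))
})

test_that("ista agrees with glmnet on the equal-weight lasso", {
  skip_if_not_installed("glmnet")
  inst <- make_standardized_instance(60, 30, seed = 62)
  lam <- 0.3
  m <- ista_solve(inst$X, inst$y, primary_idx = 1:15, a1 = 0.5, lam = lam,
                  max_iter = 50000L, tol = 1e-12)
  gl <- glmnet::glmnet(inst$X, inst$y, lambda = lam / 2, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(m$omega - as.numeric(gl$beta))), 1e-5)
})

test_that("orthonormal design reduces ista to prox of the least-squares solution", {
  set.seed(71)
  N <- 40L; D <- 8L
  Q <- qr.Q(qr(matrix(rnorm(N * D), N, D))) * sqrt(N)  # X'X / N = I
  beta <- c(2, -1.5, 0.8, rep(0, D - 3))
  y <- drop(Q %*% beta) + rnorm(N, sd = 0.1)
  lam <- 0.3; a1 <- 0.25
  m <- ista_solve(Q, y, primary_idx = 1:4, a1 = a1, lam = lam,
                  max_iter = 20000L, tol = 1e-12)
  w_ls <- drop(crossprod(Q, y)) / N
  a_of_p <- c(rep(a1, 4), rep(1 - a1, 4))
  closed <- prox_step(w_ls, a_of_p, lam, 1)
  expect_lt(max(abs(m$omega - closed)), 1e-8)
})

test_that("lambda = 0 on an overdetermined instance recovers least squares", {
  set.seed(81)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- rnorm(100)
  m <- ista_solve(X, y, primary_idx = 1:5, a1 = 0.5, lam = 0,
                  max_iter = 50000L, tol = 1e-13)
  w_ls <- qr.solve(crossprod(X), crossprod(X, y))
  expect_lt(max(abs(m$omega - drop(w_ls))), 1e-6)
})

test_that("select_support thresholds |omega| and falls back on empty supports", {
  layout <- list(v1 = 1:4, v2 = 5:8)
  m <- structure(list(omega = c(0.5, 0, 1e-10, -0.2, rep(0, 4))),
                 class = "sel_model")
  expect_warning(sup <- select_support(m, layout), "empty support.*v2")
  expect_equal(sup$v1, c(1L, 4L))
  expect_length(sup$v2, 4L)  # top-k capped at the view width

  m0 <- structure(list(omega = rep(0, 8)), class = "sel_model")
  expect_warning(sup0 <- select_support(m0, layout, fallback_k = 2L))
  expect_length(sup0$v1, 2L)
})

test_that("selection targets are a centered two-class coding", {
  y <- factor(c("a", "a", "b"))
  t <- selection_targets(y)
  expect_equal(mean(t), 0)
  expect_equal(t[1], t[2])
  expect_true(t[3] > t[1])
  expect_error(selection_targets(factor(c("a", "b", "c"))), "2 classes")
})

test_that("per-view selection returns within-view supports; a1 controls their size", {
  gen <- generate_multiview(synth_config(N = 120L, seed = 5L))
  sel <- run_per_view_selection(gen$data, a1 = 0.2, lam = 0.5)
  expect_named(sel$support, names(gen$data$views))
  widths <- vapply(gen$data$views, ncol, integer(1L))
  for (v in names(sel$support)) {
    expect_true(all(sel$support[[v]] >= 1 & sel$support[[v]] <= widths[[v]]))
  }
  # smaller a1 = lighter primary penalty = no smaller support
  sel_heavy <- run_per_view_selection(gen$data, a1 = 0.8, lam = 0.5)
  sizes_light <- vapply(sel$support, length, integer(1L))
  sizes_heavy <- vapply(sel_heavy$support, length, integer(1L))
  expect_true(all(sizes_light >= sizes_heavy))
  expect_true(sum(sizes_light) > sum(sizes_heavy))
})

test_that("single-view selection degrades to a plain lasso", {
  gen <- generate_multiview(synth_config(N = 80L, region_counts = c(8L),
                                         s = 5L, seed = 9L))
  sel <- run_per_view_selection(gen$data, a1 = 0.3, lam = 0.4)
  # oracle: plain lasso with penalty lam * a1 on the standardized design
  X <- gen$data$views$view1
  Xs <- scale(X)
  attr(Xs, "scaled:center") <- NULL; attr(Xs, "scaled:scale") <- NULL
  y <- selection_targets(gen$data$labels)
  w <- cd_lasso_oracle(Xs, y, 0.4 * 0.3)
  expect_equal(sel$support$view1, which(abs(w) > 1e-8), ignore_attr = TRUE)
})

test_that("apply_selection uses training statistics and keeps row alignment", {
  gen <- generate_multiview(synth_config(N = 60L, seed = 13L))
  train <- mvfcc:::subset_mv(gen$data, 1:40)
  test <- mvfcc:::subset_mv(gen$data, 41:60)
  sel <- run_per_view_selection(train)
  tr <- apply_selection(sel, train)
  te <- apply_selection(sel, test)
  expect_equal(vapply(tr$views, ncol, integer(1L)),
               vapply(sel$support, length, integer(1L)))
  # training columns are standardized with training stats
  expect_lt(max(abs(colMeans(tr$views$view1))), 1e-10)
  expect_equal(apply(tr$views$view1, 2, sd), rep(1, ncol(tr$views$view1)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # test transformation reuses training stats (means not re-centered to 0)
  expect_gt(max(abs(colMeans(te$views$view1))), 1e-6)
})
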