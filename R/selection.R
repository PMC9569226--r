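# Multiview feature selection: L1-regularized linear regression in which the
# primary view's weight block is penalized by a1 and the auxiliary views' block
# by a2 = 1 - a1, solved by proximal gradient (ISTA) with a fixed 1/L step.
#
# Objective, for concatenated features x_i (length D) and scalar targets y_i:
#   (1/2N) sum_i (y_i - w' x_i)^2 + lambda * sum_g a_g ||w_g||_1

#' Squared-error data term of the selection objective
#'
#' `(1/2N) sum_i (y_i - omega . x_i)^2`.
#'
#' @param omega Weight vector of length `D`.
#' @param X `N x D` design matrix.
#' @param y Numeric target vector of length `N`.
#' @return Nonnegative scalar.
#' @export
sel_objective_f <- function(omega, X, y) {
  if (length(omega) != ncol(X)) stop("omega length != ncol(X)")
  if (length(y) != nrow(X)) stop("y length != nrow(X)")
  r <- y - drop(X %*% omega)
  sum(r^2) / (2 * nrow(X))
}

#' Full selection objective including the view-weighted L1 penalty
#'
#' @inheritParams sel_objective_f
#' @param a_of_p Per-position view weight (a1 on primary positions, a2
#'   elsewhere), length `D`.
#' @param lam Penalty strength `lambda >= 0`.
#' @return Scalar objective value.
#' @export
sel_objective <- function(omega, X, y, a_of_p, lam) {
  sel_objective_f(omega, X, y) + lam * sum(a_of_p * abs(omega))
}

#' Gradient of the data term
#'
#' `(1/N) X' (X omega - y)`.
#'
#' @inheritParams sel_objective_f
#' @return Numeric vector of length `D`.
#' @export
sel_gradient <- function(omega, X, y) {
  if (length(omega) != ncol(X)) stop("omega length != ncol(X)")
  if (length(y) != nrow(X)) stop("y length != nrow(X)")
  drop(crossprod(X, drop(X %*% omega) - y)) / nrow(X)
}

#' Lipschitz constant of the data-term gradient
#'
#' `L = sigma_max(X)^2 / N`, the largest eigenvalue of `X'X / N`, obtained by
#' power iteration on `X'X` (no dense decomposition needed at connectome
#' scale). Any upper bound on this value also yields monotone ISTA descent.
#'
#' @param X `N x D` design matrix, not all zero.
#' @param tol Relative convergence tolerance of the power iteration.
#' @param max_iter Iteration cap.
#' @return Positive scalar `L`.
#' @export
lipschitz_estimate <- function(X, tol = 1e-8, max_iter = 1000L) {
  if (all(X == 0)) stop("design matrix is identically zero")
  D <- ncol(X)
  # deterministic start: right singular vector direction seeded from X itself
  v <- drop(crossprod(X, X %*% rep(1 / sqrt(D), D)))
  if (sum(v^2) == 0) v <- rep(1, D)
  v <- v / sqrt(sum(v^2))
  lam_old <- 0
  for (i in seq_len(max_iter)) {
    w <- drop(crossprod(X, X %*% v))
    lam <- sqrt(sum(w^2))
    if (lam == 0) break
    v <- w / lam
    if (abs(lam - lam_old) <= tol * max(1, lam)) break
    lam_old <- lam
  }
  lam / nrow(X)
}

#' Closed-form proximal (soft-threshold) step of the view-weighted L1 penalty
#'
#' With per-position threshold `theta_p = lam * a_p / L`:
#' `xi_p - theta_p` if `xi_p > theta_p`, `0` if `|xi_p| <= theta_p`,
#' `xi_p + theta_p` otherwise. Components are separable, so the minimizer of
#' the quadratic-plus-L1 surrogate is exact.
#'
#' @param xi Gradient-step point, length `D`.
#' @param a_of_p Per-position view weight, length `D` (recycled if scalar).
#' @param lam Penalty strength.
#' @param L Lipschitz constant (step size `1/L`), `L > 0`.
#' @return Thresholded vector of length `D`.
#' @export
prox_step <- function(xi, a_of_p, lam, L) {
  if (L <= 0) stop("L must be positive")
  theta <- lam * a_of_p / L
  sign(xi) * pmax(abs(xi) - theta, 0)
}

#' Solve the view-weighted L1 selection problem by ISTA
#'
#' Iterates `xi = omega - (1/L) grad f(omega)` followed by [prox_step()],
#' starting from `omega = 0`, until the max absolute update falls below `tol`
#' or `max_iter` is reached. The objective trace is recorded; with a valid
#' `L` it is nonincreasing.
#'
#' @param X `N x D` design matrix (concatenated views).
#' @param y Targets, length `N` (class codes +1/-1, centered).
#' @param primary_idx Integer positions (within `1..D`) of the primary view.
#' @param a1 Primary-view weight coefficient in `[0, 1]`; auxiliary views get
#'   `a2 = 1 - a1`.
#' @param lam Penalty strength.
#' @param max_iter Iteration cap (default 5000).
#' @param tol Convergence tolerance on `max |omega_new - omega|`
#'   (default 1e-7).
#' @param L Optional Lipschitz constant; estimated from `X` when `NULL`.
#' @return List of class `sel_model`: `omega`, `a_of_p`, `a1`, `a2`, `lam`,
#'   `L`, `iters_run`, `converged`, `objective_trace`.
#' @export
ista_solve <- function(X, y, primary_idx, a1, lam,
                       max_iter = 5000L, tol = 1e-7, L = NULL) {
  if (a1 < 0 || a1 > 1) stop("a1 must lie in [0, 1]")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  D <- ncol(X)
  a2 <- 1 - a1
  a_of_p <- rep(a2, D)
  a_of_p[primary_idx] <- a1
  if (is.null(L)) L <- lipschitz_estimate(X)
  omega <- numeric(D)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- sel_objective(omega, X, y, a_of_p, lam)
  iters <- 0L
  converged <- FALSE
  for (j in seq_len(max_iter)) {
    xi <- omega - sel_gradient(omega, X, y) / L
    omega_new <- prox_step(xi, a_of_p, lam, L)
    if (!all(is.finite(omega_new))) {
      stop("ISTA diverged at iteration ", j, " (non-finite weights; check L)")
    }
    delta <- max(abs(omega_new - omega))
    omega <- omega_new
    iters <- j
    trace[j + 1L] <- sel_objective(omega, X, y, a_of_p, lam)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(omega = omega, a_of_p = a_of_p, a1 = a1, a2 = a2, lam = lam, L = L,
         iters_run = iters, converged = converged,
         objective_trace = trace[seq_len(iters + 1L)]),
    class = "sel_model")
}

#' Extract the per-view support of a solved selection model
#'
#' Positions whose `|omega|` exceeds `zero_tol` are the selected
#' (discriminative) features. ISTA yields exact zeros, so the tolerance only
#' guards float noise. If a view's support is empty, the `fallback_k` largest
#' `|omega|` positions of that view are kept (with a warning) so downstream
#' stages never receive a zero-width view.
#'
#' @param model A `sel_model` from [ista_solve()].
#' @param view_layout Named list mapping view id to its integer positions in
#'   the concatenated layout.
#' @param zero_tol Zero threshold (default 1e-8).
#' @param fallback_k Support size used when a view's support is empty
#'   (default 10).
#' @return Named list of integer vectors of within-view (1-based) positions.
#' @export
select_support <- function(model, view_layout, zero_tol = 1e-8,
                           fallback_k = 10L) {
  lapply_named <- function(x, f) stats::setNames(lapply(names(x), f), names(x))
  lapply_named(view_layout, function(v) {
    pos <- view_layout[[v]]
    w <- abs(model$omega[pos])
    sup <- which(w > zero_tol)
    if (length(sup) == 0L) {
      warning("empty support for view '", v, "'; keeping top-",
              fallback_k, " |omega| positions")
      k <- min(fallback_k, length(w))
      sup <- order(w, decreasing = TRUE)[seq_len(k)]
      sup <- sort(sup)
    }
    as.integer(sup)
  })
}

#' Concatenated layout of an mv_dataset
#'
#' @param data An `mv_dataset`.
#' @return Named list of integer position vectors, one per view, covering
#'   `1..D`.
#' @export
view_layout <- function(data) {
  widths <- vapply(data$views, ncol, integer(1L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  stats::setNames(
    lapply(seq_along(widths), function(v) seq.int(starts[v], ends[v])),
    names(data$views))
}

#' Encode binary class labels as centered +1/-1 regression targets
#'
#' The two classes are coded +1 (second factor level) and -1 (first level)
#' and the coding is centered by the class balance so the target has zero
#' mean, playing the role of an intercept.
#'
#' @param labels Factor with two levels.
#' @return Numeric vector with zero mean.
#' @export
selection_targets <- function(labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("selection targets require exactly 2 classes")
  y <- ifelse(as.integer(labels) == 2L, 1, -1)
  y - mean(y)
}

#' Run per-view multiview feature selection
#'
#' For each view in turn, solves the selection problem with that view as
#' primary (weight `a1`) and all others auxiliary (weight `a2 = 1 - a1`), on
#' the concatenated, optionally per-feature standardized design. Each view
#' keeps only the support found in the run where it was primary. Selection is
#' fitted on the supplied (training) rows only; apply the returned supports to
#' held-out rows downstream.
#'
#' @param data An `mv_dataset` (training rows only).
#' @param a1 Primary-view weight coefficient (default 0.2).
#' @param lam Penalty strength (default 0.5; see the package vignette for
#'   the calibration on the synthetic benchmark).
#' @param standardize Per-feature z-scoring of the concatenated design before
#'   selection (default `TRUE`).
#' @param max_iter,tol Passed to [ista_solve()].
#' @return List of class `mv_selection`: `support` (named list of within-view
#'   index vectors), `models` (per-primary-view `sel_model`s), `a1`, `lam`,
#'   `standardize`, plus the feature `center`/`scale` used.
#' @export
run_per_view_selection <- function(data, a1 = 0.2, lam = 0.5,
                                   standardize = TRUE,
                                   max_iter = 5000L, tol = 1e-7) {
  stopifnot(inherits(data, "mv_dataset"))
  layout <- view_layout(data)
  Xall <- do.call(cbind, data$views)
  ctr <- colMeans(Xall)
  scl <- apply(Xall, 2L, stats::sd)
  scl[scl == 0] <- 1
  if (standardize) {
    Xs <- sweep(sweep(Xall, 2L, ctr, "-"), 2L, scl, "/")
  } else {
    Xs <- sweep(Xall, 2L, ctr, "-")
  }
  y <- selection_targets(data$labels)
  L <- lipschitz_estimate(Xs)
  models <- list()
  support <- list()
  for (v in names(layout)) {
    m <- ista_solve(Xs, y, primary_idx = layout[[v]], a1 = a1, lam = lam,
                    max_iter = max_iter, tol = tol, L = L)
    models[[v]] <- m
    # only the primary view's support is retained from this run
    support[[v]] <- select_support(m, layout[v])[[v]]
  }
  structure(
    list(support = support, models = models, a1 = a1, lam = lam,
         standardize = standardize, center = ctr, scale = scl,
         layout = layout),
    class = "mv_selection")
}

#' Apply a fitted selection to a multiview dataset
#'
#' Restricts each view to its selected columns and applies the training
#' centering/scaling, so held-out rows are transformed with training
#' statistics only.
#'
#' @param sel An `mv_selection` from [run_per_view_selection()].
#' @param data An `mv_dataset` with the same views.
#' @return An `mv_dataset` with reduced views.
#' @export
apply_selection <- function(sel, data) {
  stopifnot(inherits(sel, "mv_selection"), inherits(data, "mv_dataset"))
  views <- list()
  for (v in names(sel$support)) {
    if (!v %in% names(data$views)) stop("dataset lacks view '", v, "'")
    pos_global <- sel$layout[[v]][sel$support[[v]]]
    X <- data$views[[v]][, sel$support[[v]], drop = FALSE]
    X <- sweep(X, 2L, sel$center[pos_global], "-")
    if (sel$standardize) X <- sweep(X, 2L, sel$scale[pos_global], "/")
    views[[v]] <- X
  }
  out <- data
  out$views <- views
  out$D <- sum(vapply(views, ncol, integer(1L)))
  out
}
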