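# Independent oracles, written from definitional sums / brute force so the
# implementations they check share no code path with them.

# Pearson correlation matrix from the definitional sums
pearson_oracle <- function(ts) {
  n <- ncol(ts)
  T_len <- nrow(ts)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- ts[, i]; xj <- ts[, j]
      mi <- sum(xi) / T_len; mj <- sum(xj) / T_len
      num <- sum((xi - mi) * (xj - mj))
      den <- sqrt(sum((xi - mi)^2)) * sqrt(sum((xj - mj)^2))
      out[i, j] <- num / den
    }
  }
  out
}

# row-major strict upper triangle by explicit index-pair enumeration
upper_oracle <- function(m) {
  n <- nrow(m)
  out <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      out <- c(out, m[i, j])
    }
  }
  out
}

# plain lasso (1/2N ||y - Xw||^2 + lam ||w||_1) by cyclic coordinate descent
cd_lasso_oracle <- function(X, y, lam, max_iter = 50000L, tol = 1e-13) {
  N <- nrow(X); D <- ncol(X)
  w <- numeric(D)
  z <- colSums(X^2) / N
  r <- y
  for (it in seq_len(max_iter)) {
    dmax <- 0
    for (j in seq_len(D)) {
      rho <- sum(X[, j] * r) / N + z[j] * w[j]
      wj <- sign(rho) * max(abs(rho) - lam, 0) / z[j]
      d <- wj - w[j]
      if (d != 0) {
        r <- r - X[, j] * d
        w[j] <- wj
      }
      dmax <- max(dmax, abs(d))
    }
    if (dmax < tol) break
  }
  w
}

# Pearson correlation of two vectors from the definitional sums
corr_sums_oracle <- function(u1, u2) {
  K <- length(u1)
  m1 <- sum(u1) / K; m2 <- sum(u2) / K
  s1 <- sqrt(sum((u1 - m1)^2) / (K - 1))
  s2 <- sqrt(sum((u2 - m2)^2) / (K - 1))
  sum((u1 - m1) * (u2 - m2)) / ((K - 1) * s1 * s2)
}

# central-difference gradient of a scalar function of a flat parameter list
numeric_grad <- function(f, pars, h = 1e-6, max_per_block = 6L) {
  out <- list()
  for (k in names(pars)) {
    p <- pars[[k]]
    g <- if (is.null(dim(p))) rep(NA_real_, length(p)) else
      array(NA_real_, dim = dim(p))
    idxs <- seq_len(min(max_per_block, length(p)))
    for (i in idxs) {
      pp <- pars
      pp[[k]][i] <- p[i] + h
      lp <- f(pp)
      pp[[k]][i] <- p[i] - h
      lm <- f(pp)
      g[i] <- (lp - lm) / (2 * h)
    }
    out[[k]] <- g
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
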