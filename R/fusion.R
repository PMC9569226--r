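# Multiview feature fusion: per-view linear maps into a common K-dimensional
# space, additive combination, and a normalized cross-correlation (NCC)
# regularizer that rewards alignment of the per-view transformed features.

#' Linear per-view transform into the fused space
#'
#' `u_v = v_v W_v'`: each fused coordinate k is the dot product of the view's
#' deep features with the k-th parameter column. No activation is applied
#' before fusion.
#'
#' @param v_features Batch matrix (batch x view width) of deep features.
#' @param W `K x width` parameter matrix for this view.
#' @return Batch matrix `batch x K`.
#' @export
view_transform <- function(v_features, W) {
  v_features <- as.matrix(v_features)
  if (ncol(v_features) != ncol(W)) {
    stop("input width ", ncol(v_features), " != transform width ", ncol(W))
  }
  v_features %*% t(W)
}

#' Additive fusion of per-view transformed features
#'
#' `z = sum_v u_v`, the natural additive extension of two-view fusion to V
#' views. With a single view this is the identity.
#'
#' @param u_per_view List of `batch x K` matrices, identical shapes.
#' @return `batch x K` fused feature matrix.
#' @export
fuse_views <- function(u_per_view) {
  if (length(u_per_view) < 1L) stop("need at least one view")
  dims <- lapply(u_per_view, dim)
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
    stop("all u_v must share the same shape")
  }
  Reduce(`+`, u_per_view)
}

#' Normalized cross-correlation of two feature vectors
#'
#' The sample Pearson correlation over the K fused coordinates:
#' `sum_k (u1_k - mu1)(u2_k - mu2) / ((K-1) s1 s2)` with `s` the sample
#' standard deviations, so the value is bounded in `[-1, 1]`. A zero-variance
#' input makes the correlation undefined; it is reported as 0 with a warning
#' (no alignment signal).
#'
#' @param u1,u2 Numeric vectors of equal length `K >= 2`.
#' @return Scalar in `[-1, 1]`.
#' @export
ncc <- function(u1, u2) {
  u1 <- as.numeric(u1); u2 <- as.numeric(u2)
  K <- length(u1)
  if (length(u2) != K) stop("u1 and u2 must have equal length")
  if (K < 2L) stop("need K >= 2 coordinates")
  c1 <- u1 - mean(u1); c2 <- u2 - mean(u2)
  n1 <- sqrt(sum(c1^2)); n2 <- sqrt(sum(c2^2))
  if (n1 == 0 || n2 == 0) {
    warning("zero-variance input to ncc; returning 0")
    return(0)
  }
  val <- sum(c1 * c2) / (n1 * n2)
  min(1, max(-1, val))
}

#' Multiview alignment regularizer
#'
#' Sum over consecutive view pairs (v, v+1), v = 1..V-1, of the NCC between
#' their transformed features; with `pairing = "all_pairs"` every unordered
#' pair contributes. For a batch the NCC is computed per sample over the K
#' coordinates and averaged over the batch. Maximizing the term aligns the
#' views' deep features in the common space.
#'
#' @param u_per_view List of `batch x K` matrices (or bare vectors).
#' @param pairing `"consecutive"` (default) or `"all_pairs"`.
#' @return Scalar; in `[-(P), P]` for P contributing pairs.
#' @export
mv_regularizer <- function(u_per_view, pairing = c("consecutive", "all_pairs")) {
  pairing <- match.arg(pairing)
  u_per_view <- lapply(u_per_view, function(u) {
    if (is.null(dim(u))) matrix(u, nrow = 1L) else as.matrix(u)
  })
  V <- length(u_per_view)
  if (V < 2L) {
    warning("mv_regularizer needs >= 2 views; returning 0")
    return(0)
  }
  pairs <- if (pairing == "consecutive") {
    lapply(seq_len(V - 1L), function(v) c(v, v + 1L))
  } else {
    unlist(lapply(seq_len(V - 1L), function(a) {
      lapply(seq.int(a + 1L, V), function(b) c(a, b))
    }), recursive = FALSE)
  }
  B <- nrow(u_per_view[[1L]])
  total <- 0
  for (pr in pairs) {
    per_sample <- vapply(seq_len(B), function(i) {
      ncc(u_per_view[[pr[1L]]][i, ], u_per_view[[pr[2L]]][i, ])
    }, numeric(1L))
    total <- total + mean(per_sample)
  }
  total
}

#' Concatenation baseline for multiview features
#'
#' Horizontal concatenation of the per-view deep features; the comparison
#' point for additive fusion in the ablation harness.
#'
#' @param v_per_view List of batch matrices with equal row counts.
#' @return Matrix of width `sum` of per-view widths.
#' @export
concat_views <- function(v_per_view) {
  if (length(v_per_view) < 1L) stop("need at least one view")
  v_per_view <- lapply(v_per_view, as.matrix)
  ns <- vapply(v_per_view, nrow, integer(1L))
  if (length(unique(ns)) != 1L) stop("batch sizes differ across views")
  do.call(cbind, v_per_view)
}

# per-sample NCC value and gradients wrt both (row) vectors; used by the
# training loop. Centered inputs make the centering projector a no-op in the
# gradient.
ncc_with_grad <- function(u1, u2) {
  K <- length(u1)
  c1 <- u1 - mean(u1); c2 <- u2 - mean(u2)
  n1 <- sqrt(sum(c1^2)); n2 <- sqrt(sum(c2^2))
  if (n1 == 0 || n2 == 0) {
    return(list(value = 0, g1 = numeric(K), g2 = numeric(K)))
  }
  r <- sum(c1 * c2) / (n1 * n2)
  g1 <- c2 / (n1 * n2) - r * c1 / n1^2
  g2 <- c1 / (n1 * n2) - r * c2 / n2^2
  # project out the mean direction (d centered / d raw = I - 11'/K)
  list(value = r, g1 = g1 - mean(g1), g2 = g2 - mean(g2))
}
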