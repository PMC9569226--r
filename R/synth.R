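# Synthetic multiview connectome generator with known ground truth: a sparse
# set of class-discriminative edges per view, a subset of which share a latent
# driver across views, so selection, fusion and classification can all be
# checked against planted truth without any data download.

#' Synthetic multiview dataset configuration
#'
#' Defaults are scaled-down analogues of a three-atlas study (region counts
#' 20/12/16 standing in for the 200/90/160-region parcellations), with 10
#' planted discriminative edges per view at per-feature signal-to-noise 1
#' (mean shift `effect` against `noise_sd`), half of them driven by a latent
#' factor shared across views.
#'
#' @param N Total subjects (balanced classes), default 200.
#' @param region_counts Integer vector of per-view region counts,
#'   default `c(20, 12, 16)`.
#' @param s Planted discriminative edges per view, default 10.
#' @param shared_fraction Fraction of planted edges whose latent driver is
#'   common across views, default 0.5.
#' @param effect Class mean shift on planted edges, in Fisher-z units,
#'   default 1.
#' @param noise_sd Baseline feature noise standard deviation, default 1.
#' @param seed Integer seed, default 0.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(N = 200L, region_counts = c(20L, 12L, 16L),
                         s = 10L, shared_fraction = 0.5, effect = 1.0,
                         noise_sd = 1.0, seed = 0L) {
  region_counts <- as.integer(region_counts)
  if (any(region_counts < 2L)) stop("region counts must be >= 2")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]")
  }
  if (effect < 0) stop("effect must be >= 0")
  widths <- feature_count(region_counts)
  if (any(s > widths)) {
    stop("s = ", s, " planted edges exceed the feature count of a view (",
         paste(widths, collapse = ", "), ")")
  }
  structure(list(N = as.integer(N), region_counts = region_counts,
                 s = as.integer(s), shared_fraction = shared_fraction,
                 effect = effect, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a multiview feature dataset with planted discriminative edges
#'
#' Per view, features are baseline Gaussian noise (`sd = noise_sd`); planted
#' edges additionally receive a class-dependent shift of `±effect/2`. A
#' per-subject latent factor adds a common perturbation (sd `0.5 noise_sd`)
#' to the shared planted edges of every view, creating cross-view correlation
#' of the shared signal. Classes are balanced; everything is reproducible
#' from the seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `data` (an `mv_dataset`) and `truth` (list of class
#'   `synth_truth`: per-view planted edge indices, shared-edge flags, class
#'   feature means).
#' @export
generate_multiview <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  N <- cfg$N
  V <- length(cfg$region_counts)
  widths <- feature_count(cfg$region_counts)
  n1 <- N %/% 2L
  y <- factor(rep(c("control", "patient"), c(N - n1, n1)))
  sign_y <- ifelse(y == "patient", 1, -1)
  ids <- sprintf("sub%04d", seq_len(N))
  n_shared <- round(cfg$shared_fraction * cfg$s)
  latent <- stats::rnorm(N, 0, 0.5 * cfg$noise_sd)
  planted <- list(); shared_flag <- list(); views <- list(); means <- list()
  for (v in seq_len(V)) {
    vn <- paste0("view", v)
    p <- sort(sample.int(widths[v], cfg$s))
    shr <- rep(FALSE, cfg$s)
    if (n_shared > 0L) shr[seq_len(n_shared)] <- TRUE
    X <- matrix(stats::rnorm(N * widths[v], 0, cfg$noise_sd), N, widths[v])
    X[, p] <- X[, p] + outer(sign_y, rep(cfg$effect / 2, cfg$s))
    if (n_shared > 0L) {
      X[, p[shr]] <- X[, p[shr]] + latent
    }
    rownames(X) <- ids
    colnames(X) <- sprintf("e%04d", seq_len(widths[v]))
    mu <- matrix(0, 2L, widths[v], dimnames = list(c("control", "patient"),
                                                   colnames(X)))
    mu["patient", p] <- cfg$effect / 2
    mu["control", p] <- -cfg$effect / 2
    planted[[vn]] <- p
    shared_flag[[vn]] <- shr
    views[[vn]] <- X
    means[[vn]] <- mu
  }
  data <- assemble_views(views, stats::setNames(as.character(y), ids))
  truth <- structure(list(planted = planted, shared = shared_flag,
                          class_means = means, config = cfg),
                     class = "synth_truth")
  list(data = data, truth = truth)
}

#' Jaccard overlap between a selected support and the planted edges
#'
#' @param support Integer vector of selected within-view positions.
#' @param planted Integer vector of planted within-view positions.
#' @return Scalar in `[0, 1]`.
#' @export
support_jaccard <- function(support, planted) {
  u <- length(union(support, planted))
  if (u == 0L) return(1)
  length(intersect(support, planted)) / u
}

#' Generate per-subject ROI time series with class-dependent correlations
#'
#' For each view, draws `T`-timepoint multivariate normal series whose
#' population correlation matrix is the identity except on planted region
#' pairs, where the correlation is `r_patient` for patients and `r_control`
#' for controls. The target matrix is shrunk toward the identity as needed to
#' stay positive definite. Running the connectivity chain on the output
#' recovers the planted correlation differences within sampling error
#' (Fisher-z sampling sd about `1/sqrt(T - 3)`).
#'
#' @param cfg A [synth_config()]; `s` planted region pairs per view.
#' @param T_len Timepoints per series, default 200.
#' @param r_patient,r_control Planted-pair correlations per class, defaults
#'   0.6 and 0.
#' @return List with `series` (per-view list of per-subject T x n matrices),
#'   `labels` (named character), `pairs` (per-view matrix of planted region
#'   pairs).
#' @export
generate_timeseries <- function(cfg = synth_config(), T_len = 200L,
                                r_patient = 0.6, r_control = 0.0) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 59L)
  N <- cfg$N
  n1 <- N %/% 2L
  y <- rep(c("control", "patient"), c(N - n1, n1))
  ids <- sprintf("sub%04d", seq_len(N))
  names(y) <- ids
  out_series <- list()
  out_pairs <- list()
  for (v in seq_along(cfg$region_counts)) {
    n <- cfg$region_counts[v]
    vn <- paste0("view", v)
    all_pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    sel <- all_pairs[sample.int(nrow(all_pairs), cfg$s), , drop = FALSE]
    make_target <- function(r) {
      C <- diag(n)
      for (k in seq_len(nrow(sel))) {
        C[sel[k, 1L], sel[k, 2L]] <- r
        C[sel[k, 2L], sel[k, 1L]] <- r
      }
      # shrink toward identity until positive definite (cap at 20 steps)
      for (i in 0:20) {
        Cs <- (1 - 0.05 * i) * C + 0.05 * i * diag(n)
        ev <- min(eigen(Cs, symmetric = TRUE, only.values = TRUE)$values)
        if (ev > 1e-8) return(Cs)
      }
      stop("target correlation matrix is not positive definite")
    }
    targets <- list(control = make_target(r_control),
                    patient = make_target(r_patient))
    chols <- lapply(targets, chol)
    out_series[[vn]] <- lapply(seq_len(N), function(i) {
      Z <- matrix(stats::rnorm(T_len * n), T_len, n)
      Z %*% chols[[y[i]]]
    })
    names(out_series[[vn]]) <- ids
    out_pairs[[vn]] <- sel
  }
  list(series = out_series, labels = y, pairs = out_pairs)
}
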