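# Evaluation: confusion counts, the five derived indicators
# (ACC/SEN/SPE/PPV/NPV as percentages), rotating 5-fold train/validation/test
# splits at a 3:1:1 ratio, the full cross-validated experiment driver, and the
# ablation harnesses (view subsets, primary-view weight sweep, fusion mode and
# position).

#' Confusion counts for binary classification
#'
#' @param truth,predicted Vectors of class labels (coercible to character).
#' @param positive_class The class counted as positive (the patient group by
#'   convention); defaults to the last sorted level of `truth`.
#' @return List of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive_class = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  classes <- sort(unique(truth))
  if (is.null(positive_class)) positive_class <- classes[length(classes)]
  unknown <- setdiff(unique(predicted), unique(c(classes, positive_class)))
  if (length(unknown) > 0L) {
    stop("unknown predicted label(s): ", paste(unknown, collapse = ", "))
  }
  tpos <- truth == positive_class
  ppos <- predicted == positive_class
  structure(list(TP = sum(tpos & ppos), TN = sum(!tpos & !ppos),
                 FP = sum(!tpos & ppos), FN = sum(tpos & !ppos),
                 positive_class = positive_class),
            class = "confusion_counts")
}

#' Five classification indicators from confusion counts
#'
#' ACC, SEN, SPE, PPV, NPV, each as a percentage. A metric whose denominator
#' is zero is reported as `NA` (undefined), never coerced to 0 or 100.
#'
#' @param cc A `confusion_counts` (or list with TP/TN/FP/FN).
#' @return Named numeric vector of percentages (NA where undefined).
#' @export
classification_metrics <- function(cc) {
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("no evaluated instances")
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(ACC = rate(TP + TN, total),
    SEN = rate(TP, TP + FN),
    SPE = rate(TN, TN + FP),
    PPV = rate(TP, TP + FP),
    NPV = rate(TN, TN + FN))
}

#' Rotating 5-fold split plan at a 3:1:1 train/validation/test ratio
#'
#' Subjects are shuffled by seed into 5 near-equal folds. Round r uses fold r
#' as the test set, fold r+1 (mod 5) as the validation set and the remaining
#' three folds as the training set, so the test folds are disjoint across
#' rounds and cover every subject while each round realizes the 3:1:1 ratio.
#'
#' @param N Number of subjects, `N >= 5`.
#' @param seed Integer seed.
#' @return List of class `split_plan`: 5 rounds, each with integer index
#'   vectors `train`, `validation`, `test`.
#' @export
make_cv_splits <- function(N, seed = 0L) {
  if (N < 5L) stop("need N >= 5 subjects for 5-fold splitting")
  set.seed(seed)
  ord <- sample.int(N)
  # shuffled subjects dealt into folds of near-equal size
  fold <- integer(N)
  fold[ord] <- rep(seq_len(5L), length.out = N)
  rounds <- lapply(seq_len(5L), function(r) {
    test_f <- r
    val_f <- r %% 5L + 1L
    list(train = which(!fold %in% c(test_f, val_f)),
         validation = which(fold == val_f),
         test = which(fold == test_f))
  })
  structure(list(rounds = rounds, N = N, seed = as.integer(seed)),
            class = "split_plan")
}

subset_mv <- function(data, rows) {
  out <- data
  out$views <- lapply(data$views, function(m) m[rows, , drop = FALSE])
  out$labels <- data$labels[rows]
  out$subject_ids <- data$subject_ids[rows]
  out
}

#' Run one cross-validated multiview classification experiment
#'
#' Per round: fit the multiview selection on the training rows only, reduce
#' all splits with the training statistics, train the network with
#' validation-accuracy checkpointing, and evaluate on the untouched test
#' fold. Reports per-fold and mean/sd of the five indicators. Every random
#' component is seeded from one master seed.
#'
#' @param data An `mv_dataset`.
#' @param config Full run configuration from [default_config()] /
#'   [parse_config()] (a plain nested list is accepted).
#' @param seed Master seed; overrides `config$cv$seed` when given.
#' @return List of class `mv_experiment`: `per_fold` (data frame),
#'   `mean`, `sd`, `support_sizes`, `config`.
#' @export
run_experiment <- function(data, config = default_config(), seed = NULL) {
  stopifnot(inherits(data, "mv_dataset"))
  config <- merge_config(default_config(), config)
  if (!is.null(seed)) config$cv$seed <- as.integer(seed)
  master <- config$cv$seed
  plan <- make_cv_splits(length(data$subject_ids), seed = master)
  spec <- encoder_spec(layer_widths = config$encoder$widths,
                       activation = config$encoder$activation,
                       pretrain = config$encoder$pretrain,
                       pretrain_epochs = config$encoder$pretrain_epochs,
                       pretrain_lr = config$encoder$pretrain_lr)
  lcfg <- loss_config(gamma = config$loss$gamma, margin = config$loss$margin,
                      lambda1 = config$loss$lambda1,
                      lambda2 = config$loss$lambda2)
  per_fold <- NULL
  support_sizes <- list()
  positive <- levels(data$labels)[nlevels(data$labels)]
  for (r in seq_along(plan$rounds)) {
    rd <- plan$rounds[[r]]
    train <- subset_mv(data, rd$train)
    sel <- run_per_view_selection(train, a1 = config$selection$a1,
                                  lam = config$selection$lambda,
                                  standardize = config$selection$standardize,
                                  max_iter = config$selection$max_iter,
                                  tol = config$selection$tol)
    support_sizes[[r]] <- vapply(sel$support, length, integer(1L))
    tr <- apply_selection(sel, train)
    va <- apply_selection(sel, subset_mv(data, rd$validation))
    te <- apply_selection(sel, subset_mv(data, rd$test))
    widths <- vapply(tr$views, ncol, integer(1L))
    fold_seed <- master + 10000L * r
    net <- mvnet_init(widths, spec, K = config$fusion$K,
                      position = config$fusion$position,
                      mode = config$fusion$mode, seed = fold_seed,
                      pretrain_data = tr$views)
    tcfg <- train_config(epochs = config$train$epochs,
                         batch_size = config$train$batch_size,
                         learning_rate = config$train$learning_rate,
                         seed = fold_seed)
    fit <- mvnet_train(net, tr$views, tr$labels, tcfg, lcfg,
                       val_views = va$views, val_labels = va$labels)
    pred <- mvnet_predict(fit, te$views)
    cc <- confusion_counts(te$labels, pred$label, positive_class = positive)
    per_fold <- rbind(per_fold,
                      data.frame(fold = r, t(classification_metrics(cc))))
  }
  metrics <- c("ACC", "SEN", "SPE", "PPV", "NPV")
  structure(
    list(per_fold = per_fold,
         mean = colMeans(per_fold[, metrics], na.rm = TRUE),
         sd = apply(per_fold[, metrics], 2L, stats::sd, na.rm = TRUE),
         support_sizes = support_sizes,
         config = config),
    class = "mv_experiment")
}

#' @export
print.mv_experiment <- function(x, ...) {
  cat("Cross-validated multiview classification (", nrow(x$per_fold),
      " folds)\n", sep = "")
  print(round(x$per_fold, 2), row.names = FALSE)
  cat("mean:", paste(names(x$mean), sprintf("%.2f", x$mean), collapse = "  "),
      "\n")
  invisible(x)
}

#' Ablation over view subsets
#'
#' Runs the experiment on every non-empty subset of views (2^V - 1 rows).
#' Single-view rows bypass fusion trivially (additive fusion of one view is
#' its own transform). Rows are ordered by subset size, then lexicographically
#' by view names.
#'
#' @param data An `mv_dataset`.
#' @param config Run configuration.
#' @param seed Master seed.
#' @return Data frame, one row per subset with the mean metrics.
#' @export
ablate_views <- function(data, config = default_config(), seed = 0L) {
  vns <- names(data$views)
  V <- length(vns)
  subsets <- unlist(lapply(seq_len(V), function(k) {
    utils::combn(vns, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(ss) {
    d <- data
    d$views <- data$views[ss]
    d$D <- sum(vapply(d$views, ncol, integer(1L)))
    res <- run_experiment(d, config, seed = seed)
    data.frame(views = paste(ss, collapse = "+"), n_views = length(ss),
               t(res$mean))
  })
  do.call(rbind, rows)
}

#' Ablation over the primary-view weight coefficient
#'
#' Sweeps `a1` (with `a2 = 1 - a1`) over a grid, re-running selection and
#' training per value.
#'
#' @param data An `mv_dataset`.
#' @param grid Values of `a1` (default `seq(0, 1, by = 0.1)`).
#' @param config Run configuration.
#' @param seed Master seed.
#' @return Data frame keyed by `a1` with mean metrics and the mean support
#'   size.
#' @export
ablate_a1 <- function(data, grid = seq(0, 1, by = 0.1),
                      config = default_config(), seed = 0L) {
  rows <- lapply(grid, function(a1) {
    cfg <- merge_config(default_config(), config)
    cfg$selection$a1 <- a1
    res <- run_experiment(data, cfg, seed = seed)
    mean_support <- mean(unlist(res$support_sizes))
    data.frame(a1 = a1, mean_support = mean_support, t(res$mean))
  })
  do.call(rbind, rows)
}

#' Ablation over fusion mode and position
#'
#' Runs the experiment for every combination of mode (concat, fuse) and
#' fusion position 1..depth: the concatenation baselines have no alignment
#' regularizer, the fusion rows do.
#'
#' @param data An `mv_dataset`.
#' @param config Run configuration.
#' @param seed Master seed.
#' @return Data frame with `mode`, `position` and mean metrics.
#' @export
ablate_fusion <- function(data, config = default_config(), seed = 0L) {
  cfg0 <- merge_config(default_config(), config)
  depth <- length(cfg0$encoder$widths)
  grid <- expand.grid(mode = c("concat", "fuse"), position = seq_len(depth),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- cfg0
    cfg$fusion$mode <- grid$mode[i]
    cfg$fusion$position <- grid$position[i]
    res <- run_experiment(data, cfg, seed = seed)
    data.frame(mode = grid$mode[i], position = grid$position[i], t(res$mean))
  })
  do.call(rbind, rows)
}
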