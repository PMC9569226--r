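# Run configuration: one nested list carries every stage's parameters.
# Unknown keys are rejected so typos cannot silently fall back to defaults,
# and the effective configuration is echoed into every output directory.

#' Default run configuration
#'
#' Nested list with one block per stage. Selection: `a1 = 0.2`
#' (primary-view weight), `lambda`, ISTA tolerances. Encoder: hidden widths
#' `c(1000, 100, 100)`, tanh, layer-wise pretraining. Fusion: additive mode
#' at the final hidden layer, `K = 100` fused features, consecutive-pair NCC.
#' Loss: `gamma = 1`, `margin = 1`, `lambda1 = 0.5`, `lambda2 = 0.1`.
#' Training: Adam, batch 96, learning rate 1e-4, 300 epochs.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    selection = list(a1 = 0.2, lambda = 0.5, tol = 1e-7, max_iter = 5000L,
                     standardize = TRUE),
    encoder = list(widths = c(1000L, 100L, 100L), activation = "tanh",
                   pretrain = TRUE, pretrain_epochs = 50L, pretrain_lr = 1e-3),
    fusion = list(mode = "fuse", position = 3L, K = 100L,
                  pairing = "consecutive"),
    loss = list(gamma = 1.0, margin = 1.0, lambda1 = 0.5, lambda2 = 0.1),
    train = list(epochs = 300L, batch_size = 96L, learning_rate = 1e-4),
    cv = list(n_folds = 5L, seed = 0L),
    io = list(out_dir = ".")
  )
}

#' Benchmark configuration for the synthetic study conditions
#'
#' The defaults above carry the full-scale settings (hidden widths
#' 1000/100/100, learning rate 1e-4) appropriate for connectome-scale inputs
#' with tens of thousands of features. The synthetic benchmark generated by
#' [synth_config()] is two orders of magnitude smaller (a few hundred
#' features, a dozen selected per view), so this configuration scales the
#' network down with it: hidden widths 16/8, fusion at the final (second)
#' hidden layer with K = 8 fused features, 60 epochs at learning rate 0.01,
#' 20 pretraining epochs. All other settings keep their defaults.
#'
#' @return Nested named list (same shape as [default_config()]).
#' @export
synthetic_benchmark_config <- function() {
  merge_config(default_config(), list(
    encoder = list(widths = c(16L, 8L), pretrain_epochs = 20L),
    fusion = list(position = 2L, K = 8L),
    train = list(epochs = 60L, learning_rate = 0.01)
  ))
}

#' Merge a partial configuration over the defaults
#'
#' Recursive: unknown keys at any level raise an error naming the key.
#'
#' @param base Full configuration (usually [default_config()]).
#' @param override Partial nested list.
#' @param path Internal (error messages).
#' @return Merged configuration.
#' @export
merge_config <- function(base, override, path = "") {
  if (is.null(override)) return(base)
  if (!is.list(override)) stop("config block '", path, "' must be a mapping")
  for (k in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]], full)
    } else {
      v <- override[[k]]
      if (is.list(v)) stop("config key '", full, "' expects a scalar/vector")
      if (is.numeric(base[[k]]) && !is.numeric(v)) {
        stop("config key '", full, "' expects a numeric value")
      }
      base[[k]] <- if (is.integer(base[[k]])) {
        as.integer(v)
      } else {
        v
      }
    }
  }
  base
}

#' Parse a YAML run configuration
#'
#' Missing keys take their defaults; unknown keys are rejected. An empty file
#' yields the full default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated nested configuration list.
#' @export
parse_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(base)
  merge_config(base, raw)
}

#' Echo the effective configuration to a file
#'
#' @param config Configuration list.
#' @param path Output YAML path.
#' @export
echo_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
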