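#' Default configuration
#'
#' All tunables of the pipeline with their defaults: semantic decay factor
#' `delta = 0.5`; GCN with 2 layers and embedding size 128 (ReLU hidden
#' activation, identity output — a row-softmax output is selectable via
#' `gcn$final_activation` but collapses the embeddings toward the uniform
#' vector and is not the default); a 2-layer transformer encoder with 4
#' attention heads, 4x feed-forward expansion and layer-norm epsilon 1e-5;
#' Adam training at learning rate 1e-3 for 250 epochs with score clamp
#' 1e-7, supervision-edge dropout 0.3 and per-epoch negative resampling;
#' evaluation with balanced negatives, 20% test split, 5 folds, decision
#' threshold 0.5 and edge masking on.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    delta = 0.5,
    gcn = list(layers = 2L, embedding = 128L,
               hidden_activation = "relu", final_activation = "identity"),
    transformer = list(heads = 4L, layers = 2L, ffn_mult = 4L,
                       ln_eps = 1e-5, use_add = TRUE, use_norm = TRUE,
                       use_ffn = TRUE),
    train = list(lr = 1e-3, epochs = 250L, clamp = 1e-7,
                 edge_dropout = 0.3, resample_negatives = TRUE),
    eval = list(threshold = 0.5, folds = 5L, test_fraction = 0.2,
                repeats = 10L, negative_ratio = 1, mask = TRUE)
  )
}

#' Load and validate a configuration
#'
#' Starts from [default_config()], overlays an optional YAML file and an
#' optional list of overrides (nested, same shape as the defaults), and
#' validates every value. Unknown keys are rejected.
#'
#' @param path optional path to a YAML configuration file.
#' @param overrides optional nested list of overrides applied after the
#'   file.
#' @return validated configuration list of class `graphlda_config`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    cfg <- .merge_config(cfg, yaml::read_yaml(path), "")
  }
  if (!is.null(overrides)) cfg <- .merge_config(cfg, overrides, "")
  .validate_config(cfg)
  class(cfg) <- c("graphlda_config", "list")
  cfg
}

.merge_config <- function(base, new, prefix) {
  if (length(new) == 0) return(base)
  nms <- names(new)
  if (is.null(nms) || any(nms == "")) {
    stop(sprintf("config section '%s' must be a named mapping",
                 sub("\\.$", "", prefix)))
  }
  for (nm in nms) {
    key <- paste0(prefix, nm)
    if (!nm %in% names(base)) stop(sprintf("unknown config key '%s'", key))
    if (is.list(base[[nm]])) {
      if (!is.list(new[[nm]])) {
        stop(sprintf("config key '%s' must be a section", key))
      }
      base[[nm]] <- .merge_config(base[[nm]], new[[nm]], paste0(key, "."))
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

.validate_config <- function(cfg) {
  fail <- function(key, value, constraint) {
    stop(sprintf("invalid config: %s = %s (%s)", key,
                 paste(format(value), collapse = ","), constraint))
  }
  num_in <- function(key, value, lo, hi, open = FALSE) {
    ok <- is.numeric(value) && length(value) == 1 && is.finite(value) &&
      (if (open) value > lo && value < hi else value >= lo && value <= hi)
    if (!ok) fail(key, value, sprintf("must lie in %s%g, %g%s",
                                      if (open) "(" else "[", lo, hi,
                                      if (open) ")" else "]"))
  }
  pos_int <- function(key, value) {
    if (!is.numeric(value) || length(value) != 1 || value < 1 ||
        value != as.integer(value)) {
      fail(key, value, "must be a positive integer")
    }
  }
  num_in("delta", cfg$delta, 0, 1, open = TRUE)
  pos_int("gcn.layers", cfg$gcn$layers)
  pos_int("gcn.embedding", cfg$gcn$embedding)
  if (!cfg$gcn$hidden_activation %in% c("relu", "softmax", "identity")) {
    fail("gcn.hidden_activation", cfg$gcn$hidden_activation,
         "must be relu, softmax or identity")
  }
  if (!cfg$gcn$final_activation %in% c("relu", "softmax", "identity")) {
    fail("gcn.final_activation", cfg$gcn$final_activation,
         "must be relu, softmax or identity")
  }
  pos_int("transformer.heads", cfg$transformer$heads)
  pos_int("transformer.layers", cfg$transformer$layers)
  pos_int("transformer.ffn_mult", cfg$transformer$ffn_mult)
  if (cfg$gcn$embedding %% cfg$transformer$heads != 0) {
    fail("transformer.heads", cfg$transformer$heads,
         sprintf("must divide gcn.embedding = %d", cfg$gcn$embedding))
  }
  num_in("transformer.ln_eps", cfg$transformer$ln_eps, 1e-12, 1)
  for (k in c("use_add", "use_norm", "use_ffn")) {
    if (!is.logical(cfg$transformer[[k]]) || length(cfg$transformer[[k]]) != 1) {
      fail(paste0("transformer.", k), cfg$transformer[[k]], "must be TRUE/FALSE")
    }
  }
  num_in("train.lr", cfg$train$lr, 1e-8, 1)
  pos_int("train.epochs", cfg$train$epochs)
  num_in("train.clamp", cfg$train$clamp, 1e-12, 0.1)
  num_in("train.edge_dropout", cfg$train$edge_dropout, 0, 1)
  if (!is.logical(cfg$train$resample_negatives) ||
      length(cfg$train$resample_negatives) != 1) {
    fail("train.resample_negatives", cfg$train$resample_negatives,
         "must be TRUE/FALSE")
  }
  num_in("eval.threshold", cfg$eval$threshold, 0, 1, open = TRUE)
  pos_int("eval.folds", cfg$eval$folds)
  num_in("eval.test_fraction", cfg$eval$test_fraction, 0, 0.9)
  pos_int("eval.repeats", cfg$eval$repeats)
  num_in("eval.negative_ratio", cfg$eval$negative_ratio, 0.1, 100)
  if (!is.logical(cfg$eval$mask) || length(cfg$eval$mask) != 1) {
    fail("eval.mask", cfg$eval$mask, "must be TRUE/FALSE")
  }
  invisible(cfg)
}
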