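# Run configuration. Optimisation defaults are the study hyperparameters
# (Adam, lr 0.001, batch 16, 300 epochs, step-decay schedule, He
# initialization, dropout 0.5); architecture dimensions are package
# defaults, freely reducible for desk-scale runs.

#' Training/evaluation run configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param lr_schedule `"step_decay"` (x `lr_decay_factor` every
#'   `lr_decay_every` epochs) or `"constant"`.
#' @param lr_decay_every,lr_decay_factor step-decay parameters.
#' @param dropout dropout rate in the text encoder and fusion trunk.
#' @param loss_weights named vector `w_ce`, `w_consis`, `w_compl`.
#' @param modality `"both"`, `"image"` or `"text"`.
#' @param consistency_enabled,complementarity_enabled ablation switches for
#'   the two auxiliary losses.
#' @param data_fraction fraction of the training split to use, in `(0,1]`;
#'   subsampling is seeded, stratified by any-positive-label, and nested
#'   across fractions.
#' @param task `"both"`, `"pathology"` or `"location"`.
#' @param max_steps optional cap on total optimization steps (`Inf` =
#'   epochs decide).
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param curvature Poincare-ball curvature magnitude c.
#' @param ball_eps clipping margin for ball points.
#' @param consistency_denominator `"plain"` (cosine) or `"squared"`.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param hidden_channels,n_levels,conv_groups,kernels,strides image-encoder
#'   dimensions.
#' @param embed_dim shared embedding dimension d of both modalities.
#' @param attr_embed_dim,text_hidden text-encoder dimensions.
#' @param fused_channels,ema_groups,tile fused feature layout: the fused
#'   vector of length `fused_channels * tile^2` is viewed as
#'   `(fused_channels, tile, tile)` in `ema_groups` channel groups for the
#'   multi-scale attention.
#' @param kan_hidden hidden width of the two-layer KAN heads.
#' @param eval_every validation-metric evaluation period in epochs.
#' @return A `tongue_run_config` list.
#' @export
runConfig <- function(learning_rate = 0.001, batch_size = 16L, epochs = 300L,
                      lr_schedule = c("step_decay", "constant"),
                      lr_decay_every = 100L, lr_decay_factor = 0.1,
                      dropout = 0.5,
                      loss_weights = c(w_ce = 1, w_consis = 0.5, w_compl = 0.5),
                      modality = c("both", "image", "text"),
                      consistency_enabled = TRUE,
                      complementarity_enabled = TRUE,
                      data_fraction = 1.0,
                      task = c("both", "pathology", "location"),
                      max_steps = Inf, seed = 1L,
                      curvature = 1, ball_eps = 1e-5,
                      consistency_denominator = c("plain", "squared"),
                      grad_clip = 5,
                      hidden_channels = 64L, n_levels = 4L, conv_groups = 4L,
                      kernels = NULL, strides = NULL,
                      embed_dim = 128L, attr_embed_dim = 8L,
                      text_hidden = 128L,
                      fused_channels = 8L, ema_groups = 4L, tile = 4L,
                      kan_hidden = 64L, eval_every = 10L) {
  modality <- match.arg(modality)
  task <- match.arg(task)
  lr_schedule <- match.arg(lr_schedule)
  consistency_denominator <- match.arg(consistency_denominator)
  if (is.null(kernels)) kernels <- rep(3L, n_levels)
  if (is.null(strides)) strides <- c(1L, rep(2L, n_levels - 1L))
  stopifnot(length(kernels) == n_levels, length(strides) == n_levels,
            data_fraction > 0, data_fraction <= 1,
            hidden_channels %% conv_groups == 0L,
            fused_channels %% ema_groups == 0L)
  w <- loss_weights[c("w_ce", "w_consis", "w_compl")]
  stopifnot(!any(is.na(w)))
  structure(list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), lr_schedule = lr_schedule,
    lr_decay_every = as.integer(lr_decay_every),
    lr_decay_factor = lr_decay_factor, dropout = dropout,
    loss_weights = w, modality = modality,
    consistency_enabled = isTRUE(consistency_enabled),
    complementarity_enabled = isTRUE(complementarity_enabled),
    data_fraction = data_fraction, task = task, max_steps = max_steps,
    seed = as.integer(seed), curvature = curvature, ball_eps = ball_eps,
    consistency_denominator = consistency_denominator, grad_clip = grad_clip,
    hidden_channels = as.integer(hidden_channels),
    n_levels = as.integer(n_levels), conv_groups = as.integer(conv_groups),
    kernels = as.integer(kernels), strides = as.integer(strides),
    embed_dim = as.integer(embed_dim),
    attr_embed_dim = as.integer(attr_embed_dim),
    text_hidden = as.integer(text_hidden),
    fused_channels = as.integer(fused_channels),
    ema_groups = as.integer(ema_groups), tile = as.integer(tile),
    kan_hidden = as.integer(kan_hidden), eval_every = as.integer(eval_every)),
    class = "tongue_run_config")
}

#' Reduced test-scale configuration
#'
#' The package's documented desk-scale profile: the same architecture with
#' smaller widths (16 hidden channels over 3 levels, 32-dimensional
#' embeddings, 32-wide KAN hidden layer), suited to CPU runs on the
#' bundled synthetic data.
#'
#' @param ... overrides passed to [runConfig()].
#' @export
toyRunConfig <- function(...) {
  args <- list(hidden_channels = 16L, n_levels = 3L, conv_groups = 4L,
               embed_dim = 32L, text_hidden = 48L, kan_hidden = 32L,
               fused_channels = 8L, eval_every = 1000L, dropout = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(runConfig, args)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [runConfig()] arguments.
#' @return A `tongue_run_config`.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$loss_weights)) vals$loss_weights <- unlist(vals$loss_weights)
  do.call(runConfig, vals)
}
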