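# Training loop: Adam with step-decay schedule, global gradient clipping,
# seeded shuffling, JSON-lines-friendly per-step loss log, periodic
# validation, NaN diagnostics.

adam_state <- function(params)
  lapply(params, function(p) list(m = array(0, dim(p$v) %||% length(p$v)),
                                  v = array(0, dim(p$v) %||% length(p$v)),
                                  t = 0L))

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 0) {
  if (clip > 0) {
    gn2 <- 0
    for (p in params) if (!is.null(p$grad)) gn2 <- gn2 + sum(p$grad^2)
    gn <- sqrt(gn2)
    if (is.finite(gn) && gn > clip)
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * (clip / gn)
  }
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    s <- st[[i]]
    s$t <- s$t + 1L
    s$m <- beta1 * s$m + (1 - beta1) * p$grad
    s$v <- beta2 * s$v + (1 - beta2) * p$grad^2
    mh <- s$m / (1 - beta1^s$t)
    vh <- s$v / (1 - beta2^s$t)
    upd <- lr * mh / (sqrt(vh) + eps)
    dim(upd) <- dim(p$v)
    p$v <- p$v - upd
    st[[i]] <- s
  }
  st
}

#' Train the multimodal model
#'
#' Minibatch Adam on the weighted total loss (cross-entropy plus the
#' consistency and complementarity terms as enabled). Fully seeded:
#' identical config and data give bitwise-identical runs. Training aborts
#' with a diagnostic naming the diverging component if any loss becomes
#' non-finite.
#'
#' @param ds a [TongueDataset-class].
#' @param cfg a [runConfig()] configuration.
#' @param verbose print per-epoch means.
#' @return A [TongueModel-class].
#' @export
trainModel <- function(ds, cfg, verbose = FALSE) {
  set.seed(cfg$seed)
  tr_idx <- splitIdx(ds, "train")
  if (cfg$data_fraction < 1)
    tr_idx <- subsampleStratified(ds, tr_idx, cfg$data_fraction, cfg$seed)
  prior_of <- function(task) {
    pbar <- colMeans(labelMatrix(ds, task)[tr_idx, , drop = FALSE])
    pbar <- pmin(pmax(pbar, 0.02), 0.98)
    log(pbar / (1 - pbar))
  }
  priors <- list(pathology = prior_of("pathology"),
                 location = prior_of("location"))
  net <- net_init(cfg, priors)
  params <- netParameters(net)
  st <- adam_state(params)
  sidx <- if (cfg$modality != "image") dataset_text_indices(ds) else NULL
  n <- length(tr_idx)
  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  log_rows <- list()
  val_rows <- list()
  step <- 0L
  lr <- cfg$learning_rate
  model_env <- new.env(parent = emptyenv())
  for (ep in seq_len(cfg$epochs)) {
    if (cfg$lr_schedule == "step_decay")
      lr <- cfg$learning_rate *
        cfg$lr_decay_factor^((ep - 1L) %/% cfg$lr_decay_every)
    ord <- tr_idx[sample.int(n)]
    for (bi in seq_len(steps_per_epoch)) {
      take <- ord[((bi - 1L) * cfg$batch_size + 1L):
                    min(bi * cfg$batch_size, n)]
      if (length(take) < 2L) next
      bt <- batch_tensors(ds, take, cfg, sidx)
      ls <- tryCatch({
        fw <- net_forward(net, cfg, bt$imgs, bt$text_idx, training = TRUE)
        net_loss(net, cfg, fw, bt$y_path, bt$y_loc)
      }, error = function(e) {
        bad <- any(vapply(params, function(p)
          any(!is.finite(p$v)) || max(abs(p$v)) > 1e50, logical(1)))
        if (bad)
          stop("training diverged at step ", step + 1L,
               ": non-finite or runaway parameters (check the learning rate)",
               call. = FALSE)
        stop(e)
      })
      comp <- c(total = ag_value(ls$total),
                ce = ag_value(ls$ce),
                consis = if (is.null(ls$consis)) 0 else ag_value(ls$consis),
                compl = if (is.null(ls$compl)) 0 else ag_value(ls$compl))
      if (any(!is.finite(comp))) {
        bad <- names(comp)[!is.finite(comp)][1]
        stop("training diverged at step ", step + 1L,
             ": loss component '", bad, "' is non-finite")
      }
      ag_zero_grad(params)
      ag_backward(ls$total)
      st <- adam_step(params, st, lr, clip = cfg$grad_clip)
      step <- step + 1L
      log_rows[[step]] <- c(step = step, epoch = ep, comp)
      if (step >= cfg$max_steps) break
    }
    if (verbose) {
      ep_rows <- do.call(rbind, log_rows)
      ep_mask <- ep_rows[, "epoch"] == ep
      message(sprintf("epoch %d: total %.4f ce %.4f", ep,
                      mean(ep_rows[ep_mask, "total"]),
                      mean(ep_rows[ep_mask, "ce"])))
    }
    if (ep %% cfg$eval_every == 0L && length(splitIdx(ds, "val"))) {
      tmp <- new("TongueModel", net = net, config = unclass(cfg),
                 log = data.frame(), val = data.frame())
      vm <- evaluateModel(tmp, ds, "val")
      f1s <- vapply(vm, function(r) r$f1, numeric(1))
      val_rows[[length(val_rows) + 1L]] <-
        c(epoch = ep, macro_f1 = mean(f1s))
    }
    if (step >= cfg$max_steps) break
  }
  logdf <- as.data.frame(do.call(rbind, log_rows))
  valdf <- if (length(val_rows)) as.data.frame(do.call(rbind, val_rows))
           else data.frame()
  new("TongueModel", net = net, config = unclass(cfg), log = logdf,
      val = valdf)
}

#' Seeded stratified training subsample
#'
#' Draws a nested fraction of the ids: the subsample at a smaller fraction
#' is contained in that at any larger fraction (ids are ranked by a seeded
#' random priority within strata defined by any-positive-label).
#'
#' @param ds dataset; `idx` candidate row ids; `fraction` in (0,1];
#'   `seed` integer.
#' @param idx,fraction,seed see above.
#' @return Subset of `idx`.
#' @export
subsampleStratified <- function(ds, idx, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(idx)
  any_pos <- rowSums(labelMatrix(ds, "pathology")[idx, , drop = FALSE]) > 0
  set.seed(seed + 104729L)
  prio <- stats::runif(length(idx))
  keep <- logical(length(idx))
  for (s in unique(any_pos)) {
    grp <- which(any_pos == s)
    k <- max(1L, round(fraction * length(grp)))
    keep[grp[order(prio[grp])][seq_len(k)]] <- TRUE
  }
  sort(idx[keep])
}

#' Evaluate a trained model on one split
#'
#' @param model a [TongueModel-class].
#' @param ds a [TongueDataset-class].
#' @param split `"train"`, `"val"` or `"test"`.
#' @param tasks tasks to report (default from the model's config).
#' @return Named list of [metricsReport()] results, one per task, each with
#'   keys `acc`, `precision`, `recall`, `f1`, `map`, `auc`.
#' @export
evaluateModel <- function(model, ds, split = "test", tasks = NULL) {
  cfg <- model@config
  if (is.null(tasks))
    tasks <- switch(cfg$task, both = c("pathology", "location"),
                    pathology = "pathology", location = "location")
  idx <- splitIdx(ds, split)
  if (!length(idx)) stop("split '", split, "' is empty")
  pr <- predictModel(model, ds, idx)
  out <- lapply(tasks, function(tk)
    metricsReport(pr[[tk]], labelMatrix(ds, tk)[idx, , drop = FALSE]))
  names(out) <- tasks
  out
}
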