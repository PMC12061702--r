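# Experiment protocols: loss-term ablations, data-fraction learning curves,
# and unimodal-vs-multimodal comparison.

run_and_report <- function(ds, cfg, split = "test") {
  m <- trainModel(ds, cfg)
  ev <- evaluateModel(m, ds, split)
  data.frame(task = names(ev),
             acc = vapply(ev, function(r) r$acc, numeric(1)),
             precision = vapply(ev, function(r) r$precision, numeric(1)),
             recall = vapply(ev, function(r) r$recall, numeric(1)),
             f1 = vapply(ev, function(r) r$f1, numeric(1)),
             map = vapply(ev, function(r) r$map, numeric(1)),
             auc = vapply(ev, function(r) r$auc, numeric(1)),
             row.names = NULL)
}

#' Loss-term ablation grid
#'
#' Trains the four configurations (a) neither auxiliary loss, (b)
#' consistency only, (c) complementarity only, (d) both, with shared seeds,
#' and reports the six evaluation metrics per configuration and task.
#'
#' @param ds a [TongueDataset-class].
#' @param cfg base [runConfig()]; its ablation flags are overridden.
#' @param seeds integer vector of seeds (runs are repeated and averaged
#'   per configuration when several are given).
#' @param split evaluation split.
#' @return data.frame with columns `config`, `consistency`,
#'   `complementarity`, `seed`, `task` and the six metrics.
#' @export
runAblationGrid <- function(ds, cfg, seeds = cfg$seed, split = "test") {
  grid <- data.frame(config = c("a", "b", "c", "d"),
                     consistency = c(FALSE, TRUE, FALSE, TRUE),
                     complementarity = c(FALSE, FALSE, TRUE, TRUE))
  out <- list()
  for (s in seeds) for (i in seq_len(nrow(grid))) {
    ci <- cfg
    ci$consistency_enabled <- grid$consistency[i]
    ci$complementarity_enabled <- grid$complementarity[i]
    ci$seed <- as.integer(s)
    rep_ <- run_and_report(ds, ci, split)
    rep_$config <- grid$config[i]
    rep_$consistency <- grid$consistency[i]
    rep_$complementarity <- grid$complementarity[i]
    rep_$seed <- s
    out[[length(out) + 1L]] <- rep_
  }
  do.call(rbind, out)
}

#' Data-fraction learning curve
#'
#' Trains on nested seeded subsamples of the training split (25% of the
#' data is contained in the 50% subsample, and so on) and evaluates each
#' run; optionally repeats with the auxiliary losses disabled.
#'
#' @param ds a [TongueDataset-class].
#' @param cfg base configuration.
#' @param fractions data fractions in (0, 1].
#' @param seeds integer seeds.
#' @param with_constraints_off also run each fraction with both auxiliary
#'   losses disabled.
#' @param split evaluation split.
#' @return data.frame with `fraction`, `constraints`, `seed`, `task` and
#'   the six metrics.
#' @export
runFractionExperiment <- function(ds, cfg, fractions = c(0.25, 0.5, 1.0),
                                  seeds = cfg$seed,
                                  with_constraints_off = FALSE,
                                  split = "test") {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  modes <- if (with_constraints_off) c(TRUE, FALSE) else TRUE
  out <- list()
  for (s in seeds) for (fr in fractions) for (on in modes) {
    ci <- cfg
    ci$data_fraction <- fr
    ci$seed <- as.integer(s)
    ci$consistency_enabled <- on
    ci$complementarity_enabled <- on
    rep_ <- run_and_report(ds, ci, split)
    rep_$fraction <- fr
    rep_$constraints <- if (on) "on" else "off"
    rep_$seed <- s
    out[[length(out) + 1L]] <- rep_
  }
  do.call(rbind, out)
}

#' Unimodal vs multimodal comparison
#'
#' Trains image-only, text-only and image+text models under otherwise
#' identical configurations and reports the six metrics for each.
#'
#' @param ds a [TongueDataset-class].
#' @param cfg base configuration.
#' @param seeds integer seeds.
#' @param split evaluation split.
#' @return data.frame with `modality`, `seed`, `task` and the six metrics.
#' @export
runModalityComparison <- function(ds, cfg, seeds = cfg$seed, split = "test") {
  out <- list()
  for (s in seeds) for (mo in c("image", "text", "both")) {
    ci <- cfg
    ci$modality <- mo
    ci$seed <- as.integer(s)
    rep_ <- run_and_report(ds, ci, split)
    rep_$modality <- mo
    rep_$seed <- s
    out[[length(out) + 1L]] <- rep_
  }
  do.call(rbind, out)
}
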