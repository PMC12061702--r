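# Training loop, determinism, ablation identities, evaluation schema.

tiny_ds <- function(n = 48L, seed = 31L, ...) {
  buildDataset(generatorConfig(n_samples = n, image_size = 16L,
                               effect_size = 2, cross_modal_agreement = 1,
                               seed = seed, ...))
}

tiny_cfg <- function(...) {
  tonguenet:::toyRunConfig(hidden_channels = 8L, n_levels = 2L,
                           conv_groups = 2L, embed_dim = 8L,
                           text_hidden = 16L, attr_embed_dim = 4L,
                           kan_hidden = 8L, fused_channels = 4L,
                           ema_groups = 2L, strides = c(1L, 2L), ...)
}

test_that("training is bitwise reproducible under a fixed seed", {
  ds <- tiny_ds()
  cfg <- tiny_cfg(max_steps = 8L, epochs = 4L, seed = 5L, dropout = 0.3)
  m1 <- trainModel(ds, cfg)
  m2 <- trainModel(ds, cfg)
  expect_identical(trainingLog(m1)$total, trainingLog(m2)$total)
  expect_equal(tail(trainingLog(m1)$total, 1), tail(trainingLog(m2)$total, 1),
               tolerance = 1e-6)
  p1 <- predictModel(m1, ds, 1:4)
  p2 <- predictModel(m2, ds, 1:4)
  expect_identical(p1, p2)
})

test_that("disabling both auxiliary losses reduces the trace to pure BCE", {
  ds <- tiny_ds()
  cfg <- tiny_cfg(max_steps = 10L, epochs = 4L, seed = 2L,
                  consistency_enabled = FALSE, complementarity_enabled = FALSE)
  m <- trainModel(ds, cfg)
  lg <- trainingLog(m)
  expect_equal(lg$total, lg$ce, tolerance = 1e-12)
  expect_true(all(lg$consis == 0))
  expect_true(all(lg$compl == 0))
  # identical trace when the same ablation is expressed through zero weights
  cfg2 <- tiny_cfg(max_steps = 10L, epochs = 4L, seed = 2L,
                   loss_weights = c(w_ce = 1, w_consis = 0, w_compl = 0))
  m2 <- trainModel(ds, cfg2)
  expect_equal(lg$total, trainingLog(m2)$total, tolerance = 1e-12)
})

test_that("training loss decreases on an easy synthetic set", {
  ds <- tiny_ds(n = 96L, seed = 13L)
  cfg <- tiny_cfg(max_steps = 60L, epochs = 12L, seed = 1L,
                  consistency_enabled = FALSE, complementarity_enabled = FALSE)
  m <- trainModel(ds, cfg)
  lg <- trainingLog(m)
  first <- mean(lg$total[lg$epoch <= 2])
  last <- mean(lg$total[lg$epoch >= max(lg$epoch) - 1])
  expect_lt(last, first)
})

test_that("evaluation reports the six-metric schema and sane null behaviour", {
  ds <- tiny_ds(n = 60L, seed = 41L)
  cfg <- tiny_cfg(max_steps = 2L, epochs = 1L, seed = 3L)
  m <- trainModel(ds, cfg)
  ev <- evaluateModel(m, ds, "test")
  expect_named(ev, c("pathology", "location"))
  for (r in ev) {
    expect_true(all(c("acc", "precision", "recall", "f1", "map", "auc")
                    %in% names(r)))
    expect_true(all(unlist(r[c("acc", "precision", "recall", "f1", "map")])
                    >= 0))
  }
  # near-untrained model on balanced-ish labels: AUC close to chance
  set.seed(44)
  sc <- matrix(runif(300), 100)
  y <- matrix(rbinom(300, 1, 0.5), 100)
  rep_ <- metricsReport(sc, y)
  expect_lt(abs(rep_$auc - 0.5), 0.07)
})

test_that("overfitting a memorized set ranks train above validation", {
  ds <- tiny_ds(n = 72L, seed = 51L)
  cfg <- tiny_cfg(max_steps = 80L, epochs = 16L, seed = 6L,
                  consistency_enabled = FALSE, complementarity_enabled = FALSE)
  m <- trainModel(ds, cfg)
  tr <- evaluateModel(m, ds, "train")
  va <- evaluateModel(m, ds, "val")
  expect_gte(mean(c(tr$pathology$f1, tr$location$f1)) + 1e-9,
             mean(c(va$pathology$f1, va$location$f1)))
})

test_that("image-only training never reads the text records", {
  ds <- tiny_ds(n = 48L, seed = 61L)
  # scramble all text; an image-only run must be unaffected
  ds2 <- ds
  txt <- textRecords(ds2)
  txt[] <- "garbled"
  ds2@text <- txt
  cfg <- tiny_cfg(max_steps = 6L, epochs = 2L, seed = 9L, modality = "image")
  m1 <- trainModel(ds, cfg)
  m2 <- trainModel(ds2, cfg)
  expect_identical(trainingLog(m1)$total, trainingLog(m2)$total)
  expect_identical(predictModel(m1, ds, 1:5), predictModel(m2, ds2, 1:5))
})

test_that("stratified subsampling is seeded, sized, and nested", {
  ds <- tiny_ds(n = 80L, seed = 71L)
  idx <- splitIdx(ds, "train")
  s25 <- subsampleStratified(ds, idx, 0.25, seed = 4L)
  s50 <- subsampleStratified(ds, idx, 0.50, seed = 4L)
  s100 <- subsampleStratified(ds, idx, 1.0, seed = 4L)
  expect_true(all(s25 %in% s50))
  expect_true(all(s50 %in% s100))
  expect_equal(s100, idx)
  expect_equal(s25, subsampleStratified(ds, idx, 0.25, seed = 4L))
  expect_lt(abs(length(s50) - 0.5 * length(idx)), 2)
})

test_that("experiment grids have the contracted shape", {
  ds <- tiny_ds(n = 48L, seed = 81L)
  cfg <- tiny_cfg(max_steps = 2L, epochs = 1L, seed = 1L)
  ab <- runAblationGrid(ds, cfg)
  expect_equal(nrow(ab), 8L)  # 4 configs x 2 tasks
  expect_setequal(unique(ab$config), c("a", "b", "c", "d"))
  expect_equal(unique(ab[ab$config == "d", c("consistency", "complementarity")]),
               data.frame(consistency = TRUE, complementarity = TRUE,
                          row.names = 7L))
  fr <- runFractionExperiment(ds, cfg, fractions = c(0.5, 1.0))
  expect_equal(nrow(fr), 4L)
  mo <- runModalityComparison(ds, cfg)
  expect_setequal(unique(mo$modality), c("image", "text", "both"))
  expect_equal(nrow(mo), 6L)
  # fraction 1.0 equals a direct run with the same seed
  direct <- tonguenet:::run_and_report(ds, cfg)
  expect_equal(fr[fr$fraction == 1, c("acc", "f1", "auc")],
               direct[, c("acc", "f1", "auc")], ignore_attr = TRUE)
})

test_that("non-finite losses abort with a component diagnostic", {
  ds <- tiny_ds(n = 48L, seed = 91L)
  cfg <- tiny_cfg(max_steps = 5L, epochs = 2L, seed = 1L,
                  learning_rate = 1e200, grad_clip = 0)
  expect_error(trainModel(ds, cfg), "non-finite|diverged")
})
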