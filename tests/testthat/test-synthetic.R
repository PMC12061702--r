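# Synthetic dataset generator: labels, images, text, annotators, splits.

test_that("label sampling respects prevalence and the healthy rule", {
  cfg <- generatorConfig(n_samples = 10000L, seed = 2L)
  set.seed(2)
  lab <- sampleLabels(cfg)
  expect_equal(dim(lab$pathology), c(10000L, 10L))
  expect_equal(dim(lab$location), c(10000L, 9L))
  # healthy samples carry no pathology
  healthy <- lab$location[, "healthy"] == 1
  expect_true(all(lab$pathology[healthy, ] == 0))
  # empirical prevalence within 3 binomial SE (healthy-driven zeroing aside,
  # check the location labels and the conditional pathology rate)
  for (j in 1:8) {
    p <- cfg$location_prevalence[j]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(lab$location[, j]) - p), 3 * se)
  }
  pat_rate <- colMeans(lab$pathology[!healthy, , drop = FALSE])
  for (j in 1:10) {
    p <- cfg$pathology_prevalence[j]
    se <- sqrt(p * (1 - p) / sum(!healthy))
    expect_lt(abs(pat_rate[j] - p), 3 * se)
  }
})

test_that("rendered images are deterministic and label-separable", {
  cfg <- generatorConfig(image_size = 32L, effect_size = 1, seed = 9L)
  p0 <- rep(0L, 10); l0 <- rep(0L, 9)
  img1 <- renderImage(p0, l0, cfg, seed = 5)
  img2 <- renderImage(p0, l0, cfg, seed = 5)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(3L, 32L, 32L))
  expect_true(all(img1 >= 0 & img1 <= 1))
  # heat raises the red channel mean (n images per side, 3 SE separation)
  heat <- p0; heat[4] <- 1L
  red_on <- red_off <- numeric(40)
  for (i in 1:40) {
    red_on[i] <- mean(renderImage(heat, l0, cfg, seed = i)[1, , ])
    red_off[i] <- mean(renderImage(p0, l0, cfg, seed = 1000 + i)[1, , ])
  }
  se <- sqrt(var(red_on) / 40 + var(red_off) / 40)
  expect_gt(mean(red_on) - mean(red_off), 3 * se)
  # effect_size = 0 removes the separation
  cfg0 <- generatorConfig(image_size = 32L, effect_size = 0, seed = 9L)
  for (i in 1:40) {
    red_on[i] <- mean(renderImage(heat, l0, cfg0, seed = i)[1, , ])
    red_off[i] <- mean(renderImage(p0, l0, cfg0, seed = 1000 + i)[1, , ])
  }
  se0 <- sqrt(var(red_on) / 40 + var(red_off) / 40)
  expect_lt(abs(mean(red_on) - mean(red_off)), 3 * se0)
})

test_that("label-appearance separation grows with effect size", {
  p0 <- rep(0L, 10); l0 <- rep(0L, 9)
  heat <- p0; heat[4] <- 1L
  sep <- vapply(c(0.5, 1, 2), function(es) {
    cfg <- generatorConfig(image_size = 24L, effect_size = es, seed = 3L)
    d <- numeric(25)
    for (i in 1:25)
      d[i] <- mean(renderImage(heat, l0, cfg, seed = i)[1, , ]) -
        mean(renderImage(p0, l0, cfg, seed = 500 + i)[1, , ])
    mean(d)
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("text records track labels exactly at full agreement", {
  cfg <- generatorConfig(cross_modal_agreement = 1, seed = 4L)
  p <- rep(0L, 10); p[4] <- 1L   # heat
  l <- rep(0L, 9); l[7] <- 1L    # heart
  rec <- renderText(p, l, cfg, seed = 1)
  expect_equal(unname(rec["red_body"]), "present")
  expect_equal(unname(rec["tip_red_points"]), "present")
  expect_equal(unname(rec["pale_blue_body"]), "absent")
  expect_identical(rec, renderText(p, l, cfg, seed = 1))
  # agreement 1/k makes attributes independent of labels
  cfg0 <- generatorConfig(cross_modal_agreement = 0.5, seed = 4L)
  n <- 4000
  vals <- character(n); labs <- integer(n)
  for (i in 1:n) {
    pi_ <- rep(0L, 10); pi_[4] <- rbinom(1, 1, 0.5)
    labs[i] <- pi_[4]
    vals[i] <- renderText(pi_, l, cfg0, seed = i)["red_body"]
  }
  # plug-in mutual information close to zero
  tab <- table(vals, labs) / n
  mi <- 0
  for (a in rownames(tab)) for (b in colnames(tab)) {
    pxy <- tab[a, b]
    if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(tab[a, ]) * sum(tab[, b])))
  }
  expect_lt(mi, 0.002)
})

test_that("annotator simulation matches the exact unanimity probability", {
  set.seed(70)
  truth <- matrix(rbinom(500 * 19, 1, 0.3), 500)
  ann0 <- simulateAnnotators(truth, 0, seed = 1)
  expect_identical(ann0$a1, truth)
  expect_true(all(consensusFilter(ann0$a1, ann0$a2, ann0$a3)))
  # error 0.05: retained fraction within 3 SE of ((1-e)^3 + e^3)^L
  n <- 10000L
  truth2 <- matrix(rbinom(n * 19, 1, 0.3), n)
  ann <- simulateAnnotators(truth2, 0.05, seed = 2)
  kept <- mean(consensusFilter(ann$a1, ann$a2, ann$a3))
  p_exact <- unanimityProbability(0.05, 19)
  se <- sqrt(p_exact * (1 - p_exact) / n)
  expect_lt(abs(kept - p_exact), 3 * se)
  # pairwise kappa decreases with the error rate
  ks <- vapply(c(0, 0.1, 0.3), function(e) {
    a <- simulateAnnotators(truth, e, seed = 3)
    cohensKappa(a$a1, a$a2)
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("dataset build is reproducible with correct splits and files", {
  cfg <- generatorConfig(n_samples = 100L, image_size = 20L, seed = 8L)
  d1 <- tempfile(); d2 <- tempfile()
  ds1 <- buildDataset(cfg, d1)
  ds2 <- buildDataset(cfg, d2)
  counts <- table(manifest(ds1)$split)
  expect_equal(as.vector(counts[c("train", "val", "test")]), c(70, 15, 15))
  # byte-identical outputs from identical seeds
  expect_identical(readLines(file.path(d1, "manifest.jsonl")),
                   readLines(file.path(d2, "manifest.jsonl")))
  h1 <- tools::md5sum(list.files(file.path(d1, "images"), full.names = TRUE))
  h2 <- tools::md5sum(list.files(file.path(d2, "images"), full.names = TRUE))
  expect_identical(unname(h1), unname(h2))
  # round trip through the manifest reader
  back <- readDataset(d1)
  expect_equal(labelMatrix(back, "pathology"), labelMatrix(ds1, "pathology"))
  expect_equal(labelMatrix(back, "location"), labelMatrix(ds1, "location"))
  expect_equal(textRecords(back), textRecords(ds1))
  expect_equal(manifest(back), manifest(ds1))
  # PNG round trip preserves images to 8-bit precision
  imgs <- datasetImages(back, 1:3)
  for (i in 1:3)
    expect_lt(max(abs(imgs[[i]] - ds1@images[[i]])), 1 / 255)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("split rounding follows the documented round() rule", {
  cfg <- generatorConfig(n_samples = 4815L, image_size = 16L, seed = 1L)
  n_train <- round(0.70 * 4815); n_val <- round(0.15 * 4815)
  expect_equal(n_train, 3370)
  expect_equal(n_val, 722)
  expect_equal(4815 - n_train - n_val, 723)
})

test_that("text-only signal supports classification iff attributes are informative", {
  # logistic probe on the vectorized text, label 'heat'
  probe_auc <- function(agreement) {
    cfg <- generatorConfig(n_samples = 600L, image_size = 16L,
                           cross_modal_agreement = agreement, seed = 21L)
    set.seed(21)
    lab <- sampleLabels(cfg)
    X <- matrix(0, 600, 19)
    for (i in 1:600)
      X[i, ] <- vectorizeText(renderText(lab$pathology[i, ], lab$location[i, ],
                                         cfg, seed = i), textSchema())
    y <- lab$pathology[, "heat"]
    tr <- 1:400; te <- 401:600
    fit <- suppressWarnings(glm(y[tr] ~ X[tr, ], family = binomial()))
    sc <- cbind(1, X[te, ]) %*% coef(fit)
    aucScore(as.vector(sc), y[te])
  }
  expect_gt(probe_auc(1), 0.95)
  expect_lt(abs(probe_auc(0.5) - 0.5), 0.07)
})
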