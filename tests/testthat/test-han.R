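# Hierarchical aggregation image encoder.

test_that("receptive field recursion matches printed arithmetic", {
  expect_equal(receptiveField(3L, 1L), 3L)
  expect_equal(receptiveField(c(3, 3, 3), c(1, 1, 1)), c(3L, 5L, 7L))
  expect_equal(receptiveField(c(3, 3), c(2, 2)), c(3L, 7L))
  expect_equal(receptiveField(integer(0), integer(0)), integer(0))
  expect_equal(receptiveField(c(5, 3), c(2, 1)), c(5L, 5L + 2L * 2L))
})

test_that("receptive field agrees with a gradient-support brute-force oracle", {
  # the oracle perturbs single input pixels of a linear conv chain and
  # measures the support of the centre output unit
  support_oracle <- function(kernels, strides) {
    n <- length(kernels)
    S <- 65L
    base <- array(0, c(1L, S, S))
    run <- function(x) {
      z <- x
      for (i in seq_len(n)) {
        w <- array(1, c(1, 1, kernels[i], kernels[i]))
        z <- groupedConv(z, w, stride = strides[i], pad = 0L)
      }
      z
    }
    out0 <- run(base)
    ctr <- (dim(out0)[2] + 1L) %/% 2L
    touched <- 0L
    for (px in seq_len(S)) {
      x <- base; x[1, px, (S + 1L) %/% 2L] <- 1
      if (abs(run(x)[1, ctr, (dim(out0)[3] + 1L) %/% 2L]) > 1e-12)
        touched <- touched + 1L
    }
    touched
  }
  configs <- list(list(k = c(3L), s = c(1L)),
                  list(k = c(3L, 3L), s = c(1L, 1L)),
                  list(k = c(3L, 3L), s = c(2L, 1L)),
                  list(k = c(5L, 3L), s = c(1L, 2L)),
                  list(k = c(3L, 3L, 3L), s = c(1L, 2L, 1L)))
  for (cf in configs) {
    rf <- receptiveField(cf$k, cf$s)
    expect_equal(support_oracle(cf$k, cf$s), tail(rf, 1),
                 info = paste("k =", paste(cf$k, collapse = ","),
                              "s =", paste(cf$s, collapse = ",")))
  }
})

test_that("stem projection is a per-pixel linear map", {
  x <- array(runif(1 * 4 * 4), c(1, 4, 4))
  expect_equal(stemProject(x, matrix(1, 1, 1)), x)
  z <- stemProject(array(0, c(3, 4, 4)), matrix(rnorm(6), 2, 3), bias = c(1, -1))
  expect_equal(z[1, , ], matrix(1, 4, 4))
  expect_equal(z[2, , ], matrix(-1, 4, 4))
  set.seed(20)
  x <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  W <- matrix(rnorm(15), 5, 3); b <- rnorm(5)
  z <- stemProject(x, W, b)
  for (i in sample(8, 3)) for (j in sample(8, 3))
    expect_equal(z[, i, j], as.vector(W %*% x[, i, j] + b))
  expect_error(stemProject(x, matrix(numeric(0), 0, 3)), "hidden")
})

test_that("grouped convolution matches hand and nested-loop oracles", {
  # depthwise 3x3 averaging kernel: centre of [[1..9]] -> 5
  x <- array(matrix(1:9, 3, byrow = TRUE), c(1, 3, 3))
  w <- array(1 / 9, c(1, 1, 3, 3))
  z <- groupedConv(x, w, stride = 1L, pad = 1L, groups = 1L)
  expect_equal(z[1, 2, 2], 5.0)
  # stride-2 shape arithmetic
  z2 <- groupedConv(array(rnorm(2 * 8 * 8), c(2, 8, 8)),
                    array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3)),
                    stride = 2L, groups = 2L)
  expect_equal(dim(z2), c(2L, 4L, 4L))
  # random small config vs nested loops
  set.seed(21)
  C <- 4L; H <- 6L; W <- 5L; k <- 3L; groups <- 2L; c_out <- 4L
  x <- array(rnorm(C * H * W), c(C, H, W))
  w <- array(rnorm(c_out * (C / groups) * k * k), c(c_out, C / groups, k, k))
  b <- rnorm(c_out)
  z <- groupedConv(x, w, b, stride = 1L, pad = 1L, groups = groups)
  cg_in <- C / groups; cg_out <- c_out / groups
  for (co in seq_len(c_out)) for (ho in seq_len(H)) for (wo in seq_len(W)) {
    g <- ceiling(co / cg_out)
    acc <- b[co]
    for (ci in seq_len(cg_in)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
      hh <- ho - 2L + kh; ww <- wo - 2L + kw
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        acc <- acc + w[co, ci, kh, kw] * x[(g - 1) * cg_in + ci, hh, ww]
    }
    expect_equal(z[co, ho, wo], acc)
  }
  expect_error(groupedConv(x, w, groups = 3L), "group")
})

test_that("hierarchical encoding chains levels with the nonlinearity", {
  set.seed(22)
  z0 <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  layers <- list(
    list(w = array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3)), groups = 2L),
    list(w = array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3)), groups = 2L,
         stride = 2L)
  )
  zs <- hierarchicalEncode(z0, layers)
  expect_length(zs, 2)
  expect_equal(dim(zs[[1]]), c(2L, 6L, 6L))
  expect_equal(dim(zs[[2]]), c(2L, 3L, 3L))
  raw1 <- groupedConv(z0, layers[[1]]$w, groups = 2L)
  expect_equal(zs[[1]], raw1 * pnorm(raw1))  # GELU applied
})

test_that("global context is the broadcast per-channel mean", {
  z <- array(2.5, c(3, 4, 4))
  expect_equal(globalContext(z), z)
  z2 <- array(0, c(1, 2, 2)); z2[1, , ] <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(globalContext(z2), array(2.5, c(1, 2, 2)))
  set.seed(23)
  z3 <- array(rnorm(3 * 5 * 5), c(3, 5, 5))
  g <- globalContext(z3)
  for (cidx in 1:3)
    expect_equal(g[cidx, 1, 1], sum(z3[cidx, , ]) / 25)
})

test_that("gated aggregation is a softmax-normalized convex combination", {
  set.seed(24)
  d <- c(2L, 4L, 4L)
  z <- array(rnorm(prod(d)), d)
  # identical features at all levels: any gates give back the feature
  res <- gatedAggregate(list(z, z, z), array(rnorm(3 * 16), c(3, 4, 4)))
  expect_equal(res$map, z, tolerance = 1e-12)
  expect_equal(apply(res$gates, c(2, 3), sum), matrix(1, 4, 4),
               tolerance = 1e-6)
  # near-one-hot gate selects one level
  z2 <- array(rnorm(prod(d)), d)
  gl <- array(0, c(2, 4, 4)); gl[1, , ] <- 50
  res2 <- gatedAggregate(list(z, z2), gl)
  expect_equal(res2$map, z, tolerance = 1e-8)
  # random case vs per-pixel weighted-sum oracle
  levels <- list(array(rnorm(prod(d)), d), array(rnorm(prod(d)), d),
                 array(rnorm(prod(d)), d))
  gl3 <- array(rnorm(3 * 16), c(3, 4, 4))
  res3 <- gatedAggregate(levels, gl3)
  for (i in 1:4) for (j in 1:4) {
    wts <- exp(gl3[, i, j]); wts <- wts / sum(wts)
    for (cidx in 1:2)
      expect_equal(res3$map[cidx, i, j],
                   sum(wts * vapply(levels, function(L) L[cidx, i, j],
                                    numeric(1))))
  }
  expect_error(gatedAggregate(list(z, z2), array(0, c(3, 4, 4))), "gate")
})

test_that("aggregation pipeline with symmetric kernels is flip-equivariant", {
  set.seed(25)
  flip <- function(a) a[, , dim(a)[3]:1, drop = FALSE]
  x <- array(runif(3 * 8 * 8), c(3, 8, 8))
  W0 <- matrix(rnorm(6), 2, 3)
  layers <- list(list(w = array(1 / 9, c(2, 1, 3, 3)), groups = 2L),
                 list(w = array(1 / 18, c(2, 1, 3, 3)), groups = 2L))
  run <- function(img) {
    z0 <- stemProject(img, W0)
    zs <- hierarchicalEncode(z0, layers)
    zs <- c(zs, list(globalContext(zs[[2]])))
    # constant gate logits: softmax weights are flip-invariant
    gatedAggregate(zs, array(rep(c(0.3, -0.2, 0.1), 64), c(3, 8, 8)))$map
  }
  expect_equal(run(flip(x)), flip(run(x)), tolerance = 1e-10)
})
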