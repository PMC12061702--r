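# Cross-modal fusion: bridging, three-subspace projection, and multi-scale
# (EMA) grouped attention.
#
# The bridged feature vector is reshaped to a small grouped spatial tile
# (groups, channels-per-group, tile, tile) so the height/width/global
# poolings of the attention are well defined on fused features; each of the
# three subspace projections is reweighted by its own attention, and the
# reweighted subspaces are summed and layer-normalized into the classifier
# input.

#' Per-height channel pooling
#'
#' \eqn{z^H_c(h) = \frac{1}{W}\sum_i x_c(h, i)}: mean over the width axis at
#' every height, per channel.
#'
#' @param x array `(C,H,W)`.
#' @return Matrix `(C,H)`.
#' @export
emaPoolHeight <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  apply(x, c(1, 2), mean)
}

#' Per-width channel pooling
#'
#' \eqn{z^W_c(w) = \frac{1}{H}\sum_j x_c(j, w)}.
#'
#' @param x array `(C,H,W)`.
#' @return Matrix `(C,W)`.
#' @export
emaPoolWidth <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  apply(x, c(1, 3), mean)
}

#' Global channel pooling
#'
#' \eqn{z_c = \frac{1}{HW}\sum_{j,i} x_c(j,i)}.
#'
#' @param x array `(C,H,W)`.
#' @return Numeric vector, one mean per channel.
#' @export
emaPoolGlobal <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  apply(x, 1, mean)
}

#' Cross-modal bridge
#'
#' Concatenates the image and text embeddings and applies an affine map
#' followed by GELU.
#'
#' @param zt,zs embedding vectors (or matrices, one sample per row) of equal
#'   dimension.
#' @param W matrix `(d_f, 2d)`; `b` length `d_f`.
#' @param b bias vector.
#' @return Fused feature vector/matrix.
#' @export
bridgeFeatures <- function(zt, zs, W, b = NULL) {
  one <- is.null(dim(zt))
  zt <- if (one) matrix(zt, 1) else zt
  zs <- if (is.null(dim(zs))) matrix(zs, 1) else zs
  if (!all(dim(zt) == dim(zs))) stop("bridge: dimension mismatch")
  if (is.null(b)) b <- numeric(nrow(W))
  h <- cbind(zt, zs) %*% t(W)
  h <- sweep(h, 2L, b, "+")
  out <- h * stats::pnorm(h)
  if (one) as.vector(out) else out
}

#' Three-subspace projection
#'
#' The three printed affine maps \eqn{F_i = W_i F + b_i}, producing
#' complementary views of the fused feature.
#'
#' @param F fused feature vector (or matrix, samples in rows).
#' @param params list with `W1,W2,W3` (matrices) and `b1,b2,b3`.
#' @return List `F1`, `F2`, `F3`.
#' @export
projectSubspaces <- function(F, params) {
  one <- is.null(dim(F))
  Fm <- if (one) matrix(F, 1) else F
  proj <- function(W, b) {
    out <- sweep(Fm %*% t(W), 2L, b, "+")
    if (one) as.vector(out) else out
  }
  list(F1 = proj(params$W1, params$b1),
       F2 = proj(params$W2, params$b2),
       F3 = proj(params$W3, params$b3))
}

#' Recombine attention-weighted subspaces
#'
#' Element-wise sum of the three reweighted subspace features followed by
#' layer normalization (zero mean, unit variance per sample; no learned
#' affine).
#'
#' @param F1w,F2w,F3w equal-shape vectors or matrices (samples in rows).
#' @param eps variance floor.
#' @return Normalized combined feature, flattened per sample.
#' @export
recombineSubspaces <- function(F1w, F2w, F3w, eps = 1e-5) {
  one <- is.null(dim(F1w))
  s <- F1w + F2w + F3w
  sm <- if (one) matrix(as.vector(s), 1) else {
    d <- dim(s); if (length(d) > 2L) matrix(s, d[1]) else s
  }
  mu <- rowMeans(sm)
  xc <- sm - mu
  v <- rowSums(xc^2) / ncol(sm)
  out <- xc / sqrt(v + eps)
  if (one) as.vector(out) else out
}

# ---- trainable EMA attention --------------------------------------------

ema_init <- function(Cg) {
  list(
    w1 = new_linear(Cg, Cg),                 # shared 1x1 on concatenated zH|zW
    conv3 = new_conv(Cg, Cg, k = 3L),        # 3x3 branch
    w_out = ag_param(0),                     # 1-channel 1x1 on the cross map
    b_out = ag_param(0),
    Cg = Cg
  )
}

ema_params <- function(em)
  c(list(em$w1$W, em$w1$b), em$conv3$W, list(em$conv3$b, em$w_out, em$b_out))

# broadcast helpers over a (N,C,H,W) ag array
ag_bmul_hvec <- function(x, gh) {
  # gh: (N,C,H) broadcast over width
  x <- as_ag(x); gh <- as_ag(gh)
  d <- dim(x$v)
  ge <- array(as.vector(gh$v), d)            # recycles along last (W) axis
  ag_node(x$v * ge, list(x, gh), function(g) {
    dgh <- rowSums(matrix(g * x$v, prod(d[1:3]), d[4]))
    dim(dgh) <- d[1:3]
    list(g * ge, dgh)
  })
}

ag_bmul_wvec <- function(x, gw) {
  # gw: (N,C,W) broadcast over height
  x <- as_ag(x); gw <- as_ag(gw)
  d <- dim(x$v)
  ge <- aperm(array(as.vector(gw$v), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  ag_node(x$v * ge, list(x, gw), function(g) {
    t_ <- aperm(g * x$v, c(1, 2, 4, 3))      # (N,C,W,H)
    dgw <- rowSums(matrix(t_, prod(d[c(1, 2, 4)]), d[3]))
    dim(dgw) <- d[c(1, 2, 4)]
    list(g * ge, dgw)
  })
}

ag_bmul_cvec <- function(x, s) {
  # s: (N,C) broadcast over space
  x <- as_ag(x); s <- as_ag(s)
  d <- dim(x$v)
  ge <- array(as.vector(s$v), d)             # recycles along H,W
  ag_node(x$v * ge, list(x, s), function(g) {
    ds <- rowSums(matrix(g * x$v, d[1] * d[2], d[3] * d[4]))
    dim(ds) <- d[1:2]
    list(g * ge, ds)
  })
}

ag_mean_axis_w <- function(x) {
  # (N,C,H,W) -> (N,C,H)
  x <- as_ag(x)
  d <- dim(x$v)
  xm <- ag_reshape(x, c(d[1] * d[2] * d[3], d[4]))
  ag_reshape(ag_scale(ag_rowsums(xm), 1 / d[4]), d[1:3])
}

ag_mean_axis_h <- function(x) {
  # (N,C,H,W) -> (N,C,W)
  x <- as_ag(x)
  d <- dim(x$v)
  xp <- ag_aperm(x, c(1, 2, 4, 3))
  xm <- ag_reshape(xp, c(d[1] * d[2] * d[4], d[3]))
  ag_reshape(ag_scale(ag_rowsums(xm), 1 / d[3]), d[c(1, 2, 4)])
}

ema_fwd <- function(em, x) {
  # x: ag array (N, Cg, H, W) (group axis already folded into N)
  d <- dim(x$v)
  N <- d[1]; Cg <- d[2]; H <- d[3]; W <- d[4]
  # 1x1 branch: shared transform of concatenated height/width poolings
  zH <- ag_mean_axis_w(x)                         # (N,Cg,H)
  zW <- ag_mean_axis_h(x)                         # (N,Cg,W)
  zHm <- ag_reshape(zH, c(N * Cg, H))
  zWm <- ag_reshape(zW, c(N * Cg, W))
  zc <- ag_concat_cols(list(zHm, zWm))            # (N*Cg, H+W)
  zc3 <- ag_reshape(zc, c(N, Cg, H + W))
  zc3 <- ag_reshape(ag_aperm(zc3, c(1, 3, 2)), c(N * (H + W), Cg))
  tr <- linear_fwd(em$w1, zc3)                    # shared 1x1 over channels
  tr <- ag_aperm(ag_reshape(tr, c(N, H + W, Cg)), c(1, 3, 2))  # (N,Cg,H+W)
  trm <- ag_reshape(tr, c(N * Cg, H + W))
  gh <- ag_sigmoid(ag_reshape(ag_slice_cols(trm, seq_len(H)), c(N, Cg, H)))
  gw <- ag_sigmoid(ag_reshape(ag_slice_cols(trm, H + seq_len(W)), c(N, Cg, W)))
  x1 <- ag_bmul_wvec(ag_bmul_hvec(x, gh), gw)
  # 3x3 branch
  x2 <- conv_fwd(em$conv3, x)
  # cross-dimensional interaction
  s1 <- ag_softmax_rows(ag_spatial_mean(x1))      # (N,Cg)
  s2 <- ag_softmax_rows(ag_spatial_mean(x2))
  y1 <- sum_dim2_ag(ag_bmul_cvec(x2, s1))         # (N,1,H,W)
  y2 <- sum_dim2_ag(ag_bmul_cvec(x1, s2))
  cross <- ag_add(y1, y2)
  pre <- ag_add(ag_mul(cross, em$w_out), em$b_out)
  gate <- ag_sigmoid(pre)
  ag_bmul_channel(x, gate)
}

sum_dim2_ag <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  ag_node(sum_dim2(x$v), list(x), function(g) {
    ge <- array(g[, rep(1L, d[2]), , , drop = FALSE], d)
    list(ge)
  })
}

#' Multi-scale grouped attention reweighting
#'
#' Reweights a grouped feature map with two parallel branches: a shared 1x1
#' transform of the concatenated per-height and per-width poolings whose
#' sigmoid gates modulate the map, and a 3x3 convolution branch; the two
#' branches interact by matrix-multiplying each branch's softmaxed global
#' pooling against the other's spatial features, and the projected
#' interaction map passes through a sigmoid to gate the input. Output shape
#' equals input shape, and all gate activations lie in (0,1).
#'
#' @param x array `(C,H,W)` or `(N,C,H,W)`; `C` must be divisible by
#'   `groups`.
#' @param params parameter list from [emaAttentionParams()].
#' @param groups number of channel sub-groups.
#' @return Reweighted array, same shape as `x`.
#' @export
emaAttention <- function(x, params, groups = 1L) {
  bx <- as_bchw(x)
  d <- dim(bx$x)
  if (d[2] %% groups != 0L) stop("channels not divisible by groups")
  Cg <- d[2] %/% groups
  xg <- fold_groups(ag_const(bx$x), groups)
  em <- list(
    w1 = list(W = ag_const(params$W1), b = ag_const(params$b1)),
    conv3 = local({
      cv <- new_conv(Cg, Cg, k = 3L)
      cv$W[[1]] <- ag_const(matrix(params$w3, Cg, Cg * 9L))
      cv$b <- ag_const(params$b3)
      cv
    }),
    w_out = ag_const(params$w_out), b_out = ag_const(params$b_out)
  )
  out <- unfold_groups(ema_fwd(em, xg), groups, d)
  un_bchw(ag_value(out), bx$batched)
}

#' Zero-initialized parameters for [emaAttention()]
#' @param Cg channels per group.
#' @return List with `W1`, `b1` (shared 1x1), `w3`, `b3` (3x3 branch,
#'   `w3` an `(Cg, Cg, 3, 3)` array), `w_out`, `b_out` (cross projection).
#' @export
emaAttentionParams <- function(Cg) {
  list(W1 = matrix(0, Cg, Cg), b1 = numeric(Cg),
       w3 = array(0, c(Cg, Cg, 3, 3)), b3 = numeric(Cg),
       w_out = 0, b_out = 0)
}

fold_groups <- function(x, G) {
  # (B, G*Cg, H, W) -> (B*G, Cg, H, W); channel index is group-major
  x <- as_ag(x)
  d <- dim(x$v)
  Cg <- d[2] %/% G
  y <- ag_reshape(x, c(d[1], Cg, G, d[3], d[4]))   # c = cg + Cg*(g-1)? no:
  # channel order is group-major (g-1)*Cg + cg, i.e. cg fastest -> correct
  y <- ag_aperm(y, c(1, 3, 2, 4, 5))               # (B, G, Cg, H, W)
  ag_reshape(y, c(d[1] * G, Cg, d[3], d[4]))
}

unfold_groups <- function(x, G, d_orig) {
  x <- as_ag(x)
  d <- dim(x$v)
  Cg <- d[2]
  y <- ag_reshape(x, c(d_orig[1], G, Cg, d[3], d[4]))
  y <- ag_aperm(y, c(1, 3, 2, 4, 5))
  ag_reshape(y, c(d_orig[1], G * Cg, d[3], d[4]))
}
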