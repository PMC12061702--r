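# Hierarchical Aggregation Network (HAN) image encoder.
#
# A 1x1 stem lifts the RGB input into hidden-channel space (Z0); a chain of
# grouped convolutions extracts features at growing receptive fields
# (Z1..ZN); global average pooling of ZN gives a global-context level
# (Z{N+1}). Levels 1..N+1 are resampled to the grid of Z1, a learned gate
# network assigns each pixel a softmax weight over levels, and the gated sum
# sum_l G_l (.) Z_l is pooled and projected to the image embedding.

#' Receptive field sizes of a convolution chain
#'
#' Computes the receptive field at each level of a stacked convolution
#' hierarchy via the recursion
#' \eqn{l(N) = l(N-1) + (k(N)-1)\prod_{i=1}^{N-1} s(i)}.
#'
#' @param kernels integer vector of kernel sizes k(1..N).
#' @param strides integer vector of strides s(1..N) (same length).
#' @param l0 receptive field of the input level (default 1).
#' @return Integer vector l(1..N); empty input gives an empty vector.
#' @examples
#' receptiveField(c(3, 3, 3), c(1, 1, 1))  # 3 5 7
#' @export
receptiveField <- function(kernels, strides, l0 = 1L) {
  stopifnot(length(kernels) == length(strides), l0 >= 1)
  n <- length(kernels)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  l_prev <- as.integer(l0)
  for (i in seq_len(n)) {
    jump <- if (i == 1L) 1L else prod(strides[seq_len(i - 1L)])
    out[i] <- l_prev + (kernels[i] - 1L) * as.integer(jump)
    l_prev <- out[i]
  }
  out
}

as_bchw <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(1L, d); list(x = x, batched = FALSE) }
  else if (length(d) == 4L) list(x = x, batched = TRUE)
  else stop("expected a (C,H,W) or (B,C,H,W) array")
}

un_bchw <- function(x, batched) {
  if (!batched) { d <- dim(x); dim(x) <- d[-1] }
  x
}

#' Pointwise (1x1) stem projection
#'
#' Linear map over channels at every pixel: lifts the input image into
#' hidden-channel space while leaving the spatial grid untouched.
#'
#' @param x array `(C,H,W)` or `(B,C,H,W)`.
#' @param weight matrix `(hidden, C)`.
#' @param bias numeric of length `hidden` (default zeros).
#' @return Array with `hidden` channels, same spatial size.
#' @export
stemProject <- function(x, weight, bias = NULL) {
  if (is.null(dim(weight))) weight <- matrix(weight, 1, 1)
  if (nrow(weight) <= 0) stop("non-positive hidden channel count")
  if (is.null(bias)) bias <- numeric(nrow(weight))
  bx <- as_bchw(x)
  lin <- list(W = ag_const(weight), b = ag_const(bias))
  out <- conv1x1_fwd(lin, ag_const(bx$x))
  un_bchw(ag_value(out), bx$batched)
}

#' Grouped 2-D convolution
#'
#' @param x array `(C,H,W)` or `(B,C,H,W)`.
#' @param w weight array `(c_out, c_in/groups, k, k)`.
#' @param b bias, length `c_out` (default zeros).
#' @param stride,pad convolution stride and zero padding (pad defaults to
#'   `(k-1)/2`, i.e. "same" for stride 1).
#' @param groups number of channel groups; input and output channels must be
#'   divisible by it.
#' @return Convolved array.
#' @export
groupedConv <- function(x, w, b = NULL, stride = 1L, pad = NULL, groups = 1L) {
  bx <- as_bchw(x)
  d <- dim(bx$x)
  dw <- dim(w)
  k <- dw[3]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  c_out <- dw[1]; cg_in <- dw[2]
  if (d[2] %% groups != 0L || c_out %% groups != 0L || d[2] %/% groups != cg_in)
    stop("channel/group mismatch: input ", d[2], " channels, ", groups,
         " groups, weight expects ", cg_in, " per group")
  if (is.null(b)) b <- numeric(c_out)
  cv <- new_conv(d[2], c_out, k = k, stride = stride, pad = pad, groups = groups)
  cg_out <- c_out %/% groups
  for (g in seq_len(groups)) {
    # rows of W[[g]]: output channel; columns ordered (cg_in fastest, kh, kw)
    wg <- w[(g - 1L) * cg_out + seq_len(cg_out), , , , drop = FALSE]
    cv$W[[g]] <- ag_const(matrix(aperm(wg, c(1, 2, 3, 4)), cg_out, cg_in * k * k))
  }
  cv$b <- ag_const(b)
  un_bchw(ag_value(conv_fwd(cv, ag_const(bx$x))), bx$batched)
}

#' Hierarchical grouped-convolution encoding
#'
#' Applies a chain of grouped convolutions (each followed by a pointwise
#' nonlinearity) to the stem output, returning the feature map at every
#' level.
#'
#' @param z0 array `(C,H,W)` or `(B,C,H,W)`, the stem output.
#' @param layers list of layers; each a list with `w` (weight array),
#'   optional `b`, `stride`, `pad`, `groups`, and `activation`
#'   (`"gelu"` or `"identity"`, default `"gelu"`).
#' @return List of feature maps Z1..ZN.
#' @export
hierarchicalEncode <- function(z0, layers) {
  stopifnot(length(layers) >= 1L)
  z <- z0
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    act <- if (is.null(ly$activation)) "gelu" else ly$activation
    z <- groupedConv(z, ly$w, ly$b,
                     stride = if (is.null(ly$stride)) 1L else ly$stride,
                     pad = ly$pad,
                     groups = if (is.null(ly$groups)) 1L else ly$groups)
    if (act == "gelu") z <- z * stats::pnorm(z)
    out[[i]] <- z
  }
  out
}

#' Global context level
#'
#' Per-channel spatial mean of the deepest hierarchical level, broadcast
#' back over the spatial grid so it can enter the gated aggregation as the
#' (N+1)-th level.
#'
#' @param z array `(C,H,W)` or `(B,C,H,W)`.
#' @return Array of the same shape, constant over space per channel.
#' @export
globalContext <- function(z) {
  bx <- as_bchw(z)
  d <- dim(bx$x)
  m <- ag_value(ag_spatial_mean(ag_const(bx$x)))
  out <- ag_value(ag_broadcast_spatial(ag_const(m), d[3], d[4]))
  un_bchw(out, bx$batched)
}

#' Gated aggregation of hierarchical levels
#'
#' Normalizes gate logits with a softmax over the level axis at every pixel
#' and returns the gated sum \eqn{\sum_l G_l \odot Z_l}.
#'
#' @param levels list of feature maps `(C,H,W)` on a common grid.
#' @param gate_logits array `(L,H,W)` with `L = length(levels)`.
#' @return List with `map` (the aggregated `(C,H,W)` map) and `gates`
#'   (the normalized `(L,H,W)` gate array, summing to 1 over levels).
#' @export
gatedAggregate <- function(levels, gate_logits) {
  L <- length(levels)
  d <- dim(levels[[1]])
  for (z in levels) if (!all(dim(z) == d)) stop("levels not on a common grid")
  dg <- dim(gate_logits)
  if (length(dg) != 3L || dg[1] != L || dg[2] != d[2] || dg[3] != d[3])
    stop("gate_logits must be (L,H,W) on the common grid")
  gl <- matrix(gate_logits, L, d[2] * d[3])
  gl <- sweep(gl, 2L, apply(gl, 2L, max), "-")
  e <- exp(gl)
  G <- sweep(e, 2L, colSums(e), "/")
  map <- array(0, d)
  for (l in seq_len(L)) {
    gmap <- array(rep(G[l, ], each = d[1]), d)
    map <- map + gmap * levels[[l]]
  }
  list(map = map, gates = array(t(G), c(d[2], d[3], L)) |>
         aperm(c(3, 1, 2)))
}

# ---- trainable HAN used by the model ------------------------------------

han_init <- function(cfg) {
  C <- cfg$hidden_channels; N <- cfg$n_levels
  list(
    stem = new_linear(3L, C),
    convs = lapply(seq_len(N), function(i)
      new_conv(C, C, k = cfg$kernels[i], stride = cfg$strides[i],
               groups = cfg$conv_groups)),
    gate = new_linear((N + 1L) * C, N + 1L),
    head = new_linear(C * 16L, cfg$embed_dim)
  )
}

han_params <- function(h)
  c(list(h$stem$W, h$stem$b),
    unlist(lapply(h$convs, function(cv) c(cv$W, list(cv$b))), recursive = FALSE),
    list(h$gate$W, h$gate$b, h$head$W, h$head$b))

han_fwd <- function(h, x, cfg) {
  # x: ag array (B, 3, H, W) -> embedding (B, d)
  z <- conv1x1_fwd(h$stem, x)
  N <- cfg$n_levels
  levels <- vector("list", N + 1L)
  for (i in seq_len(N)) {
    z <- ag_gelu(conv_fwd(h$convs[[i]], z))
    levels[[i]] <- z
  }
  grid <- dim(levels[[1]]$v)[3:4]
  gap <- ag_spatial_mean(levels[[N]])
  levels[[N + 1L]] <- ag_broadcast_spatial(gap, grid[1], grid[2])
  for (i in seq_len(N)) levels[[i]] <- ag_resample(levels[[i]], grid[1], grid[2])
  cat_ <- ag_concat_dim2(levels)
  glog <- conv1x1_fwd(h$gate, cat_)            # (B, N+1, H, W)
  d <- dim(glog$v)
  gm <- ag_reshape(ag_aperm(glog, c(1, 3, 4, 2)), c(d[1] * d[3] * d[4], N + 1L))
  gsm <- ag_softmax_rows(gm)
  agg <- NULL
  for (l in seq_len(N + 1L)) {
    gl <- ag_reshape(ag_slice_cols(gsm, l), c(d[1], 1L, d[3], d[4]))
    term <- ag_bmul_channel(levels[[l]], gl)
    agg <- if (is.null(agg)) term else ag_add(agg, term)
  }
  # coarse 4x4 mean-pool preserves tongue-region topography (tip/sides/
  # centre/root) that a global pooling would erase
  pooled <- ag_pool_grid(agg, 4L, 4L)
  d2 <- dim(pooled$v)
  linear_fwd(h$head, ag_reshape(ag_aperm(pooled, c(1, 3, 4, 2)),
                                c(d2[1], d2[2] * 16L)))
}

ag_softmax_rows <- function(x) {
  x <- as_ag(x)
  m <- x$v
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  s <- e / rowSums(e)
  ag_node(s, list(x), function(g) {
    dots <- rowSums(g * s)
    list(s * (g - dots))
  })
}
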