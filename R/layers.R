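# Layer parameter containers and shared array machinery.
#
# Feature maps are arrays with dim (B, C, H, W). Convolutions are expressed
# as index gathers (im2col) followed by matrix products, so the autodiff
# engine needs no convolution-specific backward pass. Gather index tables
# depend only on shapes and are cached per layer.

he_init <- function(n_out, n_in, fan_in = n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / fan_in)), n_out, n_in)
}

new_linear <- function(n_in, n_out) {
  list(W = ag_param(he_init(n_out, n_in)), b = ag_param(numeric(n_out)))
}

linear_fwd <- function(lin, x) {
  # x: (n, n_in) ag matrix
  ag_add_bias(ag_matmul(x, ag_node(t(lin$W$v), list(lin$W),
                                   function(g) list(t(g)))), lin$b)
}

# -- im2col index table ----------------------------------------------------

conv_index_key <- function(d, k, stride, pad, groups)
  paste(c(d, k, stride, pad, groups), collapse = "_")

make_conv_indices <- function(d, k, stride, pad, groups) {
  # d = dim(x) = (B, C, H, W). Returns list(idx = list per group of
  # (B*Pout x Cg*k*k) integer matrices, Ho, Wo).
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Cg <- C %/% groups
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  P <- Ho * Wo
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  # source upper-left corners
  h0 <- (ho - 1L) * stride - pad
  w0 <- (wo - 1L) * stride - pad
  kh <- rep(seq_len(k), times = k)
  kw <- rep(seq_len(k), each = k)
  idx_groups <- vector("list", groups)
  b_off <- seq_len(B)                     # fastest axis of (B,C,H,W)
  for (g in seq_len(groups)) {
    cset <- (g - 1L) * Cg + seq_len(Cg)
    # columns ordered (cg fastest, then kh, then kw)
    M <- matrix(0L, B * P, Cg * k * k)
    col <- 0L
    for (kk in seq_len(k * k)) {
      hh <- h0 + kh[kk]                    # length P
      ww <- w0 + kw[kk]
      ok <- hh >= 1L & hh <= H & ww >= 1L & ww <= W
      base <- (hh - 1L) + H * (ww - 1L)    # spatial offset, length P
      for (cg in seq_len(Cg)) {
        col2 <- (kk - 1L) * Cg + cg
        lin <- B * ((cset[cg] - 1L) + C * base)  # length P
        full <- outer(b_off, lin, "+")           # (B, P)
        full[, !ok] <- 0L
        M[, col2] <- as.integer(full)
      }
    }
    idx_groups[[g]] <- M
  }
  n <- prod(d)
  plans <- lapply(idx_groups, function(M) {
    i2 <- as.vector(M); i2[i2 == 0L] <- n + 1L
    make_scatter_plan(i2)
  })
  list(idx = idx_groups, plans = plans, Ho = Ho, Wo = Wo)
}

new_conv <- function(c_in, c_out, k = 3L, stride = 1L, pad = NULL,
                     groups = 1L) {
  if (c_in %% groups != 0L || c_out %% groups != 0L)
    stop("channel counts must be divisible by groups")
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  cg_in <- c_in %/% groups
  cg_out <- c_out %/% groups
  fan_in <- cg_in * k * k
  Ws <- lapply(seq_len(groups), function(g)
    ag_param(matrix(stats::rnorm(cg_out * fan_in, sd = sqrt(2 / fan_in)),
                    cg_out, fan_in)))
  list(W = Ws, b = ag_param(numeric(c_out)),
       k = k, stride = stride, pad = pad, groups = groups,
       c_in = c_in, c_out = c_out, cache = new.env(parent = emptyenv()))
}

.conv_cache <- new.env(parent = emptyenv())

conv_fwd <- function(cv, x) {
  # x: ag array (B, C_in, H, W) -> (B, C_out, Ho, Wo)
  x <- as_ag(x)
  d <- dim(x$v)
  key <- conv_index_key(d, cv$k, cv$stride, cv$pad, cv$groups)
  ci <- get0(key, envir = .conv_cache, inherits = FALSE)
  if (is.null(ci)) {
    ci <- make_conv_indices(d, cv$k, cv$stride, cv$pad, cv$groups)
    assign(key, ci, envir = .conv_cache)
  }
  B <- d[1]
  outs <- vector("list", cv$groups)
  for (g in seq_len(cv$groups)) {
    cols <- ag_gather(x, ci$idx[[g]],
                      out_dim = c(nrow(ci$idx[[g]]), ncol(ci$idx[[g]])),
                      plan = ci$plans[[g]])
    Wg <- cv$W[[g]]
    outs[[g]] <- ag_matmul(cols, ag_node(t(Wg$v), list(Wg),
                                         function(g2) list(t(g2))))
  }
  out <- if (cv$groups > 1L) ag_concat_cols(outs) else outs[[1]]
  out <- ag_add_bias(out, cv$b)
  # (B*P, C_out) with rows b-fastest then p (h-fastest) -> (B,Ho,Wo,C) -> BCHW
  out <- ag_reshape(out, c(B, ci$Ho, ci$Wo, cv$c_out))
  ag_aperm(out, c(1, 4, 2, 3))
}

conv1x1_fwd <- function(lin, x) {
  # pointwise conv as a plain linear map over channels; x: (B,C,H,W)
  x <- as_ag(x)
  d <- dim(x$v)
  xp <- ag_aperm(x, c(1, 3, 4, 2))               # (B,H,W,C)
  xm <- ag_reshape(xp, c(d[1] * d[3] * d[4], d[2]))
  ym <- linear_fwd(lin, xm)
  co <- nrow(lin$W$v)
  y <- ag_reshape(ym, c(d[1], d[3], d[4], co))
  ag_aperm(y, c(1, 4, 2, 3))
}

# -- resampling ------------------------------------------------------------

resample_indices <- function(d, Ht, Wt) {
  # bilinear resize (B,C,Hs,Ws) -> (B,C,Ht,Wt); returns idx/weight matrices
  B <- d[1]; C <- d[2]; Hs <- d[3]; Ws <- d[4]
  map1 <- function(nt, ns) {
    pos <- ((seq_len(nt) - 0.5) * ns / nt) - 0.5
    lo <- floor(pos)
    fr <- pos - lo
    lo0 <- pmin(pmax(lo, 0), ns - 1)
    hi0 <- pmin(lo0 + 1, ns - 1)
    fr[lo < 0] <- 0; fr[lo + 1 > ns - 1] <- 0
    list(lo = lo0 + 1, hi = hi0 + 1, fr = fr)
  }
  mh <- map1(Ht, Hs); mw <- map1(Wt, Ws)
  # output order: b fastest, then c, h, w
  n_out <- B * C * Ht * Wt
  bi <- rep(seq_len(B), times = C * Ht * Wt)
  ci <- rep(rep(seq_len(C), each = B), times = Ht * Wt)
  hi <- rep(rep(seq_len(Ht), each = B * C), times = Wt)
  wi <- rep(seq_len(Wt), each = B * C * Ht)
  lin <- function(hsrc, wsrc)
    bi + B * ((ci - 1) + C * ((hsrc - 1) + Hs * (wsrc - 1)))
  h_lo <- mh$lo[hi]; h_hi <- mh$hi[hi]; h_fr <- mh$fr[hi]
  w_lo <- mw$lo[wi]; w_hi <- mw$hi[wi]; w_fr <- mw$fr[wi]
  idx <- cbind(lin(h_lo, w_lo), lin(h_hi, w_lo), lin(h_lo, w_hi), lin(h_hi, w_hi))
  wts <- cbind((1 - h_fr) * (1 - w_fr), h_fr * (1 - w_fr),
               (1 - h_fr) * w_fr, h_fr * w_fr)
  storage.mode(idx) <- "integer"
  n <- prod(d)
  i2 <- as.vector(idx); i2[i2 == 0L] <- n + 1L
  list(idx = idx, w = wts, dim = c(B, C, Ht, Wt),
       plan = make_scatter_plan(i2))
}

.resample_cache <- new.env(parent = emptyenv())

ag_resample <- function(x, Ht, Wt) {
  x <- as_ag(x)
  d <- dim(x$v)
  if (d[3] == Ht && d[4] == Wt) return(x)
  key <- paste(c(d, Ht, Wt), collapse = "_")
  ri <- get0(key, envir = .resample_cache, inherits = FALSE)
  if (is.null(ri)) {
    ri <- resample_indices(d, Ht, Wt)
    assign(key, ri, envir = .resample_cache)
  }
  ag_gather_ws(x, ri$idx, ri$w, out_dim = ri$dim, plan = ri$plan)
}

# block-mean pooling (B,C,H,W) -> (B,C,Ht,Wt) for integer factors;
# falls back to bilinear resampling otherwise
.pool_cache <- new.env(parent = emptyenv())

pool_indices <- function(d, Ht, Wt) {
  B <- d[1]; C <- d[2]; Hs <- d[3]; Ws <- d[4]
  fh <- Hs %/% Ht; fw <- Ws %/% Wt
  K <- fh * fw
  bi <- rep(seq_len(B), times = C * Ht * Wt)
  ci <- rep(rep(seq_len(C), each = B), times = Ht * Wt)
  hi <- rep(rep(seq_len(Ht), each = B * C), times = Wt)
  wi <- rep(seq_len(Wt), each = B * C * Ht)
  idx <- matrix(0L, B * C * Ht * Wt, K)
  k <- 0L
  for (dw in seq_len(fw)) for (dh in seq_len(fh)) {
    k <- k + 1L
    hs <- (hi - 1L) * fh + dh
    ws <- (wi - 1L) * fw + dw
    idx[, k] <- bi + B * ((ci - 1L) + C * ((hs - 1L) + Hs * (ws - 1L)))
  }
  n <- prod(d)
  i2 <- as.vector(idx)
  list(idx = idx, w = matrix(1 / K, nrow(idx), K),
       dim = c(B, C, Ht, Wt), plan = make_scatter_plan(i2))
}

ag_pool_grid <- function(x, Ht, Wt) {
  x <- as_ag(x)
  d <- dim(x$v)
  if (d[3] == Ht && d[4] == Wt) return(x)
  if (d[3] %% Ht != 0L || d[4] %% Wt != 0L) return(ag_resample(x, Ht, Wt))
  key <- paste(c(d, Ht, Wt), collapse = "_")
  ri <- get0(key, envir = .pool_cache, inherits = FALSE)
  if (is.null(ri)) {
    ri <- pool_indices(d, Ht, Wt)
    assign(key, ri, envir = .pool_cache)
  }
  ag_gather_ws(x, ri$idx, ri$w, out_dim = ri$dim, plan = ri$plan)
}

# spatial mean over (H, W): (B,C,H,W) -> (B,C); batch/channel are the two
# fastest axes of the column-major layout, so no transposition is needed
ag_spatial_mean <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  xm <- ag_reshape(x, c(d[1] * d[2], d[3] * d[4]))
  ag_reshape(ag_scale(ag_rowsums(xm), 1 / (d[3] * d[4])), c(d[1], d[2]))
}

# broadcast (B,C) -> (B,C,H,W)
ag_broadcast_spatial <- function(x, H, W) {
  x <- as_ag(x)
  d <- dim(x$v)
  xm <- ag_reshape(x, c(d[1] * d[2], 1))
  y <- ag_matmul(xm, ag_const(matrix(1, 1, H * W)))   # (B*C, H*W)
  ag_reshape(y, c(d[1], d[2], H, W))
}
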