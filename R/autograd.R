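#' @title Reverse-mode automatic differentiation engine
#' @description Internal tape-based autodiff over plain R arrays. Every
#'   differentiable building block of the model (convolutions via im2col,
#'   poolings, attention gates, B-spline edge activations, hyperbolic
#'   distances) is expressed in these primitives, so one engine backs both
#'   the user-facing value-level functions and the trainer.
#' @details Nodes are environments holding a value `v`, an accumulated
#'   gradient `grad`, the parent nodes and a backward closure returning one
#'   gradient per parent. Nodes whose ancestors carry no parameters are
#'   folded to constants eagerly, so forward-only calls pay no tape cost.
#' @name autograd
#' @keywords internal
NULL

.ag <- new.env(parent = emptyenv())
.ag$n <- 0L

ag_node <- function(v, parents = list(), bw = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  req <- any(vapply(parents, function(p) isTRUE(p$req), logical(1)))
  if (length(parents) == 0L || !req) {
    e$req <- FALSE
    e$parents <- list()
    e$bw <- NULL
  } else {
    e$req <- TRUE
    e$parents <- parents
    e$bw <- bw
  }
  .ag$n <- .ag$n + 1L
  e$id <- .ag$n
  class(e) <- "ag_tensor"
  e
}

ag_const <- function(x) ag_node(x)

ag_param <- function(x) {
  e <- ag_node(x)
  e$req <- TRUE
  e$leaf <- TRUE
  e
}

as_ag <- function(x) if (inherits(x, "ag_tensor")) x else ag_const(x)

ag_value <- function(x) if (inherits(x, "ag_tensor")) x$v else x

#' @keywords internal
ag_backward <- function(root) {
  stopifnot(length(root$v) == 1L)
  if (!isTRUE(root$req)) return(invisible(NULL))
  # collect reachable differentiable nodes; a per-call visit stamp on each
  # node avoids interning per-node symbols (R never frees symbols)
  .ag$visit <- (.ag$visit %||% 0L) + 1L
  stamp <- .ag$visit
  nodes <- vector("list", 256L); nn <- 0L
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (identical(nd$.visit, stamp)) next
    nd$.visit <- stamp
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) if (isTRUE(p$req)) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  root$grad <- if (is.null(dim(root$v))) 1 else array(1, dim(root$v))
  for (nd in nodes[ord]) {
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!isTRUE(p$req) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    if (!isTRUE(nd$leaf)) nd$grad <- NULL  # free intermediate grads
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise binary ops (same shape, or one scalar) ----

reduce_like <- function(g, v) {
  # g has shape of the op output; reduce to the shape of operand value v
  if (length(v) == 1L && length(g) > 1L) return(sum(g))
  g
}

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$v + b$v, list(a, b),
          function(g) list(reduce_like(g, a$v), reduce_like(g, b$v)))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$v - b$v, list(a, b),
          function(g) list(reduce_like(g, a$v), reduce_like(-g, b$v)))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$v * b$v, list(a, b),
          function(g) list(reduce_like(g * b$v, a$v), reduce_like(g * a$v, b$v)))
}

ag_scale <- function(a, s) {
  a <- as_ag(a)
  ag_node(a$v * s, list(a), function(g) list(g * s))
}

ag_addc <- function(a, k) {
  a <- as_ag(a)
  ag_node(a$v + k, list(a), function(g) list(g))
}

ag_recip <- function(a) {
  a <- as_ag(a)
  v <- 1 / a$v
  ag_node(v, list(a), function(g) list(-g * v * v))
}

# ---- matrix ops ----

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$v %*% b$v, list(a, b),
          function(g) list(g %*% t(b$v), crossprod(a$v, g)))
}

ag_add_bias <- function(m, b) {
  # m: (n, k) matrix; b: length-k bias broadcast over rows
  m <- as_ag(m); b <- as_ag(b)
  ag_node(sweep(m$v, 2L, b$v, "+"), list(m, b),
          function(g) list(g, colSums(g)))
}

ag_rowscale <- function(m, s) {
  # multiply row i of m by s[i]
  m <- as_ag(m); s <- as_ag(s)
  ag_node(m$v * s$v, list(m, s),
          function(g) list(g * s$v, rowSums(g * m$v)))
}

ag_rowsums <- function(m) {
  m <- as_ag(m)
  nc <- ncol(m$v)
  ag_node(rowSums(m$v), list(m),
          function(g) list(matrix(g, nrow = length(g), ncol = nc)))
}

ag_sum <- function(x) {
  x <- as_ag(x)
  dm <- dim(x$v)
  ag_node(sum(x$v), list(x),
          function(g) list(if (is.null(dm)) rep(g, length(x$v)) else array(g, dm)))
}

ag_mean <- function(x) {
  x <- as_ag(x)
  n <- length(x$v); dm <- dim(x$v)
  ag_node(mean(x$v), list(x),
          function(g) list(if (is.null(dm)) rep(g / n, n) else array(g / n, dm)))
}

ag_reshape <- function(x, dm) {
  x <- as_ag(x)
  old <- dim(x$v)
  v <- x$v; dim(v) <- dm
  ag_node(v, list(x), function(g) { dim(g) <- old; list(g) })
}

ag_aperm <- function(x, perm) {
  x <- as_ag(x)
  inv <- order(perm)
  ag_node(aperm(x$v, perm), list(x), function(g) list(aperm(g, inv)))
}

ag_concat_cols <- function(xs) {
  xs <- lapply(xs, as_ag)
  ncols <- vapply(xs, function(x) ncol(x$v), integer(1))
  ends <- cumsum(ncols); starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(do.call(cbind, lapply(xs, function(x) x$v)), xs,
          function(g) lapply(seq_along(xs), function(j) g[, starts[j]:ends[j], drop = FALSE]))
}

ag_slice_cols <- function(x, idx) {
  x <- as_ag(x)
  nc <- ncol(x$v); nr <- nrow(x$v)
  ag_node(x$v[, idx, drop = FALSE], list(x),
          function(g) { out <- matrix(0, nr, nc); out[, idx] <- g; list(out) })
}

# ---- gather / scatter ----

# Precomputed scatter-add plan: sort the (flattened) index table once, then
# every backward pass is a cumsum over contiguous runs instead of a rowsum.
make_scatter_plan <- function(idx2) {
  o <- order(idx2, method = "radix")
  v <- idx2[o]
  ends <- which(v != c(v[-1L], -1L))
  list(o = o, ends = ends, targets = v[ends])
}

scatter_add <- function(gvals, plan, n_slots) {
  cs <- cumsum(gvals[plan$o])
  sums <- diff(c(0, cs[plan$ends]))
  out <- numeric(n_slots)
  out[plan$targets] <- sums
  out
}

ag_gather <- function(x, idx, out_dim = NULL, plan = NULL) {
  # idx: integer vector of linear indices into x's flattened value;
  # an index of 0 yields 0 (implicit zero padding).
  force(plan)
  x <- as_ag(x)
  n <- length(x$v)
  xv <- c(as.vector(x$v), 0)
  idx2 <- as.vector(idx)
  idx2[idx2 == 0L] <- n + 1L
  v <- xv[idx2]
  if (!is.null(out_dim)) dim(v) <- out_dim
  xd <- dim(x$v)
  ag_node(v, list(x), function(g) {
    if (is.null(plan)) plan <- make_scatter_plan(idx2)
    out <- scatter_add(as.vector(g), plan, n + 1L)
    out <- out[seq_len(n)]
    if (!is.null(xd)) dim(out) <- xd
    list(out)
  })
}

ag_gather_ws <- function(x, idxmat, wmat, out_dim = NULL, plan = NULL) {
  # weighted sum of gathers: v[j] = sum_k w[j,k] * x[idx[j,k]] (idx 0 -> 0)
  force(plan)
  x <- as_ag(x)
  n <- length(x$v)
  xv <- c(as.vector(x$v), 0)
  K <- ncol(idxmat)
  idx2 <- idxmat
  idx2[idx2 == 0L] <- n + 1L
  v <- numeric(nrow(idxmat))
  for (k in seq_len(K)) v <- v + wmat[, k] * xv[idx2[, k]]
  if (!is.null(out_dim)) dim(v) <- out_dim
  xd <- dim(x$v)
  wvec <- as.vector(wmat)
  ag_node(v, list(x), function(g) {
    if (is.null(plan)) plan <- make_scatter_plan(as.vector(idx2))
    gv <- as.vector(g)
    out <- scatter_add(rep(gv, K) * wvec, plan, n + 1L)
    out <- out[seq_len(n)]
    if (!is.null(xd)) dim(out) <- xd
    list(out)
  })
}

# ---- elementwise nonlinearities ----

ag_sigmoid <- function(x) {
  x <- as_ag(x)
  s <- 1 / (1 + exp(-x$v))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(x) {
  x <- as_ag(x)
  t <- tanh(x$v)
  ag_node(t, list(x), function(g) list(g * (1 - t * t)))
}

ag_gelu <- function(x) {
  x <- as_ag(x)
  ph <- stats::pnorm(x$v)
  ag_node(x$v * ph, list(x),
          function(g) list(g * (ph + x$v * stats::dnorm(x$v))))
}

ag_silu <- function(x) {
  x <- as_ag(x)
  s <- 1 / (1 + exp(-x$v))
  ag_node(x$v * s, list(x),
          function(g) list(g * (s + x$v * s * (1 - s))))
}

ag_log <- function(x) {
  x <- as_ag(x)
  ag_node(log(x$v), list(x), function(g) list(g / x$v))
}

ag_sqrt <- function(x) {
  x <- as_ag(x)
  v <- sqrt(x$v)
  ag_node(v, list(x), function(g) list(g / (2 * v)))
}

ag_acosh_safe <- function(x, floor_arg = 1 + 1e-12) {
  # arccosh with the argument floored just above 1 to absorb rounding
  x <- as_ag(x)
  xc <- pmax(x$v, floor_arg)
  v <- acosh(xc)
  ag_node(v, list(x), function(g)
    list(g / sqrt(pmax(xc * xc - 1, 1e-24))))
}

ag_clamp_min <- function(x, lo) {
  x <- as_ag(x)
  keep <- x$v >= lo
  ag_node(pmax(x$v, lo), list(x), function(g) list(g * keep))
}

# ---- softmax / layernorm / dropout ----

ag_softmax_cols <- function(x) {
  # softmax within each column of a matrix
  x <- as_ag(x)
  m <- x$v
  mx <- apply(m, 2L, max)
  e <- exp(sweep(m, 2L, mx, "-"))
  s <- sweep(e, 2L, colSums(e), "/")
  ag_node(s, list(x), function(g) {
    dots <- colSums(g * s)
    list(s * sweep(g, 2L, dots, "-"))
  })
}

ag_layernorm_rows <- function(x, eps = 1e-5) {
  # per-row standardization of a matrix (no learned affine)
  x <- as_ag(x)
  m <- x$v
  k <- ncol(m)
  mu <- rowMeans(m)
  xc <- m - mu
  va <- rowSums(xc * xc) / k
  sd_ <- sqrt(va + eps)
  y <- xc / sd_
  ag_node(y, list(x), function(g) {
    gm <- rowMeans(g)
    gy <- rowSums(g * y) / k
    list((g - gm - y * gy) / sd_)
  })
}

ag_dropout <- function(x, p, training, rng_mask = NULL) {
  if (!training || p <= 0) return(as_ag(x))
  x <- as_ag(x)
  mask <- if (is.null(rng_mask)) {
    (stats::runif(length(x$v)) >= p) / (1 - p)
  } else rng_mask
  dm <- dim(x$v)
  v <- x$v * mask
  if (!is.null(dm)) dim(v) <- dm
  ag_node(v, list(x), function(g) list(g * mask))
}

# ---- 4D (B,C,H,W) helpers ----

ag_concat_dim2 <- function(xs) {
  xs <- lapply(xs, as_ag)
  dms <- lapply(xs, function(x) dim(x$v))
  B <- dms[[1]][1]; H <- dms[[1]][3]; W <- dms[[1]][4]
  cs <- vapply(dms, `[`, numeric(1), 2L)
  ends <- cumsum(cs); starts <- c(1, head(ends, -1) + 1)
  out <- array(0, c(B, sum(cs), H, W))
  for (j in seq_along(xs)) out[, starts[j]:ends[j], , ] <- xs[[j]]$v
  ag_node(out, xs, function(g)
    lapply(seq_along(xs), function(j) g[, starts[j]:ends[j], , , drop = FALSE]))
}

ag_bmul_channel <- function(x, g1) {
  # x: (B,C,H,W); g1: (B,1,H,W) broadcast-multiplied over channels
  x <- as_ag(x); g1 <- as_ag(g1)
  d <- dim(x$v); C <- d[2]
  ge <- array(g1$v[, rep(1L, C), , , drop = FALSE], d)
  ag_node(x$v * ge, list(x, g1), function(g) {
    dg <- colSums(aperm(g * x$v, c(2, 1, 3, 4)))
    dim(dg) <- c(d[1], 1L, d[3], d[4])
    list(g * ge, dg)
  })
}

sum_dim2 <- function(a) {
  d <- dim(a)
  out <- colSums(aperm(a, c(2, 1, 3, 4)))
  dim(out) <- c(d[1], 1L, d[3], d[4])
  out
}
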