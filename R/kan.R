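# Kolmogorov-Arnold classifier head.
#
# Each edge carries a learnable univariate function
# phi(x) = base_weight * silu(x) + sum_m coeff_m * B_m(x)
# with B_m a cubic B-spline basis on a fixed uniform grid; outside the grid
# the spline part is extrapolated linearly. A layer output is the plain sum
# x_{l+1,j} = sum_i phi_{l,j,i}(x_{l,i}); the network is the composition of
# layer maps.

default_kan_grid <- function(lim = 2, n_intervals = 8L, order = 4L) {
  h <- 2 * lim / n_intervals
  degree <- order - 1L
  knots <- seq(-lim - degree * h, lim + degree * h, by = h)
  list(knots = knots, lo = -lim, hi = lim, order = order,
       n_basis = length(knots) - order)
}

kan_basis <- function(x, grid) {
  # returns values and x-derivatives of all basis functions at x (vector);
  # outside [lo, hi] each basis function is continued linearly
  xc <- pmin(pmax(x, grid$lo), grid$hi)
  delta <- x - xc
  B0 <- splines::splineDesign(grid$knots, xc, ord = grid$order,
                              outer.ok = TRUE)
  B1 <- splines::splineDesign(grid$knots, xc, ord = grid$order,
                              derivs = rep(1L, length(xc)), outer.ok = TRUE)
  list(B = B0 + B1 * delta, dB = B1)
}

silu <- function(x) x / (1 + exp(-x))
dsilu <- function(x) { s <- 1 / (1 + exp(-x)); s + x * s * (1 - s) }

#' Construct a KAN edge
#'
#' @param spline_coeffs coefficients for the B-spline basis (length must be
#'   `n_intervals + order - 1`).
#' @param base_weight weight of the silu residual path.
#' @param lim half-width of the spline grid `[-lim, lim]`.
#' @param n_intervals number of grid intervals.
#' @param order B-spline order (4 = cubic).
#' @return An object usable with [kanEdgeEval()].
#' @export
kanEdge <- function(spline_coeffs = NULL, base_weight = 0, lim = 2,
                    n_intervals = 8L, order = 4L) {
  g <- default_kan_grid(lim, n_intervals, order)
  if (is.null(spline_coeffs)) spline_coeffs <- numeric(g$n_basis)
  if (length(spline_coeffs) != g$n_basis)
    stop("expected ", g$n_basis, " spline coefficients")
  structure(list(coeffs = spline_coeffs, base_weight = base_weight, grid = g),
            class = "kan_edge")
}

#' Evaluate a KAN edge function
#'
#' \eqn{\phi(x) = w_{base}\,\mathrm{silu}(x) + \sum_m c_m B_m(x)}.
#'
#' @param e edge from [kanEdge()].
#' @param x numeric vector of evaluation points.
#' @return \eqn{\phi(x)}, same length as `x`.
#' @export
kanEdgeEval <- function(e, x) {
  bs <- kan_basis(x, e$grid)
  as.vector(e$base_weight * silu(x) + bs$B %*% e$coeffs)
}

#' Fit a KAN edge's spline coefficients to a univariate target
#'
#' Least-squares fit of the spline part (base weight forced to zero) to
#' `f` evaluated on a dense grid; used to probe edge expressivity.
#'
#' @param f function of one variable.
#' @param lim,n_intervals,order grid parameters, see [kanEdge()].
#' @param n_fit number of fitting points.
#' @return A fitted edge.
#' @export
kanEdgeFit <- function(f, lim = 2, n_intervals = 8L, order = 4L,
                       n_fit = 512L) {
  g <- default_kan_grid(lim, n_intervals, order)
  xs <- seq(g$lo, g$hi, length.out = n_fit)
  B <- splines::splineDesign(g$knots, xs, ord = g$order)
  co <- stats::lsfit(B, f(xs), intercept = FALSE)$coefficients
  kanEdge(as.numeric(co), base_weight = 0, lim = lim,
          n_intervals = n_intervals, order = order)
}

#' Forward pass of one KAN layer
#'
#' \eqn{x_{l+1,j} = \sum_i \phi_{l,j,i}(x_{l,i})}.
#'
#' @param layer list with `coeffs` (array `(n_out, n_in, n_basis)`),
#'   `base_w` (matrix `(n_out, n_in)`), and optionally `grid` (from
#'   [kanEdge()]'s defaults otherwise).
#' @param x numeric vector of length `n_in`, or matrix `(B, n_in)`.
#' @return Vector of length `n_out` (or matrix `(B, n_out)`).
#' @export
kanLayerForward <- function(layer, x) {
  grid <- if (is.null(layer$grid)) default_kan_grid() else layer$grid
  one <- is.null(dim(x))
  X <- if (one) matrix(x, 1) else x
  n_in <- dim(layer$coeffs)[2]
  if (ncol(X) != n_in)
    stop("kanLayerForward: expected ", n_in, " inputs, got ", ncol(X))
  out <- ag_value(ag_kan_layer(ag_const(X), ag_const(layer$coeffs),
                               ag_const(layer$base_w), grid))
  if (one) as.vector(out) else out
}

#' Forward pass of a stacked KAN
#'
#' Composition of layer maps \eqn{\Phi_{L-1}\circ\cdots\circ\Phi_0}.
#'
#' @param layers list of layers as in [kanLayerForward()]; widths must
#'   chain.
#' @param x input vector or matrix.
#' @return Network output (logits).
#' @export
kanForward <- function(layers, x) {
  for (i in seq_along(layers)) {
    if (i > 1L) {
      n_in <- dim(layers[[i]]$coeffs)[2]
      n_prev <- dim(layers[[i - 1L]]$coeffs)[1]
      if (n_in != n_prev) stop("kanForward: layer widths do not chain")
    }
    x <- kanLayerForward(layers[[i]], x)
  }
  x
}

# ---- autodiff op ---------------------------------------------------------

ag_kan_layer <- function(X, Cc, BW, grid) {
  # X: (B, n_in); Cc: (n_out, n_in, nb); BW: (n_out, n_in)
  X <- as_ag(X); Cc <- as_ag(Cc); BW <- as_ag(BW)
  Xv <- X$v
  B <- nrow(Xv); n_in <- ncol(Xv)
  dc <- dim(Cc$v); n_out <- dc[1]; nb <- dc[3]
  bs <- kan_basis(as.vector(Xv), grid)
  arrB <- array(bs$B, c(B, n_in, nb))
  Bflat <- matrix(aperm(arrB, c(1, 3, 2)), B, nb * n_in)
  Cmat <- matrix(aperm(Cc$v, c(1, 3, 2)), n_out, nb * n_in)
  S <- silu(Xv)
  Y <- S %*% t(BW$v) + Bflat %*% t(Cmat)
  ag_node(Y, list(X, Cc, BW), function(g) {
    dBW <- crossprod(g, S)
    dCmat <- crossprod(g, Bflat)
    dC <- aperm(array(dCmat, c(n_out, nb, n_in)), c(1, 3, 2))
    arrD <- array(bs$dB, c(B, n_in, nb))
    dBflat <- matrix(aperm(arrD, c(1, 3, 2)), B, nb * n_in)
    U <- (g %*% Cmat) * dBflat
    T_ <- colSums(aperm(array(U, c(B, nb, n_in)), c(2, 1, 3)))
    dX <- (g %*% BW$v) * dsilu(Xv) + T_
    list(dX, dC, dBW)
  })
}

kan_head_init <- function(n_in, widths, grid = default_kan_grid(),
                          prior_logits = NULL) {
  # prior_logits: optional per-output logits for the last layer; since the
  # B-spline basis is a partition of unity on its grid, setting every
  # coefficient of edge (j, i) to prior_logits[j] / n_in makes the head
  # output the prior before training (the base path starts at zero there).
  dims <- c(n_in, widths)
  layers <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    ni <- dims[i]; no <- dims[i + 1L]
    last <- i == length(widths) && !is.null(prior_logits)
    co <- array(stats::rnorm(no * ni * grid$n_basis, sd = 0.01),
                c(no, ni, grid$n_basis))
    bw <- matrix(stats::rnorm(no * ni, sd = sqrt(2 / ni)), no, ni)
    if (last) {
      stopifnot(length(prior_logits) == no)
      co <- co + array(rep(prior_logits / ni, ni * grid$n_basis),
                       c(no, ni, grid$n_basis))
      bw <- bw * 0.3   # keep the base path alive so gradients reach the trunk
    }
    layers[[i]] <- list(coeffs = ag_param(co), base_w = ag_param(bw))
  }
  list(layers = layers, grid = grid)
}

kan_head_params <- function(kh)
  unlist(lapply(kh$layers, function(l) list(l$coeffs, l$base_w)),
         recursive = FALSE)

kan_head_fwd <- function(kh, x) {
  for (l in kh$layers) x <- ag_kan_layer(x, l$coeffs, l$base_w, kh$grid)
  x
}
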