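#' Squared Euclidean distance
#'
#' Distance metric used in Euclidean representation space. Note this is the
#' *squared* L2 norm of the difference, \eqn{D_{es}(x,y) = \|x-y\|_2^2}: the
#' cross-space consistency loss is defined against this quantity, and it is
#' deliberately not a metric (no triangle inequality).
#'
#' @param x,y numeric vectors of equal length, or matrices with one point
#'   per row (then a per-row distance vector is returned).
#' @return Non-negative squared distance(s).
#' @examples
#' euclideanDistance(c(0, 0), c(1, 1))  # 2
#' @export
euclideanDistance <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) == 1L && ncol(y) == 1L) { x <- t(x); y <- t(y) }
  if (!all(dim(x) == dim(y)))
    stop("euclideanDistance: dimension mismatch (", paste(dim(x), collapse = "x"),
         " vs ", paste(dim(y), collapse = "x"), ")")
  d <- rowSums((x - y)^2)
  if (length(d) == 1L) unname(d) else unname(d)
}

#' Poincare-ball (hyperbolic) distance
#'
#' Geodesic distance on the Poincare ball of curvature \code{-c}:
#' \deqn{d_c(x,y) = \frac{1}{\sqrt{c}} \,\mathrm{arccosh}\!\left(1 +
#'   \frac{2c\|x-y\|^2}{(1-c\|x\|^2)(1-c\|y\|^2)}\right).}
#' Points must lie strictly inside the ball of radius \eqn{1/\sqrt{c}}
#' (use [clipToBall()] first). The arccosh argument is floored at 1 to
#' absorb rounding.
#'
#' @param x,y numeric vectors (one point) or matrices (points in rows).
#' @param c positive curvature magnitude; default 1.
#' @return Non-negative distance(s); zero iff \code{x == y}.
#' @examples
#' hyperbolicDistance(c(0, 0), c(0.5, 0))  # log(3)
#' @export
hyperbolicDistance <- function(x, y, c = 1) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0)
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) == 1L && ncol(y) == 1L) { x <- t(x); y <- t(y) }
  if (!all(dim(x) == dim(y)))
    stop("hyperbolicDistance: dimension mismatch")
  r2 <- 1 / c
  nx <- rowSums(x^2); ny <- rowSums(y^2)
  if (any(nx >= r2) || any(ny >= r2))
    stop("hyperbolicDistance: point on or outside the ball boundary; ",
         "clip with clipToBall() first")
  d2 <- rowSums((x - y)^2)
  arg <- 1 + 2 * c * d2 / ((1 - c * nx) * (1 - c * ny))
  unname(acosh(pmax(arg, 1)) / sqrt(c))
}

#' Exponential map at the ball origin
#'
#' Maps a Euclidean (tangent) vector into the Poincare ball:
#' \eqn{\exp_0(v) = \tanh(\sqrt{c}\|v\|)\, v / (\sqrt{c}\|v\|)}, with
#' \eqn{\exp_0(0) = 0}. Direction is preserved and the image norm is a
#' strictly increasing, saturating function of \eqn{\|v\|}, so the output
#' always lies strictly inside the ball.
#'
#' @param v numeric vector or matrix (rows are vectors).
#' @param c positive curvature magnitude.
#' @return Point(s) in the ball, same shape as `v`.
#' @export
expMapOrigin <- function(v, c = 1) {
  stopifnot(c > 0)
  vec <- is.null(dim(v))
  v <- as.matrix(v)
  if (ncol(v) == 1L && vec) v <- t(v)
  r <- sqrt(rowSums(v^2))
  sc <- sqrt(c)
  # cap tanh just below 1 so saturated inputs stay strictly inside the ball
  t_ <- pmin(tanh(sc * r), 1 - 1e-12)
  f <- ifelse(r < 1e-12, 1, t_ / (sc * pmax(r, 1e-12)))
  out <- v * f
  if (vec) as.vector(out) else out
}

#' Clip points to the open Poincare ball
#'
#' Rescales any point with norm \eqn{\ge 1/\sqrt{c} - \epsilon} back to norm
#' \eqn{1/\sqrt{c} - \epsilon}; interior points are returned unchanged.
#'
#' @param x numeric vector or matrix (rows are points).
#' @param c positive curvature magnitude.
#' @param eps clipping margin in `(0, 1e-2]`; default `1e-5`.
#' @export
clipToBall <- function(x, c = 1, eps = 1e-5) {
  stopifnot(c > 0, eps > 0, eps <= 1e-2)
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (ncol(x) == 1L && vec) x <- t(x)
  rmax <- 1 / sqrt(c) - eps
  r <- sqrt(rowSums(x^2))
  f <- ifelse(r > rmax, rmax / r, 1)
  out <- x * f
  if (vec) as.vector(out) else out
}

# ---- autodiff counterparts (row-wise over matrices) ----------------------

ag_expmap0 <- function(v, c = 1) {
  # v: ag matrix (n, d) -> ball points (n, d)
  v <- as_ag(v)
  sc <- sqrt(c)
  r <- ag_sqrt(ag_addc(ag_rowsums(ag_mul(v, v)), 1e-24))
  t_ <- ag_tanh(ag_scale(r, sc))
  f <- ag_mul(t_, ag_recip(ag_scale(r, sc)))
  ag_rowscale(v, f)
}

ag_clip_ball <- function(x, c = 1, eps = 1e-5) {
  # projection factor treated as locally constant (scale pass-through)
  x <- as_ag(x)
  rmax <- 1 / sqrt(c) - eps
  r <- sqrt(rowSums(x$v^2))
  f <- ifelse(r > rmax, rmax / r, 1)
  ag_node(x$v * f, list(x), function(g) list(g * f))
}

ag_hyperbolic_distance <- function(x, y, c = 1) {
  # row-wise distance between ag matrices of ball points
  x <- as_ag(x); y <- as_ag(y)
  dlt <- ag_sub(x, y)
  d2 <- ag_rowsums(ag_mul(dlt, dlt))
  nx <- ag_rowsums(ag_mul(x, x))
  ny <- ag_rowsums(ag_mul(y, y))
  den <- ag_mul(ag_addc(ag_scale(nx, -c), 1), ag_addc(ag_scale(ny, -c), 1))
  arg <- ag_addc(ag_mul(ag_scale(d2, 2 * c), ag_recip(den)), 1)
  ag_scale(ag_acosh_safe(arg), 1 / sqrt(c))
}

ag_euclidean_distance <- function(x, y) {
  dlt <- ag_sub(as_ag(x), as_ag(y))
  ag_rowsums(ag_mul(dlt, dlt))
}
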