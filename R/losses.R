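# Dual-space training losses.
#
# Cross-entropy drives the Euclidean label predictions; the consistency loss
# compares the batch vector of per-sample image-text distances measured in
# Euclidean space (squared norm) with the same vector measured on the
# Poincare ball; the complementarity loss is the hyperbolic distance between
# label predictions and targets after both are mapped into the ball by the
# origin exponential map. The total loss is their weighted sum.

#' Cross-space consistency loss
#'
#' One minus the cosine similarity between the batch vector of Euclidean
#' (squared) image-text distances and the corresponding hyperbolic distance
#' vector: zero iff the two vectors are positively proportional, and at most
#' 1 for (componentwise) non-negative inputs. With
#' `denominator = "squared"` the printed norm-ratio form (squared norms in
#' the denominator) is used instead of the cosine; it is not
#' scale-invariant and is provided for fidelity experiments.
#'
#' @param d_es,d_hs non-negative distance vectors of equal length (>= 2).
#' @param denominator `"plain"` (cosine, default) or `"squared"`.
#' @return Scalar loss. If either vector has zero norm the cosine is
#'   undefined; returns 1 with a warning.
#' @export
consistencyLoss <- function(d_es, d_hs, denominator = c("plain", "squared")) {
  denominator <- match.arg(denominator)
  stopifnot(length(d_es) == length(d_hs), length(d_es) >= 2L)
  na <- sqrt(sum(d_es^2)); nb <- sqrt(sum(d_hs^2))
  if (na == 0 || nb == 0) {
    warning("zero-norm distance vector; consistency loss undefined, returning 1")
    return(1)
  }
  den <- if (denominator == "plain") na * nb else na^2 * nb^2
  1 - sum(d_es * d_hs) / den
}

#' Multi-label binary cross-entropy
#'
#' Mean over labels (and samples) of
#' \eqn{-[y \log \hat y + (1-y)\log(1-\hat y)]}, with predictions clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param y_es predicted probabilities (vector or matrix).
#' @param Y_es binary targets, same shape.
#' @return Non-negative scalar.
#' @export
ceLoss <- function(y_es, Y_es) {
  if (length(y_es) != length(Y_es)) stop("ceLoss: shape mismatch")
  p <- pmin(pmax(y_es, 1e-7), 1 - 1e-7)
  -mean(Y_es * log(p) + (1 - Y_es) * log(1 - p))
}

#' Hyperbolic complementarity loss
#'
#' Mean Poincare-ball distance between the hyperbolic images of the
#' predicted and target label vectors (both mapped by [expMapOrigin()] and
#' clipped into the ball).
#'
#' @param y_hs,Y_hs ball points (vectors or matrices with points in rows),
#'   e.g. `expMapOrigin(probabilities)` and `expMapOrigin(targets)`.
#' @param c curvature magnitude.
#' @return Non-negative scalar; zero iff predictions map onto targets.
#' @export
complementarityLoss <- function(y_hs, Y_hs, c = 1) {
  mean(hyperbolicDistance(y_hs, Y_hs, c = c))
}

#' Weighted total loss
#'
#' \eqn{L_{total} = w_{ce} L_{ce} + w_{consis} L_{consis} + w_{compl}
#' L_{compl}}.
#'
#' @param l_ce,l_consis,l_compl loss components.
#' @param weights list or named vector with `w_ce`, `w_consis`, `w_compl`
#'   (non-negative, not all zero).
#' @return Scalar weighted sum.
#' @export
totalLoss <- function(l_ce, l_consis, l_compl, weights) {
  w <- unlist(weights)[c("w_ce", "w_consis", "w_compl")]
  if (any(is.na(w)) || any(w < 0) || all(w == 0))
    stop("weights must be non-negative, not all zero, named w_ce/w_consis/w_compl")
  unname(w["w_ce"] * l_ce + w["w_consis"] * l_consis + w["w_compl"] * l_compl)
}

# ---- autodiff counterparts ----------------------------------------------

ag_consistency_loss <- function(d_es, d_hs, denominator = "plain") {
  # d_es, d_hs: ag vectors over the batch
  na2 <- ag_sum(ag_mul(d_es, d_es))
  nb2 <- ag_sum(ag_mul(d_hs, d_hs))
  dot <- ag_sum(ag_mul(d_es, d_hs))
  den <- if (denominator == "plain")
    ag_sqrt(ag_addc(ag_mul(na2, nb2), 1e-24))
  else ag_addc(ag_mul(na2, nb2), 1e-24)
  ag_sub(1, ag_mul(dot, ag_recip(den)))
}

ag_bce_loss <- function(probs, targets) {
  # probs: ag matrix in (0,1); targets: constant 0/1 matrix
  p <- ag_clamp_minmax(probs, 1e-7, 1 - 1e-7)
  t1 <- ag_mul(ag_const(targets), ag_log(p))
  t2 <- ag_mul(ag_const(1 - targets), ag_log(ag_sub(1, p)))
  ag_scale(ag_mean(ag_add(t1, t2)), -1)
}

ag_clamp_minmax <- function(x, lo, hi) {
  x <- as_ag(x)
  keep <- x$v >= lo & x$v <= hi
  ag_node(pmin(pmax(x$v, lo), hi), list(x), function(g) list(g * keep))
}

ag_complementarity_loss <- function(probs, targets, c = 1, eps = 1e-5) {
  yh <- ag_clip_ball(ag_expmap0(probs, c), c, eps)
  Yh <- ag_clip_ball(ag_expmap0(ag_const(targets), c), c, eps)
  ag_mean(ag_hyperbolic_distance(yh, Yh, c))
}
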