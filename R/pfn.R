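#' Interval-valued Pythagorean fuzzy numbers
#'
#' A Pythagorean fuzzy number (PFN) carries a membership degree \eqn{\mu} and a
#' non-membership degree \eqn{\nu} constrained by \eqn{\mu^2 + \nu^2 \le 1};
#' the residual \eqn{\pi = \sqrt{1 - \mu^2 - \nu^2}} is the hesitancy.  The
#' interval-valued variant replaces each degree by an interval
#' \eqn{[\mu_{lo}, \mu_{hi}]}, \eqn{[\nu_{lo}, \nu_{hi}]}, with the Pythagorean
#' constraint enforced at the upper bounds (so it holds everywhere in the box).
#'
#' A `pfn` object stores the four bounds as parallel numeric arrays of a
#' common shape, so a single object can hold a scalar, a vector, or a whole
#' weight matrix of fuzzy numbers; all algebra in this file is vectorised
#' elementwise over that shape.
#'
#' @param mu_lo,mu_hi Lower/upper membership bounds in \[0, 1\].
#' @param nu_lo,nu_hi Lower/upper non-membership bounds in \[0, 1\].
#' @param tol Numerical slack allowed when checking the invariants.
#' @return An object of class `pfn`: a list with fields `mu_lo`, `mu_hi`,
#'   `nu_lo`, `nu_hi`.
#' @examples
#' pfn(0.2, 0.8, 0.1, 0.5)
#' pfn(0.6, 0.6, 0.8, 0.8)   # boundary case, hesitancy 0
#' @export
pfn <- function(mu_lo, mu_hi = mu_lo, nu_lo, nu_hi = nu_lo, tol = 1e-9) {
  dims <- dim(mu_lo)
  n <- length(mu_lo)
  if (length(mu_hi) != n || length(nu_lo) != n || length(nu_hi) != n)
    stop("all four bound arrays must have the same length")
  bad <- function(x) any(!is.finite(x)) || any(x < -tol) || any(x > 1 + tol)
  if (bad(mu_lo) || bad(mu_hi) || bad(nu_lo) || bad(nu_hi))
    stop("PFN invariant violated: all bounds must lie in [0, 1]")
  if (any(mu_lo > mu_hi + tol))
    stop("PFN invariant violated: mu_lo > mu_hi (interval ordering)")
  if (any(nu_lo > nu_hi + tol))
    stop("PFN invariant violated: nu_lo > nu_hi (interval ordering)")
  if (any(mu_hi^2 + nu_hi^2 > 1 + 2 * tol))
    stop("PFN invariant violated: mu_hi^2 + nu_hi^2 > 1 (Pythagorean constraint)")
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  out <- list(mu_lo = clamp01(as.numeric(mu_lo)), mu_hi = clamp01(as.numeric(mu_hi)),
              nu_lo = clamp01(as.numeric(nu_lo)), nu_hi = clamp01(as.numeric(nu_hi)))
  # re-impose exact ordering after clamping fp slack
  out$mu_lo <- pmin(out$mu_lo, out$mu_hi)
  out$nu_lo <- pmin(out$nu_lo, out$nu_hi)
  if (!is.null(dims)) out <- lapply(out, function(x) { dim(x) <- dims; x })
  structure(out, class = "pfn")
}

#' @rdname pfn
#' @param ... Passed on to [pfn()].
#' @export
make_pfn <- function(mu_lo, mu_hi = mu_lo, nu_lo, nu_hi = nu_lo, ...) {
  pfn(mu_lo, mu_hi, nu_lo, nu_hi, ...)
}

#' @export
print.pfn <- function(x, ...) {
  n <- length(x$mu_lo)
  if (n == 1) {
    cat(sprintf("PFN([%.4g, %.4g], [%.4g, %.4g]), pi_hi = %.4g\n",
                x$mu_lo, x$mu_hi, x$nu_lo, x$nu_hi,
                sqrt(max(0, 1 - x$mu_lo^2 - x$nu_lo^2))))
  } else {
    d <- if (is.null(dim(x$mu_lo))) as.character(n) else paste(dim(x$mu_lo), collapse = " x ")
    cat(sprintf("<pfn array [%s]>\n", d))
    cm <- pfn_centroid(x)
    cat(sprintf("  centroid mu in [%.3g, %.3g], centroid nu in [%.3g, %.3g]\n",
                min(cm$c_mu), max(cm$c_mu), min(cm$c_nu), max(cm$c_nu)))
  }
  invisible(x)
}

#' @export
length.pfn <- function(x) length(x$mu_lo)

#' @export
`[.pfn` <- function(x, i, ...) {
  structure(lapply(unclass(x), function(ch) ch[i, ...]), class = "pfn")
}

is_pfn <- function(x) inherits(x, "pfn")

#' Restore PFN invariants after unconstrained arithmetic
#'
#' Clips the four bounds to \[0, 1\], enforces interval ordering by swapping,
#' and, where the Pythagorean constraint is violated at the upper bounds,
#' rescales \eqn{(\mu_{hi}, \nu_{hi})} radially onto the unit circle (lower
#' bounds are then clipped to stay below the uppers).  Idempotent.
#'
#' @inheritParams pfn
#' @return A valid `pfn` object.
#' @export
project_valid <- function(mu_lo, mu_hi = mu_lo, nu_lo, nu_hi = nu_lo) {
  dims <- dim(mu_lo)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  ml <- clamp01(mu_lo); mh <- clamp01(mu_hi)
  nl <- clamp01(nu_lo); nh <- clamp01(nu_hi)
  m_lo <- pmin(ml, mh); m_hi <- pmax(ml, mh)
  n_lo <- pmin(nl, nh); n_hi <- pmax(nl, nh)
  r2 <- m_hi^2 + n_hi^2
  f <- ifelse(r2 > 1, 1 / sqrt(r2), 1)
  m_hi <- m_hi * f
  n_hi <- n_hi * f
  m_lo <- pmin(m_lo, m_hi)
  n_lo <- pmin(n_lo, n_hi)
  if (!is.null(dims)) { dim(m_lo) <- dim(m_hi) <- dim(n_lo) <- dim(n_hi) <- dims }
  structure(list(mu_lo = m_lo, mu_hi = m_hi, nu_lo = n_lo, nu_hi = n_hi), class = "pfn")
}

#' Centroid (defuzzification) of an interval-valued PFN
#'
#' With a uniform density over each bound interval the ratio-of-integrals
#' centroid reduces to the interval midpoints:
#' \eqn{c_\mu = (\mu_{lo} + \mu_{hi})/2}, \eqn{c_\nu = (\nu_{lo} + \nu_{hi})/2}.
#'
#' @param p A `pfn` object.
#' @return A list with fields `c_mu` and `c_nu` (same shape as `p`).
#' @export
pfn_centroid <- function(p) {
  stopifnot(is_pfn(p))
  list(c_mu = (p$mu_lo + p$mu_hi) / 2, c_nu = (p$nu_lo + p$nu_hi) / 2)
}

#' Hesitancy of a PFN at its centroid
#'
#' \eqn{\pi = \sqrt{\max(0, 1 - c_\mu^2 - c_\nu^2)}}; the max absorbs
#' floating-point negatives.
#'
#' @param p A `pfn` object.
#' @return Numeric array of hesitancies.
#' @export
pfn_hesitancy <- function(p) {
  ct <- pfn_centroid(p)
  sqrt(pmax(0, 1 - ct$c_mu^2 - ct$c_nu^2))
}

#' Distance between a crisp number and a PFN
#'
#' Default form \eqn{\sqrt{(c_\mu - \alpha)^2/2 + c_\nu^2}}; the alternative
#' reading \eqn{\sqrt{((c_\mu - \alpha)^2 + c_\nu^2)/2}} is selected with
#' `variant = "half_both"`.  Both coincide whenever \eqn{c_\nu = 0}.
#'
#' @param alpha Crisp value(s) in \[0, 1\].
#' @param p A `pfn` object (same shape as `alpha`, or scalar).
#' @param variant Which algebraic reading of the formula to use.
#' @return Non-negative numeric array of distances.
#' @export
crisp_distance <- function(alpha, p, variant = c("half_mu", "half_both")) {
  variant <- match.arg(variant)
  ct <- pfn_centroid(p)
  if (variant == "half_mu") sqrt((ct$c_mu - alpha)^2 / 2 + ct$c_nu^2)
  else sqrt(((ct$c_mu - alpha)^2 + ct$c_nu^2) / 2)
}

#' Reconstruction distance between a crisp vector and a PFN vector
#'
#' Root-mean-square aggregation of the per-coordinate crisp-PFN distances:
#' \eqn{\sqrt{(1/D) \sum_d |x_d, \tilde x'_d|^2}}.
#'
#' @param x Crisp numeric vector in \[0, 1\]^D.
#' @param p A `pfn` object of length D.
#' @inheritParams crisp_distance
#' @return A single non-negative number.
#' @export
crisp_fuzzy_vector_distance <- function(x, p, variant = c("half_mu", "half_both")) {
  if (length(x) != length(p)) stop("length mismatch between crisp and fuzzy vectors")
  d <- crisp_distance(x, p, variant)
  sqrt(mean(d^2))
}

#' Distance between two PFNs
#'
#' Evaluated at the centroids: with \eqn{\mu = c_\mu}, \eqn{\nu = c_\nu} and
#' \eqn{\pi^2 = \max(0, 1 - \mu^2 - \nu^2)},
#' \deqn{|p_1, p_2| = \sqrt{((\mu_1^2-\mu_2^2)^2 + (\nu_1^2-\nu_2^2)^2 +
#'   (\pi_1^2-\pi_2^2)^2)/2}.}
#' This is a Euclidean metric in \eqn{(\mu^2, \nu^2, \pi^2)} space scaled by
#' \eqn{1/\sqrt 2}, with range \[0, 1\].
#'
#' @param p1,p2 `pfn` objects of the same shape.
#' @return Numeric array of distances in \[0, 1\].
#' @export
pfn_distance <- function(p1, p2) {
  a <- pfn_squared_channels(p1)
  b <- pfn_squared_channels(p2)
  sqrt(((a$t1 - b$t1)^2 + (a$t2 - b$t2)^2 + (a$t3 - b$t3)^2) / 2)
}

# squared-degree channels (mu^2, nu^2, pi^2) at the centroid
pfn_squared_channels <- function(p) {
  ct <- pfn_centroid(p)
  t1 <- ct$c_mu^2
  t2 <- ct$c_nu^2
  list(t1 = t1, t2 = t2, t3 = pmax(1 - t1 - t2, 0))
}

#' RMS distance between two PFN vectors
#'
#' \eqn{\sqrt{(1/D)\sum_d |x_d, v_d|^2}} with [pfn_distance()] per coordinate.
#'
#' @param x,v `pfn` objects of equal length D.
#' @return A single non-negative number.
#' @export
pfn_vector_distance <- function(x, v) {
  if (length(x) != length(v)) stop("length mismatch between PFN vectors")
  sqrt(mean(pfn_distance(x, v)^2))
}

#' Pythagorean fuzzy operational laws
#'
#' Standard Pythagorean algebraic sum and scalar law, applied bound-wise to the
#' intervals (both laws are monotone, so interval ordering is preserved, and
#' both are closed under the Pythagorean constraint):
#' \itemize{
#'   \item sum: \eqn{\mu = \sqrt{\mu_1^2 + \mu_2^2 - \mu_1^2\mu_2^2}},
#'     \eqn{\nu = \nu_1 \nu_2};
#'   \item scale by \eqn{\lambda \ge 0}: \eqn{\mu = \sqrt{1 - (1-\mu^2)^\lambda}},
#'     \eqn{\nu = \nu^\lambda}.
#' }
#' `pfn_add(p, pfn(0, 0, 1, 1))` returns `p` (additive identity);
#' `pfn_scale(0, p)` returns the identity element P(0, 1).
#'
#' @param p1,p2,p `pfn` objects (elementwise over a common shape).
#' @param lam Non-negative scalar or array broadcastable over `p`.
#' @return A valid `pfn` object.
#' @export
pfn_add <- function(p1, p2) {
  mu <- function(a, b) sqrt(pmin(1, a^2 + b^2 - a^2 * b^2))
  project_valid(mu(p1$mu_lo, p2$mu_lo), mu(p1$mu_hi, p2$mu_hi),
                p1$nu_lo * p2$nu_lo, p1$nu_hi * p2$nu_hi)
}

#' @rdname pfn_add
#' @export
pfn_scale <- function(lam, p) {
  if (any(lam < 0)) stop("lam must be non-negative")
  mu <- function(m) sqrt(pmax(0, 1 - (1 - m^2)^lam))
  project_valid(mu(p$mu_lo), mu(p$mu_hi), p$nu_lo^lam, p$nu_hi^lam)
}

#' Exponential-style activation on a PFN
#'
#' Applies the monotone squashing \eqn{s(t) = e^{t-1}} endpoint-wise to the
#' membership bounds and the dual map \eqn{t \mapsto 1 - e^{-t}} to the
#' non-membership bounds, then projects onto the Pythagorean constraint with
#' [project_valid()].  \eqn{\mu = 1} is a fixed point.
#'
#' @param p A `pfn` object.
#' @return A valid `pfn` object of the same shape.
#' @export
pfn_activate <- function(p) {
  project_valid(exp(p$mu_lo - 1), exp(p$mu_hi - 1),
                1 - exp(-p$nu_lo), 1 - exp(-p$nu_hi))
}

#' Fuzzify a crisp value into a degenerate-interval PFN
#'
#' The declared convention for turning crisp features in \[0, 1\] into PFN data
#' points: \eqn{\mu = x}, \eqn{\nu = 1 - x} (always valid since
#' \eqn{x^2 + (1-x)^2 \le 1}).  Round-trips through the centroid:
#' `pfn_centroid(fuzzify(x))$c_mu == x`.
#'
#' @param x Numeric array with values in \[0, 1\].
#' @return A `pfn` object of the same shape with degenerate intervals.
#' @export
fuzzify <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("fuzzify() requires values in [0, 1]")
  pfn(x, x, 1 - x, 1 - x)
}
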