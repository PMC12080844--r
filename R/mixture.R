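#' Weighted chi-square mixtures
#'
#' Null distributions of the quadratic-form statistics used in gene-based
#' testing are weighted sums of independent 1-df chi-square variables,
#' \eqn{\sum_k \lambda_k \chi^2_{1}(\delta_k)}, with weights \eqn{\lambda_k}
#' the eigenvalues of the LD-transformed kernel matrix and (optionally)
#' noncentralities \eqn{\delta_k}.  Tail probabilities are computed by
#' numerical inversion of the characteristic function (Imhof's method);
#' deep tails, where quadrature loses absolute precision relative to the
#' tiny target value, use a Lugannani-Rice saddlepoint approximation of
#' the same cumulant generating function.
#'
#' @name mixture
NULL

# Clamp tiny negative eigenvalues (numerical noise on near-singular LD
# matrices) to zero; anything more negative is a genuine input error.
.clean_weights <- function(weights, ncp = NULL, tol = 1e-10) {
  if (length(weights) == 0L) stop("empty weight vector")
  if (any(!is.finite(weights))) stop("non-finite mixture weights")
  if (any(weights < -tol)) {
    stop("mixture weights must be non-negative (got ", min(weights), ")")
  }
  weights <- pmax(weights, 0)
  if (is.null(ncp)) ncp <- numeric(length(weights))
  if (length(ncp) != length(weights)) stop("ncp length mismatch")
  keep <- weights > 0
  if (!any(keep)) stop("all mixture weights are zero")
  list(lambda = weights[keep], delta = ncp[keep])
}

# --- Imhof (1961) characteristic-function inversion -----------------------
# P(Q > q) = 1/2 + (1/pi) * int_0^inf sin(theta(u)) / (u * rho(u)) du

.imhof_theta <- function(u, lambda, delta, q) {
  lu <- outer(u, lambda)
  del <- rep(delta, each = length(u))
  ones <- rep(1, length(lambda))
  0.5 * as.vector((atan(lu) + del * lu / (1 + lu^2)) %*% ones) - 0.5 * q * u
}

.imhof_dtheta <- function(u, lambda, delta, q) {
  lu2 <- outer(u, lambda)^2
  lam <- rep(lambda, each = length(u))
  del <- rep(delta, each = length(u))
  ones <- rep(1, length(lambda))
  0.5 * as.vector((lam / (1 + lu2) + del * lam * (1 - lu2) / (1 + lu2)^2) %*%
                    ones) - 0.5 * q
}

.imhof_f <- function(u, lambda, delta, q) {
  lu <- outer(u, lambda)
  lu2 <- lu^2
  del <- rep(delta, each = length(u))
  ones <- rep(1, length(lambda))
  theta <- 0.5 * as.vector((atan(lu) + del * lu / (1 + lu2)) %*% ones) -
    0.5 * q * u
  logrho <- as.vector((0.25 * log1p(lu2) + 0.5 * del * lu2 / (1 + lu2)) %*%
                        ones)
  out <- sin(theta) / (u * exp(logrho))
  out[u == 0] <- 0.5 * sum(lambda * (1 + delta)) - 0.5 * q  # limit u -> 0
  out
}

# n-point Gauss-Legendre rule on [-1, 1] via Golub-Welsch, cached by n.
.gl_rule <- local({
  cache <- list()
  function(n = 15L) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      k <- seq_len(n - 1L)
      b <- k / sqrt(4 * k^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(k, k + 1L)] <- b
      J[cbind(k + 1L, k)] <- b
      e <- eigen(J, symmetric = TRUE)
      cache[[key]] <<- list(x = e$values, w = 2 * e$vectors[1L, ]^2)
    }
    cache[[key]]
  }
})
.gl15 <- function() .gl_rule(15L)

# The integrand decays only algebraically (u^(-1 - m/2)) while oscillating
# with asymptotic period 4*pi/q, so blind adaptive quadrature on (0, Inf)
# cannot reach absolute accuracies near 1e-9 for small m.  Instead:
# integrate adaptively up to a point T beyond which the phase is strictly
# decreasing, then sum the single-signed panels between consecutive zeros
# of sin(theta) and accelerate the alternating panel series with an Euler
# transformation.
.imhof_tail <- function(q, lambda, delta, panels = 28L, rtol = 1e-12) {
  # T such that for u >= T, theta'(u) <= -q/4:
  # theta'(u) <= (s(u) - q)/2 with s(u) = sum lambda*(1+delta)/(1+l^2 u^2).
  s_fun <- function(u) sum(lambda * (1 + delta) / (1 + (lambda * u)^2))
  Tcut <- max(1, 2 * pi / q)
  while (s_fun(Tcut) > q / 2 && Tcut < 1e7) Tcut <- Tcut * 2
  if (s_fun(Tcut) > q / 2) {
    # q so small that oscillation never dominates; direct quadrature is
    # adequate there (the tail probability is essentially 1).
    int <- stats::integrate(.imhof_f, 0, Inf,
                            lambda = lambda, delta = delta, q = q,
                            subdivisions = 2000L,
                            rel.tol = 1e-10, abs.tol = 1e-12,
                            stop.on.error = FALSE)
    return(0.5 + int$value / pi)
  }
  head_int <- stats::integrate(.imhof_f, 0, Tcut,
                               lambda = lambda, delta = delta, q = q,
                               subdivisions = 2000L,
                               rel.tol = rtol, abs.tol = rtol / 100,
                               stop.on.error = FALSE)
  if (!is.finite(head_int$value)) return(NA_real_)
  # zeros of sin(theta) beyond Tcut: theta is monotone there, crossing
  # successive multiples of pi; locate them by a vectorized, safeguarded
  # Newton iteration (|theta'| >= q/4 bounds the step).
  th0 <- .imhof_theta(Tcut, lambda, delta, q)
  targets <- (ceiling(th0 / pi) - seq_len(panels + 1L)) * pi
  u <- Tcut + (th0 - targets) / (q / 2)
  # panel boundaries need only approximate the zeros: the Gauss-Legendre
  # panel integrals are exact for any partition, and near-zero boundaries
  # just keep the panel series cleanly alternating for the acceleration.
  for (it in 1:4) {
    resid <- .imhof_theta(u, lambda, delta, q) - targets
    if (max(abs(resid)) < 1e-4) break
    step <- resid / .imhof_dtheta(u, lambda, delta, q)
    step <- pmin(pmax(step, -4 * pi / q), 4 * pi / q)
    u <- pmax(u - step, Tcut)
  }
  zeros <- sort(u)
  bridge <- stats::integrate(.imhof_f, Tcut, zeros[1L],
                             lambda = lambda, delta = delta, q = q,
                             rel.tol = 1e-10, abs.tol = 1e-15,
                             stop.on.error = FALSE)$value
  # fixed Gauss-Legendre rule per panel, all panels in one evaluation
  gl <- .gl15()
  a <- zeros[seq_len(panels)]
  b <- zeros[seq_len(panels) + 1L]
  half <- (b - a) / 2
  mid <- (a + b) / 2
  nodes <- as.vector(outer(gl$x, half) + rep(mid, each = 15L))
  vals <- matrix(.imhof_f(nodes, lambda, delta, q), nrow = 15L)
  panel_vals <- colSums(vals * gl$w) * half
  tail_sum <- .euler_alternating(panel_vals)
  0.5 + (head_int$value + bridge + tail_sum) / pi
}

# Euler transformation of an alternating series given its signed terms.
.euler_alternating <- function(terms) {
  n <- length(terms)
  if (n == 0L || all(terms == 0)) return(0)
  a <- abs(terms)
  sgn <- sign(terms[1L])
  total <- 0
  coef <- 0.5
  for (k in seq_len(min(n, 30L))) {
    total <- total + coef * a[1L]
    a <- -(a[-1L] - a[-length(a)])   # signed forward difference
    coef <- coef / 2
    if (length(a) == 0L || abs(coef * a[1L]) < 1e-17) break
  }
  sgn * total
}

# --- saddlepoint route ----------------------------------------------------
# Cumulant generating function of the mixture and derivatives.
# Domain: t < 1 / (2 max(lambda)).
.mix_K <- function(t, lambda, delta) {
  r <- 1 - 2 * t * lambda
  sum(-0.5 * log(r) + delta * lambda * t / r)
}
.mix_K1 <- function(t, lambda, delta) {
  r <- 1 - 2 * t * lambda
  sum(lambda / r + delta * lambda / r^2)
}
.mix_K2 <- function(t, lambda, delta) {
  r <- 1 - 2 * t * lambda
  sum(2 * lambda^2 / r^2 + 4 * delta * lambda^2 / r^3)
}

.saddle_root <- function(q, lambda, delta) {
  tmax <- 1 / (2 * max(lambda))
  f <- function(t) .mix_K1(t, lambda, delta) - q
  if (f(0) == 0) return(0)
  if (f(0) < 0) {                       # q above the mean: zeta > 0
    lo <- 0
    hi <- tmax * (1 - 1e-8)
    while (f(hi) < 0 && tmax - hi > .Machine$double.xmin) {
      hi <- tmax - (tmax - hi) / 10
    }
  } else {                              # q below the mean: zeta < 0
    hi <- 0
    lo <- -1
    while (f(lo) > 0 && lo > -1e12) lo <- lo * 4
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
}

# Lugannani-Rice upper-tail approximation (both sides of the mean).
.saddlepoint_tail <- function(q, lambda, delta) {
  zeta <- .saddle_root(q, lambda, delta)
  if (abs(zeta) < 1e-10) return(0.5)
  w <- sign(zeta) * sqrt(2 * (zeta * q - .mix_K(zeta, lambda, delta)))
  v <- zeta * sqrt(.mix_K2(zeta, lambda, delta))
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# Saddlepoint density, used for Newton steps in quantile inversion.
.saddlepoint_pdf <- function(q, lambda, delta) {
  zeta <- .saddle_root(q, lambda, delta)
  exp(.mix_K(zeta, lambda, delta) - zeta * q) /
    sqrt(2 * pi * .mix_K2(zeta, lambda, delta))
}

# Tail and density from a single saddle-root solve.
.sp_tail_pdf <- function(q, lambda, delta) {
  zeta <- .saddle_root(q, lambda, delta)
  K <- .mix_K(zeta, lambda, delta)
  K2 <- .mix_K2(zeta, lambda, delta)
  pdf <- exp(K - zeta * q) / sqrt(2 * pi * K2)
  if (abs(zeta) < 1e-10) return(c(0.5, pdf))
  w <- sign(zeta) * sqrt(2 * (zeta * q - K))
  v <- zeta * sqrt(K2)
  c(stats::pnorm(w + log(v / w) / w, lower.tail = FALSE), pdf)
}

.mixture_tail_core <- function(q, lambda, delta, panels = 28L,
                               rtol = 1e-12) {
  if (q == 0) return(1)
  if (length(lambda) == 1L) {
    p <- stats::pchisq(q / lambda, df = 1, ncp = delta, lower.tail = FALSE)
    return(min(max(p, .Machine$double.xmin), 1))
  }
  p <- tryCatch(.imhof_tail(q, lambda, delta, panels, rtol),
                error = function(e) NA_real_)
  mu <- sum(lambda * (1 + delta))
  if (is.na(p) || p < 1e-8) {
    if (q > mu) {
      p2 <- tryCatch(.saddlepoint_tail(q, lambda, delta),
                     error = function(e) NA_real_)
      if (!is.na(p2)) p <- p2
    } else if (is.na(p)) {
      p <- 1  # left of the mean, inversion failed: tail is essentially 1
    }
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Upper-tail probability of a weighted chi-square mixture
#'
#' Computes \eqn{P(\sum_k \lambda_k \chi^2_{1,\delta_k} > q)}.  The primary
#' route is Imhof-type characteristic-function inversion (adaptive
#' quadrature plus Euler-accelerated oscillatory tail summation); when the
#' tail probability falls below `1e-8`, where absolute quadrature error
#' would swamp the value, the saddlepoint approximation takes over, which
#' keeps a small *relative* error arbitrarily far into the tail.  A single
#' positive weight is evaluated exactly with [stats::pchisq()].
#'
#' @param q Non-negative quantile.
#' @param weights Numeric vector of mixture weights (eigenvalues); tiny
#'   negatives within `-1e-10` are clamped to zero, zero weights dropped.
#' @param ncp Optional per-component noncentrality parameters.
#' @return A tail probability clipped to `(0, 1]`.
#' @examples
#' mixture_tail(3.841459, 1)              # chi-square_1 at its 5% point
#' mixture_tail(5.991465, c(1, 1))        # chi-square_2 at its 5% point
#' @export
mixture_tail <- function(q, weights, ncp = NULL) {
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q))
  if (q < 0) stop("q must be non-negative")
  mix <- .clean_weights(weights, ncp)
  .mixture_tail_core(q, mix$lambda, mix$delta)
}

#' Upper-tail quantile of a weighted chi-square mixture
#'
#' Inverts [mixture_tail()]: cheap saddlepoint Newton iterations bring the
#' quantile close, then accurate Imhof evaluations polish it.
#'
#' @param p Target upper-tail probability in `(0, 1)`.
#' @inheritParams mixture_tail
#' @return `q` such that `mixture_tail(q, weights, ncp)` equals `p` to a
#'   relative tolerance of about `1e-8` on the probability.
#' @export
mixture_quantile <- function(p, weights, ncp = NULL) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1)
  mix <- .clean_weights(weights, ncp)
  lambda <- mix$lambda
  delta <- mix$delta
  if (length(lambda) == 1L) {
    return(lambda * stats::qchisq(p, df = 1, ncp = delta, lower.tail = FALSE))
  }
  mu <- sum(lambda * (1 + delta))
  s2 <- 2 * sum(lambda^2 * (1 + 2 * delta))
  df_eff <- max(2 * mu^2 / s2, 0.5)
  q <- mu + (stats::qchisq(p, df_eff, lower.tail = FALSE) - df_eff) *
    sqrt(s2 / (2 * df_eff))
  q <- max(q, mu * 1e-4)
  # saddlepoint Newton on log-probability scale
  for (it in 1:40) {
    tp <- .sp_tail_pdf(q, lambda, delta)
    dq <- (log(tp[1L]) - log(p)) * tp[1L] / tp[2L]
    q <- max(q + dq, q / 8)
    if (abs(dq) < 1e-10 * q) break
  }
  # polish with the accurate tail evaluation
  for (it in 1:6) {
    pa <- mixture_tail(q, lambda, delta)
    if (abs(pa - p) <= 1e-8 * p) break
    q <- max(q + (log(pa) - log(p)) * pa / .saddlepoint_pdf(q, lambda, delta),
             q / 8)
  }
  q
}
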