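#' Gene-based association tests from summary statistics
#'
#' Given a gene's vector of per-variant Z-scores \eqn{z = (z_1, ..., z_m)}
#' and the LD correlation matrix \eqn{R} estimated from a reference panel,
#' three tests of the gene-level null \eqn{z \sim MVN(0, R)} are available:
#'
#' * the **sum test** (a burden-type test) on \eqn{B = \sum_j z_j}, most
#'   powerful when effects share a direction;
#' * the **squared-sum test** (a SKAT-type variance-component test) on
#'   \eqn{Q = \sum_j z_j^2}, robust to mixed effect directions, whose null
#'   is the weighted chi-square mixture with weights the eigenvalues of
#'   \eqn{R};
#' * the **adaptive test**, the minimum p-value of the family
#'   \eqn{Q_\rho = (1-\rho) Q + \rho B^2} over a grid of \eqn{\rho} in
#'   `[0, 1]`, calibrated analytically for the minimum-taking.
#'
#' @name assoc_tests
NULL

.check_zR <- function(z, R) {
  z <- as.numeric(z)
  R <- as.matrix(R)
  m <- length(z)
  if (m < 2L) stop("gene-based tests require at least 2 variants")
  if (!all(dim(R) == m)) stop("dim(R) does not match length(z)")
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  list(z = z, R = (R + t(R)) / 2, m = m)
}

#' Sum (burden) test
#'
#' Tests \eqn{B = \sum_j z_j} against its null \eqn{N(0, 1'R1)}.
#'
#' @param z Numeric vector of variant Z-scores (length `m >= 2`).
#' @param R `m x m` LD correlation matrix of the Z-scores.
#' @return List with `statistic` (B) and `p`.
#' @export
sum_test <- function(z, R) {
  x <- .check_zR(z, R)
  B <- sum(x$z)
  v <- sum(x$R)
  if (v <= 0) stop("degenerate null variance 1'R1 <= 0")
  list(statistic = B, p = 2 * stats::pnorm(-abs(B) / sqrt(v)))
}

#' Squared-sum (SKAT-type) test
#'
#' Tests \eqn{Q = \sum_j z_j^2}; under the null Q follows the weighted
#' chi-square mixture with weights the eigenvalues of `R`.
#'
#' @inheritParams sum_test
#' @return List with `statistic` (Q), `p`, and the mixture `weights`.
#' @export
ssq_test <- function(z, R) {
  x <- .check_zR(z, R)
  Q <- sum(x$z^2)
  lambda <- eigen(x$R, symmetric = TRUE, only.values = TRUE)$values
  list(statistic = Q, p = mixture_tail(Q, lambda), weights = lambda)
}

# Eigenvalues of the null kernel of Q_rho = (1-rho) Q + rho B^2, i.e. of
# R^{1/2} A_rho R^{1/2} with A_rho = (1-rho) I + rho 11'.  Computed in the
# symmetric form (1-rho) R + rho u u', u = R^{1/2} 1, from one spectral
# decomposition of R.
.rho_weights <- function(Rsqrt_u, R, rho) {
  m <- nrow(R)
  M <- (1 - rho) * R + rho * tcrossprod(Rsqrt_u)
  eigen(M, symmetric = TRUE, only.values = TRUE)$values
}

.R_sqrt_one <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  as.vector(e$vectors %*% (sqrt(vals) * crossprod(e$vectors, rep(1, nrow(R)))))
}

#' Adaptive (omnibus) gene-based test
#'
#' Computes \eqn{Q_\rho = (1-\rho) Q + \rho B^2} over `rho_grid`, takes the
#' minimum of the per-\eqn{\rho} p-values, and calibrates that minimum for
#' the multiplicity of the grid search via [calibrate_min_p()].
#'
#' @inheritParams sum_test
#' @param rho_grid Grid of mixing values in `[0, 1]`; default 11 equally
#'   spaced points.  `rho = 0` recovers the squared-sum test, `rho = 1` the
#'   (squared) sum test.
#' @return List with `p_at` (calibrated p-value), `rho_hat` (grid value
#'   attaining the minimum; ties broken toward smaller rho), `t_min` (raw
#'   minimum p over the grid), and `p_per_rho`.
#' @export
adaptive_test <- function(z, R, rho_grid = seq(0, 1, by = 0.1)) {
  x <- .check_zR(z, R)
  rho_grid <- sort(unique(as.numeric(rho_grid)))
  if (length(rho_grid) == 0L) stop("empty rho grid")
  if (any(rho_grid < 0 | rho_grid > 1)) stop("rho grid must lie in [0, 1]")
  B <- sum(x$z)
  Q <- sum(x$z^2)
  u <- .R_sqrt_one(x$R)
  p_per_rho <- vapply(rho_grid, function(rho) {
    q_rho <- (1 - rho) * Q + rho * B^2
    mixture_tail(q_rho, .rho_weights(u, x$R, rho))
  }, numeric(1))
  t_min <- min(p_per_rho)
  rho_hat <- rho_grid[which.min(p_per_rho)]
  p_at <- calibrate_min_p(t_min, x$R, rho_grid)
  list(p_at = p_at, rho_hat = rho_hat, t_min = t_min,
       p_per_rho = stats::setNames(p_per_rho, rho_grid))
}

#' Calibrate the minimum p-value of the adaptive test
#'
#' Computes \eqn{P(\min_\rho p_\rho \le t_{min})} under the gene-level null
#' \eqn{z \sim MVN(0, R)}.  The joint event is handled by conditioning on
#' the burden component: write \eqn{z = R1 \, b / (1'R1) + e} with
#' \eqn{b = 1'z \sim N(0, 1'R1)} independent of the residual \eqn{e}.  Each
#' per-\eqn{\rho} acceptance region \eqn{Q_\rho < q_\rho(t_{min})} becomes a
#' bound on \eqn{S = e'e + (2b/1'R1) (R1)'e}, whose conditional law given
#' `b` is an *exact* noncentral weighted chi-square (weights the nonzero
#' eigenvalues of \eqn{Cov(e)}, noncentralities proportional to
#' \eqn{b^2}), evaluated by the Imhof machinery and integrated over `b` by
#' adaptive one-dimensional quadrature.
#'
#' @param t_min Raw minimum p-value over the grid, in `(0, 1]`.
#' @param R LD correlation matrix.
#' @param rho_grid The grid the minimum was taken over.
#' @return Calibrated p-value, clamped into the Bonferroni sandwich
#'   `[t_min, min(1, t_min * length(rho_grid))]`.
#' @export
calibrate_min_p <- function(t_min, R, rho_grid) {
  stopifnot(is.numeric(t_min), length(t_min) == 1L, t_min > 0, t_min <= 1)
  rho_grid <- sort(unique(as.numeric(rho_grid)))
  K <- length(rho_grid)
  if (K == 0L) stop("empty rho grid")
  if (K == 1L || t_min >= 1) {
    return(min(max(t_min, 0), 1))
  }
  R <- as.matrix(R)
  m <- nrow(R)
  cc <- sum(R)                       # 1'R1, null variance of the burden sum
  w <- as.vector(R %*% rep(1, m))    # R1
  wtw <- sum(w^2)
  u <- .R_sqrt_one(R)
  # per-rho thresholds on Q_rho at tail probability t_min
  q_rho <- vapply(rho_grid, function(rho) {
    mixture_quantile(t_min, .rho_weights(u, R, rho))
  }, numeric(1))
  has_one <- any(rho_grid >= 1 - 1e-12)
  sub <- rho_grid < 1 - 1e-12
  rho_s <- rho_grid[sub]
  q_s <- q_rho[sub]
  tau <- rho_s + (1 - rho_s) * wtw / cc^2
  # residual spectral pieces: Cov(e) = R - ww'/c
  Sig_e <- R - tcrossprod(w) / cc
  ee <- eigen(Sig_e, symmetric = TRUE)
  pos <- ee$values > max(ee$values) * 1e-12
  lam_e <- ee$values[pos]
  Uw <- as.vector(crossprod(ee$vectors[, pos, drop = FALSE], w))
  # P(S >= s | b = eta): S + shift(eta) ~ sum lam_e * chisq_1(delta(eta)),
  # an exact noncentral mixture; moderate quadrature accuracy suffices
  # here because the outer integral smooths the values and the final
  # answer is clamped into the Bonferroni sandwich.
  cond_tail <- function(eta, s) {
    dl <- (eta / cc)^2 * Uw^2 / lam_e
    shift <- sum(lam_e * dl)
    if (s + shift <= 0) return(1)
    .mixture_tail_core(s + shift, lam_e, dl, panels = 20L, rtol = 1e-9)
  }
  accept_prob <- function(eta) {      # P(no rho rejects | b = eta)
    s_min <- min((q_s - tau * eta^2) / (1 - rho_s))
    1 - cond_tail(eta, s_min)
  }
  upper <- if (has_one) sqrt(q_rho[which(!sub)[1L]]) else 8.3 * sqrt(cc)
  # fixed Gauss-Legendre rule on b in [0, upper] (integrand is even in b)
  gl <- .gl_rule(48L)
  eta <- (gl$x + 1) / 2 * upper
  wts <- gl$w * upper / 2
  vals <- vapply(eta, function(e1) {
    accept_prob(e1) * stats::dnorm(e1, sd = sqrt(cc))
  }, numeric(1))
  p_no <- 2 * sum(wts * vals)
  p_at <- 1 - p_no
  # Bonferroni sandwich: the exact answer must lie in this band; clamping
  # absorbs residual quadrature error.
  min(max(p_at, t_min), min(1, t_min * K))
}

#' Bonferroni family-wise significance threshold
#'
#' @param n_tests Number of tests performed (>= 1).
#' @param alpha Family-wise error rate.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(20000, 0.05)   # 2.5e-6, the genome-wide gene level
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a positive integer")
  }
  alpha / n_tests
}

#' Scan a collection of gene SNP sets
#'
#' Runs the three tests on every gene, applies the Bonferroni threshold
#' for the number of genes actually tested, and returns Manhattan-plot
#' ready coordinates (chromosome, window midpoint, -log10 adaptive p).
#'
#' @param sets List of [gene_snp_set()] objects.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param rho_grid Grid for the adaptive test.
#' @return List with `results` (one row per gene: gene_id, chrom, m, p_st,
#'   p_s2t, p_at, rho_hat, significant), `threshold`, and `manhattan`.
#' @export
genome_scan <- function(sets, alpha = 0.05, rho_grid = seq(0, 1, by = 0.1)) {
  if (length(sets) == 0L) {
    empty <- data.frame(gene_id = character(), chrom = integer(),
                        m = integer(), p_st = numeric(), p_s2t = numeric(),
                        p_at = numeric(), rho_hat = numeric(),
                        significant = logical())
    return(list(results = empty, threshold = NA_real_,
                manhattan = data.frame(gene_id = character(),
                                       chrom = integer(), pos = numeric(),
                                       neglog10_p = numeric())))
  }
  rows <- lapply(sets, function(s) {
    st <- sum_test(s$z, s$R)
    s2 <- ssq_test(s$z, s$R)
    at <- adaptive_test(s$z, s$R, rho_grid)
    data.frame(gene_id = s$gene$gene_id, chrom = s$gene$chrom,
               m = length(s$z), p_st = st$p, p_s2t = s2$p,
               p_at = at$p_at, rho_hat = at$rho_hat,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  thr <- bonferroni_threshold(nrow(res), alpha)
  res$significant <- res$p_at < thr
  man <- data.frame(
    gene_id = res$gene_id,
    chrom = res$chrom,
    pos = vapply(sets, function(s) (s$gene$tx_start + s$gene$tx_end) / 2,
                 numeric(1)),
    neglog10_p = -log10(res$p_at)
  )
  rownames(man) <- NULL
  list(results = res, threshold = thr, manhattan = man)
}
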