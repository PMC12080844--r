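# Small in-code fixtures shared across test files.

# a well-formed PGC daner-style summary-statistics file
write_toy_sumstats <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      CHR = c(1L, 1L, 2L),
      SNP = c("rs1", "rs2", "rs3"),
      BP = c(1000L, 2000L, 3000L),
      A1 = c("A", "G", "C"),
      A2 = c("G", "A", "T"),
      INFO = c(0.95, 0.99, 0.92),
      OR = c(1.10, 0.92, 1.05),
      SE = c(0.04, 0.05, 0.03),
      P = c(0.02, 0.10, 0.30)
    )
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a tiny deterministic reference panel: 4 variants on chr 1, 6 samples
toy_panel <- function() {
  variants <- data.frame(
    chrom = "1", pos = c(1000, 2000, 3000, 4000),
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    ref_allele = c("G", "A", "T", "C"),
    alt_allele = c("A", "G", "C", "A"),
    stringsAsFactors = FALSE
  )
  dos <- cbind(
    c(0, 1, 2, 1, 0, 2),
    c(2, 1, 0, 1, 2, 0),
    c(0, 1, 2, 2, 1, 0),
    c(1, 0, 2, 1, 2, 0)
  )
  reference_panel(variants, dos)
}

# correlation matrix with exchangeable structure
exch_cor <- function(m, rho) {
  R <- matrix(rho, m, m)
  diag(R) <- 1
  R
}

# random positive-definite correlation matrix
rand_cor <- function(m, seed) {
  set.seed(seed)
  A <- matrix(rnorm(m * m), m)
  stats::cov2cor(crossprod(A) + diag(m) * 0.5)
}

# Monte-Carlo oracle for the calibrated adaptive test: the probability
# that the minimum per-rho p-value falls at or below the observed one,
# evaluated by simulating the full min-p statistic.  Works through the
# per-rho quantiles at t_min, which is an exact reformulation because
# each per-rho p-value is monotone in its statistic.
mc_adaptive_oracle <- function(z, R, grid, n = 1e6, seed = 99) {
  m <- length(z)
  B <- sum(z); Q <- sum(z * z)
  u <- sumgene:::.R_sqrt_one(R)
  pr <- vapply(grid, function(r) {
    mixture_tail((1 - r) * Q + r * B^2, sumgene:::.rho_weights(u, R, r))
  }, numeric(1))
  tmin <- min(pr)
  qr <- vapply(grid, function(r) {
    mixture_quantile(tmin, sumgene:::.rho_weights(u, R, r))
  }, numeric(1))
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = R)
  Bs <- rowSums(Z); Qs <- rowSums(Z^2)
  rej <- rep(FALSE, n)
  for (i in seq_along(grid)) {
    rej <- rej | ((1 - grid[i]) * Qs + grid[i] * Bs^2 >= qr[i])
  }
  list(p = mean(rej), se = stats::sd(rej) / sqrt(n), t_min = tmin)
}
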