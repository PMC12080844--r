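# Summary-statistic reading, QC filtering, and the Z computation.

test_that("a well-formed file reads into one record per row", {
  f <- write_toy_sumstats(tempfile(fileext = ".tsv"))
  x <- read_sumstats(f)
  expect_equal(nrow(x), 3L)
  expect_equal(attr(x, "n_dropped"), 0L)
  expect_equal(x$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(x$odds_ratio, c(1.10, 0.92, 1.05))
})

test_that("rows with unparseable numerics are dropped and counted", {
  rows <- data.frame(CHR = 1L, SNP = c("rs1", "rs2"), BP = c(100L, 200L),
                     A1 = "A", A2 = "G", INFO = 0.95,
                     OR = c("NA", "1.1"), SE = 0.04, P = 0.5)
  f <- write_toy_sumstats(tempfile(fileext = ".tsv"), rows)
  x <- read_sumstats(f)
  expect_equal(nrow(x), 1L)
  expect_equal(attr(x, "n_dropped"), 1L)
  expect_equal(x$rsid, "rs2")
})

test_that("a missing required column raises a configuration error", {
  rows <- data.frame(CHR = 1L, SNP = "rs1", BP = 100L, A1 = "A", A2 = "G",
                     INFO = 0.95, OR = 1.1, P = 0.5)   # no SE
  f <- write_toy_sumstats(tempfile(fileext = ".tsv"), rows)
  expect_error(read_sumstats(f), "se")
})

test_that("write-then-read round-trips under the default dialect", {
  f <- write_toy_sumstats(tempfile(fileext = ".tsv"))
  x <- compute_z(read_sumstats(f))
  f2 <- tempfile(fileext = ".tsv")
  write_sumstats(x, f2)
  y <- read_sumstats(f2)
  expect_equal(y$rsid, x$rsid)
  expect_equal(y$odds_ratio, x$odds_ratio, tolerance = 1e-12)
  expect_equal(y$info, x$info)
  expect_equal(compute_z(y)$z, x$z, tolerance = 1e-12)
})

make_rec <- function(chrom = "1", rsid = "rsX", pos = 1, a1 = "A",
                     a2 = "G", info = 0.95, or = 1.1, se = 0.05,
                     p = 0.5) {
  data.frame(chrom = chrom, pos = pos, rsid = rsid, effect_allele = a1,
             other_allele = a2, info = info, odds_ratio = or, se = se,
             pvalue = p, z = NA_real_, stringsAsFactors = FALSE)
}

test_that("each QC rule removes what it should, at the boundary", {
  recs <- rbind(
    make_rec(rsid = "ok"),
    make_rec(rsid = "chrX", chrom = "X"),
    make_rec(rsid = "indel", a1 = "AT"),
    make_rec(rsid = "ambig", a1 = "A", a2 = "T"),
    make_rec(rsid = "lowinfo", info = 0.89),
    make_rec(rsid = "exactinfo", info = 0.9),
    make_rec(rsid = "noinfo", info = NA),
    make_rec(rsid = "dup"), make_rec(rsid = "dup")
  )
  out <- qc_filter(recs)
  expect_setequal(out$retained$rsid, c("ok", "exactinfo"))
  expect_equal(out$removed[["autosome"]], 1L)
  expect_equal(out$removed[["alleles"]], 1L)
  expect_equal(out$removed[["strand_ambiguous"]], 1L)
  expect_equal(out$removed[["info"]], 2L)       # low + missing
  expect_equal(out$removed[["duplicate_rsid"]], 2L)  # both copies
})

test_that("removal attribution is exact: retained + removed = input", {
  set.seed(42)
  n <- 200
  recs <- make_rec()[rep(1, n), ]
  recs$rsid <- sprintf("rs%d", sample(120, n, replace = TRUE))
  recs$chrom <- sample(c(1:22, "X"), n, replace = TRUE)
  recs$info <- runif(n, 0.8, 1)
  recs$effect_allele <- sample(c("A", "C", "G", "T", "AT"), n, TRUE)
  recs$other_allele <- sample(c("A", "C", "G", "T"), n, TRUE)
  recs <- recs[recs$effect_allele != recs$other_allele, ]
  out <- qc_filter(recs)
  expect_equal(nrow(out$retained) + sum(out$removed), nrow(recs))
})

test_that("qc_filter is idempotent and tolerates empty input", {
  f <- write_toy_sumstats(tempfile(fileext = ".tsv"))
  x <- read_sumstats(f)
  once <- qc_filter(x)
  twice <- qc_filter(once$retained)
  expect_equal(twice$retained, once$retained)
  expect_true(all(twice$removed == 0L))
  empty <- qc_filter(x[0, ])
  expect_equal(nrow(empty$retained), 0L)
  expect_true(all(empty$removed == 0L))
})

test_that("Z = log(OR)/SE with the right sign and exact inverse", {
  expect_equal(compute_z(make_rec(or = 1, se = 0.3))$z, 0)
  expect_equal(compute_z(make_rec(or = 1.2, se = 0.05))$z,
               log(1.2) / 0.05, tolerance = 1e-12)
  expect_lt(compute_z(make_rec(or = 0.8, se = 0.1))$z, 0)
  # exponentiating z * se recovers the odds ratio
  set.seed(1)
  recs <- make_rec()[rep(1, 50), ]
  recs$odds_ratio <- exp(rnorm(50, 0, 0.2))
  recs$se <- runif(50, 0.01, 0.2)
  z <- compute_z(recs)
  expect_equal(exp(z$z * z$se), recs$odds_ratio, tolerance = 1e-10)
  expect_error(compute_z(make_rec(or = 0)), "odds_ratio")
  expect_error(compute_z(make_rec(se = 0)), "se")
})
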