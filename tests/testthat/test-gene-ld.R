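# Gene windows, panel harmonization, LD estimation, perfect-LD pruning.

test_that("gene window boundaries are inclusive at exactly +/- flank", {
  g <- gene_annotation("g1", chrom = 1, tx_start = 10000, tx_end = 20000)
  v <- data.frame(chrom = "1",
                  pos = c(9000, 8999, 21000, 21001, 15000),
                  rsid = paste0("rs", 1:5), stringsAsFactors = FALSE)
  got <- assign_to_gene(v, g, flank = 1000)
  expect_setequal(got$rsid, c("rs1", "rs3", "rs5"))
})

test_that("window assignment is monotone in the flank", {
  g <- gene_annotation("g1", chrom = 2, tx_start = 5000, tx_end = 9000)
  set.seed(7)
  v <- data.frame(chrom = "2", pos = sample(1000:15000, 80),
                  rsid = sprintf("rs%03d", 1:80), stringsAsFactors = FALSE)
  narrow <- assign_to_gene(v, g, flank = 0)
  wide <- assign_to_gene(v, g, flank = 1000)
  expect_true(all(narrow$rsid %in% wide$rsid))
})

hvar <- function(rsid, a1, a2, z = 1.5, chrom = "1", pos = 1000) {
  data.frame(chrom = chrom, pos = pos, rsid = rsid, effect_allele = a1,
             other_allele = a2, info = 0.95, odds_ratio = exp(z * 0.05),
             se = 0.05, pvalue = 0.5, z = z, stringsAsFactors = FALSE)
}

test_that("harmonization keeps, flips, or drops by allele orientation", {
  pan <- toy_panel()   # rs1: ref G / alt A
  keep <- harmonize_to_panel(hvar("rs1", "A", "G"), pan)
  expect_equal(keep$harmonized$z, 1.5)
  flip <- harmonize_to_panel(hvar("rs1", "G", "A"), pan)
  expect_equal(flip$harmonized$z, -1.5)
  drop <- harmonize_to_panel(hvar("rs1", "C", "T"), pan)
  expect_equal(nrow(drop$harmonized), 0L)
  expect_equal(drop$dropped$reason, "allele_mismatch")
  absent <- harmonize_to_panel(hvar("rs99", "A", "G", pos = 777), pan)
  expect_equal(absent$dropped$reason, "absent_from_panel")
})

test_that("harmonization is idempotent", {
  pan <- toy_panel()
  v <- rbind(hvar("rs1", "G", "A"), hvar("rs2", "G", "A", z = -0.7,
                                         pos = 2000))
  once <- harmonize_to_panel(v, pan)$harmonized
  twice <- harmonize_to_panel(once, pan)$harmonized
  expect_equal(twice, once)
})

test_that("a shared rsid at a different position is dropped with reason", {
  pan <- toy_panel()
  v <- hvar("rs1", "A", "G", pos = 99999)
  out <- harmonize_to_panel(v, pan)
  expect_equal(out$dropped$reason, "position_mismatch")
})

test_that("LD is the Pearson correlation of panel dosages", {
  variants <- data.frame(chrom = "1", pos = c(100, 200),
                         rsid = c("x", "y"), ref_allele = "G",
                         alt_allele = "A", stringsAsFactors = FALSE)
  pan <- reference_panel(variants, cbind(c(0, 1, 2, 1), c(2, 1, 0, 1)))
  R <- ld_matrix(pan, c("x", "y"))
  expect_equal(R["x", "y"], -1)
  expect_equal(diag(R), c(x = 1, y = 1))
  # independent two-pass covariance oracle
  a <- c(0, 1, 2, 1); b <- c(0, 1, 2, 2)
  two_pass <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  pan2 <- reference_panel(variants, cbind(a, b))
  expect_equal(ld_matrix(pan2, c("x", "y"))["x", "y"], two_pass,
               tolerance = 1e-12)
})

test_that("zero-variance dosages raise an error naming the variant", {
  variants <- data.frame(chrom = "1", pos = c(100, 200),
                         rsid = c("flat", "ok"), ref_allele = "G",
                         alt_allele = "A", stringsAsFactors = FALSE)
  pan <- reference_panel(variants, cbind(rep(1, 4), c(0, 1, 2, 1)))
  expect_error(ld_matrix(pan, c("flat", "ok")), "flat")
})

test_that("pruning keeps the earlier member of a perfect pair", {
  g <- gene_annotation("g1", chrom = 1, tx_start = 1, tx_end = 10)
  R <- exch_cor(3, 0.2)
  R[1, 3] <- R[3, 1] <- 1          # rs_a and rs_c duplicated
  s <- gene_snp_set(g, c("rs_a", "rs_b", "rs_c"), c(1, 2, 1), R)
  out <- prune_perfect_ld(s)
  expect_equal(out$rsids, c("rs_a", "rs_b"))
  expect_equal(out$z, c(1, 2))
})

test_that("three mutually perfect variants collapse to one survivor", {
  g <- gene_annotation("g1", chrom = 1, tx_start = 1, tx_end = 10)
  R <- matrix(1, 3, 3)
  s <- gene_snp_set(g, c("a", "b", "c"), c(1, 1, 1), R)
  expect_null(prune_perfect_ld(s))   # below 2 SNPs: gene dropped
  # with a fourth independent variant, exactly one of the triple survives
  R4 <- rbind(cbind(R, 0), 0)
  R4[4, 4] <- 1
  s4 <- gene_snp_set(g, c("a", "b", "c", "d"), c(1, 1, 1, 0.5), R4)
  out <- prune_perfect_ld(s4)
  expect_equal(out$rsids, c("a", "d"))
})

test_that("pruning leaves sub-threshold and negative correlations alone", {
  g <- gene_annotation("g1", chrom = 1, tx_start = 1, tx_end = 10)
  R <- matrix(c(1, -1, -1, 1), 2)
  s <- gene_snp_set(g, c("a", "b"), c(1, -1), R)
  expect_equal(prune_perfect_ld(s)$rsids, c("a", "b"))  # r = -1 retained
  R2 <- exch_cor(4, 0.999999999)   # above 1 - epsilon for default epsilon
  s2 <- gene_snp_set(g, letters[1:4], rep(1, 4), R2)
  expect_null(prune_perfect_ld(s2))
  R3 <- exch_cor(4, 0.95)
  s3 <- gene_snp_set(g, letters[1:4], rep(1, 4), R3)
  expect_equal(prune_perfect_ld(s3)$rsids, letters[1:4])
})

test_that("after pruning no off-diagonal reaches 1 - epsilon", {
  set.seed(11)
  g <- gene_annotation("g1", chrom = 1, tx_start = 1, tx_end = 10)
  for (rep in 1:20) {
    m <- sample(3:7, 1)
    R0 <- rand_cor(m, seed = rep)
    dup <- sample(m, 1)
    R <- rbind(cbind(R0, R0[, dup]), c(R0[dup, ], 1))
    ids <- sprintf("v%d", seq_len(m + 1))
    s <- gene_snp_set(g, ids, rnorm(m + 1), R)
    out <- prune_perfect_ld(s)
    if (!is.null(out)) {
      off <- out$R; diag(off) <- 0
      expect_lt(max(off), 1 - 1e-8)
    }
  }
})

test_that("panel TSV round-trips", {
  pan <- toy_panel()
  f <- tempfile(fileext = ".tsv")
  write_panel_tsv(pan, f)
  back <- read_panel_tsv(f)
  expect_equal(back$variants$rsid, pan$variants$rsid)
  expect_equal(unname(back$dosages), unname(pan$dosages))
})
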