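# Synthetic-data generators: determinism, LD structure, QC bookkeeping.

test_that("generators are pure functions of the configuration", {
  cfg <- sim_config(seed = 11, n_genes = 6)
  a <- sim_reference_panel(cfg)
  b <- sim_reference_panel(cfg)
  expect_identical(a$panel$dosages, b$panel$dosages)
  expect_identical(sim_gwas_sumstats(a, cfg)$sumstats,
                   sim_gwas_sumstats(b, cfg)$sumstats)
  expect_identical(sim_counts(cfg, "nb")$study$counts,
                   sim_counts(cfg, "nb")$study$counts)
  expect_identical(sim_mr(cfg)$exposure, sim_mr(cfg)$exposure)
  # a different seed changes the data
  cfg2 <- sim_config(seed = 12, n_genes = 6)
  expect_false(identical(sim_reference_panel(cfg2)$panel$dosages,
                         a$panel$dosages))
})

test_that("panel LD matches the requested exchangeable correlation", {
  cfg0 <- sim_config(seed = 2, n_genes = 4, n_ref_samples = 2000,
                     ld_block_rho = 0, dup_ld_gene_fraction = 0,
                     snps_per_gene = c(6L, 6L))
  sim0 <- sim_reference_panel(cfg0)
  for (g in sim0$genes) {
    ids <- sumgene:::.gene_rsids(sim0$panel, g)
    R <- cor(sim0$panel$dosages[, ids])
    off <- abs(R[upper.tri(R)])
    expect_lt(mean(off), 3 / sqrt(cfg0$n_ref_samples))
  }
  cfg8 <- sim_config(seed = 3, n_genes = 4, n_ref_samples = 5000,
                     ld_block_rho = 0.8, dup_ld_gene_fraction = 0,
                     snps_per_gene = c(6L, 6L))
  sim8 <- sim_reference_panel(cfg8)
  offs <- unlist(lapply(sim8$genes, function(g) {
    ids <- sumgene:::.gene_rsids(sim8$panel, g)
    R <- cor(sim8$panel$dosages[, ids])
    R[upper.tri(R)]
  }))
  expect_lt(abs(mean(offs) - 0.8), 0.05)
})

test_that("back-filled OR/SE reproduce the simulated Z exactly", {
  cfg <- sim_config(seed = 4, n_genes = 8, n_strand_ambiguous = 0L,
                    n_duplicate_pairs = 0L, frac_swapped_alleles = 0)
  sim <- sim_reference_panel(cfg)
  ss <- sim_gwas_sumstats(sim, cfg)$sumstats
  z <- compute_z(ss)$z
  expect_equal(exp(z * ss$se), ss$odds_ratio, tolerance = 1e-12)
  expect_equal(ss$pvalue, 2 * pnorm(-abs(z)), tolerance = 1e-10)
})

test_that("injected QC violations are recovered by the filter counts", {
  cfg <- sim_config(seed = 5, n_genes = 10, n_strand_ambiguous = 7L,
                    n_duplicate_pairs = 4L)
  sim <- sim_reference_panel(cfg)
  gw <- sim_gwas_sumstats(sim, cfg)
  out <- qc_filter(gw$sumstats)
  expect_equal(out$removed[["strand_ambiguous"]],
               unname(gw$injected["strand_ambiguous"]))
  expect_equal(out$removed[["duplicate_rsid"]],
               unname(gw$injected["duplicate_rsid"]))
  expect_equal(out$removed[["info"]], sum(!is.na(gw$sumstats$info) &
                                            gw$sumstats$info < 0.9 &
                                            !grepl("AMB|DUP", gw$sumstats$rsid)))
})

test_that("swapped-allele rows harmonize back to the panel orientation", {
  cfg <- sim_config(seed = 6, n_genes = 5, frac_swapped_alleles = 1,
                    info_range = c(0.95, 1), n_strand_ambiguous = 0L,
                    n_duplicate_pairs = 0L, dup_ld_gene_fraction = 0)
  sim <- sim_reference_panel(cfg)
  ss <- compute_z(sim_gwas_sumstats(sim, cfg)$sumstats)
  h <- harmonize_to_panel(ss, sim$panel)
  expect_equal(nrow(h$harmonized), nrow(ss))       # nothing dropped
  # after harmonization the effect allele is the panel alt allele
  idx <- match(h$harmonized$rsid, sim$panel$variants$rsid)
  expect_equal(h$harmonized$effect_allele,
               sim$panel$variants$alt_allele[idx])
})

test_that("generated files round-trip through the module readers", {
  cfg <- sim_config(seed = 7, n_genes = 4)
  sim <- sim_reference_panel(cfg)
  pf <- tempfile(fileext = ".tsv")
  write_panel_tsv(sim$panel, pf)
  pan2 <- read_panel_tsv(pf)
  expect_equal(pan2$variants$rsid, sim$panel$variants$rsid)
  expect_equal(unname(pan2$dosages), unname(sim$panel$dosages),
               tolerance = 1e-12)
  gw <- sim_gwas_sumstats(sim, cfg)
  sf <- tempfile(fileext = ".tsv")
  write_sumstats(gw$sumstats, sf)
  ss2 <- read_sumstats(sf)
  expect_equal(nrow(ss2), nrow(gw$sumstats))
  expect_equal(ss2$odds_ratio, gw$sumstats$odds_ratio, tolerance = 1e-12)
  cc <- sim_counts(cfg, "logistic")
  cf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  write_expression_study(cc$study, cf, mf)
  st2 <- read_expression_study(cf, mf)
  expect_equal(st2$counts, cc$study$counts)
  expect_equal(st2$samples$diagnosis, cc$study$samples$diagnosis)
})

test_that("MR generator injects exactly the advertised harmonization work", {
  cfg <- sim_config(seed = 8)
  mr <- sim_mr(cfg)
  inst <- mr_instruments(mr$exposure, mr$outcome)
  h <- harmonize_pair(inst)
  expect_equal(nrow(h$dropped), unname(mr$injected["palindromic"]))
  expect_true(all(h$dropped$reason == "palindromic_maf_not_inferable"))
  expect_equal(nrow(h$harmonized),
               cfg$mr_model$n_tissues - mr$injected[["palindromic"]])
  # swapped rows come back to the exposure orientation with the sign
  # of the raw outcome beta reversed
  swapped <- mr$outcome$effect_allele != mr$exposure$effect_allele
  idx <- match(mr$outcome$tissue[swapped], h$harmonized$tissue)
  expect_equal(h$harmonized$outcome_beta[idx],
               -mr$outcome$beta[swapped])
  expect_equal(h$harmonized$outcome_ea[idx],
               mr$exposure$effect_allele[swapped])
})
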