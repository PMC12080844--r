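#' Seed-deterministic synthetic data for every pipeline stage
#'
#' Generators that emulate the structure of the real inputs — a
#' European-reference-style dosage panel with block-exchangeable LD,
#' case/control GWAS summary statistics whose gene-level Z-vectors are
#' multivariate normal around a known signal, covariate-linked RNA-seq
#' count matrices for both differential-expression designs, and
#' per-tissue top-eQTL instrument tables with a known causal effect —
#' so that every stage of the pipeline can be validated against ground
#' truth.  All generators are pure functions of the configuration: the
#' same [sim_config()] always yields byte-identical outputs.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults encode the study conditions the generators emulate: a
#' 503-sample reference panel (the size of the 1000 Genomes European
#' panel), 20 case / 19 control and 3 case / 3 control expression
#' designs, covariate effects at the scale of the dichotomized logistic
#' model's reported coefficients, a log2 fold change of 1.17 for
#' expression signal genes, and 30 MR tissues.
#'
#' @param seed Integer master seed.
#' @param n_ref_samples Reference panel sample count.
#' @param n_genes Number of genes in the GWAS simulation.
#' @param snps_per_gene Integer range (min, max) of SNPs per gene.
#' @param ld_block_rho Within-gene exchangeable dosage correlation in
#'   `[0, 1)`.
#' @param causal_gene_fraction Fraction of genes given a mean shift.
#' @param signal_mean_shift Per-SNP mean of Z under the alternative.
#' @param info_range INFO scores are drawn uniformly from this range
#'   (straddling the 0.9 filter so QC is exercised).
#' @param se_range Range of per-variant log-odds standard errors.
#' @param frac_swapped_alleles Fraction of summary rows written with
#'   effect/other alleles in the opposite order to the panel (their Z is
#'   negated accordingly, so harmonization must recover the sign).
#' @param n_strand_ambiguous,n_duplicate_pairs Deliberately injected
#'   QC-violating intergenic rows: A/T-allele rows, and pairs of rows
#'   sharing a fresh rsID (both copies of each pair are removed by QC).
#' @param dup_ld_gene_fraction Fraction of genes given one exactly
#'   duplicated dosage column, to exercise perfect-LD pruning.
#' @param count_model List: `n_case`, `n_control`, `n_genes`,
#'   `mean_log`, `mean_sdlog` (log-normal baseline means), `dispersion`
#'   range, `lfc` for signal genes, and `coef` (intercept, age,
#'   sex_male, race_white, pmi, ge_high) for the logistic design.
#' @param nb_model List: `n_case`, `n_control`, `n_genes`, `frac_de`,
#'   `lfc`, `dispersion` range, `libsize_sdlog`.
#' @param mr_model List: `theta` (true causal effect), `n_tissues`,
#'   `beta_exp_mean`, `beta_exp_sd`, `se_exp`, `se_out`,
#'   `n_palindromic`, `n_swapped`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ref_samples = 503L,
                       n_genes = 100L,
                       snps_per_gene = c(6L, 12L),
                       ld_block_rho = 0.5,
                       causal_gene_fraction = 0.02,
                       signal_mean_shift = 0.8,
                       info_range = c(0.85, 1),
                       se_range = c(0.02, 0.05),
                       frac_swapped_alleles = 0.15,
                       n_strand_ambiguous = 5L,
                       n_duplicate_pairs = 3L,
                       dup_ld_gene_fraction = 0.1,
                       count_model = list(),
                       nb_model = list(),
                       mr_model = list()) {
  cm <- utils::modifyList(list(
    n_case = 20L, n_control = 19L, n_genes = 50L,
    mean_log = log(60), mean_sdlog = 1.2,
    dispersion = c(0.05, 0.3),
    lfc = 1.17,
    coef = c(intercept = -5.2, age = -0.01, sex_male = 0.02,
             race_white = 2.71, pmi = 0.11, ge_high = 2.58)
  ), count_model)
  nm <- utils::modifyList(list(
    n_case = 3L, n_control = 3L, n_genes = 500L, frac_de = 0.04,
    lfc = 1.17, dispersion = c(0.05, 0.2), libsize_sdlog = 0.2
  ), nb_model)
  mm <- utils::modifyList(list(
    theta = 0.1, n_tissues = 30L, beta_exp_mean = 0.5,
    beta_exp_sd = 0.15, se_exp = 0.03, se_out = 0.04,
    n_palindromic = 3L, n_swapped = 5L
  ), mr_model)
  stopifnot(ld_block_rho >= 0, ld_block_rho < 1,
            causal_gene_fraction >= 0, causal_gene_fraction <= 1,
            snps_per_gene[1L] >= 2L)
  structure(list(seed = as.integer(seed), n_ref_samples = n_ref_samples,
                 n_genes = n_genes, snps_per_gene = snps_per_gene,
                 ld_block_rho = ld_block_rho,
                 causal_gene_fraction = causal_gene_fraction,
                 signal_mean_shift = signal_mean_shift,
                 info_range = info_range, se_range = se_range,
                 frac_swapped_alleles = frac_swapped_alleles,
                 n_strand_ambiguous = n_strand_ambiguous,
                 n_duplicate_pairs = n_duplicate_pairs,
                 dup_ld_gene_fraction = dup_ld_gene_fraction,
                 count_model = cm, nb_model = nm, mr_model = mm),
            class = "sim_config")
}

# non-ambiguous ref/alt pairs (so generated variants pass the strand QC)
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2L, byrow = TRUE)

#' Simulate a reference panel with block-exchangeable LD
#'
#' One LD block per gene: continuous alt-allele dosages are an affine map
#' of an exchangeable-correlation Gaussian (clipped to `[0, 2]`; the
#' scale is kept small enough that clipping is negligible, so the dosage
#' Pearson correlation equals `ld_block_rho` up to sampling error).
#' MAFs are uniform on `[0.05, 0.5]`; gene windows are consistent with
#' the SNP positions.  A configurable fraction of genes carries one
#' exactly duplicated dosage column to exercise perfect-LD pruning.
#'
#' @param cfg A [sim_config()].
#' @return List with `panel` (a [reference_panel()]), `genes` (list of
#'   [gene_annotation()]), and `dup_genes` (ids of genes with an exact
#'   duplicate column).
#' @export
sim_reference_panel <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_ref_samples
  rho <- cfg$ld_block_rho
  genes <- list()
  var_rows <- list()
  dos_blocks <- list()
  dup_genes <- character()
  snp_counter <- 0L
  for (i in seq_len(cfg$n_genes)) {
    chrom <- (i - 1L) %% 22L + 1L
    slot <- (i - 1L) %/% 22L
    tx_start <- 1e6 + slot * 2e6
    tx_end <- tx_start + 5e4
    gid <- sprintf("G%04d", i)
    genes[[gid]] <- gene_annotation(gid, chrom = chrom,
                                    tx_start = tx_start, tx_end = tx_end)
    m_range <- seq(cfg$snps_per_gene[1L], cfg$snps_per_gene[2L])
    m <- if (length(m_range) == 1L) m_range else sample(m_range, 1L)
    maf <- stats::runif(m, 0.05, 0.5)
    g <- stats::rnorm(n)
    x <- sqrt(rho) * g + sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
    mu <- 2 * maf
    sig <- pmin(sqrt(2 * maf * (1 - maf)), mu / 3.2, (2 - mu) / 3.2)
    d <- pmin(pmax(sweep(sweep(x, 2L, sig, "*"), 2L, mu, "+"), 0), 2)
    if (stats::runif(1) < cfg$dup_ld_gene_fraction && m >= 2L) {
      d <- cbind(d, d[, 1L])
      maf <- c(maf, maf[1L])
      m <- m + 1L
      dup_genes <- c(dup_genes, gid)
    }
    pos <- sort(sample(seq(tx_start, tx_end), m))
    al <- .allele_pairs[sample(nrow(.allele_pairs), m, replace = TRUE), ,
                        drop = FALSE]
    rsid <- sprintf("rs%06d", snp_counter + seq_len(m))
    snp_counter <- snp_counter + m
    var_rows[[i]] <- data.frame(chrom = as.character(chrom), pos = pos,
                                rsid = rsid, ref_allele = al[, 1L],
                                alt_allele = al[, 2L],
                                stringsAsFactors = FALSE)
    dos_blocks[[i]] <- d
  }
  variants <- do.call(rbind, var_rows)
  dosages <- do.call(cbind, dos_blocks)
  list(panel = reference_panel(variants, dosages), genes = genes,
       dup_genes = dup_genes)
}

#' Simulate GWAS summary statistics over a panel
#'
#' Per gene, the Z-vector is drawn from `MVN(shift * 1, R_sample)` with
#' `R_sample` the panel's dosage correlation (shift 0 for null genes).
#' Odds ratios and standard errors are back-filled so that
#' `log(OR)/SE` reproduces Z exactly; INFO straddles the 0.9 filter; a
#' configurable fraction of rows is written with swapped alleles (Z
#' negated) and intergenic strand-ambiguous and duplicate-rsID rows are
#' injected deliberately.
#'
#' @param sim Output of [sim_reference_panel()].
#' @param cfg The same [sim_config()].
#' @param causal_ids Optional explicit causal gene ids (e.g. to generate
#'   a replication dataset sharing the discovery's signal genes);
#'   default: sampled at `causal_gene_fraction`.
#' @return List with `sumstats` (canonical variant table), `truth`
#'   (gene_id, causal, shift), and `injected` (named counts of
#'   QC-violating rows: strand_ambiguous, duplicate_rsid).
#' @export
sim_gwas_sumstats <- function(sim, cfg, causal_ids = NULL) {
  set.seed(cfg$seed + 1L)
  panel <- sim$panel
  genes <- sim$genes
  if (is.null(causal_ids)) {
    n_causal <- round(cfg$causal_gene_fraction * length(genes))
    causal_ids <- sample(names(genes), n_causal)
  } else {
    stopifnot(all(causal_ids %in% names(genes)))
  }
  rows <- list()
  for (gid in names(genes)) {
    vsub <- panel$variants[panel$variants$rsid %in%
                             .gene_rsids(panel, genes[[gid]]), ,
                           drop = FALSE]
    m <- nrow(vsub)
    R <- stats::cor(panel$dosages[, vsub$rsid, drop = FALSE])
    shift <- if (gid %in% causal_ids) cfg$signal_mean_shift else 0
    z <- as.vector(MASS::mvrnorm(1L, mu = rep(shift, m),
                                 Sigma = R, tol = 1e-6))
    se <- stats::runif(m, cfg$se_range[1L], cfg$se_range[2L])
    swap <- stats::runif(m) < cfg$frac_swapped_alleles
    z_rep <- ifelse(swap, -z, z)        # reported relative to written EA
    rows[[gid]] <- data.frame(
      chrom = vsub$chrom,
      pos = vsub$pos,
      rsid = vsub$rsid,
      effect_allele = ifelse(swap, vsub$ref_allele, vsub$alt_allele),
      other_allele = ifelse(swap, vsub$alt_allele, vsub$ref_allele),
      info = stats::runif(m, cfg$info_range[1L], cfg$info_range[2L]),
      odds_ratio = exp(z_rep * se),
      se = se,
      pvalue = 2 * stats::pnorm(-abs(z)),
      z = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  sumstats <- do.call(rbind, rows)
  # injected QC violations, placed far from any gene window
  inj <- list()
  if (cfg$n_strand_ambiguous > 0L) {
    k <- cfg$n_strand_ambiguous
    inj$amb <- data.frame(
      chrom = "1", pos = 1e3 + seq_len(k), rsid = sprintf("rsAMB%03d", seq_len(k)),
      effect_allele = c("A", "C")[sample(2L, k, replace = TRUE)],
      other_allele = NA_character_, info = 0.95,
      odds_ratio = exp(stats::rnorm(k, 0, 0.03)), se = 0.03,
      pvalue = stats::runif(k), z = NA_real_, stringsAsFactors = FALSE
    )
    inj$amb$other_allele <- ifelse(inj$amb$effect_allele == "A", "T", "G")
  }
  if (cfg$n_duplicate_pairs > 0L) {
    k <- cfg$n_duplicate_pairs
    base <- data.frame(
      chrom = "2", pos = 2e3 + seq_len(k), rsid = sprintf("rsDUP%03d", seq_len(k)),
      effect_allele = "A", other_allele = "G", info = 0.95,
      odds_ratio = exp(stats::rnorm(k, 0, 0.03)), se = 0.03,
      pvalue = stats::runif(k), z = NA_real_, stringsAsFactors = FALSE
    )
    inj$dup <- rbind(base, base)
  }
  if (length(inj)) sumstats <- rbind(sumstats, do.call(rbind, inj))
  rownames(sumstats) <- NULL
  truth <- data.frame(
    gene_id = names(genes),
    causal = names(genes) %in% causal_ids,
    shift = ifelse(names(genes) %in% causal_ids, cfg$signal_mean_shift, 0),
    stringsAsFactors = FALSE
  )
  list(sumstats = sumstats, truth = truth,
       injected = c(strand_ambiguous = cfg$n_strand_ambiguous,
                    duplicate_rsid = 2L * cfg$n_duplicate_pairs))
}

.gene_rsids <- function(panel, gene) {
  v <- panel$variants
  v$rsid[v$chrom == as.character(gene$chrom) & v$pos >= gene$tx_start &
           v$pos <= gene$tx_end]
}

#' Simulate an expression study
#'
#' Two designs:
#'
#' * `design = "logistic"` emulates the covariate-adjusted cohort: NB
#'   counts for `count_model$n_genes` genes, covariates (age at death,
#'   sex, race, PMI) drawn from plausible ranges, and diagnosis drawn
#'   from the dichotomized-expression logistic model using one designated
#'   signal gene's high/low indicator with the configured coefficients
#'   (so the true coefficient vector is known exactly).
#' * `design = "nb"` emulates the small two-group count design: NB
#'   counts with log-normal baseline means and sample-specific library
#'   factors; a fraction of genes has its case mean multiplied by
#'   `2^lfc`.
#'
#' @param cfg A [sim_config()].
#' @param design `"logistic"` or `"nb"`.
#' @return List with `study` (an [expression_study()]) and `truth`
#'   (design-specific: coefficients and signal gene, or per-gene lfc).
#' @export
sim_counts <- function(cfg, design = c("logistic", "nb")) {
  design <- match.arg(design)
  if (design == "logistic") {
    set.seed(cfg$seed + 2L)
    cm <- cfg$count_model
    n <- cm$n_case + cm$n_control
    ng <- cm$n_genes
    mu0 <- exp(stats::rnorm(ng, cm$mean_log, cm$mean_sdlog))
    disp <- stats::runif(ng, cm$dispersion[1L], cm$dispersion[2L])
    counts <- t(vapply(seq_len(ng), function(g) {
      stats::rnbinom(n, mu = mu0[g], size = 1 / disp[g])
    }, numeric(n)))
    rownames(counts) <- sprintf("GE%04d", seq_len(ng))
    age <- pmax(stats::rnorm(n, 45, 15), 1)
    sex <- ifelse(stats::runif(n) < 0.7, "male", "female")
    race <- ifelse(stats::runif(n) < 0.8, "white", "other")
    pmi <- stats::runif(n, 5, 35)
    signal_gene <- rownames(counts)[1L]
    ge <- as.integer(dichotomize(counts[signal_gene, ]) == "high")
    b <- cm$coef
    lp <- b[["intercept"]] + b[["age"]] * age +
      b[["sex_male"]] * (sex == "male") +
      b[["race_white"]] * (race == "white") + b[["pmi"]] * pmi +
      b[["ge_high"]] * ge
    diagnosis <- ifelse(stats::runif(n) < stats::plogis(lp),
                        "case", "control")
    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      diagnosis = diagnosis, age_at_death = age, sex = sex, race = race,
      pmi = pmi, stringsAsFactors = FALSE
    )
    list(study = expression_study(counts, samples),
         truth = list(signal_gene = signal_gene, coef = b))
  } else {
    set.seed(cfg$seed + 3L)
    nm <- cfg$nb_model
    n <- nm$n_case + nm$n_control
    ng <- nm$n_genes
    diagnosis <- rep(c("case", "control"), c(nm$n_case, nm$n_control))
    mu0 <- exp(stats::rnorm(ng, log(50), 1.5))
    disp <- stats::runif(ng, nm$dispersion[1L], nm$dispersion[2L])
    n_de <- round(nm$frac_de * ng)
    de <- sample(ng, n_de)
    lib <- exp(stats::rnorm(n, 0, nm$libsize_sdlog))
    counts <- matrix(0L, ng, n)
    for (g in seq_len(ng)) {
      mu <- rep(mu0[g], n)
      if (g %in% de) mu[diagnosis == "case"] <- mu[diagnosis == "case"] *
          2^nm$lfc
      counts[g, ] <- stats::rnbinom(n, mu = mu * lib, size = 1 / disp[g])
    }
    rownames(counts) <- sprintf("GN%04d", seq_len(ng))
    samples <- data.frame(
      sample_id = sprintf("S%02d", seq_len(n)),
      diagnosis = diagnosis, stringsAsFactors = FALSE
    )
    truth <- data.frame(
      gene_id = rownames(counts),
      lfc = ifelse(seq_len(ng) %in% de, nm$lfc, 0),
      stringsAsFactors = FALSE
    )
    list(study = expression_study(counts, samples), truth = truth)
  }
}

#' Simulate per-tissue MR instrument tables
#'
#' Per tissue, a true instrument strength is drawn around
#' `beta_exp_mean`; the observed exposure effect adds `N(0, se_exp^2)`
#' noise and the outcome effect is `theta * true_strength` plus
#' `N(0, se_out^2)` noise.  A configurable number of swapped-allele rows
#' (outcome alleles reversed, outcome beta negated) and palindromic A/T
#' rows with eaf 0.45 (not inferable, so harmonization must drop them)
#' are injected.
#'
#' @param cfg A [sim_config()].
#' @return List with `exposure` and `outcome` data.frames (tissue, rsid,
#'   beta, se, effect_allele, other_allele, eaf), `theta`, and
#'   `injected` (counts: palindromic, swapped).
#' @export
sim_mr <- function(cfg) {
  set.seed(cfg$seed + 4L)
  mm <- cfg$mr_model
  k <- mm$n_tissues
  tissue <- sprintf("tissue_%02d", seq_len(k))
  rsid <- sprintf("rs9%05d", seq_len(k))
  beta_true <- stats::rnorm(k, mm$beta_exp_mean, mm$beta_exp_sd)
  al <- .allele_pairs[sample(nrow(.allele_pairs), k, replace = TRUE), ,
                      drop = FALSE]
  eaf <- stats::runif(k, 0.1, 0.9)
  pal <- seq_len(min(mm$n_palindromic, k))
  al[pal, ] <- matrix(c("A", "T"), length(pal), 2L, byrow = TRUE)
  eaf[pal] <- 0.45
  exposure <- data.frame(
    tissue = tissue, rsid = rsid,
    beta = beta_true + stats::rnorm(k, 0, mm$se_exp),
    se = mm$se_exp,
    effect_allele = al[, 2L], other_allele = al[, 1L], eaf = eaf,
    stringsAsFactors = FALSE
  )
  outcome <- data.frame(
    tissue = tissue, rsid = rsid,
    beta = mm$theta * beta_true + stats::rnorm(k, 0, mm$se_out),
    se = mm$se_out,
    effect_allele = al[, 2L], other_allele = al[, 1L], eaf = eaf,
    stringsAsFactors = FALSE
  )
  swap <- setdiff(seq_len(k), pal)
  swap <- utils::head(swap, mm$n_swapped)
  outcome$effect_allele[swap] <- al[swap, 1L]
  outcome$other_allele[swap] <- al[swap, 2L]
  outcome$beta[swap] <- -outcome$beta[swap]
  outcome$eaf[swap] <- 1 - outcome$eaf[swap]
  list(exposure = exposure, outcome = outcome, theta = mm$theta,
       injected = c(palindromic = length(pal), swapped = length(swap)))
}
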