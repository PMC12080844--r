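#' Single-instrument Wald-ratio Mendelian randomization
#'
#' Per-tissue top-eQTL effects on gene expression (the exposure) are
#' harmonized with GWAS log-odds effects on disease (the outcome), and the
#' causal effect of expression on disease is estimated by the Wald ratio
#' `outcome_beta / exposure_beta`, with a first-order delta-method
#' standard error and a per-tissue Bonferroni threshold.
#'
#' @name mr_wald
NULL

#' Assemble an MR instrument table
#'
#' One row per tissue: the tissue's top eQTL matched to the same variant
#' in the outcome GWAS.  Exposure and outcome sides each carry their own
#' effect/other alleles and (optionally) effect-allele frequency.
#'
#' @param exposure `data.frame` with columns tissue, rsid, beta, se,
#'   effect_allele, other_allele, and optionally eaf.
#' @param outcome `data.frame` with columns rsid, beta, se,
#'   effect_allele, other_allele, and optionally eaf (log-odds scale for
#'   a binary outcome).
#' @return `data.frame` of class `mr_instruments`, one row per tissue
#'   whose rsid was found in the outcome table.
#' @export
mr_instruments <- function(exposure, outcome) {
  idx <- match(exposure$rsid, outcome$rsid)
  found <- !is.na(idx)
  ex <- exposure[found, , drop = FALSE]
  ou <- outcome[idx[found], , drop = FALSE]
  out <- data.frame(
    tissue = ex$tissue,
    rsid = ex$rsid,
    exposure_beta = ex$beta,
    exposure_se = ex$se,
    exposure_ea = toupper(ex$effect_allele),
    exposure_oa = toupper(ex$other_allele),
    exposure_eaf = if ("eaf" %in% names(ex)) ex$eaf else NA_real_,
    outcome_beta = ou$beta,
    outcome_se = ou$se,
    outcome_ea = toupper(ou$effect_allele),
    outcome_oa = toupper(ou$other_allele),
    outcome_eaf = if ("eaf" %in% names(ou)) ou$eaf else NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(out$exposure_se <= 0, na.rm = TRUE) ||
        any(out$outcome_se <= 0, na.rm = TRUE)) {
    stop("standard errors must be positive")
  }
  class(out) <- c("mr_instruments", "data.frame")
  out
}

#' Harmonize exposure and outcome alleles
#'
#' Aligns each instrument so the outcome effect refers to the exposure's
#' effect allele: identical allele order is kept, swapped order negates
#' the outcome beta (and reflects its eaf), anything else is dropped.
#' Palindromic variants (A/T or C/G) are kept only when both sides have a
#' known eaf, both minor-allele frequencies are below
#' `palindrome_maf_limit` (so strand can be inferred), and the
#' orientations agree (both eafs on the same side of 0.5); otherwise they
#' are dropped with a reason.
#'
#' @param inst An [mr_instruments()] table.
#' @param palindrome_maf_limit MAF below which a palindromic variant's
#'   strand is considered inferable (default 0.42).
#' @return List with `harmonized` (aligned instruments) and `dropped`
#'   (tissue, rsid, reason).
#' @export
harmonize_pair <- function(inst, palindrome_maf_limit = 0.42) {
  n <- nrow(inst)
  keep <- logical(n)
  reason <- character(n)
  out <- inst
  for (i in seq_len(n)) {
    ea_x <- inst$exposure_ea[i]; oa_x <- inst$exposure_oa[i]
    ea_y <- inst$outcome_ea[i];  oa_y <- inst$outcome_oa[i]
    if (!all(c(ea_x, oa_x, ea_y, oa_y) %in% c("A", "C", "G", "T"))) {
      reason[i] <- "non_single_base_alleles"
      next
    }
    pal <- .is_ambiguous(ea_x, oa_x)
    aligned <- ea_x == ea_y && oa_x == oa_y
    swapped <- ea_x == oa_y && oa_x == ea_y
    if (!aligned && !swapped) {
      reason[i] <- "allele_mismatch"
      next
    }
    if (swapped) {
      out$outcome_beta[i] <- -inst$outcome_beta[i]
      out$outcome_ea[i] <- ea_x
      out$outcome_oa[i] <- oa_x
      if (!is.na(inst$outcome_eaf[i])) {
        out$outcome_eaf[i] <- 1 - inst$outcome_eaf[i]
      }
    }
    if (pal) {
      fx <- inst$exposure_eaf[i]
      fy <- out$outcome_eaf[i]
      if (is.na(fx) || is.na(fy)) {
        reason[i] <- "palindromic_missing_eaf"
        next
      }
      if (min(fx, 1 - fx) >= palindrome_maf_limit ||
            min(fy, 1 - fy) >= palindrome_maf_limit) {
        reason[i] <- "palindromic_maf_not_inferable"
        next
      }
      if ((fx - 0.5) * (fy - 0.5) <= 0) {
        reason[i] <- "palindromic_discordant_orientation"
        next
      }
    }
    keep[i] <- TRUE
  }
  harmonized <- out[keep, , drop = FALSE]
  rownames(harmonized) <- NULL
  dropped <- data.frame(tissue = inst$tissue[!keep],
                        rsid = inst$rsid[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  rownames(dropped) <- NULL
  list(harmonized = harmonized, dropped = dropped)
}

#' Wald-ratio causal estimate for one instrument
#'
#' `beta = outcome_beta / exposure_beta`; the default standard error is
#' the first-order delta approximation `outcome_se / |exposure_beta|`
#' (exposure uncertainty ignored); `second_order = TRUE` adds the
#' exposure-side term
#' \eqn{\sqrt{se_y^2/\beta_x^2 + \beta_y^2 se_x^2/\beta_x^4}}.
#'
#' @param inst One harmonized instrument row (or a list with
#'   exposure_beta, exposure_se, outcome_beta, outcome_se, tissue).
#' @param second_order Include the exposure variance term in the SE?
#' @return List with tissue, beta, se, p.
#' @export
wald_ratio <- function(inst, second_order = FALSE) {
  bx <- inst$exposure_beta
  if (is.na(bx) || bx == 0) {
    stop("exposure effect is zero: Wald ratio is not estimable ",
         "(weak instrument)")
  }
  beta <- inst$outcome_beta / bx
  se <- if (second_order) {
    sqrt(inst$outcome_se^2 / bx^2 + inst$outcome_beta^2 *
           inst$exposure_se^2 / bx^4)
  } else {
    inst$outcome_se / abs(bx)
  }
  list(tissue = inst$tissue, beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Per-tissue MR scan with Bonferroni control
#'
#' Harmonizes the instruments, computes the Wald ratio per tissue, and
#' flags tissues below `alpha / n_tested` where `n_tested` counts tissues
#' surviving harmonization.
#'
#' @param inst An [mr_instruments()] table.
#' @param alpha Family-wise error rate (default 0.05).
#' @param palindrome_maf_limit Passed to [harmonize_pair()].
#' @param second_order Passed to [wald_ratio()].
#' @return List with `results` (tissue, rsid, beta, se, p, significant),
#'   `threshold`, `n_tested`, and `dropped`.
#' @export
mr_scan <- function(inst, alpha = 0.05, palindrome_maf_limit = 0.42,
                    second_order = FALSE) {
  h <- harmonize_pair(inst, palindrome_maf_limit)
  if (nrow(h$harmonized) == 0L) {
    stop("no instruments survive harmonization")
  }
  rows <- lapply(seq_len(nrow(h$harmonized)), function(i) {
    w <- wald_ratio(h$harmonized[i, ], second_order)
    data.frame(tissue = w$tissue, rsid = h$harmonized$rsid[i],
               beta = w$beta, se = w$se, p = w$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  n_tested <- nrow(res)
  thr <- bonferroni_threshold(n_tested, alpha)
  res$significant <- res$p <= thr
  rownames(res) <- NULL
  list(results = res, threshold = thr, n_tested = n_tested,
       dropped = h$dropped)
}
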