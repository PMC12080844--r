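#' Differential expression: dichotomized logistic and negative-binomial
#'
#' Two complementary analyses of gene-by-sample count matrices with
#' case/control diagnosis:
#'
#' * **Dichotomized logistic regression** (suited to moderate sample
#'   sizes with covariates): each gene's counts are split at the median
#'   into low/high expression, and diagnosis is regressed on age at
#'   death, sex, race (white vs non-white, optional), postmortem interval
#'   and the high-expression indicator; per-term Wald z and p-values are
#'   reported.
#' * **Negative-binomial count test** (suited to small designs without
#'   covariates): genes with total count below a floor are removed,
#'   counts are normalized by median-of-ratios size factors, a NB
#'   log-link GLM with a diagnosis term is fit per gene with
#'   method-of-moments dispersion, and the diagnosis Wald p-values are
#'   Benjamini-Hochberg adjusted.
#'
#' @name diffexpr
NULL

#' Expression study container
#'
#' @param counts Gene-by-sample matrix of non-negative integers; rows
#'   named by gene, columns by sample.
#' @param samples `data.frame` with columns `sample_id`, `diagnosis`
#'   (`"case"`/`"control"`), and optionally `age_at_death` (years), `sex`
#'   (`"male"`/`"female"`), `race` (character; `"white"` is the modeled
#'   indicator level), `pmi` (hours).
#' @return A list of class `expression_study`.
#' @export
expression_study <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(samples)) {
    stop("column count of counts must equal sample count")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(samples$diagnosis %in% c("case", "control"))) {
    stop("diagnosis must be 'case' or 'control'")
  }
  if (!is.null(samples$pmi) && any(samples$pmi < 0, na.rm = TRUE)) {
    stop("pmi must be non-negative")
  }
  if (!is.null(samples$age_at_death) &&
        any(samples$age_at_death < 0, na.rm = TRUE)) {
    stop("age_at_death must be non-negative")
  }
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples),
            class = "expression_study")
}

#' Read an expression study from counts + metadata TSVs
#'
#' Counts: headered TSV, first column `gene_id`, remaining columns one
#' per sample.  Metadata: headered TSV with the sample columns of
#' [expression_study()].
#'
#' @param counts_path,meta_path File paths.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(counts_path, meta_path) {
  cts <- data.table::fread(counts_path, header = TRUE, data.table = FALSE)
  meta <- data.table::fread(meta_path, header = TRUE, data.table = FALSE)
  genes <- cts[[1L]]
  mat <- as.matrix(cts[, -1L, drop = FALSE])
  rownames(mat) <- genes
  mat <- mat[, meta$sample_id, drop = FALSE]
  expression_study(mat, meta)
}

#' Write an expression study to counts + metadata TSVs
#'
#' @param study An [expression_study()].
#' @inheritParams read_expression_study
#' @export
write_expression_study <- function(study, counts_path, meta_path) {
  out <- data.frame(gene_id = rownames(study$counts), study$counts,
                    check.names = FALSE)
  data.table::fwrite(out, counts_path, sep = "\t", quote = FALSE)
  data.table::fwrite(study$samples, meta_path, sep = "\t", quote = FALSE)
  invisible(counts_path)
}

#' Dichotomize a gene's counts at the median
#'
#' `"low"` iff count <= median of the row (over the samples in the
#' analysis set), `"high"` otherwise.  A constant row cannot be split and
#' is flagged degenerate; downstream fits refuse it.
#'
#' @param counts_row Numeric vector of counts for one gene (>= 2 values).
#' @return Factor with levels `low`, `high` and attribute `degenerate`.
#' @examples
#' dichotomize(c(1, 2, 3, 4))   # low low high high (median 2.5)
#' @export
dichotomize <- function(counts_row) {
  if (length(counts_row) < 2L) stop("need at least 2 samples")
  med <- stats::median(counts_row)
  out <- factor(ifelse(counts_row <= med, "low", "high"),
                levels = c("low", "high"))
  attr(out, "degenerate") <- length(unique(counts_row)) == 1L
  out
}

#' Dichotomized-expression logistic differential analysis for one gene
#'
#' Fits `diagnosis ~ age_at_death + sex + race + pmi + GE` by maximum
#' likelihood, where GE is the high-expression indicator from
#' [dichotomize()] computed on the samples actually analyzed.  With
#' `include_race = FALSE` (e.g. for a single-race subset) the race term
#' is omitted.  Per-term Wald `z = beta/se` and `p = 2*pnorm(-|z|)`.
#'
#' @param study An [expression_study()].
#' @param gene_id Row name of the gene to test.
#' @param include_race Include the white-race indicator term?
#' @param subset Optional logical/integer index of samples to analyze
#'   (the dichotomization median is recomputed on this subset).
#' @return `data.frame` with columns term, beta, se, z, p; the GE row is
#'   named `ge_high`.
#' @export
fit_logistic_de <- function(study, gene_id, include_race = TRUE,
                            subset = NULL) {
  if (!gene_id %in% rownames(study$counts)) {
    stop("gene not found: ", gene_id)
  }
  meta <- study$samples
  row <- study$counts[gene_id, ]
  if (!is.null(subset)) {
    meta <- meta[subset, , drop = FALSE]
    row <- row[subset]
  }
  if (length(unique(meta$diagnosis)) < 2L) {
    stop("both diagnosis classes are required")
  }
  ge <- dichotomize(row)
  if (attr(ge, "degenerate")) {
    stop("gene ", gene_id, ": constant counts, expression cannot be ",
         "dichotomized")
  }
  if (length(unique(ge)) < 2L) {
    stop("gene ", gene_id, ": dichotomized expression has a single level")
  }
  df <- data.frame(
    y = as.integer(meta$diagnosis == "case"),
    age_at_death = meta$age_at_death,
    sex_male = as.integer(meta$sex == "male"),
    pmi = meta$pmi,
    ge_high = as.integer(ge == "high")
  )
  form <- if (include_race) {
    df$race_white <- as.integer(meta$race == "white")
    y ~ age_at_death + sex_male + race_white + pmi + ge_high
  } else {
    y ~ age_at_death + sex_male + pmi + ge_high
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  sep_warn <- sep_warn || !fit$converged ||
    any(abs(sm[-1L, "Estimate"]) > 10 & sm[-1L, "Std. Error"] > 10)
  if (sep_warn && any(abs(sm[-1L, "Estimate"]) > 10)) {
    bad <- rownames(sm)[-1L][which.max(abs(sm[-1L, "Estimate"]))]
    stop("gene ", gene_id, ": quasi-complete separation, term '", bad,
         "' is not estimable")
  }
  out <- data.frame(
    term = rownames(sm),
    beta = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    z = sm[, "z value"],
    p = 2 * stats::pnorm(-abs(sm[, "z value"])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "gene_id") <- gene_id
  attr(out, "n") <- nrow(df)
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample median of count / geometric-mean ratios over genes with
#' all-positive counts, normalized so the factors have geometric mean 1.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  allpos <- rowSums(counts <= 0) == 0L
  if (!any(allpos)) {
    stop("no gene has all-positive counts; size factors are not ",
         "estimable by median-of-ratios (consider a pseudo-reference)")
  }
  lg <- log(counts[allpos, , drop = FALSE])
  ref <- rowMeans(lg)                     # log geometric mean per gene
  sf <- exp(apply(lg - ref, 2L, stats::median))
  sf <- sf / exp(mean(log(sf)))           # geometric mean 1
  stats::setNames(sf, colnames(counts))
}

# Method-of-moments NB dispersion on the normalized scale, pooled within
# diagnosis groups; floored so the NB family never degenerates.
.mom_dispersion <- function(y, group, floor = 1e-8) {
  mu <- ave(y, group)
  n <- length(y)
  k <- length(unique(group))
  vres <- sum((y - mu)^2) / max(n - k, 1L)
  mbar <- mean(y)
  max((vres - mbar) / mbar^2, floor)
}

#' Negative-binomial differential expression
#'
#' For genes with total count >= `min_total`: per-gene NB log-link GLM of
#' counts on diagnosis with log size factors as offset, method-of-moments
#' dispersion (floored at 1e-8), Wald test on the diagnosis coefficient,
#' log2 fold change, and BH adjustment over the retained genes.  The Wald
#' statistic is referred to a t distribution on `n - 2` degrees of
#' freedom rather than a normal: with the handful of samples this design
#' targets, the plug-in dispersion makes the normal reference visibly
#' anti-conservative, while the t reference restores nominal type-I
#' error (and converges to the normal as n grows).  When one class has
#' all-zero counts the p-value is still computed but the fold-change
#' estimate is clamped to +/- `lfc_bound` and flagged.
#'
#' @param study An [expression_study()].
#' @param min_total Minimum total count across samples to retain a gene.
#' @param lfc_bound Clamp bound for degenerate log2 fold changes.
#' @param sf Optional per-sample size factors; default median-of-ratios
#'   from the retained genes.
#' @return `data.frame` with gene_id, base_mean, lfc (log2), p, p_adj,
#'   lfc_clamped.
#' @export
nb_de <- function(study, min_total = 10, lfc_bound = 30, sf = NULL) {
  counts <- study$counts
  diag_f <- factor(study$samples$diagnosis, levels = c("control", "case"))
  if (length(unique(diag_f)) < 2L) {
    stop("both diagnosis classes are required")
  }
  keep <- rowSums(counts) >= min_total
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) {
    return(data.frame(gene_id = character(), base_mean = numeric(),
                      lfc = numeric(), p = numeric(), p_adj = numeric(),
                      lfc_clamped = logical()))
  }
  if (is.null(sf)) sf <- size_factors(counts)
  off <- log(sf)
  df_wald <- max(ncol(counts) - 2L, 1L)
  res <- lapply(rownames(counts), function(g) {
    k <- counts[g, ]
    y <- k / sf
    disp <- .mom_dispersion(y, diag_f)
    fit <- suppressWarnings(
      stats::glm(k ~ diag_f + offset(off),
                 family = MASS::negative.binomial(theta = 1 / disp))
    )
    sm <- summary(fit)$coefficients
    beta <- sm["diag_fcase", "Estimate"]
    se <- sm["diag_fcase", "Std. Error"]
    z <- beta / se
    lfc <- beta / log(2)
    clamped <- FALSE
    if (!is.finite(lfc) || abs(lfc) > lfc_bound) {
      s <- if (is.finite(lfc)) sign(lfc) else sign(mean(y[diag_f == "case"]) -
                                                    mean(y[diag_f == "control"]))
      lfc <- s * lfc_bound
      clamped <- TRUE
    }
    data.frame(gene_id = g, base_mean = mean(y), lfc = lfc,
               p = max(2 * stats::pt(-abs(z), df = df_wald),
                       .Machine$double.xmin),
               lfc_clamped = clamped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("gene_id", "base_mean", "lfc", "p", "p_adj", "lfc_clamped")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment, monotone-enforced, capped at 1, in the input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Multiplicative fold change from a log2 fold change
#'
#' @param lfc Finite log2 fold change.
#' @return `2 ^ lfc`.
#' @examples
#' fold_change(1.17)   # ~2.25
#' @export
fold_change <- function(lfc) {
  stopifnot(is.numeric(lfc), all(is.finite(lfc)))
  2^lfc
}
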