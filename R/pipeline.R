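#' Pipeline orchestration: discovery, replication, expression, MR
#'
#' Thin, reproducible drivers that wire the stage modules together:
#' QC -> gene assignment -> LD -> pruning -> genome scan (discovery);
#' adaptive-test p-values for named genes in an independent dataset
#' (replication); both differential-expression analyses; and the
#' per-tissue Wald-ratio MR scan.  Every driver can read from files or
#' take in-memory objects, and writes TSV results plus a JSON run
#' manifest (input digests, stage counts, thresholds) when given an
#' output directory.
#'
#' @name pipeline
NULL

.as_sumstats <- function(x) if (is.character(x)) read_sumstats(x) else x
.as_panel <- function(x) {
  if (is.character(x)) {
    if (grepl("\\.vcf(\\.gz)?$", x)) read_panel_vcf(x) else read_panel_tsv(x)
  } else x
}
.as_genes <- function(x) if (is.character(x)) read_gene_annotation(x) else x

.write_manifest <- function(out_dir, stage, inputs, counts, thresholds,
                            extra = list()) {
  files <- unlist(Filter(is.character, inputs))
  digests <- if (length(files)) {
    as.list(tools::md5sum(files[file.exists(files)]))
  } else list()
  manifest <- c(list(
    stage = stage,
    version = as.character(utils::packageVersion("sumgene")),
    timestamp = NULL,                  # deliberately omitted: outputs are
                                       # byte-identical across reruns
    input_digests = digests,
    counts = as.list(counts),
    thresholds = as.list(thresholds)
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Discovery gene-based genome scan
#'
#' QC-filters the summary statistics, computes Z-scores, builds per-gene
#' SNP sets against the reference panel, and runs the three association
#' tests with a Bonferroni threshold at the number of genes tested.
#'
#' @param sumstats Variant table or path to a summary-statistics file.
#' @param panel [reference_panel()] or path (TSV dosage or VCF).
#' @param genes List of [gene_annotation()] or annotation file path.
#' @param flank Gene window flank in bp (default 1000).
#' @param info_min INFO threshold (default 0.9).
#' @param alpha Family-wise error rate (default 0.05).
#' @param rho_grid Adaptive-test grid.
#' @param epsilon Perfect-LD pruning tolerance.
#' @param out_dir Optional output directory for TSVs + manifest.
#' @return List with `results`, `threshold`, `manhattan`, `qc_removed`,
#'   `dropped_genes`, `n_variants_tested`.
#' @export
run_discovery <- function(sumstats, panel, genes, flank = 1000,
                          info_min = 0.9, alpha = 0.05,
                          rho_grid = seq(0, 1, by = 0.1),
                          epsilon = 1e-8, out_dir = NULL) {
  inputs <- list(sumstats = sumstats, panel = panel, genes = genes)
  ss <- .as_sumstats(sumstats)
  pan <- .as_panel(panel)
  ann <- .as_genes(genes)
  qc <- qc_filter(ss, info_min)
  if (nrow(qc$retained) == 0L) {
    warning("no variants survive QC; empty result")
    scan <- genome_scan(list(), alpha, rho_grid)
    return(c(scan, list(qc_removed = qc$removed,
                        dropped_genes = data.frame(),
                        n_variants_tested = 0L)))
  }
  zz <- compute_z(qc$retained)
  built <- build_gene_sets(zz, ann, pan, flank, epsilon)
  scan <- genome_scan(built$sets, alpha, rho_grid)
  out <- c(scan, list(qc_removed = qc$removed,
                      dropped_genes = built$dropped_genes,
                      n_variants_tested = nrow(zz)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(scan$results, file.path(out_dir, "gene_results.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(scan$manhattan, file.path(out_dir, "manhattan.tsv"),
                       sep = "\t", quote = FALSE)
    write_qc_report(qc$removed, attr(ss, "n_dropped") %||% 0L,
                    file.path(out_dir, "qc_report.json"))
    .write_manifest(out_dir, "discovery", inputs,
                    c(variants_in = nrow(ss),
                      variants_qc = nrow(qc$retained),
                      genes_tested = nrow(scan$results)),
                    c(alpha = alpha, bonferroni = scan$threshold))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replication of discovery hits in an independent dataset
#'
#' Computes adaptive-test p-values for the named genes only, in the
#' replication summary statistics, at significance level `alpha` (no
#' multiplicity correction beyond the named set, matching a targeted
#' replication design).  Genes absent from the replication data are
#' reported untestable, not errors.  P-values within `[alpha,
#' 1.5 * alpha)` are flagged near-boundary and reported verbatim.
#'
#' @param discovery_hits Character vector of gene ids (non-empty).
#' @param sumstats,panel,genes Replication inputs (objects or paths).
#' @param alpha Replication significance level (default 0.05).
#' @inheritParams run_discovery
#' @return `data.frame` gene_id, p_at, status
#'   (`replicated`/`not_replicated`/`untestable`), near_boundary.
#' @export
run_replication <- function(discovery_hits, sumstats, panel, genes,
                            alpha = 0.05, flank = 1000, info_min = 0.9,
                            rho_grid = seq(0, 1, by = 0.1),
                            epsilon = 1e-8, out_dir = NULL) {
  if (length(discovery_hits) == 0L) {
    stop("discovery hit list is empty")
  }
  ann <- .as_genes(genes)
  ann <- Filter(function(g) g$gene_id %in% discovery_hits, ann)
  ss <- .as_sumstats(sumstats)
  pan <- .as_panel(panel)
  qc <- qc_filter(ss, info_min)
  zz <- compute_z(qc$retained)
  built <- build_gene_sets(zz, ann, pan, flank, epsilon)
  rows <- lapply(discovery_hits, function(gid) {
    s <- built$sets[[gid]]
    if (is.null(s)) {
      return(data.frame(gene_id = gid, p_at = NA_real_,
                        status = "untestable", near_boundary = FALSE,
                        stringsAsFactors = FALSE))
    }
    at <- adaptive_test(s$z, s$R, rho_grid)
    data.frame(gene_id = gid, p_at = at$p_at,
               status = if (at$p_at < alpha) "replicated" else
                 "not_replicated",
               near_boundary = at$p_at >= alpha & at$p_at < 1.5 * alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(out, file.path(out_dir, "replication.tsv"),
                       sep = "\t", quote = FALSE)
  }
  out
}

#' Both differential-expression analyses
#'
#' For the covariate cohort: the all-samples dichotomized logistic model
#' (with the race term) and the white-only variant (race term excluded,
#' median recomputed on the subset), for each requested gene.  For the
#' two-group count study: the NB test with BH adjustment.  Either study
#' may be `NULL` to skip that arm.
#'
#' @param logistic_study [expression_study()] with covariates, or `NULL`.
#' @param nb_study Two-group [expression_study()], or `NULL`.
#' @param gene_ids Genes to fit in the logistic arm (default: all rows).
#' @param min_total NB total-count filter (default 10).
#' @param out_dir Optional output directory.
#' @return List with `logistic_all`, `logistic_white` (per-gene lists of
#'   term tables, plus `summary` data.frames with the GE-term p), and
#'   `nb` (the [nb_de()] table).
#' @export
run_de <- function(logistic_study = NULL, nb_study = NULL,
                   gene_ids = NULL, min_total = 10, out_dir = NULL) {
  out <- list()
  if (!is.null(logistic_study)) {
    ids <- gene_ids %||% rownames(logistic_study$counts)
    fit_arm <- function(include_race, subset) {
      fits <- list()
      rows <- list()
      for (g in ids) {
        f <- tryCatch(
          fit_logistic_de(logistic_study, g, include_race, subset),
          error = function(e) e
        )
        if (inherits(f, "error")) {
          rows[[g]] <- data.frame(gene_id = g, beta = NA_real_,
                                  se = NA_real_, z = NA_real_,
                                  p = NA_real_, note = conditionMessage(f),
                                  stringsAsFactors = FALSE)
        } else {
          fits[[g]] <- f
          ge <- f[f$term == "ge_high", ]
          rows[[g]] <- data.frame(gene_id = g, beta = ge$beta, se = ge$se,
                                  z = ge$z, p = ge$p, note = "",
                                  stringsAsFactors = FALSE)
        }
      }
      list(fits = fits, summary = do.call(rbind, c(rows,
                                                   make.row.names = FALSE)))
    }
    out$logistic_all <- fit_arm(TRUE, NULL)
    white <- logistic_study$samples$race == "white"
    out$logistic_white <- fit_arm(FALSE, white)
  }
  if (!is.null(nb_study)) {
    out$nb <- nb_de(nb_study, min_total = min_total)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$logistic_all)) {
      data.table::fwrite(out$logistic_all$summary,
                         file.path(out_dir, "de_logistic_all.tsv"),
                         sep = "\t", quote = FALSE)
      data.table::fwrite(out$logistic_white$summary,
                         file.path(out_dir, "de_logistic_white.tsv"),
                         sep = "\t", quote = FALSE)
    }
    if (!is.null(out$nb)) {
      data.table::fwrite(out$nb, file.path(out_dir, "de_counts.tsv"),
                         sep = "\t", quote = FALSE)
    }
  }
  out
}

#' Per-tissue Wald-ratio MR run
#'
#' Matches exposure and outcome tables, harmonizes, estimates the Wald
#' ratio per tissue and applies the per-tissue Bonferroni threshold; an
#' optional tissue subset (e.g. an ancestry-restricted panel) is run the
#' same way.
#'
#' @param exposure,outcome Instrument tables (see [mr_instruments()]) or
#'   TSV paths with those columns.
#' @param alpha Family-wise error rate (default 0.05).
#' @param subset_tissues Optional character vector defining a secondary
#'   restricted analysis.
#' @param out_dir Optional output directory.
#' @return List with `full` (the [mr_scan()] result) and, when
#'   requested, `subset`.
#' @export
run_mr <- function(exposure, outcome, alpha = 0.05,
                   subset_tissues = NULL, out_dir = NULL) {
  read_tsv <- function(x) {
    if (is.character(x)) {
      data.table::fread(x, header = TRUE, data.table = FALSE)
    } else x
  }
  ex <- read_tsv(exposure)
  ou <- read_tsv(outcome)
  inst <- mr_instruments(ex, ou)
  out <- list(full = mr_scan(inst, alpha))
  if (!is.null(subset_tissues)) {
    sub <- inst[inst$tissue %in% subset_tissues, , drop = FALSE]
    out$subset <- mr_scan(sub, alpha)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(out$full$results, file.path(out_dir, "mr_full.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(out$subset)) {
      data.table::fwrite(out$subset$results,
                         file.path(out_dir, "mr_subset.tsv"),
                         sep = "\t", quote = FALSE)
    }
  }
  out
}

#' Manhattan plot of a genome scan (data-driven convenience)
#'
#' Plots `-log10(p)` per gene against a cumulative genome coordinate,
#' with the Bonferroni threshold as a dashed line.  Styling is minimal by
#' design; the `manhattan` table is the primary, plot-ready artifact.
#'
#' @param scan Result of [genome_scan()] or [run_discovery()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_manhattan <- function(scan, ...) {
  man <- scan$manhattan
  if (nrow(man) == 0L) stop("empty scan")
  chr <- as.integer(man$chrom)
  offs <- c(0, cumsum(tapply(man$pos, factor(chr, levels = 1:22),
                             function(p) max(p, na.rm = TRUE) + 1e6)))
  offs[is.na(offs)] <- 0
  x <- man$pos + offs[chr]
  graphics::plot(x, man$neglog10_p, pch = 20,
                 col = c("grey30", "steelblue")[chr %% 2 + 1],
                 xlab = "genome position", ylab = "-log10(p)", ...)
  if (is.finite(scan$threshold)) {
    graphics::abline(h = -log10(scan$threshold), lty = 2, col = "red")
  }
  invisible(NULL)
}
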