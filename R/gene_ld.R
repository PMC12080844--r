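#' Gene windows, allele harmonization and LD from a reference panel
#'
#' QC-passed variants are assigned to genes by a +/- flank window around
#' the transcription start and end, matched to a reference genotype panel
#' (aligning alleles and flipping Z signs where the effect/other order is
#' reversed), and the gene-wide LD is the Pearson correlation of the
#' panel's dosages.  One member of every perfectly correlated pair
#' (r = 1) is pruned so the LD matrix is usable in the quadratic-form
#' machinery.
#'
#' @name gene_ld
NULL

#' Gene annotation record
#'
#' @param gene_id Stable identifier.
#' @param symbol Display name.
#' @param chrom Autosome label, 1-22.
#' @param tx_start,tx_end 1-based transcription start/end,
#'   `tx_start <= tx_end`.
#' @param strand `"+"` or `"-"`.  The window uses the annotation's numeric
#'   start/end regardless of strand.
#' @return A list of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, symbol = gene_id, chrom, tx_start,
                            tx_end, strand = "+") {
  chrom <- as.integer(chrom)
  if (is.na(chrom) || chrom < 1L || chrom > 22L) {
    stop("gene ", gene_id, ": chrom must be an autosome (1-22)")
  }
  if (tx_start > tx_end) stop("gene ", gene_id, ": tx_start > tx_end")
  structure(list(gene_id = gene_id, symbol = symbol, chrom = chrom,
                 tx_start = as.numeric(tx_start),
                 tx_end = as.numeric(tx_end), strand = strand),
            class = "gene_annotation")
}

#' Read gene annotation from a headered TSV
#'
#' Expects columns `gene_id`, `chrom`, `tx_start`, `tx_end` and optionally
#' `symbol`, `strand` (refFlat-like).  A headerless 6-column BED layout
#' (chrom, start, end, name, score, strand) is also accepted.
#'
#' @param path Path to the annotation file.
#' @return List of [gene_annotation()] records.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("gene_id", first, fixed = TRUE)) {
    tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  } else {
    tab <- data.table::fread(path, header = FALSE, data.table = FALSE)
    names(tab) <- c("chrom", "tx_start", "tx_end", "gene_id", "symbol",
                    "strand")[seq_len(ncol(tab))]
  }
  if (!"symbol" %in% names(tab)) tab$symbol <- tab$gene_id
  if (!"strand" %in% names(tab)) tab$strand <- "+"
  lapply(seq_len(nrow(tab)), function(i) {
    gene_annotation(tab$gene_id[i], tab$symbol[i],
                    sub("^chr", "", tab$chrom[i]),
                    tab$tx_start[i], tab$tx_end[i], tab$strand[i])
  })
}

#' Reference genotype panel
#'
#' @param variants `data.frame` with columns chrom, pos, rsid,
#'   ref_allele, alt_allele.
#' @param dosages Numeric sample-by-variant matrix with values in
#'   `[0, 2]` (alt-allele dosage); columns named by rsid.
#' @return A list of class `reference_panel`.
#' @export
reference_panel <- function(variants, dosages) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2L) stop("reference panel needs >= 2 samples")
  if (ncol(dosages) != nrow(variants)) {
    stop("dosage column count must equal variant count")
  }
  if (min(dosages) < 0 || max(dosages) > 2) {
    stop("dosages must lie in [0, 2]")
  }
  colnames(dosages) <- variants$rsid
  structure(list(variants = variants, dosages = dosages),
            class = "reference_panel")
}

#' Read a reference panel from a headered dosage TSV
#'
#' Layout: one row per variant, columns `chrom, pos, rsid, ref_allele,
#' alt_allele` followed by one numeric column per sample.
#'
#' @param path Path to the TSV.
#' @return A [reference_panel()].
#' @export
read_panel_tsv <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  meta_cols <- c("chrom", "pos", "rsid", "ref_allele", "alt_allele")
  if (!all(meta_cols %in% names(tab))) {
    stop("panel TSV must have columns ", paste(meta_cols, collapse = ", "))
  }
  dos <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  reference_panel(tab[, meta_cols], dos)
}

#' Write a reference panel as a dosage TSV
#'
#' @param panel A [reference_panel()].
#' @param path Output path.
#' @export
write_panel_tsv <- function(panel, path) {
  dos <- t(panel$dosages)
  colnames(dos) <- if (!is.null(rownames(panel$dosages))) {
    rownames(panel$dosages)
  } else paste0("S", seq_len(nrow(panel$dosages)))
  out <- cbind(panel$variants, as.data.frame(dos))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a reference panel from a VCF
#'
#' Uses the DS FORMAT field when present, otherwise counts alt alleles in
#' GT.  Requires the `vcfR` package.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @return A [reference_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF panels requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(
    chrom = sub("^chr", "", fix$CHROM),
    pos = as.numeric(fix$POS),
    rsid = fix$ID,
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    stringsAsFactors = FALSE
  )
  fmt <- unique(unlist(strsplit(v@gt[, 1L], ":", fixed = TRUE)))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(vapply(gt, function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1L]]))
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  reference_panel(variants, t(ds))
}

#' Assign variants to a gene window
#'
#' Retains variants with `tx_start - flank <= pos <= tx_end + flank`
#' (inclusive at both boundaries) on the gene's chromosome.
#'
#' @param variants Variant table (QC-passed).
#' @param gene A [gene_annotation()].
#' @param flank Window extension in bp beyond the transcription start and
#'   end sites (default 1000).
#' @return The subset of `variants` inside the window.
#' @export
assign_to_gene <- function(variants, gene, flank = 1000) {
  keep <- .is_autosome(variants$chrom) &
    as.integer(variants$chrom) == gene$chrom &
    variants$pos >= gene$tx_start - flank &
    variants$pos <= gene$tx_end + flank
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonize GWAS variants against the reference panel
#'
#' Matches by rsID first, then by chrom:pos for variants absent from the
#' panel's rsIDs.  When the GWAS effect/other alleles equal the panel's
#' alt/ref in order the Z-score is kept; when they are swapped the sign is
#' flipped; irreconcilable allele pairs (or a shared rsID at a different
#' position) are dropped with a reason.  The operation is idempotent: a
#' harmonized set re-harmonized against the same panel is unchanged.
#'
#' @param variants Variant table with `z` computed.
#' @param panel A [reference_panel()].
#' @return List with `harmonized` (variant table, `z` aligned to the
#'   panel's alt allele) and `dropped` (data.frame rsid, reason).
#' @export
harmonize_to_panel <- function(variants, panel) {
  pv <- panel$variants
  idx <- match(variants$rsid, pv$rsid)
  pos_key <- paste(pv$chrom, pv$pos, sep = ":")
  need_pos <- is.na(idx)
  idx[need_pos] <- match(paste(variants$chrom[need_pos],
                               variants$pos[need_pos], sep = ":"),
                         pos_key)
  keep <- logical(nrow(variants))
  flip <- logical(nrow(variants))
  reason <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    j <- idx[i]
    if (is.na(j)) {
      reason[i] <- "absent_from_panel"
      next
    }
    if (!is.na(variants$rsid[i]) && variants$rsid[i] == pv$rsid[j] &&
          (as.character(variants$chrom[i]) != as.character(pv$chrom[j]) ||
             variants$pos[i] != pv$pos[j])) {
      reason[i] <- "position_mismatch"
      next
    }
    ea <- variants$effect_allele[i]
    oa <- variants$other_allele[i]
    if (ea == pv$alt_allele[j] && oa == pv$ref_allele[j]) {
      keep[i] <- TRUE
    } else if (ea == pv$ref_allele[j] && oa == pv$alt_allele[j]) {
      keep[i] <- TRUE
      flip[i] <- TRUE
    } else {
      reason[i] <- "allele_mismatch"
    }
  }
  harmonized <- variants[keep, , drop = FALSE]
  fl <- flip[keep]
  harmonized$z <- ifelse(fl, -harmonized$z, harmonized$z)
  # after flipping, record alleles in panel orientation so the operation
  # is idempotent
  swap <- which(fl)
  if (length(swap)) {
    tmp <- harmonized$effect_allele[swap]
    harmonized$effect_allele[swap] <- harmonized$other_allele[swap]
    harmonized$other_allele[swap] <- tmp
    harmonized$odds_ratio[swap] <- 1 / harmonized$odds_ratio[swap]
  }
  rownames(harmonized) <- NULL
  dropped <- data.frame(rsid = variants$rsid[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  rownames(dropped) <- NULL
  list(harmonized = harmonized, dropped = dropped)
}

#' LD correlation matrix from panel dosages
#'
#' Pearson correlation between the dosage vectors of the requested
#' variants, in the requested order.
#'
#' @param panel A [reference_panel()].
#' @param rsids Ordered variant identifiers, all present in the panel.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(panel, rsids) {
  idx <- match(rsids, panel$variants$rsid)
  if (any(is.na(idx))) {
    stop("variants absent from panel: ",
         paste(rsids[is.na(idx)], collapse = ", "))
  }
  dos <- panel$dosages[, idx, drop = FALSE]
  vars <- apply(dos, 2L, stats::var)
  if (any(vars == 0)) {
    stop("zero-variance dosage for variant(s): ",
         paste(rsids[vars == 0], collapse = ", "))
  }
  R <- stats::cor(dos)
  dimnames(R) <- list(rsids, rsids)
  (R + t(R)) / 2
}

#' Gene SNP set: harmonized Z-vector plus LD matrix
#'
#' @param gene A [gene_annotation()].
#' @param rsids Ordered variant ids (length m >= 2), assumed
#'   position-sorted.
#' @param z Harmonized Z-scores, same order.
#' @param R m-by-m LD correlation matrix.
#' @return A list of class `gene_snp_set`.
#' @export
gene_snp_set <- function(gene, rsids, z, R) {
  m <- length(rsids)
  if (m < 2L) stop("gene ", gene$gene_id, ": needs at least 2 variants")
  if (length(z) != m || !all(dim(R) == m)) {
    stop("gene ", gene$gene_id, ": z/R dimensions inconsistent")
  }
  if (max(abs(diag(R) - 1)) > 1e-8 || max(abs(R - t(R))) > 1e-8) {
    stop("gene ", gene$gene_id, ": R must be a correlation matrix")
  }
  structure(list(gene = gene, rsids = rsids, z = as.numeric(z),
                 R = as.matrix(R)),
            class = "gene_snp_set")
}

#' Prune perfectly correlated variant pairs
#'
#' While any off-diagonal `r_ij >= 1 - epsilon` remains, the later (by
#' position, i.e. higher index) member of the first offending pair in
#' row-major order is removed; `z` and `R` are subset consistently.  Only
#' r = +1 pairs are pruned; r = -1 pairs are retained.  If fewer than 2
#' variants survive, `NULL` is returned (the gene is dropped).
#'
#' @param set A [gene_snp_set()].
#' @param epsilon Tolerance; pairs with `r >= 1 - epsilon` count as
#'   perfect (default 1e-8).
#' @return The pruned `gene_snp_set`, or `NULL`.
#' @export
prune_perfect_ld <- function(set, epsilon = 1e-8) {
  keep <- seq_along(set$rsids)
  R <- set$R
  repeat {
    Rk <- R[keep, keep, drop = FALSE]
    off <- Rk
    off[lower.tri(off, diag = TRUE)] <- -Inf
    bad <- which(off >= 1 - epsilon, arr.ind = TRUE)
    if (nrow(bad) == 0L) break
    bad <- bad[order(bad[, 1L], bad[, 2L]), , drop = FALSE]
    keep <- keep[-bad[1L, 2L]]   # drop the later member of the first pair
    if (length(keep) < 2L) return(NULL)
  }
  if (length(keep) == length(set$rsids)) return(set)
  gene_snp_set(set$gene, set$rsids[keep], set$z[keep],
               R[keep, keep, drop = FALSE])
}

#' Build gene SNP sets from QC'ed variants, annotation and panel
#'
#' The per-gene pipeline: window assignment, panel harmonization, the
#' 2-SNP minimum, LD estimation, and perfect-LD pruning.  Genes ending
#' with fewer than 2 variants are dropped (and listed).
#'
#' @param variants QC-passed variant table with `z` computed.
#' @param genes List of [gene_annotation()] records.
#' @param panel A [reference_panel()].
#' @param flank Window flank in bp.
#' @param epsilon Perfect-LD tolerance for [prune_perfect_ld()].
#' @return List with `sets` (list of `gene_snp_set`) and `dropped_genes`
#'   (data.frame gene_id, reason).
#' @export
build_gene_sets <- function(variants, genes, panel, flank = 1000,
                            epsilon = 1e-8) {
  sets <- list()
  dropped <- list()
  for (g in genes) {
    sub <- assign_to_gene(variants, g, flank)
    if (nrow(sub) >= 2L) {
      h <- harmonize_to_panel(sub, panel)$harmonized
    } else {
      h <- sub
    }
    if (nrow(h) < 2L) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(gene_id = g$gene_id, reason = "fewer_than_2_snps")
      next
    }
    h <- h[order(h$pos), , drop = FALSE]
    R <- ld_matrix(panel, h$rsid)
    s <- prune_perfect_ld(gene_snp_set(g, h$rsid, h$z, R), epsilon)
    if (is.null(s)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(gene_id = g$gene_id, reason = "pruned_below_2_snps")
      next
    }
    sets[[g$gene_id]] <- s
  }
  list(sets = sets,
       dropped_genes = if (length(dropped)) {
         do.call(rbind, dropped)
       } else {
         data.frame(gene_id = character(), reason = character())
       })
}
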