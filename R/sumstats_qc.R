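#' GWAS summary-statistic input and quality control
#'
#' Readers, filters and the Z-score computation for per-variant GWAS
#' summary statistics in PGC daner-style delimited text (columns CHR, SNP,
#' BP, A1, A2, INFO, OR, SE, P by default; the mapping is configurable).
#' The QC rules match standard practice for summary-statistic gene-based
#' testing: autosomes only, single-base alleles, no strand-ambiguous
#' (A/T or C/G) pairs, imputation INFO of at least 0.9, and no duplicated
#' rsIDs.
#'
#' @name sumstats_qc
NULL

#' Default column mapping for PGC daner-style summary statistics
#'
#' @return Named character vector mapping internal field names to file
#'   column names.
#' @export
default_dialect <- function() {
  c(chrom = "CHR", rsid = "SNP", pos = "BP",
    effect_allele = "A1", other_allele = "A2",
    info = "INFO", odds_ratio = "OR", se = "SE", pvalue = "P")
}

#' Read GWAS summary statistics
#'
#' Reads a tab- or whitespace-delimited summary-statistics file into the
#' canonical variant table.  Rows whose numeric fields do not parse are
#' dropped and counted (attribute `n_dropped`); input order is preserved.
#' The INFO column is optional; when absent every variant gets `NA` INFO
#' (which the conservative QC filter will remove).
#'
#' @param path Path to the file.
#' @param dialect Named character vector as in [default_dialect()]; names
#'   are internal fields, values the file's column names.
#' @return A `data.frame` with columns chrom, pos, rsid, effect_allele,
#'   other_allele, info, odds_ratio, se, pvalue, z (NA until
#'   [compute_z()] is applied), with attribute `n_dropped`.
#' @export
read_sumstats <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) stop("summary statistics file not found: ", path)
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = "character")
  required <- setdiff(names(default_dialect()), "info")
  for (field in required) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("required column '", field, "' (file column '", col,
           "') not found in ", path)
    }
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    chrom = sub("^chr", "", raw[[dialect[["chrom"]]]]),
    pos = num(raw[[dialect[["pos"]]]]),
    rsid = raw[[dialect[["rsid"]]]],
    effect_allele = toupper(raw[[dialect[["effect_allele"]]]]),
    other_allele = toupper(raw[[dialect[["other_allele"]]]]),
    info = if (!is.null(dialect[["info"]]) &&
                 dialect[["info"]] %in% names(raw)) {
      num(raw[[dialect[["info"]]]])
    } else NA_real_,
    odds_ratio = num(raw[[dialect[["odds_ratio"]]]]),
    se = num(raw[[dialect[["se"]]]]),
    pvalue = num(raw[[dialect[["pvalue"]]]]),
    z = NA_real_,
    stringsAsFactors = FALSE
  )
  ok <- !is.na(out$pos) & !is.na(out$odds_ratio) & !is.na(out$se) &
    !is.na(out$pvalue)
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(!ok)
  res
}

#' Write summary statistics back to delimited text
#'
#' Inverse of [read_sumstats()] under the same dialect; used for
#' round-tripping QC'ed data (a `Z` column is appended when present).
#'
#' @param x Variant table as returned by [read_sumstats()].
#' @param path Output path.
#' @inheritParams read_sumstats
#' @export
write_sumstats <- function(x, path, dialect = default_dialect()) {
  out <- data.frame(
    x$chrom, x$rsid, x$pos, x$effect_allele, x$other_allele,
    x$info, x$odds_ratio, x$se, x$pvalue,
    stringsAsFactors = FALSE
  )
  names(out) <- dialect[c("chrom", "rsid", "pos", "effect_allele",
                          "other_allele", "info", "odds_ratio", "se",
                          "pvalue")]
  if (!all(is.na(x$z))) out$Z <- x$z
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

.is_autosome <- function(chrom) {
  suppressWarnings(n <- as.integer(chrom))
  !is.na(n) & n >= 1L & n <= 22L
}

.is_acgt <- function(allele) allele %in% c("A", "C", "G", "T")

.is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Quality-control filter for summary statistics
#'
#' Applies, in order: autosomal chromosome; both alleles single-base
#' A/C/G/T (this also removes non-biallelic/indel records); allele pair
#' not strand-ambiguous (not A/T or C/G); INFO >= 0.9 (missing INFO fails,
#' conservatively; INFO exactly 0.9 is retained); rsID unique (every copy
#' of a duplicated rsID is removed).  Each removed record is attributed to
#' the first rule that rejects it, so the per-rule counts plus the
#' retained count always equal the input count.
#'
#' @param records Variant table from [read_sumstats()].
#' @param info_min Minimum INFO score retained (default 0.9).
#' @return List with `retained` (filtered table) and `removed` (named
#'   per-rule counts: autosome, alleles, strand_ambiguous, info,
#'   duplicate_rsid).
#' @export
qc_filter <- function(records, info_min = 0.9) {
  n <- nrow(records)
  counts <- c(autosome = 0L, alleles = 0L, strand_ambiguous = 0L,
              info = 0L, duplicate_rsid = 0L)
  if (n == 0L) {
    return(list(retained = records, removed = counts))
  }
  fail_auto <- !.is_autosome(records$chrom)
  fail_acgt <- !fail_auto &
    !(.is_acgt(records$effect_allele) & .is_acgt(records$other_allele))
  fail_amb <- !fail_auto & !fail_acgt &
    .is_ambiguous(records$effect_allele, records$other_allele)
  fail_info <- !fail_auto & !fail_acgt & !fail_amb &
    (is.na(records$info) | records$info < info_min)
  alive <- !(fail_auto | fail_acgt | fail_amb | fail_info)
  dup_ids <- records$rsid[alive][duplicated(records$rsid[alive])]
  fail_dup <- alive & records$rsid %in% dup_ids
  keep <- alive & !fail_dup
  counts <- c(autosome = sum(fail_auto), alleles = sum(fail_acgt),
              strand_ambiguous = sum(fail_amb), info = sum(fail_info),
              duplicate_rsid = sum(fail_dup))
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, removed = counts)
}

#' Compute per-variant Z-scores
#'
#' `Z = log(OR) / SE(log(OR))` for every record; the sign of Z matches the
#' sign of `OR - 1`.
#'
#' @param records Variant table; `odds_ratio` and `se` must be positive.
#' @return The table with the `z` column filled in.
#' @examples
#' v <- data.frame(odds_ratio = 1.2, se = 0.05)
#' compute_z(v)$z   # log(1.2)/0.05 = 3.6464...
#' @export
compute_z <- function(records) {
  if (any(is.na(records$odds_ratio)) || any(records$odds_ratio <= 0)) {
    stop("odds_ratio must be positive for all records")
  }
  if (any(is.na(records$se)) || any(records$se <= 0)) {
    stop("se must be positive for all records")
  }
  records$z <- log(records$odds_ratio) / records$se
  records
}

#' Write a QC report
#'
#' Key-count JSON report of the per-rule removals plus parse drops.
#'
#' @param removed Named counts from [qc_filter()].
#' @param n_parse_dropped Rows dropped at parse time.
#' @param path Output path (`.json`).
#' @export
write_qc_report <- function(removed, n_parse_dropped = 0L, path) {
  report <- c(list(parse_dropped = n_parse_dropped), as.list(removed))
  report$note_missing_info <-
    "variants with missing INFO are removed (conservative choice)"
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
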