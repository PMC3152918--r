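#' Region-based SNP exclusion
#'
#' Intergenic SNPs are used as a proxy for neutrally evolving sequence, so
#' sites inside annotated genes, inside CpG islands, or within `flank_bp` of
#' a gene are removed before any mutation counting.
#'
#' @param snps SNP `data.table` with `chrom` and 0-based `pos`.
#' @param genes,cpg_islands [GenomicRanges::GRanges] of exclusion intervals
#'   (1-based closed, as from [read_bed3()]); `NULL` or empty means no
#'   exclusions of that kind.
#' @param flank_bp Gene flank width in bp excluded on both sides
#'   (default 1000).
#' @return Logical vector: `TRUE` where the SNP must be excluded.
#' @export
exclude_by_region <- function(snps, genes = NULL, cpg_islands = NULL,
                              flank_bp = 1000L) {
  n <- nrow(snps)
  out <- rep(FALSE, n)
  sites <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(start = snps$pos + 1L, width = 1L))
  hit <- function(subject) {
    if (is.null(subject) || length(subject) == 0L) return(rep(FALSE, n))
    known <- unique(as.character(GenomicRanges::seqnames(subject)))
    unknown <- !(snps$chrom %in% known)
    if (any(unknown))
      message("exclude_by_region: ", sum(unknown), " SNP(s) on chromosomes ",
              "absent from the exclusion intervals; treated as not excluded")
    suppressWarnings(IRanges::overlapsAny(sites, subject))
  }
  if (!is.null(genes) && length(genes) > 0L) {
    flanked <- suppressWarnings(GenomicRanges::resize(
      genes, width = GenomicRanges::width(genes) + 2L * as.integer(flank_bp),
      fix = "center"))
    flanked <- GenomicRanges::trim(flanked)
    out <- out | hit(flanked)
  }
  out <- out | hit(cpg_islands)
  out
}

# Per-position mismatch count between two equal-length window vectors over
# the 20 non-center positions of a 21-mer (center = position 11 skipped).
flank_mismatches <- function(a, b) {
  m <- integer(length(a))
  for (j in setdiff(1:21, 11L)) {
    m <- m + (substr(a, j, j) != substr(b, j, j))
  }
  m
}

#' Seven-rule SNP inclusion filter
#'
#' Applies, per record, the inclusion rules used to select reliably
#' polarizable SNPs: (1) exactly two distinct allele bases; (2) one allele
#' equals the orthologous base in both chimp and orangutan; (3) both
#' outgroup windows present; (4) no gaps or unknown bases in the three
#' windows' flanks; (5) at most 1 mismatch between the human and chimp
#' flanks (20 positions, SNP site excluded); (6) at most 6 mismatches
#' against the orangutan flanks; (7) the three bases immediately up- and
#' downstream identical between human and chimp. All failed rules are
#' reported, not only the first.
#'
#' @param snps SNP `data.table` (see [read_snp_table()]).
#' @param chimp_mismatch_limit,orang_mismatch_limit Flank mismatch limits
#'   for rules (5) and (6); defaults 1 and 6.
#' @return A `data.table` with `accepted` (logical) and `reasons`
#'   (comma-separated codes among `NOT_BIALLELIC`, `NO_OUTGROUP_MATCH`,
#'   `UNALIGNED`, `GAP_OR_N`, `CHIMP_MISMATCH_LIMIT`, `ORANG_MISMATCH_LIMIT`,
#'   `NEAR_FLANK_MISMATCH`; empty when accepted).
#' @export
check_criteria <- function(snps, chimp_mismatch_limit = 1L,
                           orang_mismatch_limit = 6L) {
  n <- nrow(snps)
  fail <- list()
  a1 <- snps$allele1; a2 <- snps$allele2
  ok_base <- function(x) x %in% c("A", "C", "G", "T")

  # (1) exactly two distinct nucleotide alleles
  fail$NOT_BIALLELIC <- !(ok_base(a1) & ok_base(a2) & a1 != a2)

  hw <- snps$human_window; cw <- snps$chimp_window; ow <- snps$orang_window
  missing_cw <- is.na(cw) | cw == "." | cw == ""
  missing_ow <- is.na(ow) | ow == "." | ow == ""
  fail$UNALIGNED <- missing_cw | missing_ow

  # malformed window length is rejected alongside gap/N content, logged
  badlen <- (nchar(hw) != 21L) |
    (!missing_cw & nchar(cw) != 21L) |
    (!missing_ow & nchar(ow) != 21L)
  if (any(badlen))
    message("check_criteria: ", sum(badlen),
            " record(s) with malformed window length rejected")

  # (4) gaps / unknown bases in flanks (center of the human window carries
  # the site and is never used for ancestry, so it is not checked here)
  noncenter <- function(w) paste0(substr(w, 1, 10), substr(w, 12, 21))
  has_bad <- function(w, missing) {
    out <- rep(FALSE, n)
    idx <- !missing & nchar(w) == 21L
    out[idx] <- grepl("[^ACGT]", noncenter(w[idx]))
    out
  }
  fail$GAP_OR_N <- badlen |
    has_bad(hw, rep(FALSE, n)) | has_bad(cw, missing_cw) | has_bad(ow, missing_ow)

  evaluable <- !fail$UNALIGNED & !fail$GAP_OR_N

  # (2) one human allele equals both outgroup center bases
  cc <- substr(cw, 11, 11); oc <- substr(ow, 11, 11)
  match1 <- a1 == cc & a1 == oc
  match2 <- a2 == cc & a2 == oc
  fail$NO_OUTGROUP_MATCH <- evaluable & !(match1 | match2)
  fail$NO_OUTGROUP_MATCH[!evaluable] <- FALSE

  # (5)-(7) flank comparisons, only where windows are clean
  mm_chimp <- rep(NA_integer_, n); mm_orang <- rep(NA_integer_, n)
  near_ok <- rep(NA, n)
  if (any(evaluable)) {
    mm_chimp[evaluable] <- flank_mismatches(hw[evaluable], cw[evaluable])
    mm_orang[evaluable] <- flank_mismatches(hw[evaluable], ow[evaluable])
    near_ok[evaluable] <-
      substr(hw[evaluable], 8, 10) == substr(cw[evaluable], 8, 10) &
      substr(hw[evaluable], 12, 14) == substr(cw[evaluable], 12, 14)
  }
  fail$CHIMP_MISMATCH_LIMIT <- evaluable & mm_chimp > chimp_mismatch_limit
  fail$ORANG_MISMATCH_LIMIT <- evaluable & mm_orang > orang_mismatch_limit
  fail$NEAR_FLANK_MISMATCH <- evaluable & !near_ok
  for (k in names(fail)) fail[[k]][is.na(fail[[k]])] <- FALSE

  codes <- names(fail)
  reason_mat <- do.call(cbind, fail)
  reasons <- apply(reason_mat, 1L, function(r) paste(codes[r], collapse = ","))
  data.table::data.table(accepted = !apply(reason_mat, 1L, any),
                         reasons = reasons)
}

#' Polarize accepted SNPs into mutation records
#'
#' When both outgroups carry the same one of the two human alleles, that
#' allele is taken as ancestral and the other as derived; the human window
#' is "ancestralized" by writing the ancestral base at its center, so the
#' window describes the sequence in which the mutation arose.
#'
#' @param snps SNP `data.table`.
#' @param decisions Output of [check_criteria()] for the same rows; only
#'   accepted rows are polarized.
#' @return A mutation-record `data.table`: `chrom`, `pos`, `ancestral`,
#'   `derived`, `window`.
#' @export
polarize <- function(snps, decisions = check_criteria(snps)) {
  if (nrow(snps) != nrow(decisions))
    stop("snps and decisions row counts differ")
  keep <- decisions$accepted
  s <- snps[keep, ]
  if (nrow(s) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ancestral = character(), derived = character(),
                                  window = character()))
  cc <- substr(s$chimp_window, 11, 11)
  anc <- ifelse(s$allele1 == cc, s$allele1, s$allele2)
  der <- ifelse(s$allele1 == cc, s$allele2, s$allele1)
  win <- paste0(substr(s$human_window, 1, 10), anc, substr(s$human_window, 12, 21))
  data.table::data.table(chrom = s$chrom, pos = s$pos,
                         ancestral = anc, derived = der, window = win)
}

#' Filter and polarize a SNP table in one pass
#'
#' Convenience wrapper: region exclusion, the seven inclusion rules, and
#' polarization, with a conservation summary (input = accepted + per-reason
#' rejections; records failing several rules are tallied once under their
#' combined reason string).
#'
#' @inheritParams exclude_by_region
#' @inheritParams check_criteria
#' @return A list with `mutations` (see [polarize()]), `decisions` (with a
#'   `REGION_EXCLUDED` code prepended where applicable), and `summary`
#'   (a `data.table` of reason/count rows, `""` = accepted).
#' @export
filter_snps <- function(snps, genes = NULL, cpg_islands = NULL,
                        flank_bp = 1000L, chimp_mismatch_limit = 1L,
                        orang_mismatch_limit = 6L) {
  excl <- exclude_by_region(snps, genes, cpg_islands, flank_bp)
  dec <- check_criteria(snps, chimp_mismatch_limit, orang_mismatch_limit)
  dec[excl, `:=`(
    accepted = FALSE,
    reasons = ifelse(reasons == "", "REGION_EXCLUDED",
                     paste("REGION_EXCLUDED", reasons, sep = ",")))]
  muts <- polarize(snps, dec)
  summ <- dec[, .N, by = "reasons"]
  data.table::setnames(summ, c("reason", "count"))
  list(mutations = muts, decisions = dec, summary = summ[order(-summ$count)])
}
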