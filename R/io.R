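#' Read a SNP table
#'
#' Tab-separated with header columns `chrom`, `pos`, `allele1`, `allele2`,
#' `human_window`, `chimp_window`, `orang_window`. Positions are 0-based;
#' windows are 21-mers (10 bp of flank either side of the site) with `.`
#' marking a missing outgroup window.
#'
#' @param path File path.
#' @return A `data.table` with the columns above (`pos` integer, 0-based).
#' @export
read_snp_table <- function(path) {
  need <- c("chrom", "pos", "allele1", "allele2",
            "human_window", "chimp_window", "orang_window")
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = setdiff(need, "pos")))
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("SNP table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  dt[, need, with = FALSE]
}

#' @rdname read_snp_table
#' @param snps SNP `data.table` as returned by [read_snp_table()] or
#'   [simulate_snp_dataset()].
#' @export
write_snp_table <- function(snps, path) {
  data.table::fwrite(snps, path, sep = "\t")
  invisible(path)
}

#' Read BED3 intervals as a GRanges
#'
#' BED is 0-based half-open; the returned `GRanges` is 1-based closed, the
#' conversion handled here. An empty or absent file yields an empty
#' `GRanges`.
#'
#' @param path BED file path (3+ columns, no header), or `NULL`.
#' @return A [GenomicRanges::GRanges] object.
#' @export
read_bed3 <- function(path) {
  if (is.null(path) || !file.exists(path) || file.size(path) == 0L)
    return(GenomicRanges::GRanges())
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          select = 1:3, col.names = c("chrom", "start", "end"))
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(start = dt$start + 1L, end = dt$end))
}

#' @rdname read_bed3
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), possibly empty.
#' @export
write_bed3 <- function(intervals, path) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    file.create(path)
  } else {
    data.table::fwrite(intervals[, c("chrom", "start", "end")], path,
                       sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  Biostrings::readDNAStringSet(path)
}

#' Read / write accepted mutation records
#'
#' Tab-separated with header `chrom`, `pos` (0-based), `ancestral`,
#' `derived`, `window` (the ancestralized 21-mer).
#'
#' @param path File path.
#' @return A `data.table` of mutation records.
#' @export
read_mutations <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos", "ancestral", "derived", "window")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("mutation table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  dt[, need, with = FALSE]
}

#' @rdname read_mutations
#' @param records Mutation `data.table` (see [polarize()]).
#' @export
write_mutations <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}
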