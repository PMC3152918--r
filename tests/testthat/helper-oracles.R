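# Independent brute-force oracles used to cross-check the streaming
# implementations. They deliberately enumerate substrings (i, j) directly
# instead of reusing the (length, position) loop of the package code.

# All strict contiguous subwords of ctx$word containing the mutated
# position, as context identifiers.
oracle_subcontext_ids <- function(ctx) {
  ctx <- mutcontext::parse_context(format(ctx))
  L <- nchar(ctx$word)
  out <- character(0)
  for (i in seq_len(L)) {
    for (j in i:L) {
      if (i == 1L && j == L) next
      if (ctx$pos < i || ctx$pos > j) next
      out <- c(out, paste0(ctx$src, ">", ctx$dst, "|", ctx$pos - i + 1L, ",",
                           substr(ctx$word, i, j)))
    }
  }
  out
}

# Quadratic recount: for each record enumerate every substring of the
# window covering the center and tally its context id.
oracle_count_contexts <- function(records, max_len = 4L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  center <- 11L
  for (r in seq_len(nrow(records))) {
    w <- records$window[r]
    for (i in seq_len(nchar(w))) {
      for (j in i:min(nchar(w), i + max_len - 1L)) {
        if (i > center || j < center) next
        word <- substr(w, i, j)
        if (grepl("[^ACGT]", word)) next
        id <- paste0(records$ancestral[r], ">", records$derived[r], "|",
                     center - i + 1L, ",", word)
        env[[id]] <- (if (is.null(env[[id]])) 0L else env[[id]]) + 1L
      }
    }
  }
  ids <- ls(env)
  stats::setNames(vapply(ids, function(k) env[[k]], 0L), ids)
}

# A clean 21-nt window with configurable center, used to build SNP records
# by hand in filter tests. Flanks are fixed arbitrary sequence.
test_window <- function(center = "C", up = "ACGTACGTAC", down = "GTACGTACGT") {
  stopifnot(nchar(up) == 10L, nchar(down) == 10L)
  paste0(up, center, down)
}

# One hand-built SNP record row; fields default to an accepted C/T SNP
# with identical human/chimp/orang windows carrying ancestral C.
make_snp <- function(allele1 = "C", allele2 = "T",
                     human_window = test_window("T"),
                     chimp_window = test_window("C"),
                     orang_window = test_window("C"),
                     chrom = "chrT", pos = 1000L) {
  data.table::data.table(chrom = chrom, pos = pos, allele1 = allele1,
                         allele2 = allele2, human_window = human_window,
                         chimp_window = chimp_window,
                         orang_window = orang_window)
}

# Substitute one position of a window (1-based), for planting mismatches.
set_base <- function(win, at, base) {
  substr(win, at, at) <- base
  win
}
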