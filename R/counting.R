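#' Tally mutations per context
#'
#' Every mutation record contributes one count to each context whose word
#' can be placed on the record's ancestralized window so that the mutated
#' site falls at the context's in-word position: for word length L there
#' are L such placements, so with `max_len = 4` a record feeds
#' 1 + 2 + 3 + 4 = 10 contexts. Words reaching outside the window or
#' containing non-ACGT letters are skipped (and, for malformed windows,
#' logged).
#'
#' @param records Mutation `data.table` (`ancestral`, `derived`, `window`;
#'   windows 21-mers with the ancestral base at position 11).
#' @param max_len Maximum context word length (default 4, at most 6).
#' @return An object of class `context_counts`: list with `counts` (a keyed
#'   `data.table` `id`, `src`, `dst`, `pos`, `word`, `len`, `count`),
#'   `total_records`, and `max_len`.
#' @export
count_mutation_contexts <- function(records, max_len = 4L) {
  max_len <- as.integer(max_len)
  stopifnot(max_len >= 1L, max_len <= 6L)
  center <- 11L
  bad <- nchar(records$window) != 21L
  if (any(bad)) {
    message("count_mutation_contexts: skipping ", sum(bad),
            " record(s) with malformed windows")
    records <- records[!bad, ]
  }
  parts <- vector("list", 0L)
  if (nrow(records) > 0L) {
    for (L in seq_len(max_len)) {
      for (p in seq_len(L)) {
        start <- center - p + 1L
        w <- substr(records$window, start, start + L - 1L)
        keep <- !grepl("[^ACGT]", w)
        if (!any(keep)) next
        parts[[length(parts) + 1L]] <- data.table::data.table(
          src = records$ancestral[keep], dst = records$derived[keep],
          pos = p, word = w[keep], len = L)
      }
    }
  }
  if (length(parts) == 0L) {
    counts <- data.table::data.table(id = character(), src = character(),
                                     dst = character(), pos = integer(),
                                     word = character(), len = integer(),
                                     count = integer())
  } else {
    long <- data.table::rbindlist(parts)
    counts <- long[, list(count = .N), by = c("src", "dst", "pos", "word", "len")]
    counts[, "id" := paste0(counts$src, ">", counts$dst, "|", counts$pos,
                            ",", counts$word)]
    data.table::setcolorder(counts, c("id", "src", "dst", "pos", "word",
                                      "len", "count"))
  }
  data.table::setkeyv(counts, "id")
  structure(list(counts = counts, total_records = nrow(records),
                 max_len = max_len),
            class = "context_counts")
}

#' @export
print.context_counts <- function(x, ...) {
  cat("<context_counts: ", nrow(x$counts), " contexts from ",
      x$total_records, " records, max_len ", x$max_len, ">\n", sep = "")
  invisible(x)
}

#' Look up context counts by identifier
#'
#' @param counts A `context_counts` object.
#' @param id Character vector of context identifiers.
#' @return Integer vector of counts (0 for unseen contexts).
#' @export
context_count <- function(counts, id) {
  stopifnot(inherits(counts, "context_counts"))
  out <- counts$counts$count[data.table::chmatch(id, counts$counts$id)]
  out[is.na(out)] <- 0L
  out
}

new_word_freqs <- function(count_list, source, max_len) {
  freq <- lapply(count_list, function(v) {
    tot <- sum(v)
    if (tot == 0) v * 0 else v / tot
  })
  structure(list(freq = freq, counts = count_list, source = source,
                 max_len = max_len),
            class = "word_freqs")
}

#' @export
print.word_freqs <- function(x, ...) {
  cat("<word_freqs (", x$source, "): lengths 1..", x$max_len, ">\n", sep = "")
  invisible(x)
}

#' Word frequency and count lookup
#'
#' @param freqs A `word_freqs` object.
#' @param word Character vector of words (all the same length).
#' @return `word_freq`: numeric frequencies (`NA` for unseen words);
#'   `word_count`: the underlying occurrence counts (0 for unseen words).
#' @export
word_freq <- function(freqs, word) {
  stopifnot(inherits(freqs, "word_freqs"))
  L <- unique(nchar(word))
  stopifnot(length(L) == 1L)
  if (L > freqs$max_len) stop("no word frequencies for length ", L)
  unname(freqs$freq[[L]][word])
}

#' @rdname word_freq
#' @export
word_count <- function(freqs, word) {
  stopifnot(inherits(freqs, "word_freqs"))
  L <- unique(nchar(word))
  stopifnot(length(L) == 1L)
  if (L > freqs$max_len) stop("no word counts for length ", L)
  out <- unname(freqs$counts[[L]][word])
  out[is.na(out)] <- 0
  out
}

#' Word frequencies from the windows' outer flank intervals
#'
#' The background word distribution is estimated from the two 5-nt
#' intervals of each record's window lying 6-10 bp from the mutated site
#' (window positions 1-5 and 17-21). These intervals do not overlap any
#' 1-4 bp context placement around the site, so the background is not
#' contaminated by the mutation itself. Words must fit entirely inside one
#' interval (`6 - L` placements per interval), so `max_len` cannot exceed 5.
#'
#' @inheritParams count_mutation_contexts
#' @return A `word_freqs` object (source `"flank-intervals"`): per word
#'   length, named vectors of frequencies (summing to 1) and raw counts.
#' @export
flank_word_freqs <- function(records, max_len = 4L) {
  max_len <- as.integer(max_len)
  if (max_len > 5L)
    stop("flank-interval frequencies support word lengths up to 5")
  if (nrow(records) == 0L) stop("no records: word frequencies undefined")
  intervals <- c(substr(records$window, 1, 5), substr(records$window, 17, 21))
  count_list <- vector("list", max_len)
  for (L in seq_len(max_len)) {
    words <- unlist(lapply(seq_len(6L - L), function(i)
      substr(intervals, i, i + L - 1L)), use.names = FALSE)
    words <- words[!grepl("[^ACGT]", words)]
    tab <- table(factor(words, levels = Biostrings::mkAllStrings(
      c("A", "C", "G", "T"), L)))
    count_list[[L]] <- stats::setNames(as.numeric(tab), names(tab))
  }
  new_word_freqs(count_list, "flank-intervals", max_len)
}

#' Word frequencies from whole genome sequence
#'
#' Sliding-window count of all L-words over the supplied sequences
#' (windows containing non-ACGT letters are skipped), normalized per
#' length. Used as the separate whole-genome control background.
#'
#' @param genome A [Biostrings::DNAStringSet], `DNAString`, or a plain
#'   character vector of sequences.
#' @param max_len Maximum word length.
#' @return A `word_freqs` object (source `"whole-genome"`).
#' @export
genome_word_freqs <- function(genome, max_len = 4L) {
  max_len <- as.integer(max_len)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (inherits(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(list(genome))
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome: word frequencies undefined")
  count_list <- vector("list", max_len)
  for (L in seq_len(max_len)) {
    m <- Biostrings::oligonucleotideFrequency(genome, width = L, step = 1L)
    v <- if (is.matrix(m)) colSums(m) else m
    count_list[[L]] <- stats::setNames(as.numeric(v), names(v))
  }
  new_word_freqs(count_list, "whole-genome", max_len)
}
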