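#' Mutation contexts
#'
#' A mutation context describes a point substitution occurring at a fixed
#' position of a short nucleotide word: a C>T substitution at the first
#' position of the word CG is written `"C>T|1,CG"`. Contexts are the unit of
#' analysis throughout the package: mutations are tallied per context,
#' contrasted against their subcontexts, and paired with their
#' reverse-complement partners.
#'
#' @param word Nucleotide word over `A`, `C`, `G`, `T` (length 1 or more).
#' @param pos 1-based position of the mutated base within `word`.
#' @param dst Derived (post-mutation) base.
#' @param src Ancestral base; defaults to the base of `word` at `pos` and
#'   must agree with it.
#' @return An object of class `mutation_context`: a list with fields `word`,
#'   `pos`, `src`, `dst`.
#' @examples
#' ctx <- mutation_context("CG", 1, "T")
#' format(ctx)
#' subcontexts(mutation_context("ACG", 2, "T"))
#' @export
mutation_context <- function(word, pos, dst, src = substr(word, pos, pos)) {
  stopifnot(is.character(word), length(word) == 1L, nchar(word) >= 1L)
  if (grepl("[^ACGT]", word))
    stop("context word must be over {A,C,G,T}: ", word)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L || pos > nchar(word))
    stop("position ", pos, " outside word ", word)
  if (substr(word, pos, pos) != src)
    stop("word '", word, "' does not carry source base '", src,
         "' at position ", pos)
  if (!dst %in% c("A", "C", "G", "T")) stop("invalid target base: ", dst)
  if (src == dst) stop("source and target base must differ")
  structure(list(word = word, pos = pos, src = src, dst = dst),
            class = "mutation_context")
}

#' @export
format.mutation_context <- function(x, ...) {
  paste0(x$src, ">", x$dst, "|", x$pos, ",", x$word)
}

#' @export
print.mutation_context <- function(x, ...) {
  cat("<mutation context {", format(x), "}>\n", sep = "")
  invisible(x)
}

#' @export
as.character.mutation_context <- function(x, ...) format(x)

#' Parse a context identifier
#'
#' Identifiers have the canonical form `"SRC>DST|POS,WORD"` (e.g.
#' `"C>T|1,CG"`); whitespace around the tokens is tolerated.
#'
#' @param id Character vector of context identifiers.
#' @return A single `mutation_context` when `id` has length 1, otherwise a
#'   list of them.
#' @export
parse_context <- function(id) {
  parse1 <- function(s) {
    s <- gsub("[[:space:]]", "", s)
    m <- regmatches(s, regexec("^([ACGT])>([ACGT])\\|([0-9]+),([ACGT]+)$", s))[[1]]
    if (length(m) != 5L) stop("malformed context identifier: '", s, "'")
    mutation_context(word = m[5], pos = as.integer(m[4]), dst = m[3], src = m[2])
  }
  out <- lapply(id, parse1)
  if (length(out) == 1L) out[[1]] else out
}

#' Enumerate the subcontexts of a context
#'
#' A subcontext lives on a strict contiguous subword of the context's word
#' that still contains the mutated position; the position is shifted
#' accordingly. A context of word length L with the mutation at position p
#' has `p * (L - p + 1) - 1` subcontexts; a 1-letter context has none.
#'
#' @param ctx A `mutation_context` or identifier string.
#' @return List of `mutation_context` objects, ordered by decreasing subword
#'   length, then by subword start.
#' @export
subcontexts <- function(ctx) {
  ctx <- as_context(ctx)
  L <- nchar(ctx$word)
  p <- ctx$pos
  out <- list()
  for (len in seq(L, 1L)) {
    for (i in seq_len(L - len + 1L)) {
      j <- i + len - 1L
      if (i > p || j < p) next
      if (len == L) next                       # strict subword only
      out[[length(out) + 1L]] <- mutation_context(
        word = substr(ctx$word, i, j), pos = p - i + 1L,
        dst = ctx$dst, src = ctx$src)
    }
  }
  out
}

#' Reverse-complement partner of a context
#'
#' Mutation data pooled over both genomic strands cannot distinguish a
#' substitution from its reverse-complement reading, so every context has a
#' complementary partner with the same expected mutation properties:
#' `{C>T|1,CG}` pairs with `{G>A|2,CG}`. The operation is an involution.
#'
#' @param ctx A `mutation_context` or identifier string.
#' @return The complementary `mutation_context`.
#' @export
context_complement <- function(ctx) {
  ctx <- as_context(ctx)
  L <- nchar(ctx$word)
  rc <- revcomp(ctx$word)
  mutation_context(word = rc, pos = L - ctx$pos + 1L,
                   dst = comp_base(ctx$dst), src = comp_base(ctx$src))
}

as_context <- function(x) {
  if (inherits(x, "mutation_context")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_context(x))
  stop("expected a mutation_context or an identifier string")
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Enumerate all mutation contexts in a word-length range
#'
#' There are `3 * L * 4^L` contexts of word length L (every word, every
#' in-word position, every non-ancestral target base): 96 of length 2, 576
#' of length 3, 3072 of length 4 — the 3744 contexts of the 2-4 bp scan.
#'
#' @param min_len,max_len Word-length bounds, `1 <= min_len <= max_len`.
#' @return A `data.table` with one row per context: `id`, `word`, `pos`,
#'   `src`, `dst`, `len`.
#' @export
enumerate_contexts <- function(min_len = 2L, max_len = 4L) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (is.na(min_len) || is.na(max_len) || min_len < 1L || min_len > max_len)
    stop("need 1 <= min_len <= max_len")
  bases <- c("A", "C", "G", "T")
  parts <- vector("list", 0L)
  for (L in min_len:max_len) {
    words <- Biostrings::mkAllStrings(bases, L)
    for (p in seq_len(L)) {
      src <- substr(words, p, p)
      for (d in bases) {
        keep <- src != d
        if (!any(keep)) next
        parts[[length(parts) + 1L]] <- data.table::data.table(
          word = words[keep], pos = p, src = src[keep], dst = d, len = L)
      }
    }
  }
  dt <- data.table::rbindlist(parts)
  dt[, "id" := paste0(dt$src, ">", dt$dst, "|", dt$pos, ",", dt$word)]
  data.table::setcolorder(dt, c("id", "word", "pos", "src", "dst", "len"))
  data.table::setkeyv(dt, "id")
  dt[]
}

#' Enumerate all context/subcontext pairs
#'
#' One row per (context, subcontext) pair with the context's word length in
#' `[min_len, max_len]`; subcontext length may fall below `min_len`. For
#' lengths 2-4 there are 13728 pairs — the multiple-comparison family of the
#' significance test.
#'
#' @inheritParams enumerate_contexts
#' @return A `data.table` with columns `context_id`, `subcontext_id`, plus
#'   the context's `word`, `pos`, `src`, `dst`, `len` and the subcontext's
#'   `sub_word`, `sub_pos`, `sub_len`.
#' @export
enumerate_context_pairs <- function(min_len = 2L, max_len = 4L) {
  ctxs <- enumerate_contexts(min_len, max_len)
  parts <- vector("list", 0L)
  for (L in unique(ctxs$len)) {
    for (p in seq_len(L)) {
      block <- ctxs[ctxs$len == L & ctxs$pos == p, ]
      if (nrow(block) == 0L) next
      for (sl in seq_len(L)) {
        for (i in seq_len(L - sl + 1L)) {
          j <- i + sl - 1L
          if (i > p || j < p || sl == L) next
          sub_word <- substr(block$word, i, j)
          sp <- p - i + 1L
          parts[[length(parts) + 1L]] <- data.table::data.table(
            context_id = block$id,
            subcontext_id = paste0(block$src, ">", block$dst, "|", sp, ",", sub_word),
            word = block$word, pos = p, src = block$src, dst = block$dst,
            len = L, sub_word = sub_word, sub_pos = sp, sub_len = sl)
        }
      }
    }
  }
  data.table::rbindlist(parts)[]
}

# Vectorized complement of context identifier strings (for report tables).
complement_ids <- function(id) {
  dt <- data.table::data.table(
    src = substr(id, 1L, 1L),
    dst = substr(id, 3L, 3L))
  rest <- substring(id, 5L)
  pos <- as.integer(sub(",.*$", "", rest))
  word <- sub("^[0-9]+,", "", rest)
  L <- nchar(word)
  paste0(comp_base(dt$src), ">", comp_base(dt$dst), "|", L - pos + 1L,
         ",", revcomp(word))
}
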