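#' Contrast between a context and one of its subcontexts
#'
#' The contrast of context W against subcontext W' is the observed ratio of
#' mutation counts divided by its expectation under context-independent
#' mutation:
#' \deqn{Contrast = \frac{N_{W} / N_{W'}}{P_W / P_{W'}}}
#' where the P are word frequencies among words of the same length. The
#' frequency ratio is the probability that an occurrence of W' extends to
#' W, which is exactly the expected count ratio when the mutation rate does
#' not depend on the added letters; contrast above 1 therefore measures
#' mutation excess in the wider context, below 1 deficiency.
#'
#' @param n_ctx,n_sub Mutation counts in context and subcontext.
#' @param p_w,p_wsub Word frequencies of the context and subcontext words.
#' @return Numeric contrast value(s); vectorized.
#' @export
contrast <- function(n_ctx, n_sub, p_w, p_wsub) {
  if (any(n_sub <= 0L)) stop("undefined contrast: subcontext count is zero")
  if (any(!is.finite(p_w) | !is.finite(p_wsub) | p_w <= 0 | p_wsub <= 0))
    stop("undefined contrast: zero or missing word frequency")
  (n_ctx / n_sub) / (p_w / p_wsub)
}

#' One-sided binomial significance of a context/subcontext pair
#'
#' Under context-independent mutation, each of the `n_sub` mutations seen
#' in the subcontext falls in the wider context independently with
#' probability `q = p_w / p_wsub`, so the context count is Binomial(n_sub,
#' q). Returns the tail probability of a deviation at least as large as
#' observed, in the observed direction (upper tail when `n_ctx >= n_sub *
#' q`, lower tail otherwise), computed with the exact binomial
#' distribution function.
#'
#' `q` marginally above 1 can arise from sampling noise in the two
#' frequency estimates and is clamped to 1; values beyond `1 + clamp_tol`
#' indicate inconsistent frequency inputs and raise an error.
#'
#' @inheritParams contrast
#' @param clamp_tol Tolerance for clamping `q` to 1 (default 0.25).
#' @return P-value(s) in `[0, 1]`; vectorized. `n_sub = 0` gives 1 (no
#'   information).
#' @export
binomial_pvalue <- function(n_ctx, n_sub, p_w, p_wsub, clamp_tol = 0.25) {
  if (any(n_ctx > n_sub)) stop("context count exceeds subcontext count")
  if (any(n_ctx < 0L)) stop("negative count")
  q <- p_w / p_wsub
  if (any(!is.finite(q) | q <= 0)) stop("undefined q: bad word frequencies")
  if (any(q > 1 + clamp_tol))
    stop("frequency inconsistency: P_W / P_W' = ", max(q), " > 1 + clamp_tol")
  q <- pmin(q, 1)
  n <- as.numeric(n_sub); k <- as.numeric(n_ctx)
  upper <- k >= n * q
  p <- ifelse(upper,
              stats::pbinom(k - 1, n, q, lower.tail = FALSE),
              stats::pbinom(k, n, q))
  p[n == 0] <- 1
  pmin(p, 1)
}

#' Minimal-contrast selection rule
#'
#' Given a context's contrast values against each of its subcontexts, the
#' minimal contrast is the value whose absolute difference from 1 is
#' smallest — the mutation excess that no single subcontext explains. Ties
#' in `|x - 1|` (e.g. 0.95 vs 1.05) resolve to the value below 1.
#'
#' @param values Numeric vector of subcontext contrast values (length >= 1).
#' @return A list with `value` (the selected contrast) and `index` (its
#'   position in `values`).
#' @export
select_minimal_contrast <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L, all(is.finite(values)))
  ord <- order(abs(values - 1), values)
  list(value = values[ord[1L]], index = ord[1L])
}

# Assemble the per-pair working table: counts, frequencies, contrast and
# binomial p for every (context, subcontext) pair in the length range.
# `defined` marks pairs with positive counts and frequencies on both sides.
build_pair_table <- function(counts, freqs, min_len = 2L, max_len = 4L,
                             clamp_tol = 0.25) {
  stopifnot(inherits(counts, "context_counts"), inherits(freqs, "word_freqs"))
  if (max_len > counts$max_len)
    stop("counts only cover word lengths up to ", counts$max_len)
  pairs <- enumerate_context_pairs(min_len, max_len)
  pairs[, "n_ctx" := context_count(counts, pairs$context_id)]
  pairs[, "n_sub" := context_count(counts, pairs$subcontext_id)]
  p_w <- numeric(nrow(pairs)); p_sub <- numeric(nrow(pairs))
  for (L in unique(pairs$len)) {
    idx <- which(pairs$len == L)
    p_w[idx] <- word_freq(freqs, pairs$word[idx])
  }
  for (L in unique(pairs$sub_len)) {
    idx <- which(pairs$sub_len == L)
    p_sub[idx] <- word_freq(freqs, pairs$sub_word[idx])
  }
  pairs[, "p_w" := p_w]
  pairs[, "p_sub" := p_sub]
  ok <- pairs$n_ctx > 0L & pairs$n_sub > 0L &
    is.finite(p_w) & p_w > 0 & is.finite(p_sub) & p_sub > 0
  pairs[, "defined" := ok]
  pairs[, "contrast" := NA_real_]
  pairs[, "pvalue" := NA_real_]
  if (any(ok)) {
    pairs[ok, "contrast" := contrast(n_ctx, n_sub, p_w, p_sub)]
    pairs[ok, "pvalue" := binomial_pvalue(n_ctx, n_sub, p_w, p_sub,
                                          clamp_tol = clamp_tol)]
  }
  pairs
}

#' Per-pair contrasts and binomial p-values
#'
#' One row for every (context, subcontext) pair with context word length in
#' `[min_len, max_len]`; pairs involving a zero count or zero frequency are
#' kept but flagged `defined = FALSE` with `NA` statistics.
#'
#' @param counts A `context_counts` object ([count_mutation_contexts()]).
#' @param freqs A `word_freqs` object ([flank_word_freqs()],
#'   [genome_word_freqs()]).
#' @param min_len,max_len Context word-length range (default 2-4).
#' @param clamp_tol Passed to [binomial_pvalue()].
#' @return A `data.table` with the pair identifiers, counts, frequencies,
#'   `contrast`, `pvalue`, `defined`.
#' @export
contrast_pairs <- function(counts, freqs, min_len = 2L, max_len = 4L,
                           clamp_tol = 0.25) {
  build_pair_table(counts, freqs, min_len, max_len, clamp_tol)
}

#' Mutation bias of a context
#'
#' The contrast of a context against its unique 1-letter subcontext: the
#' fold-excess of the context's mutation rate over the average rate of that
#' substitution type. For word length 2 it coincides with the minimal
#' contrast.
#'
#' @param ctx A `mutation_context` or identifier string (word length >= 2).
#' @inheritParams contrast_pairs
#' @return Numeric mutation bias.
#' @export
mutation_bias <- function(ctx, counts, freqs) {
  ctx <- as_context(ctx)
  if (nchar(ctx$word) < 2L)
    stop("mutation bias undefined for 1-letter contexts")
  id <- format(ctx)
  sub1 <- paste0(ctx$src, ">", ctx$dst, "|1,", ctx$src)
  contrast(context_count(counts, id), context_count(counts, sub1),
           word_freq(freqs, ctx$word), word_freq(freqs, ctx$src))
}

#' Minimal contrast of a context
#'
#' Evaluates the contrast of `ctx` against every one of its subcontexts and
#' returns the value closest to 1 (see [select_minimal_contrast()]).
#'
#' @inheritParams mutation_bias
#' @return A list: `value`, `subcontext` (identifier of the arg-min pair),
#'   `n_context`, `n_subcontext`, `pvalue` (binomial p of the arg-min pair).
#' @export
minimal_contrast <- function(ctx, counts, freqs) {
  ctx <- as_context(ctx)
  subs <- subcontexts(ctx)
  if (length(subs) == 0L) stop("context has no subcontexts")
  id <- format(ctx)
  n_ctx <- context_count(counts, id)
  sub_ids <- vapply(subs, format, "")
  n_sub <- context_count(counts, sub_ids)
  p_w <- word_freq(freqs, ctx$word)
  p_sub <- vapply(subs, function(s) word_freq(freqs, s$word), 0)
  if (n_ctx == 0L || any(n_sub == 0L) || !is.finite(p_w) || p_w <= 0 ||
      any(!is.finite(p_sub) | p_sub <= 0))
    stop("minimal contrast undefined: zero count or frequency for {",
         id, "} or a subcontext")
  vals <- contrast(n_ctx, n_sub, p_w, p_sub)
  sel <- select_minimal_contrast(vals)
  list(value = sel$value, subcontext = sub_ids[sel$index],
       n_context = n_ctx, n_subcontext = n_sub[sel$index],
       pvalue = binomial_pvalue(n_ctx, n_sub[sel$index], p_w,
                                p_sub[sel$index]))
}

#' Bonferroni significance flags
#'
#' In the default `"paper"` mode the working threshold `alpha` (default
#' 1e-15) is treated as already incorporating the correction for the
#' `m`-pair comparison family (m = 13728 for the 2-4 bp scan), and a pair
#' is significant when `p < alpha`. In `"bonferroni"` mode the flag is
#' `p < alpha / m`.
#'
#' @param pvalues Numeric vector of p-values.
#' @param alpha Significance level.
#' @param m Size of the comparison family; defaults to the number of
#'   context/subcontext pairs for word lengths 2-4.
#' @param mode `"paper"` or `"bonferroni"`.
#' @return Logical vector of significance flags, with `m` and the effective
#'   threshold attached as attributes `m` and `threshold`.
#' @export
apply_bonferroni <- function(pvalues, alpha = 1e-15, m = 13728L,
                             mode = c("paper", "bonferroni")) {
  mode <- match.arg(mode)
  thr <- if (mode == "paper") alpha else alpha / m
  structure(pvalues < thr, m = m, threshold = thr)
}

#' Per-context contrast summary table
#'
#' The package's main result table: one row per context with its mutation
#' bias, minimal contrast (value, arg-min subcontext, counts), the binomial
#' p of the minimal-contrast pair, the largest p over all its subcontext
#' pairs, and a significance flag. A context is flagged significant when
#' every one of its subcontext comparisons is significant (its rate differs
#' from each of its subcontexts), i.e. when `pvalue_max` clears the
#' threshold. Contexts touching any zero count or zero frequency are
#' excluded from the table and reported in the `diagnostics` attribute.
#'
#' @inheritParams contrast_pairs
#' @param alpha,m,mode See [apply_bonferroni()]; `m` defaults to the pair
#'   count of the enumerated family.
#' @return A `data.table` keyed by `context_id` with columns
#'   `complement_id`, `len`, `n_context`, `mutation_bias`, `se_log_bias`,
#'   `minimal_contrast`, `argmin_subcontext`, `n_subcontext_min`,
#'   `pvalue_min`, `pvalue_max`, `significant`. Attributes: `diagnostics`
#'   (excluded context ids with the reason), `m`, `threshold`,
#'   `freq_source`.
#' @export
contrast_table <- function(counts, freqs, min_len = 2L, max_len = 4L,
                           alpha = 1e-15, m = NULL,
                           mode = c("paper", "bonferroni"),
                           clamp_tol = 0.25) {
  mode <- match.arg(mode)
  pairs <- build_pair_table(counts, freqs, min_len, max_len, clamp_tol)
  if (is.null(m)) m <- nrow(pairs)

  # a context is ranked only if all of its pairs are defined
  ctx_ok <- pairs[, list(all_defined = all(defined), n_context = n_ctx[1L],
                         len = len[1L]),
                  by = "context_id"]
  good_ids <- ctx_ok$context_id[ctx_ok$all_defined]
  diag <- ctx_ok[!ctx_ok$all_defined,
                 list(context_id, reason = "zero count or zero frequency")]

  dp <- pairs[pairs$context_id %in% good_ids, ]
  res <- dp[, {
    sel <- select_minimal_contrast(contrast)
    wc <- word_count(freqs, word[1L])
    wcs <- word_count(freqs, src[1L])
    bias_i <- which(sub_len == 1L)
    list(len = len[1L],
         n_context = n_ctx[1L],
         mutation_bias = contrast[bias_i],
         se_log_bias = sqrt(1 / n_ctx[1L] + 1 / n_sub[bias_i] +
                              1 / wc + 1 / wcs),
         minimal_contrast = sel$value,
         argmin_subcontext = subcontext_id[sel$index],
         n_subcontext_min = n_sub[sel$index],
         pvalue_min = pvalue[sel$index],
         pvalue_max = max(pvalue))
  }, by = "context_id"]
  res[, "complement_id" := complement_ids(res$context_id)]
  sig <- apply_bonferroni(res$pvalue_max, alpha = alpha, m = m, mode = mode)
  res[, "significant" := as.logical(sig)]
  data.table::setcolorder(res, c("context_id", "complement_id", "len",
                                 "n_context", "mutation_bias", "se_log_bias",
                                 "minimal_contrast", "argmin_subcontext",
                                 "n_subcontext_min", "pvalue_min",
                                 "pvalue_max", "significant"))
  data.table::setkeyv(res, "context_id")
  data.table::setattr(res, "diagnostics", diag)
  data.table::setattr(res, "m", attr(sig, "m"))
  data.table::setattr(res, "threshold", attr(sig, "threshold"))
  data.table::setattr(res, "freq_source", freqs$source)
  res[]
}
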