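#' Structural CG-cluster labels
#'
#' In the bias versus minimal-contrast plane, the CpG transition contexts
#' `{C>T|1,CG}` and `{G>A|2,CG}` sit apart at the highest minimal contrast,
#' and a second cluster holds exactly the longer contexts containing one of
#' them as a subcontext. These memberships are structural — a property of
#' the subcontext lattice, invariant under reverse-complement — so they are
#' assigned from the context algebra rather than from positions on a plot.
#'
#' @param context_id Character vector of context identifiers.
#' @return Character vector of labels: `"CG-core"` (the two CpG transition
#'   dinucleotide contexts), `"CG-containing"` (contexts having one of them
#'   as a subcontext), `"other"`.
#' @export
cg_cluster_membership <- function(context_id) {
  core <- c("C>T|1,CG", "G>A|2,CG")
  has_core_sub <- function(id) {
    any(vapply(subcontexts(id), format, "") %in% core)
  }
  out <- rep("other", length(context_id))
  out[context_id %in% core] <- "CG-core"
  longer <- !(context_id %in% core)
  out[longer][vapply(context_id[longer], has_core_sub, NA)] <- "CG-containing"
  out
}

#' Bias versus minimal-contrast scatter table
#'
#' One row per ranked context with its two contrast coordinates, its
#' reverse-complement partner, and a cluster label: the structural CG
#' labels plus `"top-outlier"` for non-CG contexts exceeding configurable
#' thresholds on both coordinates (the visually isolated hypermutable
#' candidates), and `"main"` for the rest.
#'
#' @param results A contrast summary table ([contrast_table()]).
#' @param bias_threshold,mc_threshold Coordinate thresholds for the
#'   top-outlier label (defaults 2 and 2).
#' @return A `data.table`: `context_id`, `complement_id`, `mutation_bias`,
#'   `minimal_contrast`, `cluster`.
#' @export
scatter_table <- function(results, bias_threshold = 2, mc_threshold = 2) {
  stopifnot(nrow(results) > 0L)
  out <- results[, c("context_id", "complement_id", "mutation_bias",
                     "minimal_contrast"), with = FALSE]
  lab <- cg_cluster_membership(out$context_id)
  top <- lab == "other" & out$mutation_bias > bias_threshold &
    out$minimal_contrast > mc_threshold
  lab[lab == "other"] <- "main"
  lab[top] <- "top-outlier"
  out[, "cluster" := lab]
  out[]
}

#' Normal approximation of the minimal-contrast distribution
#'
#' Fits a normal to the minimal-contrast values inside `fit_range` by
#' truncated-normal maximum likelihood (the restriction to `fit_range`
#' otherwise shrinks the sample standard deviation by the truncation
#' factor, ~12% for a half-sigma-wide window), then compares the observed
#' histogram inside `test_range` with the expectation under the fitted
#' normal (scaled so the fitted curve matches the sample mass inside
#' `fit_range`) with a two-component statistic: a Pearson chi-square over
#' adjacent bins pooled to an expected count of at least 5, plus an exact
#' Poisson upper tail for the far-tail overflow cell left over by the
#' pooling (far-tail excesses are exactly what pooling would dilute away);
#' the reported p-value Bonferroni-combines the two components. Also
#' returns histograms of both statistics over all values.
#'
#' @param results A contrast summary table, or a numeric vector of minimal
#'   contrasts.
#' @param fit_range,test_range Numeric length-2 intervals; defaults
#'   `c(0.7, 1.2)` and `c(1.2, 5.1)`.
#' @param bin_width Histogram bin width (default 0.1).
#' @param min_fit Minimum number of values required inside `fit_range`
#'   (default 30).
#' @return A list of class `distribution_summary`: `mean`, `sd`, `n_fit`,
#'   `n_test`, `chisq`, `df`, `pvalue`, `fit_range`, `test_range`,
#'   `hist_minimal_contrast`, and (when a summary table was supplied)
#'   `hist_mutation_bias`; histograms as lists with `breaks` and `counts`.
#' @export
fit_minimal_contrast_normal <- function(results, fit_range = c(0.7, 1.2),
                                        test_range = c(1.2, 5.1),
                                        bin_width = 0.1, min_fit = 30L) {
  if (is.numeric(results)) {
    mc <- results
    bias <- NULL
  } else {
    mc <- results$minimal_contrast
    bias <- results$mutation_bias
  }
  mc <- mc[is.finite(mc)]
  infit <- mc[mc >= fit_range[1] & mc <= fit_range[2]]
  if (length(infit) < min_fit)
    stop("only ", length(infit), " values inside the fit range (need >= ",
         min_fit, ")")
  # truncated-normal ML, started from the (truncation-biased) moments
  trunc_nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    z <- stats::pnorm(fit_range[2], mu, sigma) -
      stats::pnorm(fit_range[1], mu, sigma)
    if (z <= 0) return(Inf)
    -sum(stats::dnorm(infit, mu, sigma, log = TRUE)) + length(infit) * log(z)
  }
  opt <- stats::optim(c(mean(infit), log(stats::sd(infit))), trunc_nll,
                      method = "Nelder-Mead")
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  if (!is.finite(sigma) || sigma <= 0) stop("degenerate fit: sd <= 0")

  breaks <- seq(test_range[1], test_range[2], by = bin_width)
  if (breaks[length(breaks)] < test_range[2])
    breaks <- c(breaks, test_range[2])
  intest <- mc[mc > test_range[1] & mc <= test_range[2]]
  obs <- as.numeric(table(cut(intest, breaks, include.lowest = FALSE)))
  # scale: the fitted curve reproduces the sample mass inside fit_range
  scale_n <- length(infit) /
    (stats::pnorm(fit_range[2], mu, sigma) - stats::pnorm(fit_range[1], mu, sigma))
  expd <- scale_n * diff(stats::pnorm(breaks, mu, sigma))

  # pool adjacent bins (left to right) to expected >= 5; the remainder is
  # the far-tail overflow cell, tested exactly
  po <- numeric(0); pe <- numeric(0); co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expd[i]
    if (ce >= 5) { po <- c(po, co); pe <- c(pe, ce); co <- 0; ce <- 0 }
  }
  if (length(pe) > 0L) {
    chisq <- sum((po - pe)^2 / pe)
    df <- max(1L, length(pe) - 1L)
    p_chisq <- stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; df <- NA_integer_; p_chisq <- 1
  }
  p_tail <- if (co == 0 && ce == 0) 1 else
    stats::ppois(co - 1L, ce, lower.tail = FALSE)
  pval <- min(1, 2 * min(p_chisq, p_tail))

  hist_of <- function(v) {
    rng <- range(v)
    brk <- seq(floor(rng[1] / bin_width) * bin_width,
               ceiling(rng[2] / bin_width) * bin_width + bin_width,
               by = bin_width)
    h <- graphics::hist(v, breaks = brk, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  }
  out <- list(mean = mu, sd = sigma, n_fit = length(infit),
              n_test = length(intest), chisq = chisq, df = df,
              p_chisq = p_chisq, p_tail = p_tail,
              tail_observed = co, tail_expected = ce, pvalue = pval,
              fit_range = fit_range, test_range = test_range,
              hist_minimal_contrast = hist_of(mc))
  if (!is.null(bias)) out$hist_mutation_bias <- hist_of(bias[is.finite(bias)])
  structure(out, class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat("<distribution_summary>\n",
      "  normal fit on [", x$fit_range[1], ", ", x$fit_range[2], "]: mean ",
      signif(x$mean, 3), ", sd ", signif(x$sd, 3), " (n = ", x$n_fit, ")\n",
      "  tail test on (", x$test_range[1], ", ", x$test_range[2], "]: X2 = ",
      signif(x$chisq, 4), ", df = ", x$df, ", p = ", signif(x$pvalue, 3),
      " (n = ", x$n_test, ")\n", sep = "")
  invisible(x)
}
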