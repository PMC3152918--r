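#' Simulation configuration
#'
#' Builds and validates the configuration for the forward simulator of
#' context-biased point mutagenesis (see [simulate_snp_dataset()]).
#'
#' Planted multipliers are expressed on the mutation-bias scale: a
#' multiplier f for context `{src>dst|pos,W}` means the per-site mutation
#' probability at sites matching the context is f times the genome-average
#' probability of that substitution type, which the simulator holds at
#' `baseline_rate` by lowering the out-of-context rate accordingly. A bias
#' f is only attainable when f * q < 1, q being the fraction of source-base
#' sites that match the context; infeasible settings are rejected at
#' simulation time.
#'
#' @param genome_length Ancestral sequence length in bases.
#' @param base_composition Named probabilities for A, C, G, T (sum 1).
#'   Default 36% GC, a typical composition for AT-rich intergenic DNA.
#' @param planted_effects Named numeric vector: context identifier ->
#'   fold-excess multiplier (> 0). Empty means context-independent rates.
#' @param baseline_rate Genome-average per-site probability of each
#'   substitution type (default 1e-3).
#' @param chimp_divergence,orang_divergence Per-site substitution
#'   probabilities applied independently to the outgroup window flanks
#'   (defaults 0.012 and 0.031, typical autosomal divergences from human).
#' @param strand_symmetric When `TRUE` (default) each planted effect is
#'   mirrored onto its reverse-complement context; setting a context and
#'   its mirror to different multipliers is a configuration error.
#' @param genes,cpg_islands Optional `data.frame`s of exclusion intervals
#'   (`chrom`, `start`, `end`; 0-based half-open) for [emit_region_beds()].
#' @param seed Integer RNG seed; the simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6,
                       base_composition = c(A = 0.32, C = 0.18,
                                            G = 0.18, T = 0.32),
                       planted_effects = numeric(0),
                       baseline_rate = 1e-3,
                       chimp_divergence = 0.012,
                       orang_divergence = 0.031,
                       strand_symmetric = TRUE,
                       genes = NULL, cpg_islands = NULL,
                       seed = 1L) {
  stopifnot(genome_length >= 100, baseline_rate > 0, baseline_rate < 1/3,
            chimp_divergence >= 0, chimp_divergence <= 1,
            orang_divergence >= 0, orang_divergence <= 1)
  stopifnot(setequal(names(base_composition), c("A", "C", "G", "T")))
  base_composition <- base_composition[c("A", "C", "G", "T")]
  if (abs(sum(base_composition) - 1) > 1e-8)
    stop("base composition must sum to 1")
  if (any(base_composition < 0)) stop("negative base composition")
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) || any(names(planted_effects) == ""))
      stop("planted_effects must be named by context identifier")
    if (any(planted_effects <= 0)) stop("multipliers must be positive")
    lapply(names(planted_effects), parse_context)  # validate identifiers
    if (anyDuplicated(names(planted_effects)))
      stop("duplicate planted context")
  }
  structure(list(genome_length = as.integer(genome_length),
                 base_composition = base_composition,
                 planted_effects = planted_effects,
                 baseline_rate = baseline_rate,
                 chimp_divergence = chimp_divergence,
                 orang_divergence = orang_divergence,
                 strand_symmetric = strand_symmetric,
                 genes = genes, cpg_islands = cpg_islands,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Mirror planted effects onto reverse-complement contexts; error on a
# conflicting multiplier for a context and its mirror.
expand_effects <- function(planted_effects, strand_symmetric) {
  if (length(planted_effects) == 0L)
    return(data.table::data.table(id = character(), word = character(),
                                  pos = integer(), src = character(),
                                  dst = character(), multiplier = numeric()))
  eff <- planted_effects
  if (strand_symmetric) {
    for (id in names(planted_effects)) {
      cid <- format(context_complement(id))
      f <- planted_effects[[id]]
      if (cid %in% names(eff)) {
        if (abs(eff[[cid]] - f) > 1e-12)
          stop("strand-symmetric conflict: {", id, "} and its complement {",
               cid, "} have different multipliers")
      } else {
        eff[cid] <- f
      }
    }
  }
  ctxs <- lapply(names(eff), parse_context)
  data.table::data.table(
    id = names(eff),
    word = vapply(ctxs, function(c) c$word, ""),
    pos = vapply(ctxs, function(c) c$pos, 0L),
    src = vapply(ctxs, function(c) c$src, ""),
    dst = vapply(ctxs, function(c) c$dst, ""),
    multiplier = as.numeric(eff))
}

# i.i.d. substitution noise on the 20 flank positions of 21-nt windows;
# the center (position 11) is never touched.
mutate_flank_windows <- function(wins, rate) {
  n <- length(wins)
  if (n == 0L || rate <= 0) return(wins)
  bases <- c("A", "C", "G", "T")
  for (j in setdiff(1:21, 11L)) {
    hit <- stats::runif(n) < rate
    if (!any(hit)) next
    w <- wins[hit]
    cur <- substr(w, j, j)
    shift <- sample.int(3L, length(w), replace = TRUE)
    substr(w, j, j) <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
    wins[hit] <- w
  }
  wins
}

#' Forward simulation of context-biased mutagenesis
#'
#' Generates (a) an ancestral genome drawn i.i.d. from the configured base
#' composition; (b) biallelic SNPs from independent per-site point
#' mutations whose rate depends on the ancestral word around the site
#' according to the planted multipliers (when several planted contexts
#' cover one site/target the largest multiplier wins; the per-type average
#' rate is held at `baseline_rate`, see [sim_config()]); (c) chimp and
#' orangutan window sequences equal to the ancestral window with
#' independent i.i.d. flank substitutions at the configured divergences
#' (the center base stays ancestral, so outgroup noise enters only through
#' the flank criteria); and (d) a truth record of the planted multipliers
#' and every SNP's true ancestral allele. Only the human lineage mutates
#' into SNPs; at most one SNP is emitted per site. The emitted SNP table
#' has the human reference carrying the derived allele at the window
#' center and alleles listed alphabetically, so nothing in the record
#' leaks the truth. Deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_result`: `genome` (character string),
#'   `snps` (SNP `data.table` in the input format of [read_snp_table()]),
#'   `truth` (list with `effects` = `data.table(context_id, multiplier)`
#'   after strand mirroring and `snps` = `data.table(chrom, pos,
#'   ancestral)`), and `config`.
#' @export
simulate_snp_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$genome_length
  b <- config$baseline_rate
  bases <- c("A", "C", "G", "T")

  gi <- sample.int(4L, N, replace = TRUE, prob = config$base_composition)
  genome <- intToUtf8(c(65L, 67L, 71L, 84L)[gi])

  eff <- expand_effects(config$planted_effects, config$strand_symmetric)
  lo <- 11L; hi <- N - 10L
  gdna <- Biostrings::DNAString(genome)

  # per planted context: genomic sites (mutated-base positions) it covers
  eff_sites <- vector("list", nrow(eff))
  if (nrow(eff) > 0L) {
    for (k in seq_len(nrow(eff))) {
      m <- Biostrings::matchPattern(eff$word[k], gdna)
      s <- BiocGenerics::start(m) + eff$pos[k] - 1L
      eff_sites[[k]] <- s[s >= lo & s <= hi]
    }
  }

  mut_site <- integer(0); mut_src <- character(0); mut_dst <- character(0)
  for (si in 1:4) {
    src <- bases[si]
    src_sites <- which(gi == si)
    src_sites <- src_sites[src_sites >= lo & src_sites <= hi]
    n_src <- length(src_sites)
    if (n_src == 0L) next
    for (dst in bases[-si]) {
      krows <- which(eff$src == src & eff$dst == dst)
      rate <- rep(b, n_src)
      if (length(krows) > 0L) {
        aff <- data.table::rbindlist(lapply(krows, function(k)
          data.table::data.table(site = eff_sites[[k]],
                                 f = eff$multiplier[k])))
        aff <- aff[, list(f = max(f)), by = "site"]
        S <- sum(aff$f); n_aff <- nrow(aff)
        if (n_aff >= n_src)
          stop("planted contexts for ", src, ">", dst,
               " cover every source site; bias unattainable")
        r0 <- b * (n_src - S) / (n_src - n_aff)
        if (r0 < 0)
          stop("requested bias unattainable for ", src, ">", dst,
               ": sum of multiplier mass ", signif(S / n_src, 4),
               " >= 1; lower the multipliers or the context frequency")
        rate <- rep(r0, n_src)
        rate[match(aff$site, src_sites)] <- b * aff$f
      }
      hits <- src_sites[stats::runif(n_src) < rate]
      if (length(hits)) {
        mut_site <- c(mut_site, hits)
        mut_src <- c(mut_src, rep(src, length(hits)))
        mut_dst <- c(mut_dst, rep(dst, length(hits)))
      }
    }
  }

  # at most one SNP per site: keep the first realized substitution
  ord <- order(mut_site)
  mut_site <- mut_site[ord]; mut_src <- mut_src[ord]; mut_dst <- mut_dst[ord]
  keep <- !duplicated(mut_site)
  mut_site <- mut_site[keep]; mut_src <- mut_src[keep]; mut_dst <- mut_dst[keep]

  anc_win <- substring(genome, mut_site - 10L, mut_site + 10L)
  human_window <- anc_win
  substr(human_window, 11L, 11L) <- mut_dst
  snps <- data.table::data.table(
    chrom = "chrSim",
    pos = mut_site - 1L,                     # external coordinates 0-based
    allele1 = pmin(mut_src, mut_dst),
    allele2 = pmax(mut_src, mut_dst),
    human_window = human_window,
    chimp_window = mutate_flank_windows(anc_win, config$chimp_divergence),
    orang_window = mutate_flank_windows(anc_win, config$orang_divergence))

  truth <- list(
    effects = data.table::data.table(context_id = eff$id,
                                     multiplier = eff$multiplier),
    snps = data.table::data.table(chrom = "chrSim", pos = mut_site - 1L,
                                  ancestral = mut_src))
  structure(list(genome = genome, snps = snps, truth = truth,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result: ", nchar(x$genome), " bp genome, ", nrow(x$snps),
      " SNPs, ", nrow(x$truth$effects), " planted effect(s), seed ",
      x$config$seed, ">\n", sep = "")
  invisible(x)
}

#' Write simulated data in the pipeline's input formats
#'
#' Emits `genome.fa` (FASTA), `snps.tsv` (SNP table), `truth_effects.tsv`
#' (`context_id`, `multiplier`), `truth_snps.tsv` (`chrom`, `pos`,
#' `ancestral`) and, via [emit_region_beds()], `genes.bed` and
#' `cpg_islands.bed`.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(genome = file.path(dir, "genome.fa"),
         snps = file.path(dir, "snps.tsv"),
         truth_effects = file.path(dir, "truth_effects.tsv"),
         truth_snps = file.path(dir, "truth_snps.tsv"))
  g <- Biostrings::DNAStringSet(sim$genome)
  names(g) <- "chrSim"
  Biostrings::writeXStringSet(g, p[["genome"]])
  write_snp_table(sim$snps, p[["snps"]])
  data.table::fwrite(sim$truth$effects, p[["truth_effects"]], sep = "\t")
  data.table::fwrite(sim$truth$snps, p[["truth_snps"]], sep = "\t")
  beds <- emit_region_beds(sim$config, dir)
  invisible(c(p, beds))
}

#' Write exclusion-region BED files for a simulation
#'
#' @param config A `sim_config`; its `genes` and `cpg_islands` interval
#'   tables (default `NULL`) become BED3 files, empty files when unset.
#' @param dir Output directory.
#' @return Named character vector `c(genes = ..., cpg_islands = ...)`.
#' @export
emit_region_beds <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(genes = file.path(dir, "genes.bed"),
         cpg_islands = file.path(dir, "cpg_islands.bed"))
  write_bed3(config$genes, p[["genes"]])
  write_bed3(config$cpg_islands, p[["cpg_islands"]])
  p
}
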