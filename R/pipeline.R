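#' Pipeline stages
#'
#' Each stage reads and writes only its declared files inside `out_dir`, so
#' runs are reproducible and restartable; [run_all()] chains them and
#' writes a manifest (`manifest.json`) with the package version, seed,
#' configuration, and per-stage record counts, including the conservation
#' line input = accepted + rejected. Logging goes to `stderr` via
#' `message()`; results are only ever written to files.
#'
#' @name pipeline
#' @param out_dir Run directory.
NULL

stage_log <- function(stage, ...) message("[", stage, "] ", ...)

require_file <- function(path, stage) {
  if (!file.exists(path))
    stop("[", stage, "] missing input file: ", path, call. = FALSE)
  path
}

#' @rdname pipeline
#' @param config A `sim_config`.
#' @return `run_simulate()`: the written file paths (invisibly a list with
#'   the `sim_result`).
#' @export
run_simulate <- function(config, out_dir) {
  sim <- simulate_snp_dataset(config)
  paths <- write_simulation(sim, out_dir)
  stage_log("simulate", nchar(sim$genome), " bp genome, ", nrow(sim$snps),
            " SNPs -> ", out_dir)
  invisible(list(sim = sim, paths = paths))
}

#' @rdname pipeline
#' @param snp_file SNP table path (default `snps.tsv` in `out_dir`).
#' @param genes_bed,cpg_bed BED3 paths of exclusion intervals (`NULL` = no
#'   exclusion of that kind).
#' @param flank_bp Gene flank exclusion width.
#' @export
run_filter <- function(out_dir, snp_file = file.path(out_dir, "snps.tsv"),
                       genes_bed = NULL, cpg_bed = NULL, flank_bp = 1000L) {
  require_file(snp_file, "filter")
  snps <- read_snp_table(snp_file)
  res <- filter_snps(snps,
                     genes = if (is.null(genes_bed)) NULL else read_bed3(genes_bed),
                     cpg_islands = if (is.null(cpg_bed)) NULL else read_bed3(cpg_bed),
                     flank_bp = flank_bp)
  write_mutations(res$mutations, file.path(out_dir, "mutations.tsv"))
  data.table::fwrite(res$summary, file.path(out_dir, "filter_summary.tsv"),
                     sep = "\t")
  stage_log("filter", nrow(snps), " SNPs in, ", nrow(res$mutations),
            " accepted, ", nrow(snps) - nrow(res$mutations), " rejected")
  invisible(res)
}

write_word_freqs <- function(freqs, path) {
  parts <- lapply(seq_len(freqs$max_len), function(L)
    data.table::data.table(word = names(freqs$counts[[L]]), len = L,
                           count = freqs$counts[[L]],
                           frequency = freqs$freq[[L]]))
  dt <- data.table::rbindlist(parts)
  dt[, "source" := freqs$source]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

read_word_freqs <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  max_len <- max(dt$len)
  counts <- lapply(seq_len(max_len), function(L) {
    d <- dt[dt$len == L, ]
    stats::setNames(d$count, d$word)
  })
  new_word_freqs(counts, dt$source[1L], max_len)
}

write_context_counts <- function(counts, path) {
  data.table::fwrite(counts$counts, path, sep = "\t")
  jsonlite::write_json(list(total_records = counts$total_records,
                            max_len = counts$max_len),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

read_context_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  data.table::setkeyv(dt, "id")
  structure(list(counts = dt, total_records = meta$total_records,
                 max_len = meta$max_len),
            class = "context_counts")
}

#' @rdname pipeline
#' @param mutations_file Accepted-mutations path (default `mutations.tsv`
#'   in `out_dir`).
#' @param max_len Maximum context word length.
#' @param freq_source `"flanks"` (window flank intervals) or `"genome"`
#'   (whole-genome control; requires `genome_fasta`).
#' @param genome_fasta FASTA path for the whole-genome background.
#' @export
run_count <- function(out_dir,
                      mutations_file = file.path(out_dir, "mutations.tsv"),
                      max_len = 4L, freq_source = c("flanks", "genome"),
                      genome_fasta = file.path(out_dir, "genome.fa")) {
  freq_source <- match.arg(freq_source)
  require_file(mutations_file, "count")
  records <- read_mutations(mutations_file)
  counts <- count_mutation_contexts(records, max_len = max_len)
  freqs <- if (freq_source == "flanks") {
    flank_word_freqs(records, max_len = max_len)
  } else {
    genome_word_freqs(read_genome_fasta(require_file(genome_fasta, "count")),
                      max_len = max_len)
  }
  write_context_counts(counts, file.path(out_dir, "context_counts.tsv"))
  write_word_freqs(freqs, file.path(out_dir, "word_freqs.tsv"))
  stage_log("count", nrow(counts$counts), " contexts tallied from ",
            counts$total_records, " records (", freqs$source, " background)")
  invisible(list(counts = counts, freqs = freqs))
}

#' @rdname pipeline
#' @param counts_file,freqs_file Paths written by [run_count()].
#' @param min_len Minimum context word length for the result table.
#' @param alpha,mode See [apply_bonferroni()].
#' @export
run_contrast <- function(out_dir,
                         counts_file = file.path(out_dir, "context_counts.tsv"),
                         freqs_file = file.path(out_dir, "word_freqs.tsv"),
                         min_len = 2L, max_len = 4L, alpha = 1e-15,
                         mode = "paper") {
  require_file(counts_file, "contrast")
  require_file(freqs_file, "contrast")
  counts <- read_context_counts(counts_file)
  freqs <- read_word_freqs(freqs_file)
  ct <- contrast_table(counts, freqs, min_len = min_len, max_len = max_len,
                       alpha = alpha, mode = mode)
  data.table::fwrite(ct, file.path(out_dir, "contrast_table.tsv"), sep = "\t")
  diag <- attr(ct, "diagnostics")
  data.table::fwrite(diag, file.path(out_dir, "contrast_diagnostics.tsv"),
                     sep = "\t")
  stage_log("contrast", nrow(ct), " contexts ranked, ", nrow(diag),
            " undefined (see contrast_diagnostics.tsv), ",
            sum(ct$significant), " significant at ", attr(ct, "threshold"))
  invisible(ct)
}

#' @rdname pipeline
#' @param contrast_file Path written by [run_contrast()].
#' @export
run_report <- function(out_dir,
                       contrast_file = file.path(out_dir, "contrast_table.tsv")) {
  require_file(contrast_file, "report")
  ct <- data.table::fread(contrast_file, sep = "\t", header = TRUE)
  sc <- scatter_table(ct)
  data.table::fwrite(sc, file.path(out_dir, "scatter.tsv"), sep = "\t")
  fit <- tryCatch(fit_minimal_contrast_normal(ct), error = function(e) {
    stage_log("report", "normal fit skipped: ", conditionMessage(e))
    NULL
  })
  if (!is.null(fit)) {
    h <- fit$hist_minimal_contrast
    data.table::fwrite(
      data.table::data.table(bin_low = h$breaks[-length(h$breaks)],
                             bin_high = h$breaks[-1L], count = h$counts),
      file.path(out_dir, "minimal_contrast_hist.tsv"), sep = "\t")
    jsonlite::write_json(
      list(mean = fit$mean, sd = fit$sd, n_fit = fit$n_fit,
           chisq = fit$chisq, df = fit$df, pvalue = fit$pvalue),
      file.path(out_dir, "minimal_contrast_fit.json"), auto_unbox = TRUE,
      digits = NA)
  }
  stage_log("report", nrow(sc), " contexts in scatter table")
  invisible(list(scatter = sc, fit = fit))
}

#' @rdname pipeline
#' @param use_region_beds Apply the simulation's emitted BED exclusions
#'   during filtering (default `TRUE`).
#' @return `run_all()`: a list with the contrast table (`contrast`), the
#'   report outputs, the filter summary, and the manifest, invisibly.
#' @export
run_all <- function(config, out_dir, max_len = 4L,
                    freq_source = c("flanks", "genome"), min_len = 2L,
                    alpha = 1e-15, mode = "paper", flank_bp = 1000L,
                    use_region_beds = TRUE) {
  freq_source <- match.arg(freq_source)
  sim <- run_simulate(config, out_dir)
  filt <- run_filter(out_dir,
                     genes_bed = if (use_region_beds)
                       file.path(out_dir, "genes.bed") else NULL,
                     cpg_bed = if (use_region_beds)
                       file.path(out_dir, "cpg_islands.bed") else NULL,
                     flank_bp = flank_bp)
  cnt <- run_count(out_dir, max_len = max_len, freq_source = freq_source)
  ct <- run_contrast(out_dir, min_len = min_len, max_len = max_len,
                     alpha = alpha, mode = mode)
  rep <- run_report(out_dir)

  n_in <- nrow(sim$sim$snps)
  n_acc <- nrow(filt$mutations)
  manifest <- list(
    package = "mutcontext",
    version = as.character(utils::packageVersion("mutcontext")),
    seed = config$seed,
    config = list(genome_length = config$genome_length,
                  base_composition = as.list(config$base_composition),
                  planted_effects = as.list(config$planted_effects),
                  baseline_rate = config$baseline_rate,
                  chimp_divergence = config$chimp_divergence,
                  orang_divergence = config$orang_divergence,
                  strand_symmetric = config$strand_symmetric),
    max_len = max_len, freq_source = freq_source, alpha = alpha, mode = mode,
    counts = list(snps_in = n_in, accepted = n_acc, rejected = n_in - n_acc,
                  contexts_ranked = nrow(ct),
                  contexts_undefined = nrow(attr(ct, "diagnostics")),
                  significant = sum(ct$significant)),
    conservation_ok = (n_in == sum(filt$summary$count)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(contrast = ct, report = rep, filter_summary = filt$summary,
                 manifest = manifest))
}
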