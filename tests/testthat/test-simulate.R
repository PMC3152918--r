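test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(genome_length = 2e5, seed = 61,
                    planted_effects = c("C>T|1,CG" = 3))
  a <- simulate_snp_dataset(cfg)
  b <- simulate_snp_dataset(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$snps, b$snps)
  expect_identical(a$truth, b$truth)
  c <- simulate_snp_dataset(sim_config(genome_length = 2e5, seed = 62,
                                       planted_effects = c("C>T|1,CG" = 3)))
  expect_false(identical(a$snps, c$snps))
})

test_that("configuration is validated", {
  expect_error(sim_config(base_composition = c(A = 1, C = 0, G = 0, T = 0.5)),
               "sum to 1")
  expect_error(sim_config(planted_effects = c("C>X|1,CG" = 2)), "malformed")
  expect_error(sim_config(planted_effects = stats::setNames(2, "")), "named")
  expect_error(sim_config(planted_effects = c("C>T|1,CG" = -1)), "positive")
  # conflicting multiplier for a context and its strand mirror
  expect_error(simulate_snp_dataset(
    sim_config(genome_length = 1e5, seed = 1,
               planted_effects = c("C>T|1,CG" = 3, "G>A|2,CG" = 4))),
    "conflict")
  # identical multiplier on both strands is fine
  expect_s3_class(simulate_snp_dataset(
    sim_config(genome_length = 1e5, seed = 1,
               planted_effects = c("C>T|1,CG" = 3, "G>A|2,CG" = 3))),
    "sim_result")
})

test_that("unattainable fold-excesses are rejected", {
  # {C>T|1,CG} covers ~18% of C sites: a 6-fold bias would need a negative
  # out-of-context rate
  expect_error(simulate_snp_dataset(
    sim_config(genome_length = 2e5, seed = 1,
               planted_effects = c("C>T|1,CG" = 6))),
    "unattainable")
})

test_that("strand mirroring plants the complementary context", {
  cfg <- sim_config(genome_length = 2e5, seed = 67,
                    planted_effects = c("T>C|2,ATTG" = 3.5))
  sim <- simulate_snp_dataset(cfg)
  expect_setequal(sim$truth$effects$context_id,
                  c("T>C|2,ATTG", "A>G|3,CAAT"))
  expect_equal(sim$truth$effects$multiplier, c(3.5, 3.5))
  asym <- simulate_snp_dataset(
    sim_config(genome_length = 2e5, seed = 67, strand_symmetric = FALSE,
               planted_effects = c("T>C|2,ATTG" = 3.5)))
  expect_identical(asym$truth$effects$context_id, "T>C|2,ATTG")
})

test_that("planted effects change realized mutation fractions as configured", {
  f <- 3
  cfg <- sim_config(genome_length = 2e6, seed = 71,
                    planted_effects = c("C>T|1,CG" = f))
  sim <- simulate_snp_dataset(cfg)
  g <- Biostrings::DNAString(sim$genome)
  n_cg <- length(Biostrings::matchPattern("CG", g))
  n_c <- Biostrings::letterFrequency(g, "C")[[1]]
  truth <- sim$truth$snps
  is_ct <- truth$ancestral == "C" &
    sim$snps$allele1 == "C" & sim$snps$allele2 == "T"
  site1 <- truth$pos + 1L
  in_cg <- substring(sim$genome, site1, site1 + 1L) == "CG"
  k <- sum(is_ct & in_cg)
  # expected CG-site C>T count: f * baseline * n_CG (renormalized model)
  lambda <- f * cfg$baseline_rate * n_cg
  expect_lt(abs(k - lambda) / sqrt(lambda), 4)
  # total C>T count is held at baseline * n_C
  ktot <- sum(is_ct)
  lam_tot <- cfg$baseline_rate * n_c
  expect_lt(abs(ktot - lam_tot) / sqrt(lam_tot), 4)
})

test_that("SNP records are well-formed and truth covers every SNP", {
  cfg <- sim_config(genome_length = 3e5, seed = 73,
                    planted_effects = c("A>C|1,ACAA" = 3.4))
  sim <- simulate_snp_dataset(cfg)
  s <- sim$snps
  expect_true(all(nchar(s$human_window) == 21L))
  expect_true(all(s$allele1 < s$allele2))       # alphabetical, truth-blind
  expect_identical(nrow(sim$truth$snps), nrow(s))
  expect_true(all(sim$truth$snps$pos == s$pos))
  expect_false(any(duplicated(s$pos)))          # at most one SNP per site
  # windows match the genome flanks; center carries the derived allele
  site1 <- s$pos + 1L
  expect_identical(substring(sim$genome, site1 - 10L, site1 - 1L),
                   substr(s$human_window, 1, 10))
  anc <- sim$truth$snps$ancestral
  der <- ifelse(s$allele1 == anc, s$allele2, s$allele1)
  expect_identical(substr(s$human_window, 11, 11), der)
  expect_identical(substring(sim$genome, site1, site1), anc)
  # outgroup centers stay ancestral
  expect_identical(substr(s$chimp_window, 11, 11), anc)
  expect_identical(substr(s$orang_window, 11, 11), anc)
})

test_that("written simulation files round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(genome_length = 1e5, seed = 79,
                    planted_effects = c("C>T|1,CG" = 2))
  sim <- simulate_snp_dataset(cfg)
  paths <- write_simulation(sim, dir)
  snps <- read_snp_table(file.path(dir, "snps.tsv"))
  expect_identical(snps$human_window, sim$snps$human_window)
  expect_identical(snps$pos, sim$snps$pos)
  g <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(as.character(g[[1]]), sim$genome)
  expect_identical(names(g), "chrSim")
  # default region BEDs are empty
  expect_identical(length(read_bed3(file.path(dir, "genes.bed"))), 0L)
})

test_that("emitted region BEDs drive the expected exclusion fractions", {
  # one gene covering the first half of the genome (no flank effect checked
  # here: flanks extend the exclusion by 1 kb each side)
  half_gene <- data.frame(chrom = "chrSim", start = 0L, end = 150000L)
  cfg <- sim_config(genome_length = 3e5, seed = 83, genes = half_gene)
  sim <- simulate_snp_dataset(cfg)
  dir <- withr::local_tempdir()
  emit_region_beds(cfg, dir)
  genes <- read_bed3(file.path(dir, "genes.bed"))
  excl <- exclude_by_region(sim$snps, genes, NULL, flank_bp = 1000L)
  frac <- mean(excl)
  # half the genome plus a 1 kb flank
  expect_lt(abs(frac - (151000 / 3e5)), 0.02)
  # a gene covering everything excludes everything
  all_gene <- data.frame(chrom = "chrSim", start = 0L, end = 3e5)
  cfg2 <- sim_config(genome_length = 3e5, seed = 83, genes = all_gene)
  excl2 <- exclude_by_region(sim$snps, read_bed3(write_bed3(
    all_gene, file.path(dir, "all.bed"))), NULL)
  expect_true(all(excl2))
  res <- filter_snps(sim$snps, genes = read_bed3(file.path(dir, "all.bed")))
  expect_identical(nrow(res$mutations), 0L)
})
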