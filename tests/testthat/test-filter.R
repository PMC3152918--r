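test_that("region exclusion honours gene flanks and CpG islands", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6001, 7000))
  cpg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9001, 9200))
  snps <- make_snp(pos = c(5000L, 4999L, 6500L, 9100L, 20000L))
  snps$chrom <- "chr1"
  out <- exclude_by_region(snps, genes, cpg, flank_bp = 1000L)
  expect_identical(out, c(TRUE,   # exactly 1000 bp from gene start
                          FALSE,  # 1001 bp away
                          TRUE,   # inside the gene
                          TRUE,   # inside the CpG island
                          FALSE))
  # unknown chromosome: not excluded
  far <- make_snp(pos = 6500L); far$chrom <- "chrUn"
  expect_false(exclude_by_region(far, genes, cpg))
  # no intervals at all
  expect_false(exclude_by_region(make_snp(), NULL, NULL))
})

test_that("the seven inclusion rules fire individually and jointly", {
  clean <- make_snp()
  expect_true(check_criteria(clean)$accepted)
  expect_identical(check_criteria(clean)$reasons, "")

  # (1) not biallelic
  expect_match(check_criteria(make_snp(allele1 = "C", allele2 = "C"))$reasons,
               "NOT_BIALLELIC")
  expect_match(check_criteria(make_snp(allele1 = "N"))$reasons, "NOT_BIALLELIC")

  # (2) outgroups disagree with each other -> no consistent ancestral allele
  s <- make_snp(orang_window = test_window("T"))
  expect_match(check_criteria(s)$reasons, "NO_OUTGROUP_MATCH")
  # outgroups agree on a base that is not a human allele
  s <- make_snp(chimp_window = test_window("G"), orang_window = test_window("G"))
  expect_match(check_criteria(s)$reasons, "NO_OUTGROUP_MATCH")

  # (3) missing outgroup window
  expect_match(check_criteria(make_snp(chimp_window = "."))$reasons, "UNALIGNED")

  # (4) N or gap in a flank
  s <- make_snp(human_window = set_base(test_window("T"), 3L, "N"))
  expect_match(check_criteria(s)$reasons, "GAP_OR_N")
  s <- make_snp(orang_window = set_base(test_window("C"), 19L, "-"))
  expect_match(check_criteria(s)$reasons, "GAP_OR_N")
  # N at the human window center is allowed: the center is never used
  expect_true(check_criteria(make_snp(human_window = test_window("N")))$accepted)

  # (5) two chimp flank mismatches reject, one is tolerated
  w <- test_window("C"); w1 <- set_base(w, 1L, "T"); w2 <- set_base(w1, 21L, "A")
  expect_true(check_criteria(make_snp(chimp_window = w1))$accepted)
  expect_match(check_criteria(make_snp(chimp_window = w2))$reasons,
               "CHIMP_MISMATCH_LIMIT")

  # (6) seven orangutan flank mismatches reject, six are tolerated
  flip <- function(w, positions) {
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    for (j in positions) w <- set_base(w, j, rot[[substr(w, j, j)]])
    w
  }
  w6 <- flip(test_window("C"), c(1L, 2L, 3L, 18L, 19L, 20L))
  expect_true(check_criteria(make_snp(orang_window = w6))$accepted)
  w7 <- flip(test_window("C"), c(1L, 2L, 3L, 4L, 18L, 19L, 20L))
  expect_match(check_criteria(make_snp(orang_window = w7))$reasons,
               "ORANG_MISMATCH_LIMIT")

  # (7) a mismatch within 3 bp of the site rejects even though (5) tolerates it
  w <- set_base(test_window("C"), 12L, ifelse(substr(test_window("C"), 12, 12)
                                              == "G", "C", "G"))
  r <- check_criteria(make_snp(chimp_window = w))$reasons
  expect_match(r, "NEAR_FLANK_MISMATCH")
  expect_no_match(r, "CHIMP_MISMATCH_LIMIT")

  # all failed codes are reported together
  s <- make_snp(allele1 = "C", allele2 = "C", chimp_window = ".")
  r <- check_criteria(s)$reasons
  expect_match(r, "NOT_BIALLELIC")
  expect_match(r, "UNALIGNED")

  # malformed window length is rejected with a log line
  expect_message(
    r <- check_criteria(make_snp(human_window = "ACGT")),
    "malformed")
  expect_false(r$accepted)
})

test_that("acceptance is monotone in the mismatch limits", {
  cfg <- sim_config(genome_length = 2e5, chimp_divergence = 0.05,
                    orang_divergence = 0.12, seed = 5)
  snps <- simulate_snp_dataset(cfg)$snps
  strict <- check_criteria(snps, chimp_mismatch_limit = 1L,
                           orang_mismatch_limit = 6L)
  loose <- check_criteria(snps, chimp_mismatch_limit = 3L,
                          orang_mismatch_limit = 10L)
  expect_true(all(loose$accepted[strict$accepted]))
})

test_that("polarization recovers the ancestral allele and window", {
  # outgroups carry C: C is ancestral, T derived
  m <- polarize(make_snp())
  expect_identical(m$ancestral, "C")
  expect_identical(m$derived, "T")
  expect_identical(substr(m$window, 11, 11), "C")
  expect_identical(m$window, test_window("C"))
  # alleles {A,G}, outgroups G
  s <- make_snp(allele1 = "A", allele2 = "G", human_window = test_window("A"),
                chimp_window = test_window("G"), orang_window = test_window("G"))
  m <- polarize(s)
  expect_identical(m$ancestral, "G")
  expect_identical(m$derived, "A")
  # alleles {A,C}, outgroups C: human center A is overwritten with C
  s <- make_snp(allele1 = "A", allele2 = "C", human_window = test_window("A"))
  m <- polarize(s)
  expect_identical(substr(m$window, 11, 11), "C")
})

test_that("noise-free simulation is fully accepted and exactly polarized", {
  cfg <- sim_config(genome_length = 3e5, chimp_divergence = 0,
                    orang_divergence = 0, seed = 3,
                    planted_effects = c("C>T|1,CG" = 3))
  sim <- simulate_snp_dataset(cfg)
  res <- filter_snps(sim$snps)
  expect_identical(nrow(res$mutations), nrow(sim$snps))
  expect_identical(res$mutations$ancestral, sim$truth$snps$ancestral)
  expect_identical(res$mutations$pos, sim$truth$snps$pos)
  # conservation: accepted + per-reason rejections = input
  expect_identical(sum(res$summary$count), nrow(sim$snps))
})

test_that("filter summary conserves records under outgroup noise", {
  cfg <- sim_config(genome_length = 3e5, seed = 9)
  sim <- simulate_snp_dataset(cfg)
  res <- filter_snps(sim$snps)
  expect_identical(sum(res$summary$count), nrow(sim$snps))
  expect_identical(res$summary$count[res$summary$reason == ""],
                   nrow(res$mutations))
  expect_gt(nrow(res$mutations), 0L)
  # polarization is still error-free on the accepted subset: outgroup
  # centers are ancestral by construction
  acc <- sim$truth$snps[sim$snps$pos %in% res$mutations$pos, ]
  expect_identical(res$mutations$ancestral, acc$ancestral)
})
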