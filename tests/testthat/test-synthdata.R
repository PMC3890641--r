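# Synthetic data generator: compositional fidelity, truth-set
# consistency, determinism, and the shredding/read models.

test_that("simulated genomes hit the target composition and are valid", {
  spec <- small_spec(n_genes = 50L, len = 55500L, mean_gene_length = 900L)
  expect_equal(spec$genic_gc, 0.2634)
  ref <- simulate_reference(spec, seed = 1L)
  st <- genome_stats(ref$seq, ref$models)
  expect_lt(abs(st$genic_gc_pct / 100 - 0.2634), 0.02)
  expect_lt(abs(st$intergenic_gc_pct / 100 - 0.1572), 0.03)
  expect_valid_cds(ref$seq, ref$models)
  # determinism: same spec, same seed -> byte-identical output
  ref2 <- simulate_reference(spec, seed = 1L)
  expect_identical(ref2$seq, ref$seq)
  expect_identical(ref2$models, ref$models)
  expect_false(identical(simulate_reference(spec, seed = 2L)$seq, ref$seq))
})

test_that("compositional fidelity holds across seeds", {
  spec <- small_spec(len = 8000L, n_genes = 7L)
  for (s in 1:10) {
    ref <- simulate_reference(spec, seed = s)
    expect_lt(abs(genome_stats(ref$seq, ref$models)$genic_gc_pct / 100 - 0.2634),
              0.02)
  }
})

test_that("polyA tract planting follows the configured rate", {
  ref0 <- simulate_reference(small_spec(polyA_tract_rate = 0), seed = 3L)
  expect_identical(nrow(ref0$tracts), 0L)
  ref2 <- simulate_reference(small_spec(polyA_tract_rate = 2), seed = 3L)
  expect_equal(nrow(ref2$tracts), round(2 * 20000 / 1000))
  # planted tracts really are homopolymers in the sequence
  for (i in seq_len(nrow(ref2$tracts))) {
    t <- ref2$tracts[i, ]
    expect_identical(substr(ref2$seq, t$start, t$end),
                     strrep(t$base, t$end - t$start + 1L))
  }
})

test_that("infeasible specs are rejected", {
  expect_error(genome_spec(chromosome_length = 1000L, n_genes = 50L,
                           mean_gene_length = 900L,
                           mean_intergenic_length = 100L),
               "infeasible")
  expect_error(genome_spec(genic_gc = 0), "GC fractions")
})

test_that("mutate_strain plants the requested mix and truth is consistent", {
  ref <- small_ref()
  # identity case
  st0 <- mutate_strain(ref, n_snps = 0L, n_indels = 0L, seed = 1L)
  expect_identical(st0$seq, ref$seq)

  st <- mutate_strain(ref, n_snps = 50L, syn_fraction = 0.5, n_indels = 5L,
                      seed = 7L)
  expect_identical(sum(st$truth$snps$synonymous), 25L)
  expect_identical(sum(!st$truth$snps$synonymous), 25L)
  # independent translate-both-codons oracle for every planted SNP
  for (i in seq_len(nrow(st$truth$snps))) {
    s <- st$truth$snps[i, ]
    expect_identical(oracle_snp_effect(ref$seq, ref$models, s$position,
                                       s$alt_base),
                     if (s$synonymous) "synonymous" else "nonsynonymous")
  }
  # indels concentrate in polyA tracts
  expect_gte(sum(st$truth$indels$in_polyA), 4L)
  # positions strictly increasing, no overlaps
  expect_true(all(diff(st$truth$snps$position) > 0))
  # truth-set consistency: re-applying events reproduces the strain
  expect_identical(apply_variants(ref$seq, st$truth), st$seq)
})

test_that("mutate_strain errors when the codon supply is exhausted", {
  # sparse genome: ~1000 codons but room for 1000 requested synonymous SNPs
  sparse <- genome_spec(chromosome_length = 23000L, n_genes = 20L,
                        mean_gene_length = 150L,
                        mean_intergenic_length = 1000L,
                        plasmid_specs = NULL)
  tiny <- simulate_reference(sparse, seed = 5L)
  expect_error(mutate_strain(tiny, n_snps = 1000L, syn_fraction = 1,
                             n_indels = 0L, seed = 1L),
               "not enough eligible codon positions")
})

test_that("shred_contigs is reversible against its truth", {
  st <- small_strain()
  # zero gaps: one contig equal to the genome
  c0 <- shred_contigs(st, n_gaps = 0L, seed = 1L)
  expect_identical(unname(c0$contigs[[1L]]), st$seq)
  expect_identical(length(c0$contigs), 1L)

  ctg <- shred_contigs(st, n_gaps = 8L, seed = 2L)
  expect_identical(nrow(ctg$gap_truth), 8L)
  # interleaving contigs and true gap sequences reconstructs the genome
  parts <- character(0)
  for (i in seq_along(ctg$contigs)) {
    parts <- c(parts, ctg$contigs[[i]])
    if (i <= nrow(ctg$gap_truth)) parts <- c(parts, ctg$gap_truth$sequence[i])
  }
  expect_identical(paste(parts, collapse = ""), st$seq)
  # gaps biased toward homopolymer tracts (binomial(8, 0.8) rarely dips
  # below half)
  expect_gte(sum(ctg$gap_truth$in_polyA), 4L)
})

test_that("homopolymer error injection matches the requested rate", {
  st <- small_strain()
  rate <- 0.5
  ctg <- shred_contigs(st, n_gaps = 0L, homopolymer_error_rate = rate,
                       seed = 9L)
  n_runs <- nrow(homopolymer_runs(st$seq, min_len = 6L))
  n_err <- nrow(ctg$hp_errors)
  # binomial 99% bounds
  bounds <- qbinom(c(0.005, 0.995), n_runs, rate)
  expect_gte(n_err, bounds[1L])
  expect_lte(n_err, bounds[2L])
})

test_that("simulate_reads: coverage arithmetic, exactness, determinism", {
  st <- small_strain()
  genome10k <- substr(st$seq, 1L, 10000L)
  reads <- simulate_reads(genome10k, coverage = 200, read_length = 36L,
                          error_rate = 0, seed = 4L)
  expect_lt(abs(length(reads$reads) - 200 * 10000 / 36) / (200 * 10000 / 36),
            0.05)
  # error-free reads are exact substrings of the genome or its complement
  doubled <- paste0(genome10k, substr(genome10k, 1L, 35L))
  for (r in reads$reads[1:200])
    expect_true(grepl(r, doubled, fixed = TRUE) ||
                  grepl(revcomp(r), doubled, fixed = TRUE))
  # determinism
  reads2 <- simulate_reads(genome10k, coverage = 200, read_length = 36L,
                           error_rate = 0, seed = 4L)
  expect_identical(reads2$reads, reads$reads)
  expect_error(simulate_reads(genome10k, coverage = 0), "positive")
})
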