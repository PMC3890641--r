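# Collinear alignment, variant calling, effect classification, the runs
# test, and genome statistics.

test_that("alignment of identical genomes is one clean block", {
  ref <- small_ref()
  al <- align_collinear(ref$seq, ref$seq)
  expect_identical(nrow(al$blocks), 1L)
  v <- call_variants(al, ref$seq, ref$seq)
  expect_identical(v$n_snps, 0L)
  expect_identical(v$n_indels, 0L)
})

test_that("planted SNPs and indels are recovered exactly", {
  ref <- small_ref()
  st <- mutate_strain(ref, n_snps = 50L, syn_fraction = 0.4, n_indels = 6L,
                      seed = 33L)
  al <- align_collinear(ref$seq, st$seq)
  v <- call_variants(al, ref$seq, st$seq)
  expect_identical(v$n_snps, 50L)
  expect_identical(v$n_indels, 6L)
  expect_identical(v$snps$a_pos, st$truth$snps$position)
  expect_identical(v$snps$a_base, st$truth$snps$ref_base)
  expect_identical(v$snps$b_base, st$truth$snps$alt_base)
  # SNP positions strictly increasing; no SNP inside an indel event
  expect_true(all(diff(v$snps$a_pos) > 0))

  # a single 5 bp deletion shows as one gapped event of length 5
  del5 <- endofinish:::splice_string(ref$seq, 5001L, 5005L, "")
  v5 <- call_variants(align_collinear(ref$seq, del5), ref$seq, del5)
  expect_identical(v5$n_indels, 1L)
  expect_identical(v5$indels$length, 5L)
  expect_identical(v5$indels$type, "del")
})

test_that("variant counts are symmetric in the pair", {
  ref <- small_ref()
  st <- small_strain()
  vab <- call_variants(align_collinear(ref$seq, st$seq), ref$seq, st$seq)
  vba <- call_variants(align_collinear(st$seq, ref$seq), st$seq, ref$seq)
  expect_identical(vab$n_snps, vba$n_snps)
  expect_identical(vab$n_indels, vba$n_indels)
  m <- pairwise_variant_matrix(list(a = ref$seq, b = st$seq))
  expect_identical(m["a", "b"], vab$n_snps)
  expect_identical(m["b", "a"], vab$n_indels)
})

test_that("coding effects match the planted truth and the translation oracle", {
  ref <- small_ref()
  st <- mutate_strain(ref, n_snps = 50L, syn_fraction = 0.5, n_indels = 0L,
                      seed = 44L)
  cmp <- compare_genomes(ref$seq, st$seq, ref$models)
  expect_identical(unname(cmp$effects$totals[["synonymous"]]), 25L)
  expect_identical(unname(cmp$effects$totals[["nonsynonymous"]]), 25L)
  expect_identical(unname(cmp$effects$totals[["unclassified"]]), 0L)
  expect_identical(cmp$effects$n_intergenic, 0L)
  # whole-gene translate-and-diff oracle: genes whose proteins differ are
  # exactly the genes with nonsynonymous counts
  diff_genes <- vapply(seq_len(nrow(ref$models)), function(i) {
    g <- ref$models[i, ]
    p1 <- translate11(endofinish:::gene_sequence(ref$seq, g))
    p2 <- translate11(endofinish:::gene_sequence(st$seq, g))
    p1 != p2
  }, logical(1L))
  pg <- cmp$effects$per_gene
  expect_identical(pg$gene_id[pg$n_nonsynonymous > 0L],
                   ref$models$gene_id[diff_genes])
})

test_that("codon-level classification handles canonical cases", {
  # GCT -> GCC is Ala -> Ala; ATG -> ATA (internal) is Met -> Ile
  m <- data.frame(gene_id = "g", start = 1L, end = 9L, strand = "+",
                  type = "CDS", product = "", segment = 1L)
  a <- "ATGGCTTAA"
  b1 <- "ATGGCCTAA"
  cmp1 <- compare_genomes(a, b1, m)
  expect_identical(unname(cmp1$effects$totals[["synonymous"]]), 1L)
  m2 <- data.frame(gene_id = "g", start = 1L, end = 12L, strand = "+",
                   type = "CDS", product = "", segment = 1L)
  a2 <- "ATGATGGCTTAA"
  b2 <- "ATGATAGCTTAA"
  cmp2 <- compare_genomes(a2, b2, m2)
  expect_identical(unname(cmp2$effects$totals[["nonsynonymous"]]), 1L)
  # start-codon swap ATG -> GTG at codon 1 is synonymous (both initiate Met)
  b3 <- "GTGATGGCTTAA"
  cmp3 <- compare_genomes(a2, b3, m2)
  expect_identical(unname(cmp3$effects$totals[["synonymous"]]), 1L)
})

test_that("runs test matches brute-force permutation enumeration", {
  enumerate_p <- function(x) {
    n1 <- sum(x); n <- length(x)
    mu <- 2 * n1 * (n - n1) / n + 1
    robs <- length(rle(x)$lengths)
    cols <- combn(n, n1)
    rr <- apply(cols, 2L, function(ii) {
      v <- integer(n); v[ii] <- 1L
      length(rle(v)$lengths)
    })
    mean(abs(rr - mu) >= abs(robs - mu) - 1e-9)
  }
  cases <- list(c(rep(1L, 5L), rep(0L, 5L)),
                rep(c(1L, 0L), 5L),
                c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 1L, 1L, 0L, 1L, 0L),
                c(rep(1L, 3L), rep(0L, 9L)))
  for (x in cases) {
    r <- runs_test(x)
    expect_identical(r$method, "exact_enumeration")
    expect_equal(r$p_value, enumerate_p(x), tolerance = 1e-12)
  }
  # |z| symmetry of the extreme clustered vs alternating sequences
  z1 <- runs_test(c(rep(1L, 5L), rep(0L, 5L)))$z_statistic
  z2 <- runs_test(rep(c(1L, 0L), 5L))$z_statistic
  expect_equal(abs(z1), abs(z2))
  # degenerate input
  expect_error(runs_test(rep(1L, 10L)), "constant")
  # beyond the exact limit the normal approximation is reported
  set.seed(1)
  big <- sample(c(rep(1L, 30L), rep(0L, 70L)))
  rb <- runs_test(big)
  expect_identical(rb$method, "normal_approx")
  expect_identical(rb$p_value, rb$p_normal)
})

test_that("runs test accepts a gene effect table ordered by position", {
  ref <- small_ref()
  st <- mutate_strain(ref, n_snps = 40L, syn_fraction = 0.3, n_indels = 0L,
                      seed = 55L)
  cmp <- compare_genomes(ref$seq, st$seq, ref$models)
  r <- runs_test(cmp$effects)
  pg <- cmp$effects$per_gene
  expect_identical(r$n1, sum(pg$n_nonsynonymous > 0L))
  expect_identical(r$n1 + r$n2, nrow(pg))
  expect_gte(r$p_value, 0)
  expect_lte(r$p_value, 1)
})

test_that("genome statistics partition exactly and handle edge cases", {
  empty <- genome_stats("ATAT", data.frame(gene_id = character(0),
                                           start = integer(0), end = integer(0),
                                           strand = character(0),
                                           type = character(0)))
  expect_identical(empty$genic_size, 0L)
  expect_identical(empty$intergenic_gc_pct, 0)

  full <- genome_stats("GGCC", data.frame(gene_id = "g", start = 1L, end = 4L,
                                          strand = "+", type = "CDS",
                                          product = "", segment = 1L))
  expect_identical(full$genic_gc_pct, 100)

  ref <- small_ref()
  st <- genome_stats(ref$seq, ref$models)
  expect_identical(st$genic_size + st$intergenic_size, st$genome_size)
  expect_lt(abs(st$genic_gc_pct - 26.34), 2)
  expect_identical(st$n_cds, 18L)

  # AT track is invariant under complementation and windows are 100/10
  at1 <- st$at_track
  comp <- chartr("ACGT", "TGCA", ref$seq)
  at2 <- genome_stats(comp, ref$models)$at_track
  expect_equal(at1$at, at2$at)
  expect_identical(diff(at1$pos[1:3]), c(10L, 10L))
})

test_that("overlapping features are unioned, never double-counted", {
  m <- data.frame(gene_id = c("a", "b"), start = c(1L, 50L), end = c(100L, 150L),
                  strand = "+", type = "CDS", product = "", segment = 1L)
  set.seed(2)
  g <- endofinish:::random_dna(200L, 0.5)
  st <- genome_stats(g, m)
  expect_identical(st$genic_size, 150L)
  expect_identical(st$intergenic_size, 50L)
})
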