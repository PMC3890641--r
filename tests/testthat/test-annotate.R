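# Annotation projection, the curation rule cascade, and gene-content
# comparison.

test_that("projection onto an identical genome is the identity", {
  ref <- small_ref()
  al <- align_collinear(ref$seq, ref$seq)
  proj <- project_annotation(ref, al, ref$seq)
  expect_identical(proj$models[, c("gene_id", "start", "end", "strand")],
                   ref$models[, c("gene_id", "start", "end", "strand")])
  expect_identical(nrow(proj$flagged), 0L)
})

test_that("a 3 bp coding deletion shortens only the affected model", {
  ref <- small_ref()
  g <- ref$models[5L, ]
  # in-frame 3 bp deletion in the middle of gene 5
  cut <- g$start + 60L
  mutant <- endofinish:::splice_string(ref$seq, cut, cut + 2L, "")
  al <- align_collinear(ref$seq, mutant)
  proj <- project_annotation(ref, al, mutant)
  len0 <- ref$models$end - ref$models$start + 1L
  len1 <- proj$models$end - proj$models$start + 1L
  expect_identical(len1[5L], len0[5L] - 3L)
  expect_identical(len1[-5L], len0[-5L])
})

test_that("features over unclosed gaps are flagged, not projected", {
  ref <- small_ref()
  g <- ref$models[7L, ]
  nrun <- strrep("N", 40L)
  gapped <- paste0(substr(ref$seq, 1L, g$start + 9L), nrun,
                   substr(ref$seq, g$start + 50L, nchar(ref$seq)))
  al <- align_collinear(ref$seq, gapped)
  proj <- project_annotation(ref, al, gapped)
  expect_true(g$gene_id %in% proj$flagged$gene_id)
  expect_false(g$gene_id %in% proj$models$gene_id)
})

test_that("the curation cascade applies each rule deterministically", {
  # toy gene: GTG start, 18 Ala codons, TAA stop = 60 bp at 101..160
  body <- paste0("GTG", strrep("GCT", 18L), "TAA")
  set.seed(5)
  toyseq <- paste0(endofinish:::random_dna(100L, 0.25), body,
                   endofinish:::random_dna(100L, 0.25))
  refm <- data.frame(gene_id = "g1", start = 101L, end = 160L, strand = "+",
                     type = "CDS", product = "", segment = 1L)

  # no deviation: no events
  cur0 <- curate_models(refm, toyseq, refm)
  expect_identical(nrow(cur0$events), 0L)

  # started 9 bp downstream, in-frame GTG upstream -> start_extension
  short <- refm; short$start <- 110L
  cur1 <- curate_models(short, toyseq, refm)
  expect_true("start_extension" %in% cur1$events$rule)
  expect_identical(cur1$models$start, 101L)

  # >10% length deviation is flagged
  dev <- refm; dev$end <- 160L - 12L
  cur2 <- curate_models(dev, toyseq, refm)
  expect_true("length_deviation" %in% cur2$events$rule)

  # an unrescuable premature stop becomes a pseudogene
  stopped <- endofinish:::splice_string(toyseq, 131L, 133L, "TAA")
  cur3 <- curate_models(refm, stopped, refm)
  expect_identical(cur3$models$type, "pseudogene")
  expect_true("pseudogene_call" %in% cur3$events$rule)
})

test_that("a planted frameshift in a genic polyA tract yields a dual-frame model", {
  spec <- small_spec()
  found <- FALSE
  for (s in c(4L, 8L, 15L)) {
    ref <- simulate_reference(spec, seed = s)
    if (sum(ref$tracts$genic) == 0L) next
    st <- mutate_strain(ref, n_snps = 0L, n_indels = 3L, seed = 9L,
                        coding_indels = TRUE, polyA_indel_prob = 1)
    genic_hit <- any(vapply(seq_len(nrow(ref$models)), function(i)
      any(st$truth$indels$position >= ref$models$start[i] &
            st$truth$indels$position <= ref$models$end[i]), logical(1L)))
    if (!genic_hit) next
    found <- TRUE
    ann <- annotate_genome(ref, st$seq)
    ev <- ann$events[ann$events$rule == "polyA_merge", ]
    expect_gte(nrow(ev), 1L)
    # merged model's conceptual translation is >=95% identical to the
    # reference protein
    for (g in ev$gene_id) {
      rows <- ann$models[ann$models$gene_id == g, ]
      expect_identical(nrow(rows), 2L)
      prot <- translate11(endofinish:::gene_sequence(st$seq, rows))
      refp <- translate11(endofinish:::gene_sequence(
        ref$seq, ref$models[ref$models$gene_id == g, ]))
      idt <- endofinish:::protein_identity(sub("\\*$", "", prot),
                                           sub("\\*$", "", refp))
      expect_gte(idt, 0.95)
    }
    # curation never edits the genome and is idempotent
    cur2 <- curate_models(ann$models, st$seq, ref$models, ref$seq)
    expect_identical(cur2$models, ann$models)
    break
  }
  expect_true(found)
})

test_that("gene content diff finds shared, unique and unrelated sets", {
  ref <- small_ref()
  d <- gene_content_diff(ref$models, ref$models, ref$seq, ref$seq)
  expect_identical(nrow(d$shared), nrow(ref$models))
  expect_identical(length(d$unique_to_a), 0L)
  expect_identical(length(d$unique_to_b), 0L)

  # delete 5 genes from b: exactly those become unique to a
  del <- ref$models$gene_id[c(2L, 5L, 9L, 12L, 17L)]
  mb <- ref$models[!(ref$models$gene_id %in% del), ]
  d2 <- gene_content_diff(ref$models, mb, ref$seq, ref$seq)
  expect_setequal(d2$unique_to_a, del)
  expect_identical(length(d2$unique_to_b), 0L)

  # unrelated random proteins share nothing at the 0.4 identity floor
  refB <- simulate_reference(small_spec(len = 6000L, n_genes = 5L), seed = 99L)
  d3 <- gene_content_diff(ref$models[1:5, ], refB$models, ref$seq, refB$seq)
  expect_identical(nrow(d3$shared), 0L)
})

test_that("zero-mutation strain annotates identically to the reference", {
  ref <- small_ref()
  st0 <- mutate_strain(ref, n_snps = 0L, n_indels = 0L, seed = 1L)
  ann <- annotate_genome(ref, st0$seq)
  expect_identical(ann$models[, c("gene_id", "start", "end", "strand", "type")],
                   ref$models[, c("gene_id", "start", "end", "strand", "type")])
  expect_identical(nrow(ann$events), 0L)
  d <- gene_content_diff(ann$models, ref$models, st0$seq, ref$seq)
  expect_identical(length(d$unique_to_a), 0L)
  expect_identical(length(d$unique_to_b), 0L)
})
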