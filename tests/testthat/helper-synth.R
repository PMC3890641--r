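# Shared fixtures, built once per session.  Small genomes keep the suite
# fast; compositional parameters stay at the full-size defaults.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_spec <- function(len = 20000L, n_genes = 18L, ...) {
  genome_spec(chromosome_length = len, n_genes = n_genes,
              plasmid_specs = NULL, ...)
}

small_ref <- function() fixture("small_ref", function()
  simulate_reference(small_spec(), seed = 101L))

small_strain <- function() fixture("small_strain", function()
  mutate_strain(small_ref(), n_snps = 40L, syn_fraction = 0.5, n_indels = 5L,
                seed = 202L, strain_id = "stA"))

# independent effect oracle: translate every gene in both genomes and diff
# the proteins; a gene has a nonsynonymous difference iff its proteins
# differ, and per-SNP classes are recovered by re-translating each codon
# with base R string ops only (no package classifier involved)
oracle_snp_effect <- function(ref_seq, models, pos, alt) {
  code <- Biostrings::GENETIC_CODE_TABLE
  gcode <- Biostrings::getGeneticCode("11")
  cds <- models[models$type == "CDS" &
                  !(models$gene_id %in% models$gene_id[duplicated(models$gene_id)]), ]
  hit <- cds[cds$start <= pos & cds$end >= pos, ]
  if (nrow(hit) == 0L) return(NA_character_)
  g <- hit[1L, ]
  gene <- substr(ref_seq, g$start, g$end)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (g$strand == "-") {
    gene <- paste(rev(comp[strsplit(gene, "")[[1L]]]), collapse = "")
    off <- g$end - pos
    alt_l <- comp[[alt]]
  } else {
    off <- pos - g$start
    alt_l <- alt
  }
  mutant <- gene
  substr(mutant, off + 1L, off + 1L) <- alt_l
  split_codons <- function(x)
    substring(x, seq(1L, nchar(x) - 2L, 3L), seq(3L, nchar(x), 3L))
  aa1 <- gcode[split_codons(gene)]
  aa2 <- gcode[split_codons(mutant)]
  starts <- c("ATG", "GTG", "TTG", "ATT")
  ci <- off %/% 3L + 1L
  if (ci == 1L && split_codons(gene)[1L] %in% starts &&
      split_codons(mutant)[1L] %in% starts)
    return("synonymous")
  if (identical(unname(aa1[ci]), unname(aa2[ci]))) "synonymous" else "nonsynonymous"
}

expect_valid_cds <- function(seq, models) {
  cds <- models[models$type == "CDS", ]
  single <- setdiff(cds$gene_id, cds$gene_id[duplicated(cds$gene_id)])
  for (g in single) {
    row <- cds[cds$gene_id == g, ]
    gs <- substr(seq, row$start, row$end)
    if (row$strand == "-") gs <- revcomp(gs)
    aa <- translate11(gs)
    expect_identical(substr(aa, 1L, 1L), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE))
  }
}
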