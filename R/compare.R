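# Pairwise comparison of finished collinear genomes: SNP and indel-event
# calling from the block alignment, synonymous/nonsynonymous
# classification of coding SNPs by codon re-translation under table 11,
# the Wald-Wolfowitz runs test of whether nonsynonymous changes are
# randomly distributed over the gene order, and genome composition
# statistics.

#' Call variants from a collinear alignment
#'
#' Mismatch columns inside aligned blocks become SNPs; each maximal gap
#' run between blocks becomes one indel event (events, not bases, are
#' counted).
#'
#' @param alignment a `collinear_alignment` of genomes `a` and `b`.
#' @param a,b the aligned sequences (strings or objects with `$seq`).
#' @return a `variant_set`: list with `snps` (a_pos, b_pos, a_base,
#'   b_base), `indels` (a_pos, length, seq, type: `ins` = present in `b`
#'   only, `del` = present in `a` only), `n_snps`, `n_indels`.
#' @export
call_variants <- function(alignment, a, b) {
  a <- if (is.character(a)) a else a$seq
  b <- if (is.character(b)) b else b$seq
  bl <- alignment$blocks
  snps <- list()
  for (i in seq_len(nrow(bl))) {
    sa <- substr(a, bl$a_start[i], bl$a_end[i])
    sb <- substr(b, bl$b_start[i], bl$b_end[i])
    mm <- mismatch_positions_cpp(sa, sb)
    if (length(mm) > 0L) {
      snps[[length(snps) + 1L]] <- data.frame(
        a_pos = bl$a_start[i] + mm - 1L,
        b_pos = bl$b_start[i] + mm - 1L,
        a_base = substring(sa, mm, mm),
        b_base = substring(sb, mm, mm))
    }
  }
  snps <- if (length(snps) > 0L) do.call(rbind, snps) else
    data.frame(a_pos = integer(0), b_pos = integer(0),
               a_base = character(0), b_base = character(0))

  indels <- list()
  # sentinel rows catch unaligned sequence before the first and after the
  # last block
  blx <- rbind(data.frame(a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L),
               bl,
               data.frame(a_start = alignment$a_len + 1L,
                          a_end = alignment$a_len + 1L,
                          b_start = alignment$b_len + 1L,
                          b_end = alignment$b_len + 1L))
  for (i in seq_len(nrow(blx) - 1L)) {
    da <- blx$a_start[i + 1L] - blx$a_end[i] - 1L
    db <- blx$b_start[i + 1L] - blx$b_end[i] - 1L
    if (da > 0L) indels[[length(indels) + 1L]] <- data.frame(
      a_pos = blx$a_end[i] + 1L, length = da,
      seq = substr(a, blx$a_end[i] + 1L, blx$a_start[i + 1L] - 1L),
      type = "del")
    if (db > 0L) indels[[length(indels) + 1L]] <- data.frame(
      a_pos = blx$a_end[i] + 1L, length = db,
      seq = substr(b, blx$b_end[i] + 1L, blx$b_start[i + 1L] - 1L),
      type = "ins")
  }
  indels <- if (length(indels) > 0L) do.call(rbind, indels) else
    data.frame(a_pos = integer(0), length = integer(0),
               seq = character(0), type = character(0))
  # SNPs never sit inside an indel event by construction (blocks are
  # gap-free), and positions are strictly increasing block by block
  structure(list(snps = snps, indels = indels,
                 n_snps = nrow(snps), n_indels = nrow(indels)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d SNPs, %d indel events\n", x$n_snps, x$n_indels))
  invisible(x)
}

#' Pairwise SNP/indel matrix for several genomes
#'
#' SNP counts in the upper triangle, indel-event counts in the lower
#' triangle, mirroring the conventional presentation of strain-pair
#' difference tables.
#'
#' @param genomes named list of sequences.
#' @param k anchor k-mer size.
#' @return integer matrix with strain names on both dimensions.
#' @export
pairwise_variant_matrix <- function(genomes, k = 17L) {
  n <- length(genomes)
  ids <- names(genomes)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- align_collinear(genomes[[i]], genomes[[j]], k)
      v <- call_variants(al, genomes[[i]], genomes[[j]])
      m[i, j] <- v$n_snps
      m[j, i] <- v$n_indels
    }
  }
  m
}

#' Classify coding SNPs as synonymous or nonsynonymous
#'
#' Each SNP inside a single-frame CDS is classified by substituting the
#' base in its reference codon and translating both codons under table 11;
#' an amino-acid change is nonsynonymous.  SNPs in dual-frame (homopolymer
#' merged) models and in genes overlapping an indel event are tallied as
#' unclassified; SNPs outside every model count as intergenic.  A
#' substitution between initiation codons (ATG/GTG/TTG/ATT) at codon 1 is
#' synonymous: both initiators translate as Met.  A codon carrying two
#' SNPs yields two independent classifications against the reference
#' codon context.
#'
#' @param variants a `variant_set` called with genome `a` as reference.
#' @param models annotation of genome `a`.
#' @return a `gene_effect_table`: list with `per_gene` (gene_id,
#'   order_index, n_synonymous, n_nonsynonymous, n_unclassified),
#'   `totals`, `n_intergenic`.
#' @export
classify_coding_effects <- function(variants, models) {
  models <- check_models(models)
  cds <- models[models$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  gene_order <- unique(cds$gene_id)
  multi <- unique(cds$gene_id[duplicated(cds$gene_id)])

  per_gene <- data.frame(gene_id = gene_order,
                         order_index = seq_along(gene_order),
                         n_synonymous = 0L, n_nonsynonymous = 0L,
                         n_unclassified = 0L, stringsAsFactors = FALSE)
  rownames(per_gene) <- per_gene$gene_id

  # genes overlapping an indel event cannot be classified codon-by-codon
  indel_genes <- character(0)
  if (nrow(variants$indels) > 0L) {
    for (i in seq_len(nrow(cds))) {
      iv <- variants$indels
      if (any(iv$a_pos >= cds$start[i] - 1L & iv$a_pos <= cds$end[i] + 1L))
        indel_genes <- c(indel_genes, cds$gene_id[i])
    }
  }

  n_intergenic <- 0L
  snps <- variants$snps
  for (i in seq_len(nrow(snps))) {
    pos <- snps$a_pos[i]
    hit <- which(cds$start <= pos & cds$end >= pos)
    if (length(hit) == 0L) { n_intergenic <- n_intergenic + 1L; next }
    g <- cds$gene_id[hit[1L]]
    if (g %in% multi || g %in% indel_genes) {
      per_gene[g, "n_unclassified"] <- per_gene[g, "n_unclassified"] + 1L
      next
    }
    eff <- codon_effect(snps$a_base[i], snps$b_base[i], pos, cds[hit[1L], ],
                        attr(variants, "a_seq"))
    if (is.na(eff)) {
      per_gene[g, "n_unclassified"] <- per_gene[g, "n_unclassified"] + 1L
    } else if (eff == "synonymous") {
      per_gene[g, "n_synonymous"] <- per_gene[g, "n_synonymous"] + 1L
    } else {
      per_gene[g, "n_nonsynonymous"] <- per_gene[g, "n_nonsynonymous"] + 1L
    }
  }
  rownames(per_gene) <- NULL
  structure(list(per_gene = per_gene,
                 totals = c(synonymous = sum(per_gene$n_synonymous),
                            nonsynonymous = sum(per_gene$n_nonsynonymous),
                            unclassified = sum(per_gene$n_unclassified)),
                 n_intergenic = n_intergenic),
            class = "gene_effect_table")
}

# effect of one substitution given its containing single-frame CDS row;
# needs the reference sequence attached to the variant set
codon_effect <- function(ref_base, alt_base, pos, gene, a_seq) {
  if (is.null(a_seq)) stop("variant set lacks the reference sequence; ",
                           "use compare_genomes() or attach attr 'a_seq'")
  gseq <- substr(a_seq, gene$start, gene$end)
  if (gene$strand == "-") gseq <- revcomp(gseq)
  off <- if (gene$strand == "+") pos - gene$start else gene$end - pos
  cstart <- off - off %% 3L
  codon <- substr(gseq, cstart + 1L, cstart + 3L)
  if (nchar(codon) < 3L) return(NA)
  alt_local <- if (gene$strand == "+") alt_base else revcomp(alt_base)
  codon2 <- codon
  substr(codon2, off %% 3L + 1L, off %% 3L + 1L) <- alt_local
  code <- genetic_code_11()
  if (is.na(code[codon]) || is.na(code[codon2])) return(NA)
  if (cstart == 0L && codon %in% START_CODONS && codon2 %in% START_CODONS)
    return("synonymous")
  if (code[codon] == code[codon2]) "synonymous" else "nonsynonymous"
}

#' Compare two genomes end to end
#'
#' Convenience wrapper: collinear alignment, variant calling (with the
#' reference sequence attached for codon lookup), and coding-effect
#' classification.
#'
#' @param a reference genome (string or object with `$seq`).
#' @param b other genome.
#' @param models annotation of `a`.
#' @param k anchor k-mer size.
#' @return list with `alignment`, `variants`, `effects`.
#' @export
compare_genomes <- function(a, b, models, k = 17L) {
  a_seq <- if (is.character(a)) a else a$seq
  al <- align_collinear(a_seq, b, k)
  v <- call_variants(al, a_seq, b)
  attr(v, "a_seq") <- a_seq
  eff <- classify_coding_effects(v, models)
  list(alignment = al, variants = v, effects = eff)
}

# ---------------------------------------------------------------------------
# Runs test
# ---------------------------------------------------------------------------

# exact permutation distribution of the number of runs given n1 ones and
# n2 zeros (all C(n1+n2, n1) arrangements equally likely)
runs_exact_distribution <- function(n1, n2) {
  n <- n1 + n2
  rmax <- 2L * min(n1, n2) + (n1 != n2)
  r <- 2:rmax
  p <- vapply(r, function(ri) {
    if (ri %% 2L == 0L) {
      k <- ri %/% 2L
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (ri - 1L) %/% 2L
      choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
        choose(n1 - 1, k - 1) * choose(n2 - 1, k)
    }
  }, numeric(1L)) / choose(n, n1)
  data.frame(runs = r, prob = p)
}

#' Wald-Wolfowitz runs test
#'
#' Tests whether the ones in a binary sequence are randomly distributed,
#' via the number of maximal runs of identical symbols.  Given a
#' `gene_effect_table`, the sequence is the position-ordered gene
#' indicator "has at least one nonsynonymous SNP".  The normal
#' approximation uses mean `mu = 2 n1 n2 / (n1 + n2) + 1` and variance
#' `sigma^2 = 2 n1 n2 (2 n1 n2 - n1 - n2) / ((n1+n2)^2 (n1+n2-1))`, with
#' a two-sided p-value and no continuity correction; for `n1 + n2 <= 20`
#' the exact permutation distribution of the run count is used instead
#' (two-sided: total probability of run counts at least as far from the
#' mean as observed).
#'
#' @param x a `gene_effect_table`, or a binary (0/1 or logical) vector.
#' @param exact_limit use the exact distribution when `n1 + n2` is at most
#'   this (default 20).
#' @return a `runs_test_result`: n1, n2, runs_observed, z_statistic,
#'   p_value, method (`normal_approx` or `exact_enumeration`), and both
#'   `p_normal`/`p_exact` (the latter `NA` beyond `exact_limit`).
#' @export
runs_test <- function(x, exact_limit = 20L) {
  if (inherits(x, "gene_effect_table")) {
    pg <- x$per_gene[order(x$per_gene$order_index), ]
    x <- as.integer(pg$n_nonsynonymous > 0L)
  }
  x <- as.integer(as.logical(x))
  if (anyNA(x)) stop("binary sequence contains NA")
  n1 <- sum(x == 1L)
  n2 <- sum(x == 0L)
  if (n1 == 0L || n2 == 0L)
    stop("runs test undefined: the indicator sequence is constant")
  n <- n1 + n2
  robs <- length(rle(x)$lengths)

  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) / (n^2 * (n - 1))
  z <- (robs - mu) / sqrt(sigma2)
  p_normal <- 2 * pnorm(-abs(z))

  p_exact <- NA_real_
  if (n <= exact_limit) {
    d <- runs_exact_distribution(n1, n2)
    p_exact <- min(1, sum(d$prob[abs(d$runs - mu) >= abs(robs - mu) - 1e-9]))
  }
  method <- if (n <= exact_limit) "exact_enumeration" else "normal_approx"
  structure(list(n1 = n1, n2 = n2, runs_observed = robs,
                 z_statistic = z,
                 p_value = if (method == "exact_enumeration") p_exact else p_normal,
                 p_normal = p_normal, p_exact = p_exact, method = method),
            class = "runs_test_result")
}

#' @export
print.runs_test_result <- function(x, ...) {
  cat(sprintf("Runs test: n1=%d n2=%d runs=%d z=%.3f p=%.4g (%s)\n",
              x$n1, x$n2, x$runs_observed, x$z_statistic, x$p_value, x$method))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Genome statistics
# ---------------------------------------------------------------------------

#' Genome composition statistics
#'
#' Genic size is the number of bases covered by the union of all annotated
#' features (overlaps are never double-counted); intergenic is the exact
#' complement, so the two always sum to the genome size.  G+C percentages
#' are reported to 2 decimal places on each partition; gene length is
#' averaged over CDS models (segments of a dual-frame model summed),
#' spacer length over the maximal intergenic intervals.  An AT-fraction
#' sliding-window track (window 100, step 10) is included for plotting.
#'
#' @param genome sequence (string or object with `$seq`).
#' @param models annotation data.frame (may be empty).
#' @param window,step sliding-window parameters for the AT track.
#' @return list with `genome_size`, `genic_size`, `intergenic_size`,
#'   `genic_gc_pct`, `intergenic_gc_pct`, `n_cds`, `n_pseudogenes`,
#'   `avg_gene_length`, `avg_intergenic_length`, `at_track` (data.frame:
#'   pos, at).
#' @export
genome_stats <- function(genome, models, window = 100L, step = 10L) {
  seq <- if (is.character(genome)) genome else genome$seq
  L <- nchar(seq)
  models <- if (nrow(models) > 0L) check_models(models) else models

  if (nrow(models) > 0L) {
    genic_ir <- IRanges::reduce(IRanges::IRanges(models$start, models$end))
    genic_ir <- IRanges::restrict(genic_ir, 1L, L)
    inter_ir <- IRanges::gaps(genic_ir, start = 1L, end = L)
  } else {
    genic_ir <- IRanges::IRanges()
    inter_ir <- IRanges::IRanges(1L, L)
  }
  genic_size <- sum(IRanges::width(genic_ir))
  inter_size <- L - genic_size

  part_gc <- function(ir) {
    if (length(ir) == 0L) return(NaN)
    s <- paste(substring(seq, BiocGenerics::start(ir), BiocGenerics::end(ir)),
               collapse = "")
    gc_fraction(s)
  }
  genic_gc <- part_gc(genic_ir)
  inter_gc <- part_gc(inter_ir)

  cds <- models[nrow(models) > 0 & models$type == "CDS", , drop = FALSE]
  gene_lengths <- if (nrow(cds) > 0L)
    tapply(cds$end - cds$start + 1L, cds$gene_id, sum) else numeric(0)

  at_track <- NULL
  if (L >= window) {
    v <- Biostrings::letterFrequencyInSlidingView(
      Biostrings::DNAString(seq), window, "AT", as.prob = TRUE)
    idx <- seq(1L, nrow(v), by = step)
    at_track <- data.frame(pos = idx, at = unname(v[idx, 1L]))
  }

  list(genome_size = L,
       genic_size = genic_size,
       intergenic_size = inter_size,
       genic_gc_pct = round(100 * genic_gc, 2L),
       intergenic_gc_pct = if (is.nan(inter_gc)) 0 else round(100 * inter_gc, 2L),
       n_cds = length(unique(cds$gene_id)),
       n_pseudogenes = length(unique(models$gene_id[nrow(models) > 0 &
                                                      models$type == "pseudogene"])),
       avg_gene_length = if (length(gene_lengths) > 0L)
         round(mean(gene_lengths), 2L) else NA_real_,
       avg_intergenic_length = if (length(inter_ir) > 0L)
         round(mean(IRanges::width(inter_ir)), 2L) else 0,
       at_track = at_track)
}
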