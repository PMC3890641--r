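# Synthetic endosymbiont genomes with a known truth set.  The generator
# emulates the compositional regime of a reduced AT-rich bacterial
# chromosome: alternating gene models and short intergenic spacers, genic
# G+C far above intergenic G+C, planted poly-A/T tracts, strain divergence
# as coding SNPs with a controlled synonymous fraction plus short indels
# concentrated in homopolymer tracts, draft contigs whose gaps are biased
# to the tracts, and 36 bp single-end reads.

#' Specification of a synthetic genome
#'
#' Defaults describe the full-size chromosome regime this generator
#' emulates: a ~643.5 kb circular chromosome carrying 581 genes of mean
#' length ~989 bp separated by ~118 bp spacers, genic G+C 26.34%,
#' intergenic G+C 15.72%, and the two small biosynthesis plasmids.  Tests
#' typically scale `chromosome_length`/`n_genes` down while keeping the
#' compositional parameters.
#'
#' @param chromosome_length target chromosome length in bases.
#' @param n_genes number of gene models.
#' @param mean_gene_length mean CDS length (bases).
#' @param mean_intergenic_length mean spacer length (bases).
#' @param genic_gc,intergenic_gc target G+C fractions of the two partitions.
#' @param polyA_tract_rate planted homopolymer tracts per kb.
#' @param polyA_length_range length range (bases) of planted tracts.
#' @param plasmid_specs list of `list(name, length, n_genes)` entries, or
#'   `NULL` for a chromosome-only genome.
#' @param circular logical; circular chromosomes are linearised at
#'   position 1, with read sampling wrapping the origin.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(chromosome_length = 643500L,
                        n_genes = 581L,
                        mean_gene_length = 989L,
                        mean_intergenic_length = 118L,
                        genic_gc = 0.2634,
                        intergenic_gc = 0.1572,
                        polyA_tract_rate = 2,
                        polyA_length_range = c(8L, 14L),
                        plasmid_specs = list(
                          list(name = "pLeu", length = 7800L, n_genes = 7L),
                          list(name = "pTrp", length = 2438L, n_genes = 2L)
                        ),
                        circular = TRUE) {
  spec <- list(chromosome_length = as.integer(chromosome_length),
               n_genes = as.integer(n_genes),
               mean_gene_length = as.integer(mean_gene_length),
               mean_intergenic_length = as.integer(mean_intergenic_length),
               genic_gc = genic_gc, intergenic_gc = intergenic_gc,
               polyA_tract_rate = polyA_tract_rate,
               polyA_length_range = as.integer(polyA_length_range),
               plasmid_specs = plasmid_specs,
               circular = isTRUE(circular))
  class(spec) <- "genome_spec"
  validate_genome_spec(spec)
  spec
}

validate_genome_spec <- function(spec) {
  with(spec, {
    if (!(genic_gc > 0 && genic_gc < 1 && intergenic_gc > 0 && intergenic_gc < 1))
      stop("GC fractions must be strictly inside (0, 1)")
    layout <- n_genes * (mean_gene_length + mean_intergenic_length)
    if (abs(layout - chromosome_length) / chromosome_length > 0.10)
      stop(sprintf(paste0("infeasible spec: n_genes * (gene + spacer) = %d ",
                          "differs from chromosome_length = %d by more than 10%%"),
                   layout, chromosome_length))
    if (n_genes * (150L + 2L) > chromosome_length)
      stop("infeasible spec: genes cannot fit in the chromosome")
  })
  invisible(spec)
}

# draw one replicon: alternating spacer/gene layout fitted exactly to `len`
simulate_replicon <- function(len, n_genes, mean_gene, mean_spacer,
                              genic_gc, intergenic_gc,
                              polyA_rate, polyA_range, id_prefix) {
  # gene lengths: multiples of 3, floor 150 bp
  gl <- round(rnorm(n_genes, mean_gene, 0.2 * mean_gene))
  gl <- pmax(150L, as.integer(3L * round(gl / 3)))
  if (sum(gl) > len - 2L * n_genes) {
    # an unlucky draw can overshoot small genomes; rescale to fit
    gl <- pmax(150L, as.integer(3L * round(gl * (len - 2L * n_genes) /
                                             sum(gl) / 3)))
  }
  genic_total <- sum(gl)
  inter_total <- len - genic_total
  if (inter_total < 2L * n_genes)
    stop("infeasible spec: genes cannot fit in the chromosome")
  # spacer lengths: proportional jitter rescaled to the exact remainder
  sl <- runif(n_genes, 0.4, 1.6)
  sl <- pmax(2L, as.integer(round(sl / sum(sl) * inter_total)))
  sl[1L] <- sl[1L] + (inter_total - sum(sl))
  if (sl[1L] < 2L) { # rare rounding corner
    sl[which.max(sl)] <- sl[which.max(sl)] + sl[1L] - 2L
    sl[1L] <- 2L
  }

  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  starts <- cumsum(sl) + cumsum(c(0L, gl[-n_genes])) + 1L  # gene start positions

  # choose homopolymer tract placements first (preferentially intergenic)
  # so the sequence composition can compensate for the planted A/T bases
  tracts <- data.frame(start = integer(0), end = integer(0),
                       base = character(0), genic = logical(0))
  n_tracts <- as.integer(round(polyA_rate * len / 1000))
  if (n_tracts > 0L) {
    used <- IRanges::IRanges()
    planted <- 0L
    attempts <- 0L
    while (planted < n_tracts && attempts < 50L * n_tracts) {
      attempts <- attempts + 1L
      tl <- sample1(seq(polyA_range[1L], polyA_range[2L]))
      genic <- runif(1L) < 0.2
      if (genic) {
        gi <- sample(n_genes, 1L)
        tl <- max(6L, 3L * (tl %/% 3L))  # codon-sized, codon-aligned
        room <- gl[gi] - tl - 6L
        if (room < 6L) next
        off <- 3L + 3L * sample.int(max(1L, (room - 3L) %/% 3L), 1L)
        tstart <- starts[gi] + off
      } else {
        gi <- sample(n_genes, 1L)
        if (sl[gi] < tl + 2L) next
        off <- sample.int(sl[gi] - tl, 1L)
        tstart <- starts[gi] - sl[gi] + off - 1L
      }
      # keep tracts well separated: two runs closer than a seed length
      # form a composite near-repeat that defeats seed-based assembly
      cand <- IRanges::IRanges(tstart, tstart + tl - 1L)
      if (length(used) > 0L &&
          sum(IRanges::countOverlaps(cand, used, maxgap = 30L)) > 0L) next
      base <- if (genic && strands[gi] == "-") "T" else
        sample(c("A", "T"), 1L, prob = c(0.7, 0.3))
      used <- c(used, cand)
      tracts <- rbind(tracts, data.frame(start = tstart, end = tstart + tl - 1L,
                                         base = base, genic = genic))
      planted <- planted + 1L
    }
  }

  # planted tracts are pure A/T; raise the sampling targets so the final
  # genome still measures on spec in both partitions
  tlen <- if (nrow(tracts) > 0L) tracts$end - tracts$start + 1L else integer(0)
  inter_planted <- sum(tlen[nrow(tracts) > 0 & !tracts$genic])
  genic_planted <- sum(tlen[nrow(tracts) > 0 & tracts$genic])
  inter_gc_eff <- min(0.95, intergenic_gc * inter_total /
                        max(1, inter_total - inter_planted))
  genic_gc_eff <- min(0.95, genic_gc * genic_total /
                        max(1, genic_total - genic_planted))
  p_codon <- solve_codon_gc(genic_gc_eff)

  pieces <- character(2L * n_genes)
  for (i in seq_len(n_genes)) {
    pieces[2L * i - 1L] <- random_dna(sl[i], inter_gc_eff)
    n_cod <- gl[i] / 3L
    stop_codon <- sample(STOP_CODONS, 1L,
                         prob = c((1 - genic_gc)^2, (1 - genic_gc) * genic_gc,
                                  (1 - genic_gc) * genic_gc))
    cds <- paste0("ATG",
                  paste(random_codons(n_cod - 2L, p_codon), collapse = ""),
                  stop_codon)
    pieces[2L * i] <- if (strands[i] == "+") cds else revcomp(cds)
  }
  seq <- paste(pieces, collapse = "")
  for (i in seq_len(nrow(tracts)))
    seq <- splice_string(seq, tracts$start[i], tracts$end[i],
                         strrep(tracts$base[i], tracts$end[i] - tracts$start[i] + 1L))

  models <- data.frame(
    gene_id = sprintf("%s_%04d", id_prefix, seq_len(n_genes)),
    start = starts, end = starts + gl - 1L,
    strand = strands, type = "CDS",
    product = "hypothetical protein", segment = 1L,
    stringsAsFactors = FALSE
  )
  list(seq = seq, models = models, tracts = tracts)
}

#' Simulate a reference genome
#'
#' Generates sequence plus annotation for the chromosome (and any plasmids
#' configured): every CDS starts with ATG, ends with a stop codon, and is
#' free of internal stops under translation table 11; measured genic and
#' intergenic G+C land on the configured targets (the per-codon base composition
#' is corrected for stop-codon rejection); poly-A/T tracts are planted at
#' the configured rate, preferentially in spacers.  Deterministic for a
#' fixed seed.
#'
#' @param spec a [genome_spec()].
#' @param seed integer RNG seed.
#' @return a `ref_genome`: list with `seq`, `models`, `tracts`, `plasmids`,
#'   `spec`, `seed`.
#' @export
simulate_reference <- function(spec = genome_spec(), seed = 1L) {
  validate_genome_spec(spec)
  set.seed(seed)
  chrom <- simulate_replicon(spec$chromosome_length, spec$n_genes,
                             spec$mean_gene_length, spec$mean_intergenic_length,
                             spec$genic_gc, spec$intergenic_gc,
                             spec$polyA_tract_rate, spec$polyA_length_range,
                             "CDS")
  plasmids <- NULL
  if (!is.null(spec$plasmid_specs)) {
    plasmids <- lapply(spec$plasmid_specs, function(p) {
      mean_g <- max(150L, as.integer(3L * round(p$length * 0.85 / p$n_genes / 3)))
      mean_s <- max(2L, as.integer((p$length - p$n_genes * mean_g) / p$n_genes))
      simulate_replicon(p$length, p$n_genes, mean_g, mean_s,
                        spec$genic_gc, spec$intergenic_gc,
                        spec$polyA_tract_rate, spec$polyA_length_range,
                        p$name)
    })
    names(plasmids) <- vapply(spec$plasmid_specs, `[[`, character(1L), "name")
  }
  structure(list(seq = chrom$seq, models = chrom$models, tracts = chrom$tracts,
                 plasmids = plasmids, spec = spec, seed = as.integer(seed)),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %d bp, %d gene models, %d planted tracts, seed %d\n",
              nchar(x$seq), nrow(x$models), nrow(x$tracts), x$seed))
  invisible(x)
}

# classify a single coding substitution by codon re-translation;
# returns NA if the position is not in a single-frame CDS
snp_effect_at <- function(seq, models, pos, alt) {
  cds <- models[models$type == "CDS", , drop = FALSE]
  multi <- cds$gene_id[duplicated(cds$gene_id)]
  cds <- cds[!(cds$gene_id %in% multi), , drop = FALSE]
  hit <- which(cds$start <= pos & cds$end >= pos)
  if (length(hit) == 0L) return(NA)
  g <- cds[hit[1L], ]
  if (g$strand == "+") {
    off <- pos - g$start           # 0-based offset in gene orientation
  } else {
    off <- g$end - pos
  }
  cstart <- off - off %% 3L        # codon-local
  gseq <- substr(seq, g$start, g$end)
  if (g$strand == "-") gseq <- revcomp(gseq)
  codon <- substr(gseq, cstart + 1L, cstart + 3L)
  base_in_codon <- off %% 3L + 1L
  alt_local <- if (g$strand == "+") alt else revcomp(alt)
  codon2 <- codon
  substr(codon2, base_in_codon, base_in_codon) <- alt_local
  code <- genetic_code_11()
  if (cstart == 0L && codon %in% START_CODONS && codon2 %in% START_CODONS)
    return("synonymous")           # initiator context: both read as Met
  if (is.na(code[codon2])) return(NA)
  if (code[codon] == code[codon2]) "synonymous" else "nonsynonymous"
}

#' Derive a diverged strain with a known truth set
#'
#' SNPs are planted at coding positions with the requested
#' synonymous/nonsynonymous mix (verified by codon re-translation); 1 bp
#' indels land inside poly-A/T tracts with probability `polyA_indel_prob`
#' (the dominant homopolymer error/variation mode of these genomes).  At
#' most one SNP per codon, no overlapping events, and -- unless
#' `coding_indels` -- indels avoid CDS so that every planted SNP remains
#' classifiable.
#'
#' @param ref a `ref_genome`.
#' @param n_snps,n_indels event counts.
#' @param syn_fraction fraction of SNPs that are synonymous.
#' @param seed RNG seed.
#' @param polyA_indel_prob probability an indel targets a homopolymer tract.
#' @param coding_indels allow indels inside CDS (frameshifts; used to test
#'   annotation curation).
#' @param strain_id label for the strain.
#' @return a `strain_genome`: list with `seq`, `truth` (list of `snps` and
#'   `indels` data.frames in reference coordinates), `strain_id`.
#' @export
mutate_strain <- function(ref, n_snps = 100L, syn_fraction = 0.5,
                          n_indels = 10L, seed = 1L,
                          polyA_indel_prob = 0.8,
                          coding_indels = FALSE,
                          strain_id = "strain") {
  stopifnot(inherits(ref, "ref_genome"),
            syn_fraction >= 0, syn_fraction <= 1)
  L <- nchar(ref$seq)
  if (n_snps + n_indels > L / 20)
    stop("requested divergence is not small relative to the genome")
  set.seed(seed)

  seq <- ref$seq
  models <- ref$models
  cds <- models[models$type == "CDS", , drop = FALSE]
  n_syn <- round(n_snps * syn_fraction)
  n_non <- n_snps - n_syn

  # --- indels first (SNPs then avoid the affected genes) -------------------
  tracts <- ref$tracts
  if (!coding_indels && nrow(tracts) > 0L)
    tracts <- tracts[!tracts$genic, , drop = FALSE]
  indels <- data.frame(position = integer(0), seq = character(0),
                       is_insertion = logical(0), in_polyA = logical(0))
  taken <- integer(0)
  if (n_indels > 0L) {
    genic_mask <- rep(FALSE, L)
    for (i in seq_len(nrow(cds)))
      genic_mask[cds$start[i]:cds$end[i]] <- TRUE
    for (j in seq_len(n_indels)) {
      placed <- FALSE
      for (try in 1:200) {
        in_tract <- nrow(tracts) > 0L && runif(1L) < polyA_indel_prob
        if (in_tract) {
          ti <- sample.int(nrow(tracts), 1L)
          t <- tracts[ti, ]
          # one indel per tract: a +1 and a -1 in the same run would
          # cancel and leave fewer observable events than planted
          tracts <- tracts[-ti, , drop = FALSE]
          pos <- t$start + sample.int(t$end - t$start, 1L) - 1L
          base <- t$base
        } else {
          pos <- sample.int(L - 2L, 1L) + 1L
          if (!coding_indels && genic_mask[pos]) next
          base <- substr(seq, pos, pos)
        }
        if (any(abs(taken - pos) < 8L)) next
        indels <- rbind(indels, data.frame(
          position = pos, seq = base,
          is_insertion = runif(1L) < 0.5, in_polyA = in_tract))
        taken <- c(taken, pos)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place the requested indels")
    }
  }

  # genes hit by an indel are excluded from SNP placement
  blocked_genes <- character(0)
  if (nrow(indels) > 0L) {
    for (i in seq_len(nrow(cds)))
      if (any(indels$position >= cds$start[i] & indels$position <= cds$end[i]))
        blocked_genes <- c(blocked_genes, cds$gene_id[i])
  }

  # --- coding SNPs with the requested effect mix ---------------------------
  ok_cds <- cds[!(cds$gene_id %in% blocked_genes), , drop = FALSE]
  if (nrow(ok_cds) == 0L && n_snps > 0L)
    stop("not enough eligible codon positions")
  snps <- data.frame(position = integer(0), ref_base = character(0),
                     alt_base = character(0), coding = logical(0),
                     synonymous = logical(0))
  if (n_snps > 0L) {
    coding_pos <- unlist(lapply(seq_len(nrow(ok_cds)),
                                function(i) ok_cds$start[i]:ok_cds$end[i]))
    coding_pos <- sample(coding_pos)
    used_codons <- character(0)
    need_syn <- n_syn; need_non <- n_non
    i <- 0L
    while ((need_syn > 0L || need_non > 0L) && i < length(coding_pos)) {
      i <- i + 1L
      pos <- coding_pos[i]
      if (any(abs(taken - pos) < 8L)) next
      gi <- which(ok_cds$start <= pos & ok_cds$end >= pos)[1L]
      g <- ok_cds[gi, ]
      codon_key <- sprintf("%s:%d", g$gene_id,
                           if (g$strand == "+") (pos - g$start) %/% 3L
                           else (g$end - pos) %/% 3L)
      if (codon_key %in% used_codons) next
      ref_base <- substr(seq, pos, pos)
      alts <- sample(setdiff(BASES, ref_base))
      for (alt in alts) {
        eff <- snp_effect_at(ref$seq, models, pos, alt)
        if (is.na(eff)) next
        # a planted stop would truncate the gene; keep strains functional
        if (eff == "nonsynonymous") {
          loc <- snp_makes_stop(ref$seq, models, pos, alt)
          if (loc) next
        }
        want <- if (eff == "synonymous") need_syn > 0L else need_non > 0L
        if (!want) next
        snps <- rbind(snps, data.frame(
          position = pos, ref_base = ref_base, alt_base = alt,
          coding = TRUE, synonymous = eff == "synonymous"))
        if (eff == "synonymous") need_syn <- need_syn - 1L
        else need_non <- need_non - 1L
        used_codons <- c(used_codons, codon_key)
        taken <- c(taken, pos)
        break
      }
    }
    if (need_syn > 0L || need_non > 0L)
      stop("not enough eligible codon positions")
  }

  truth <- list(snps = snps[order(snps$position), , drop = FALSE],
                indels = indels[order(indels$position), , drop = FALSE])
  rownames(truth$snps) <- rownames(truth$indels) <- NULL
  strain_seq <- apply_variants(ref$seq, truth)
  structure(list(seq = strain_seq, truth = truth, strain_id = strain_id,
                 ref_models = models),
            class = "strain_genome")
}

# does substituting alt at pos create a premature stop codon?
snp_makes_stop <- function(seq, models, pos, alt) {
  cds <- models[models$type == "CDS", , drop = FALSE]
  hit <- which(cds$start <= pos & cds$end >= pos)
  if (length(hit) == 0L) return(FALSE)
  g <- cds[hit[1L], ]
  off <- if (g$strand == "+") pos - g$start else g$end - pos
  if (off %/% 3L == (g$end - g$start) %/% 3L) return(FALSE)  # terminal codon
  gseq <- substr(seq, g$start, g$end)
  if (g$strand == "-") gseq <- revcomp(gseq)
  cstart <- off - off %% 3L
  codon <- substr(gseq, cstart + 1L, cstart + 3L)
  alt_local <- if (g$strand == "+") alt else revcomp(alt)
  substr(codon, off %% 3L + 1L, off %% 3L + 1L) <- alt_local
  codon %in% STOP_CODONS
}

#' Apply a truth set to a reference sequence
#'
#' Reconstructs a strain sequence from its reference and truth set; used to
#' assert truth-set consistency.
#'
#' @param seq reference sequence.
#' @param truth list with `snps` and `indels` as produced by
#'   [mutate_strain()].
#' @return the strain sequence.
#' @export
apply_variants <- function(seq, truth) {
  for (i in seq_len(nrow(truth$snps))) {
    s <- truth$snps[i, ]
    stopifnot(substr(seq, s$position, s$position) == s$ref_base)
    substr(seq, s$position, s$position) <- s$alt_base
  }
  # apply indels right-to-left so earlier positions stay valid
  ind <- truth$indels
  if (nrow(ind) > 0L) {
    for (i in order(ind$position, decreasing = TRUE)) {
      e <- ind[i, ]
      if (e$is_insertion) {
        seq <- splice_string(seq, e$position + 1L, e$position, e$seq)
      } else {
        seq <- splice_string(seq, e$position, e$position + nchar(e$seq) - 1L, "")
      }
    }
  }
  seq
}

#' Shred a genome into draft contigs
#'
#' Emulates a draft long-read assembly of an AT-rich genome: `n_gaps`
#' non-overlapping gaps, biased toward poly-A/T tracts (where such
#' assemblies characteristically break), optionally with +-1 homopolymer
#' length errors injected inside the contigs.
#'
#' @param genome a `strain_genome`/`ref_genome` or a sequence string.
#' @param n_gaps number of gaps.
#' @param gap_length_range gap length range in bases.
#' @param polyA_gap_bias probability a gap is centred on a homopolymer
#'   tract; falls back to uniform placement (with a warning) when the
#'   genome has too few tracts.
#' @param homopolymer_error_rate per-eligible-run probability of a
#'   homopolymer length error inside contigs.
#' @param homopolymer_error_magnitude maximum magnitude of a homopolymer
#'   length error (default 1: +-1 slips; larger values emulate the grosser
#'   consensus corruption of long AT-rich runs that makes short reads
#'   unmappable).
#' @param seed RNG seed.
#' @param min_contig minimum contig length retained between gaps.
#' @return a `contig_set`: list with `contigs` (named vector), `offsets`
#'   (true 1-based genome start of each contig), `gap_truth` and
#'   `hp_errors` data.frames.
#' @export
shred_contigs <- function(genome, n_gaps, gap_length_range = c(50L, 300L),
                          polyA_gap_bias = 0.8, homopolymer_error_rate = 0,
                          homopolymer_error_magnitude = 1L,
                          seed = 1L, min_contig = 100L) {
  seq <- if (is.character(genome)) genome else genome$seq
  L <- nchar(seq)
  set.seed(seed)
  gaps <- data.frame(start = integer(0), end = integer(0), in_polyA = logical(0))

  if (n_gaps > 0L) {
    tracts <- homopolymer_runs(seq, min_len = 8L)
    margin <- min_contig
    placed <- 0L
    attempts <- 0L
    warned <- FALSE
    while (placed < n_gaps) {
      attempts <- attempts + 1L
      if (attempts > 500L * n_gaps)
        stop("could not place the requested gaps")
      gl <- sample1(seq(gap_length_range[1L], gap_length_range[2L]))
      use_tract <- nrow(tracts) > 0L && runif(1L) < polyA_gap_bias
      if (use_tract) {
        t <- tracts[sample.int(nrow(tracts), 1L), ]
        centre <- (t$start + t$end) %/% 2L
        gstart <- centre - sample.int(gl, 1L) + 1L
      } else {
        if (polyA_gap_bias > 0 && nrow(tracts) == 0L && !warned) {
          warning("no homopolymer tracts available; placing gaps uniformly")
          warned <- TRUE
        }
        gstart <- sample.int(L - gl, 1L)
      }
      gend <- gstart + gl - 1L
      if (gstart <= margin || gend >= L - margin) next
      if (nrow(gaps) > 0L &&
          any(pmax(gaps$start, gstart) <= pmin(gaps$end, gend) + min_contig)) next
      gaps <- rbind(gaps, data.frame(start = gstart, end = gend,
                                     in_polyA = use_tract))
      placed <- placed + 1L
    }
    gaps <- gaps[order(gaps$start), , drop = FALSE]
  }

  # contigs = complement of the gaps
  cstart <- c(1L, gaps$end + 1L)
  cend <- c(gaps$start - 1L, L)
  contigs <- substring(seq, cstart, cend)
  names(contigs) <- sprintf("ctg_%03d", seq_along(contigs))

  gap_truth <- data.frame(
    gap_id = if (nrow(gaps) > 0L) sprintf("gap_%03d", seq_len(nrow(gaps))) else character(0),
    start = gaps$start, end = gaps$end,
    length = gaps$end - gaps$start + 1L,
    sequence = if (nrow(gaps) > 0L) substring(seq, gaps$start, gaps$end) else character(0),
    in_polyA = gaps$in_polyA,
    stringsAsFactors = FALSE
  )

  # homopolymer length errors inside contigs
  hp_errors <- data.frame(contig = character(0), contig_pos = integer(0),
                          genome_pos = integer(0), delta = integer(0))
  if (homopolymer_error_rate > 0) {
    for (ci in seq_along(contigs)) {
      runs <- homopolymer_runs(contigs[[ci]], min_len = 6L)
      if (nrow(runs) == 0L) next
      hit <- which(runif(nrow(runs)) < homopolymer_error_rate)
      for (ri in rev(hit)) {  # right-to-left keeps earlier coordinates valid
        r <- runs[ri, ]
        mag <- sample1(seq_len(homopolymer_error_magnitude))
        mag <- min(mag, r$length - 2L)  # never erase a run entirely
        delta <- mag * sample(c(-1L, 1L), 1L)
        contigs[[ci]] <- if (delta > 0L)
          splice_string(contigs[[ci]], r$start, r$start - 1L, strrep(r$base, delta))
        else
          splice_string(contigs[[ci]], r$start, r$start - delta - 1L, "")
        hp_errors <- rbind(hp_errors, data.frame(
          contig = names(contigs)[ci], contig_pos = r$start,
          genome_pos = cstart[ci] + r$start - 1L, delta = delta))
      }
    }
  }

  structure(list(contigs = contigs, offsets = cstart, gap_truth = gap_truth,
                 hp_errors = hp_errors, genome_length = L),
            class = "contig_set")
}

#' Simulate short single-end reads
#'
#' Uniform start positions over the (optionally circular) genome, both
#' strands equiprobable, independent substitution errors, constant
#' synthetic quality strings.
#'
#' @param genome a genome object or sequence string.
#' @param coverage target mean fold coverage (> 0).
#' @param read_length read length in bases (default 36).
#' @param error_rate per-base substitution error rate.
#' @param seed RNG seed.
#' @param circular wrap reads around the origin.
#' @return a `read_set`: list with `reads`, `starts`, `forward`, and the
#'   simulation parameters.
#' @export
simulate_reads <- function(genome, coverage = 200, read_length = 36L,
                           error_rate = 0, seed = 1L, circular = TRUE) {
  seq <- if (is.character(genome)) genome else genome$seq
  L <- nchar(seq)
  if (coverage <= 0) stop("coverage must be positive")
  if (read_length > L) stop("read length exceeds genome length")
  set.seed(seed)
  n <- as.integer(round(coverage * L / read_length))
  starts <- if (circular) sample.int(L, n, replace = TRUE)
  else sample.int(L - read_length + 1L, n, replace = TRUE)
  template <- if (circular) paste0(seq, substr(seq, 1L, read_length - 1L)) else seq
  reads <- substring(template, starts, starts + read_length - 1L)

  fwd <- runif(n) < 0.5
  if (any(!fwd)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[!fwd])))
    reads[!fwd] <- rc
  }

  if (error_rate > 0) {
    n_err <- rbinom(n, read_length, error_rate)
    which_err <- which(n_err > 0L)
    for (i in which_err) {
      pos <- sample.int(read_length, n_err[i])
      for (p in pos) {
        old <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(BASES, old), 1L)
      }
    }
  }

  structure(list(reads = unname(reads), starts = starts, forward = fwd,
                 read_length = as.integer(read_length),
                 coverage = coverage, error_rate = error_rate,
                 seed = as.integer(seed), circular = circular),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads of %d bp (error rate %.3g)\n",
              length(x$reads), x$read_length,
              if (is.null(x$error_rate)) NA else x$error_rate))
  invisible(x)
}
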