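# Annotation by projection and rule-based curation.  Because gene order is
# conserved in these genomes, reference gene models are mapped through the
# collinear alignment instead of re-predicted; the curation cascade then
# applies, automatically, the rules a human curator would: flag length
# deviations >10%, rescue genes truncated by a homopolymer frameshift as
# dual reading-frame models, extend to upstream alternate start codons
# (GTG/TTG and the rare ATT), and call the remainder pseudogenes.

# gene-oriented sequence of a (possibly multi-segment) model
gene_sequence <- function(seq, rows) {
  rows <- rows[order(rows$segment), , drop = FALSE]
  segs <- substring(seq, rows$start, rows$end)
  if (rows$strand[1L] == "-") segs <- vapply(segs, revcomp, character(1L))
  paste(segs, collapse = "")
}

#' Project an annotation onto another genome
#'
#' Maps every reference feature through the collinear alignment.  Features
#' whose interval falls in unaligned segments or overlaps an unfinished
#' region (an `N` run) are flagged and left out of the projected set.
#'
#' @param reference a `ref_genome` (or list with `seq` and `models`).
#' @param alignment a `collinear_alignment` of reference (`a`) to target
#'   (`b`).
#' @param target_seq the target genome sequence (for `N`-run checks).
#' @return list with `models` (projected data.frame) and `flagged`
#'   (data.frame: gene_id, reason).
#' @export
project_annotation <- function(reference, alignment, target_seq = NULL) {
  models <- check_models(reference$models)
  flagged <- list()
  out <- models
  ok <- rep(TRUE, nrow(models))
  s2 <- map_position(alignment, models$start, snap = "right")
  e2 <- map_position(alignment, models$end, snap = "left")
  for (i in seq_len(nrow(models))) {
    if (is.na(s2[i]) || is.na(e2[i]) || s2[i] > e2[i]) {
      ok[i] <- FALSE
      flagged[[length(flagged) + 1L]] <-
        data.frame(gene_id = models$gene_id[i], reason = "unaligned")
      next
    }
    out$start[i] <- s2[i]
    out$end[i] <- e2[i]
    if (!is.null(target_seq) &&
        grepl("N", substr(target_seq, s2[i], e2[i]), fixed = TRUE)) {
      ok[i] <- FALSE
      flagged[[length(flagged) + 1L]] <-
        data.frame(gene_id = models$gene_id[i], reason = "overlaps_gap")
    }
  }
  # drop all segments of any flagged gene
  bad <- unique(unlist(lapply(flagged, `[[`, "gene_id")))
  keep <- ok & !(out$gene_id %in% bad)
  list(models = out[keep, , drop = FALSE],
       flagged = if (length(flagged) > 0L) do.call(rbind, flagged) else
         data.frame(gene_id = character(0), reason = character(0)))
}

# protein percent identity by global alignment (0..1)
protein_identity <- function(p1, p2) {
  if (nchar(p1) == 0L || nchar(p2) == 0L) return(0)
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(p1),
                                      Biostrings::AAString(p2),
                                      type = "global",
                                      substitutionMatrix = unit_aa_matrix(),
                                      gapOpening = 0, gapExtension = 1)
  Biostrings::pid(al) / 100
}

unit_aa_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- strsplit("ARNDCQEGHILKMFPSTWYVBJZXU*-+.", "")[[1L]]
      m <<- matrix(-1, length(letters), length(letters),
                   dimnames = list(letters, letters))
      diag(m) <- 1
    }
    m
  }
})

# Attempt a dual reading-frame rescue of a CDS interrupted by a
# homopolymer-associated frameshift: a premature stop next to an A/T
# tract of 6+, or a length not divisible by 3.  Local coordinates are
# gene-oriented.  Tries segment-2 frame shifts of +-1/+-2 at each
# candidate tract and keeps the split whose conceptual translation best
# matches the reference protein.
try_polya_merge <- function(gseq, stop_codon_idx, ref_protein,
                            tract_min = 6L, tract_window = 10L,
                            min_identity = 0.8) {
  n <- nchar(gseq)
  all_tracts <- homopolymer_runs(gseq, min_len = tract_min)
  if (nrow(all_tracts) == 0L) return(NULL)
  tracts <- all_tracts
  if (!is.na(stop_codon_idx)) {
    stop_pos <- 3L * (stop_codon_idx - 1L) + 1L
    tracts <- tracts[tracts$start <= stop_pos + 2L + tract_window &
                       tracts$end >= stop_pos - tract_window, , drop = FALSE]
    # a frameshift can run well past its tract before hitting a stop; if
    # no tract flanks the stop, consider every tract in the gene (the
    # identity floor keeps this specific)
    if (nrow(tracts) == 0L) tracts <- all_tracts
  }
  best <- NULL
  for (ti in seq_len(nrow(tracts))) {
    tract <- tracts[ti, ]
    # segment 1 ends at the last codon boundary at/before the tract start
    e1 <- 3L * ((tract$start - 1L) %/% 3L)
    if (e1 < 3L) next
    head_aa <- translate11(substr(gseq, 1L, e1), as_start = TRUE)
    if (grepl("*", head_aa, fixed = TRUE)) next
    for (d in c(1L, -1L, 2L, -2L)) {
      s2 <- e1 + 1L + d
      if (s2 < e1) next         # segment 2 may reuse at most one base
      if (s2 < 1L || s2 > n - 2L) next
      if ((n - s2 + 1L) %% 3L != 0L) next
      tail_aa <- translate11(substr(gseq, s2, n), as_start = FALSE)
      inner <- substr(tail_aa, 1L, nchar(tail_aa) - 1L)
      if (grepl("*", inner, fixed = TRUE)) next
      if (substr(tail_aa, nchar(tail_aa), nchar(tail_aa)) != "*") next
      prot <- paste0(head_aa, inner)
      idt <- protein_identity(prot, sub("\\*$", "", ref_protein))
      if (idt >= min_identity && (is.null(best) || idt > best$identity))
        best <- list(e1 = e1, s2 = s2, identity = idt, d = d)
    }
  }
  best
}

#' Curate projected gene models
#'
#' Deterministic rule cascade per CDS: (1) flag models whose length
#' deviates from the reference model by more than 10% of the reference
#' CDS length; (2) models truncated by a premature stop adjacent to an
#' A/T homopolymer of 6+ bases are rescued, when a shifted downstream
#' frame restores similarity to the reference protein, as a dual
#' reading-frame model (the tract itself is untouched -- this stage never
#' edits the genome); (3) models starting downstream of their reference
#' length are extended to the nearest in-frame upstream ATG/GTG/TTG/ATT
#' reachable without crossing a stop; (4) models still interrupted become
#' pseudogenes.  Every action is logged as a curation event.
#'
#' @param models projected model data.frame.
#' @param genome the genome the models annotate (string or `$seq` object).
#' @param reference_models reference models (for lengths and proteins).
#' @param reference_seq reference genome sequence (for reference
#'   proteins); optional but required for homopolymer merges.
#' @return list with `models` (curated data.frame) and `events`
#'   (data.frame: gene_id, rule, detail).
#' @export
curate_models <- function(models, genome, reference_models,
                          reference_seq = NULL) {
  seq <- if (is.character(genome)) genome else genome$seq
  models <- check_models(models)
  reference_models <- check_models(reference_models)
  events <- list()
  log_event <- function(gene_id, rule, detail) {
    events[[length(events) + 1L]] <<- data.frame(
      gene_id = gene_id, rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  }

  ref_len <- tapply(reference_models$end - reference_models$start + 1L,
                    reference_models$gene_id, sum)

  out <- models
  for (g in unique(models$gene_id)) {
    rows <- out[out$gene_id == g, , drop = FALSE]
    if (rows$type[1L] != "CDS") next
    rl <- ref_len[g]
    if (is.na(rl)) next
    glen <- sum(rows$end - rows$start + 1L)

    # rule 1: length deviation
    if (abs(glen - rl) / rl > 0.10)
      log_event(g, "length_deviation",
                sprintf("length %d vs reference %d", glen, as.integer(rl)))

    # rule 3: upstream start extension (single-frame models only)
    if (nrow(rows) == 1L && glen < rl && glen %% 3L == 0L) {
      ext <- find_upstream_start(seq, rows, max_extra = rl - glen + 30L)
      if (!is.null(ext) && ext$extend_by > 0L) {
        if (rows$strand == "+") rows$start <- rows$start - ext$extend_by
        else rows$end <- rows$end + ext$extend_by
        out[out$gene_id == g, ] <- rows
        glen <- glen + ext$extend_by
        log_event(g, "start_extension",
                  sprintf("extended %d bp upstream to %s", ext$extend_by,
                          ext$codon))
      }
    }

    # rule 2/4: frame interruptions (premature stop or frameshifted length)
    if (nrow(rows) == 1L) {
      gseq <- gene_sequence(seq, rows)
      aa <- translate11(substr(gseq, 1L, 3L * (nchar(gseq) %/% 3L)))
      inner <- substr(aa, 1L, nchar(aa) - 1L)
      stop_at <- regexpr("*", inner, fixed = TRUE)
      interrupted <- stop_at > 0L || glen %% 3L != 0L
      if (interrupted) {
        merged <- NULL
        if (!is.null(reference_seq)) {
          ref_rows <- reference_models[reference_models$gene_id == g, , drop = FALSE]
          ref_prot <- translate11(gene_sequence(reference_seq, ref_rows))
          merged <- try_polya_merge(gseq,
                                    if (stop_at > 0L) stop_at else NA_integer_,
                                    ref_prot)
        }
        if (!is.null(merged)) {
          rows2 <- rows[c(1L, 1L), ]
          if (rows$strand == "+") {
            rows2$end[1L] <- rows$start + merged$e1 - 1L
            rows2$start[2L] <- rows$start + merged$s2 - 1L
          } else {
            rows2$start[1L] <- rows$end - merged$e1 + 1L
            rows2$end[2L] <- rows$end - merged$s2 + 1L
          }
          rows2$segment <- c(1L, 2L)
          out <- rbind(out[out$gene_id != g, , drop = FALSE], rows2)
          log_event(g, "polyA_merge",
                    sprintf("dual-frame model (shift %+d, identity %.2f)",
                            merged$d, merged$identity))
        } else {
          out$type[out$gene_id == g] <- "pseudogene"
          log_event(g, "pseudogene_call",
                    if (stop_at > 0L)
                      sprintf("premature stop at codon %d", stop_at)
                    else "frame length not divisible by 3")
        }
      }
    }
  }
  out <- out[order(out$start, out$gene_id, out$segment), , drop = FALSE]
  rownames(out) <- NULL
  list(models = out,
       events = if (length(events) > 0L) do.call(rbind, events) else
         data.frame(gene_id = character(0), rule = character(0),
                    detail = character(0)))
}

# nearest in-frame upstream alternate start reachable without a stop
find_upstream_start <- function(seq, row, max_extra) {
  L <- nchar(seq)
  steps <- seq(3L, 3L * (max_extra %/% 3L), by = 3L)
  for (s in steps) {
    if (row$strand == "+") {
      p <- row$start - s
      if (p < 1L) return(NULL)
      codon <- substr(seq, p, p + 2L)
    } else {
      p <- row$end + s
      if (p + 2L > L + 2L || p > L) return(NULL)
      codon <- revcomp(substr(seq, p - 2L, p))
    }
    if (codon %in% STOP_CODONS) return(NULL)
    if (codon %in% START_CODONS) return(list(extend_by = s, codon = codon))
  }
  NULL
}

#' Compare gene content between two annotations
#'
#' Reciprocal best protein match by global alignment score under a unit
#' cost scheme, with a minimum-identity floor.  Identical proteins are
#' paired directly; only the remainder goes through alignment.
#'
#' @param models_a,models_b annotations.
#' @param genome_a,genome_b the annotated sequences.
#' @param min_identity identity floor for a reciprocal pair (default 0.4).
#' @return list with `shared` (data.frame: gene_a, gene_b, identity),
#'   `unique_to_a`, `unique_to_b` (character vectors).
#' @export
gene_content_diff <- function(models_a, models_b, genome_a, genome_b,
                              min_identity = 0.4) {
  ga <- if (is.character(genome_a)) genome_a else genome_a$seq
  gb <- if (is.character(genome_b)) genome_b else genome_b$seq
  prot <- function(models, seq) {
    models <- check_models(models)
    cds <- models[models$type == "CDS", , drop = FALSE]
    ids <- unique(cds$gene_id)
    p <- vapply(ids, function(g) {
      s <- gene_sequence(seq, cds[cds$gene_id == g, , drop = FALSE])
      s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
      sub("\\*$", "", translate11(s))
    }, character(1L))
    setNames(p, ids)
  }
  pa <- prot(models_a, ga)
  pb <- prot(models_b, gb)
  if (length(pa) == 0L || length(pb) == 0L)
    return(list(shared = data.frame(gene_a = character(0),
                                    gene_b = character(0),
                                    identity = numeric(0)),
                unique_to_a = names(pa), unique_to_b = names(pb)))

  shared <- list()
  free_a <- names(pa)
  free_b <- names(pb)
  # fast path: byte-identical proteins
  mb <- match(pa[free_a], pb[free_b])
  hit <- which(!is.na(mb) & !duplicated(mb))
  for (i in hit) {
    shared[[length(shared) + 1L]] <- data.frame(
      gene_a = free_a[i], gene_b = free_b[mb[i]], identity = 1)
  }
  free_a <- setdiff(names(pa), vapply(shared, `[[`, character(1L), "gene_a"))
  free_b <- setdiff(names(pb), vapply(shared, `[[`, character(1L), "gene_b"))

  if (length(free_a) > 0L && length(free_b) > 0L) {
    scores <- matrix(NA_real_, length(free_a), length(free_b),
                     dimnames = list(free_a, free_b))
    idmat <- scores
    subj <- Biostrings::AAStringSet(pb[free_b])
    for (i in seq_along(free_a)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep(pa[[free_a[i]]], length(free_b))),
        subj, type = "global",
        substitutionMatrix = unit_aa_matrix(),
        gapOpening = 0, gapExtension = 1)
      scores[i, ] <- Biostrings::score(al)
      idmat[i, ] <- Biostrings::pid(al) / 100
    }
    best_for_a <- apply(scores, 1L, which.max)
    best_for_b <- apply(scores, 2L, which.max)
    for (i in seq_along(free_a)) {
      j <- best_for_a[i]
      if (best_for_b[j] == i && idmat[i, j] >= min_identity) {
        shared[[length(shared) + 1L]] <- data.frame(
          gene_a = free_a[i], gene_b = free_b[j], identity = idmat[i, j])
      }
    }
  }
  shared <- if (length(shared) > 0L) do.call(rbind, shared) else
    data.frame(gene_a = character(0), gene_b = character(0),
               identity = numeric(0))
  list(shared = shared,
       unique_to_a = setdiff(names(pa), shared$gene_a),
       unique_to_b = setdiff(names(pb), shared$gene_b))
}

#' Annotate a finished genome from a reference
#'
#' Convenience wrapper: collinear alignment, projection, curation.
#'
#' @param reference a `ref_genome`.
#' @param target_seq finished genome sequence.
#' @param k anchor k-mer size.
#' @return list with `models`, `events`, `flagged`, `alignment`.
#' @export
annotate_genome <- function(reference, target_seq, k = 17L) {
  target_seq <- if (is.character(target_seq)) target_seq else target_seq$seq
  al <- align_collinear(reference$seq, target_seq, k)
  proj <- project_annotation(reference, al, target_seq)
  cur <- curate_models(proj$models, target_seq, reference$models,
                       reference_seq = reference$seq)
  list(models = cur$models, events = cur$events, flagged = proj$flagged,
       alignment = al)
}
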