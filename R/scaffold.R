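# Synteny scaffolding: order and orient draft contigs against a collinear
# reference by unique k-mer anchors, then infer gap sizes from reference
# distance.  The reference is typically a related strain or species, so
# gap estimates are treated as estimates: downstream they cap, not
# dictate, extension length.

# all k-mers of x as a character vector (1-based start positions implied)
kmer_vector <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

# longest strictly increasing subsequence; returns indices
lis_indices <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  tails <- integer(0)     # indices of smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (v[tails[mid]] < v[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(0)
  i <- tails[length(tails)]
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

#' Anchor contigs on a collinear reference
#'
#' Places each contig by unique k-mer anchors: k-mers occurring exactly
#' once in the reference are matched against sampled contig k-mers on both
#' strands, anchors are chained collinearly (longest increasing
#' subsequence), and the placement offset is the median anchor diagonal.
#' Contigs whose anchors are predominantly non-monotone (rearranged) are
#' excluded rather than force-placed.
#'
#' @param contigs a `contig_set` or named character vector.
#' @param reference a `ref_genome` or sequence string.
#' @param k anchor k-mer size (default 17, unique with high probability in
#'   a sub-megabase AT-rich genome).
#' @param stride sample every `stride`-th contig k-mer as an anchor query.
#' @return list with `placements` (data.frame: contig_id, start, end,
#'   strand, identity, anchor_count) and `unplaced` (data.frame:
#'   contig_id, reason).
#' @export
anchor_contigs <- function(contigs, reference, k = 17L, stride = 7L) {
  seqs <- if (inherits(contigs, "contig_set")) contigs$contigs else contigs
  ref <- if (is.character(reference)) reference else reference$seq
  if (nchar(ref) < k) stop("reference shorter than k")
  if (length(seqs) == 0L) stop("no contigs supplied")
  if (k < 11L) stop("k must be >= 11")

  ref_kmers <- kmer_vector(ref, k)
  dup <- duplicated(ref_kmers) | duplicated(ref_kmers, fromLast = TRUE)
  uniq_kmers <- ref_kmers[!dup]
  uniq_pos <- which(!dup)

  placements <- list()
  unplaced <- list()
  for (ci in seq_along(seqs)) {
    cid <- names(seqs)[ci]
    cseq <- seqs[[ci]]
    n <- nchar(cseq)
    if (n < k) {
      unplaced[[length(unplaced) + 1L]] <-
        data.frame(contig_id = cid, reason = "shorter than k")
      next
    }
    qpos <- seq(1L, n - k + 1L, by = stride)
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") cseq else revcomp(cseq)
      qk <- substring(s, qpos, qpos + k - 1L)
      hit <- match(qk, uniq_kmers)
      ok <- !is.na(hit)
      if (!any(ok)) next
      rp <- uniq_pos[hit[ok]]
      cp <- qpos[ok]
      chain <- lis_indices(rp)   # anchors already in contig order
      cand <- list(strand = strand, n_anchor = length(chain),
                   n_match = length(rp),
                   diag = median(rp[chain] - cp[chain]))
      if (is.null(best) || cand$n_anchor > best$n_anchor) best <- cand
    }
    if (is.null(best) || best$n_anchor == 0L) {
      unplaced[[length(unplaced) + 1L]] <-
        data.frame(contig_id = cid, reason = "no unique anchors")
      next
    }
    if (best$n_anchor < 0.9 * best$n_match) {
      unplaced[[length(unplaced) + 1L]] <-
        data.frame(contig_id = cid, reason = "non-collinear anchor chain")
      next
    }
    start <- as.integer(round(best$diag)) + 1L
    end <- start + n - 1L
    oriented <- if (best$strand == "+") cseq else revcomp(cseq)
    ov_start <- max(1L, start)
    ov_end <- min(nchar(ref), end)
    identity <- NA_real_
    if (ov_end >= ov_start) {
      a <- substr(oriented, ov_start - start + 1L, ov_end - start + 1L)
      b <- substr(ref, ov_start, ov_end)
      identity <- 1 - length(mismatch_positions_cpp(a, b)) / nchar(a)
    }
    placements[[length(placements) + 1L]] <- data.frame(
      contig_id = cid, start = start, end = end, strand = best$strand,
      identity = identity, anchor_count = best$n_anchor,
      stringsAsFactors = FALSE
    )
  }
  list(
    placements = if (length(placements) > 0L) do.call(rbind, placements)
    else data.frame(contig_id = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    identity = numeric(0), anchor_count = integer(0)),
    unplaced = if (length(unplaced) > 0L) do.call(rbind, unplaced)
    else data.frame(contig_id = character(0), reason = character(0))
  )
}

#' Build a scaffold from contig placements
#'
#' Placements are ordered along the reference; a placement fully contained
#' in another is dropped with a warning; partial overlaps are trimmed at
#' the midpoint of the overlap; the estimated length of each inter-contig
#' gap is the reference distance between adjacent placed ends (0 when
#' abutting).
#'
#' @param placements placement data.frame from [anchor_contigs()].
#' @param reference_length reference length in bases.
#' @return a `scaffold`: list with `placements` (plus `trim_left`,
#'   `trim_right` columns, in oriented-contig bases) and `gaps`
#'   (upstream/downstream contig ids and `est_length`).
#' @export
build_scaffold <- function(placements, reference_length) {
  if (is.list(placements) && !is.data.frame(placements))
    placements <- placements$placements
  if (nrow(placements) == 0L) stop("no placements to scaffold")
  p <- placements[order(placements$start, -placements$end), , drop = FALSE]
  p$trim_left <- 0L
  p$trim_right <- 0L

  keep <- rep(TRUE, nrow(p))
  hi <- p$end[1L]
  for (i in seq_len(nrow(p))[-1L]) {
    if (p$end[i] <= hi) {
      keep[i] <- FALSE
      warning(sprintf("contig %s is contained in another placement; dropped",
                      p$contig_id[i]))
    } else hi <- max(hi, p$end[i])
  }
  p <- p[keep, , drop = FALSE]

  if (nrow(p) > 1L) {
    for (i in seq_len(nrow(p) - 1L)) {
      ov <- p$end[i] - p$start[i + 1L] + 1L
      if (ov > 0L) {
        cut_up <- ov %/% 2L
        cut_down <- ov - cut_up
        p$end[i] <- p$end[i] - cut_up
        p$trim_right[i] <- p$trim_right[i] + cut_up
        p$start[i + 1L] <- p$start[i + 1L] + cut_down
        p$trim_left[i + 1L] <- p$trim_left[i + 1L] + cut_down
      }
    }
  }

  gaps <- if (nrow(p) > 1L) {
    data.frame(
      gap_id = sprintf("gap_%03d", seq_len(nrow(p) - 1L)),
      upstream = p$contig_id[-nrow(p)],
      downstream = p$contig_id[-1L],
      est_length = pmax(0L, p$start[-1L] - p$end[-nrow(p)] - 1L),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(gap_id = character(0), upstream = character(0),
               downstream = character(0), est_length = integer(0))
  }
  rownames(p) <- NULL
  structure(list(placements = p, gaps = gaps,
                 reference_length = as.integer(reference_length)),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("<scaffold> %d contigs, %d gaps (est. %d bp) on %d bp reference\n",
              nrow(x$placements), nrow(x$gaps), sum(x$gaps$est_length),
              x$reference_length))
  invisible(x)
}

#' Write a scaffold as an AGP-like TSV
#'
#' Alternating component and gap rows: `object`, `part`, `kind`
#' (`contig`/`gap`), `id`, `orientation`, `length`.
#'
#' @param scaffold a `scaffold`.
#' @param contigs the `contig_set` (for component lengths).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_scaffold_tsv <- function(scaffold, contigs, path) {
  seqs <- if (inherits(contigs, "contig_set")) contigs$contigs else contigs
  p <- scaffold$placements
  rows <- list()
  for (i in seq_len(nrow(p))) {
    rows[[length(rows) + 1L]] <- data.frame(
      object = "scaffold_1", part = length(rows) + 1L, kind = "contig",
      id = p$contig_id[i], orientation = p$strand[i],
      length = nchar(seqs[[p$contig_id[i]]]))
    if (i < nrow(p)) {
      rows[[length(rows) + 1L]] <- data.frame(
        object = "scaffold_1", part = length(rows) + 1L, kind = "gap",
        id = scaffold$gaps$gap_id[i], orientation = ".",
        length = scaffold$gaps$est_length[i])
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
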