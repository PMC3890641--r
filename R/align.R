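# Collinear whole-genome alignment: unique shared k-mer anchors, longest
# monotone chain, global alignment of the interstitial segments.  The
# result is a set of gap-free aligned blocks (equal-length intervals in
# both genomes, mismatches allowed) with indels implied between blocks --
# the substrate for variant calling and annotation projection in genomes
# whose gene order is conserved.

unique_kmer_positions <- function(seq, k) {
  km <- kmer_vector(seq, k)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  list(kmers = km[!dup], pos = which(!dup))
}

# decompose a Biostrings global alignment into gap-free blocks
nw_blocks <- function(a, b, a_off, b_off) {
  if (nchar(a) == 0L && nchar(b) == 0L) return(NULL)
  if (nchar(a) == 0L || nchar(b) == 0L) return(NULL)  # pure indel, no blocks
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 3, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::subject(al)), "")[[1L]]
  ga <- pa == "-"
  gb <- pb == "-"
  apos <- cumsum(!ga)
  bpos <- cumsum(!gb)
  aligned <- !ga & !gb
  if (!any(aligned)) return(NULL)
  r <- rle(aligned)
  cend <- cumsum(r$lengths)
  cstart <- cend - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    a_start = a_off + apos[cstart[keep]],
    a_end = a_off + apos[cend[keep]],
    b_start = b_off + bpos[cstart[keep]],
    b_end = b_off + bpos[cend[keep]]
  )
}

#' Align two collinear genomes
#'
#' @param a,b genome sequences (strings or objects with `$seq`).
#' @param k anchor k-mer size.
#' @param full force a direct global alignment instead of anchor chaining
#'   (automatic for sequences shorter than `5 * k`; for large diverged
#'   genomes without shared unique k-mers this is the slow fallback the
#'   anchor error message points to).
#' @return a `collinear_alignment`: list with `blocks` (data.frame of
#'   gap-free aligned intervals, 1-based closed, equal lengths in both
#'   genomes), `a_len`, `b_len`, `anchors_used`.
#' @export
align_collinear <- function(a, b, k = 17L, full = FALSE) {
  a <- if (is.character(a)) a else a$seq
  b <- if (is.character(b)) b else b$seq
  if (!identical(a, b) && (full || min(nchar(a), nchar(b)) < 5L * k)) {
    blocks <- nw_blocks(a, b, 0L, 0L)
    if (is.null(blocks)) stop("sequences share no alignable blocks")
    out <- list(blocks = blocks, a_len = nchar(a), b_len = nchar(b),
                anchors_used = 0L)
    class(out) <- "collinear_alignment"
    return(out)
  }
  if (identical(a, b)) {
    out <- list(blocks = data.frame(a_start = 1L, a_end = nchar(a),
                                    b_start = 1L, b_end = nchar(b)),
                a_len = nchar(a), b_len = nchar(b), anchors_used = 0L)
    class(out) <- "collinear_alignment"
    return(out)
  }
  ua <- unique_kmer_positions(a, k)
  ub <- unique_kmer_positions(b, k)
  m <- match(ua$kmers, ub$kmers)
  ok <- !is.na(m)
  if (sum(ok) < 2L)
    stop(paste0("fewer than 2 unique shared k-mers; the genomes are too ",
                "diverged for anchor-based collinear alignment (a full ",
                "global alignment would be needed)"))
  pa <- ua$pos[ok]
  pb <- ub$pos[m[ok]]
  ord <- order(pa)
  pa <- pa[ord]; pb <- pb[ord]
  chain <- lis_indices(pb)
  if (length(chain) < 0.5 * length(pb))
    stop("anchor chain is non-monotone; genomes do not look collinear")
  pa <- pa[chain]; pb <- pb[chain]

  # merge anchors on a common diagonal into maximal gap-free runs
  diagd <- pb - pa
  newrun <- c(TRUE, diff(diagd) != 0L)
  run_id <- cumsum(newrun)
  runs <- data.frame(
    a_start = tapply(pa, run_id, min),
    a_end = tapply(pa, run_id, max) + k - 1L,
    b_start = tapply(pb, run_id, min),
    b_end = tapply(pb, run_id, max) + k - 1L
  )
  # successive same-diagonal runs can overlap via k-mer extent; also clip
  # runs so they never overlap the next anchor run
  blocks <- list()
  add_inter <- function(a1, a2, b1, b2) {
    # align a[a1..a2] vs b[b1..b2] (either may be empty)
    if (a2 < a1 && b2 < b1) return(NULL)
    if (a2 < a1 || b2 < b1) return(NULL)  # pure indel
    sa <- substr(a, a1, a2)
    sb <- substr(b, b1, b2)
    if (nchar(sa) == nchar(sb) && sa == sb)
      return(data.frame(a_start = a1, a_end = a2, b_start = b1, b_end = b2))
    nw_blocks(sa, sb, a1 - 1L, b1 - 1L)
  }

  prev_a <- 0L; prev_b <- 0L
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    # clip run start to stay past the previous block
    shift <- max(prev_a + 1L - r$a_start, prev_b + 1L - r$b_start, 0L)
    r$a_start <- r$a_start + shift
    r$b_start <- r$b_start + shift
    if (r$a_start > r$a_end) next
    blocks[[length(blocks) + 1L]] <-
      add_inter(prev_a + 1L, r$a_start - 1L, prev_b + 1L, r$b_start - 1L)
    blocks[[length(blocks) + 1L]] <- data.frame(
      a_start = r$a_start, a_end = r$a_end,
      b_start = r$b_start, b_end = r$b_end)
    prev_a <- r$a_end; prev_b <- r$b_end
  }
  blocks[[length(blocks) + 1L]] <-
    add_inter(prev_a + 1L, nchar(a), prev_b + 1L, nchar(b))
  blocks <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1L))])

  # merge adjacent blocks on the same diagonal
  if (nrow(blocks) > 1L) {
    merged <- blocks[1L, ]
    for (i in 2:nrow(blocks)) {
      last <- nrow(merged)
      if (blocks$a_start[i] == merged$a_end[last] + 1L &&
          blocks$b_start[i] == merged$b_end[last] + 1L) {
        merged$a_end[last] <- blocks$a_end[i]
        merged$b_end[last] <- blocks$b_end[i]
      } else {
        merged <- rbind(merged, blocks[i, ])
      }
    }
    blocks <- merged
  }
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, a_len = nchar(a), b_len = nchar(b),
                 anchors_used = length(chain)),
            class = "collinear_alignment")
}

#' @export
print.collinear_alignment <- function(x, ...) {
  cat(sprintf("<collinear_alignment> %d blocks over %d/%d bp (%d anchors)\n",
              nrow(x$blocks), x$a_len, x$b_len, x$anchors_used))
  invisible(x)
}

#' Map positions through a collinear alignment
#'
#' @param alignment a `collinear_alignment`.
#' @param pos positions in genome `a` (1-based).
#' @param snap how to resolve positions falling in an unaligned segment:
#'   `"none"` returns `NA`, `"left"`/`"right"` snap to the nearest aligned
#'   column on that side.
#' @return integer vector of positions in genome `b` (`NA` where
#'   unmappable).
#' @export
map_position <- function(alignment, pos, snap = c("none", "left", "right")) {
  snap <- match.arg(snap)
  bl <- alignment$blocks
  out <- rep(NA_integer_, length(pos))
  idx <- findInterval(pos, bl$a_start)
  for (i in seq_along(pos)) {
    j <- idx[i]
    if (j >= 1L && pos[i] <= bl$a_end[j]) {
      out[i] <- bl$b_start[j] + (pos[i] - bl$a_start[j])
    } else if (snap == "left" && j >= 1L) {
      out[i] <- bl$b_end[j]
    } else if (snap == "right" && j < nrow(bl)) {
      out[i] <- bl$b_start[j + 1L]
    }
  }
  out
}
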