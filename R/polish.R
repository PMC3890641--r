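# Coverage-based polishing: map short reads back to the assembly with a
# mismatch cap, find regions below the coverage threshold, excise each and
# re-derive it with the overlap-consensus extender anchored on its flanks
# (which fixes both wrong base calls and +-1 homopolymer indels inherited
# from the draft contigs), and emit a validation-candidate report in place
# of confirmatory resequencing.

#' Map reads to an assembly
#'
#' Indexed ungapped alignment with at most `max_mismatches` mismatches:
#' each read is assigned its unique best (fewest-mismatch) position on
#' either strand; equal-best ties are resolved uniformly at random with a
#' seeded RNG, MAQ-style, so every mapped read contributes to exactly one
#' position and the coverage sum rule stays exact.  The exact-seed index
#' uses pigeonhole seeds, so no placement within the mismatch cap is
#' missed for reads of 36 bp or more.
#'
#' @param assembly an `assembled_genome` or sequence string.
#' @param reads a `read_set`, FASTQ path, or character vector.
#' @param max_mismatches mismatch cap (default 3).
#' @param rng_seed seed for tie resolution.
#' @param circular map across the origin of a circular assembly.
#' @return list with `mapping` (data.frame: pos, forward, mismatches,
#'   n_best; `pos` is `NA` for unmapped reads) and `profile` (a
#'   `coverage_profile`: per-site `depth`, `mean_depth`, `mapped_bases`,
#'   `n_mapped`, `n_reads`).
#' @export
map_reads <- function(assembly, reads, max_mismatches = 3L, rng_seed = 1L,
                      circular = FALSE) {
  seq <- if (is.character(assembly)) assembly else assembly$seq
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  res <- map_reads_cpp(toupper(seq), toupper(seqs),
                       as.integer(max_mismatches), as.integer(rng_seed),
                       isTRUE(circular))
  profile <- structure(list(depth = res$depth,
                            mean_depth = mean(res$depth),
                            mapped_bases = res$mapped_bases,
                            n_mapped = res$n_mapped,
                            n_reads = length(seqs),
                            circular = isTRUE(circular)),
                       class = "coverage_profile")
  mapping <- data.frame(pos = res$pos, forward = res$forward,
                        mismatches = res$mismatches, n_best = res$n_best)
  list(mapping = mapping, profile = profile)
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d sites, mean depth %.1fx (%d/%d reads mapped)\n",
              length(x$depth), x$mean_depth, x$n_mapped, x$n_reads))
  invisible(x)
}

#' Find low-coverage regions
#'
#' Maximal intervals where depth falls below the threshold, each padded by
#' one seed length on both sides so the refill has anchored flanks;
#' padded intervals that touch are merged.
#'
#' @param profile a `coverage_profile` (or depth vector).
#' @param threshold coverage threshold in fold (default 21: regions below
#'   21x are treated as unreliable).
#' @param pad flank padding in bases (default 30, one seed length).
#' @return data.frame with `start`, `end` (1-based closed).
#' @export
find_low_coverage <- function(profile, threshold = 21, pad = 30L) {
  depth <- if (inherits(profile, "coverage_profile")) profile$depth else profile
  low <- depth < threshold
  if (!any(low)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ir <- IRanges::IRanges(starts[r$values], ends[r$values])
  ir <- IRanges::reduce(ir + pad)
  ir <- IRanges::restrict(ir, start = 1L, end = length(depth))
  data.frame(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
}

#' Excise and refill low-coverage regions
#'
#' Each region is removed from the assembly and re-derived with
#' [extend_consensus()] anchored on its flanks.  A successful refill
#' replaces the region (handling substitutions and +-1 homopolymer indels
#' alike); failures leave the sequence unchanged and are recorded as
#' unresolved.  Use a fresh repository built from all reads: the
#' destructive read consumption of gap filling applies within a single
#' pass, not across pipeline stages.
#'
#' @param assembly an `assembled_genome` or sequence string.
#' @param regions data.frame from [find_low_coverage()].
#' @param repo a fresh `read_repository` (mutated).
#' @param params a [gapfill_params()].
#' @param profile optional `coverage_profile` for depth bookkeeping.
#' @param flank flank length used as anchors (bases).
#' @return list with `assembly` (corrected sequence string) and `records`
#'   (data.frame of `CorrectionRecord`s: start, end, action, before,
#'   after, depth_before).
#' @export
correct_errors <- function(assembly, regions, repo, params = gapfill_params(),
                           profile = NULL, flank = 600L) {
  seq <- if (is.character(assembly)) assembly else assembly$seq
  L <- nchar(seq)
  records <- list()
  if (nrow(regions) > 0L) {
    regions <- regions[order(regions$start, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(regions))) {
      # clip to valid coordinates
      rs <- max(1L, regions$start[i])
      re <- min(L, regions$end[i])
      before <- substr(seq, rs, re)
      depth_before <- if (!is.null(profile))
        mean(profile$depth[rs:min(re, length(profile$depth))]) else NA_real_
      up <- substr(seq, max(1L, rs - flank), rs - 1L)
      down <- substr(seq, re + 1L, min(L, re + flank))
      rec <- data.frame(start = rs, end = re, action = "unresolved",
                        before = before, after = before,
                        depth_before = depth_before,
                        stringsAsFactors = FALSE)
      if (nchar(up) >= params$seed_length &&
          nchar(down) >= params$termination_overlap &&
          !grepl("[^ACGT]", up) && !grepl("[^ACGT]", down)) {
        res <- extend_consensus(up, down, repo, params,
                                gap_estimate = re - rs + 1L)
        if (res$status == "closed") {
          grown <- paste0(up, res$extension)
          new_mid <- paste0(substr(grown, 1L,
                                   nchar(grown) - params$termination_overlap),
                            down)
          after <- substr(new_mid, nchar(up) + 1L - res$upstream_trim,
                          nchar(new_mid) - nchar(down))
          # note: if the refill trims into the upstream flank the region
          # boundary moves left by upstream_trim bases
          new_rs <- rs - res$upstream_trim
          seq <- splice_string(seq, new_rs, re, after)
          rec$action <- if (nchar(after) == re - new_rs + 1L) "substituted"
          else "refilled"
          rec$after <- after
        }
      }
      records[[length(records) + 1L]] <- rec
      L <- nchar(seq)
    }
  }
  records <- if (length(records) > 0L) {
    out <- do.call(rbind, records)
    out[order(out$start), , drop = FALSE]
  } else {
    data.frame(start = integer(0), end = integer(0), action = character(0),
               before = character(0), after = character(0),
               depth_before = numeric(0))
  }
  rownames(records) <- NULL
  list(assembly = seq, records = records)
}

#' Iterative polishing to convergence
#'
#' Runs map -> find-low-coverage -> excise-and-refill rounds (a fresh
#' repository per round) until no low-coverage interval remains or
#' `max_rounds` is reached.
#'
#' @param assembly an `assembled_genome` or sequence string.
#' @param reads a `read_set` (all reads; repositories are rebuilt fresh).
#' @param threshold coverage threshold (default 21).
#' @param max_mismatches mapping mismatch cap (default 3).
#' @param params a [gapfill_params()].
#' @param max_rounds maximum correction rounds (default 3).
#' @param rng_seed seed for mapping tie resolution.
#' @param circular treat the assembly as circular when mapping.
#' @return list with `assembly` (final sequence), `records` (all
#'   correction records), `rounds` (rounds run), `profile` (final
#'   `coverage_profile`), `remaining` (low-coverage intervals left).
#' @export
polish_assembly <- function(assembly, reads, threshold = 21,
                            max_mismatches = 3L, params = gapfill_params(),
                            max_rounds = 3L, rng_seed = 1L, circular = FALSE) {
  seq <- if (is.character(assembly)) assembly else assembly$seq
  all_records <- list()
  rounds <- 0L
  repeat {
    m <- map_reads(seq, reads, max_mismatches, rng_seed + rounds, circular)
    regions <- find_low_coverage(m$profile, threshold, params$seed_length)
    if (nrow(regions) == 0L || rounds >= max_rounds) break
    rounds <- rounds + 1L
    repo <- build_repository(reads, params$seed_length, params$max_seed_mismatches)
    cr <- correct_errors(seq, regions, repo, params, m$profile)
    all_records[[rounds]] <- cr$records
    if (identical(cr$assembly, seq)) { seq <- cr$assembly; m <- map_reads(seq, reads, max_mismatches, rng_seed + rounds, circular); regions <- find_low_coverage(m$profile, threshold, params$seed_length); break }
    seq <- cr$assembly
  }
  records <- if (length(all_records) > 0L) do.call(rbind, all_records) else
    data.frame(start = integer(0), end = integer(0), action = character(0),
               before = character(0), after = character(0),
               depth_before = numeric(0))
  list(assembly = seq, records = records, rounds = rounds,
       profile = m$profile, remaining = regions)
}

#' Flag corrected and unresolved regions for external validation
#'
#' Replaces confirmatory resequencing with a machine-readable candidate
#' list: every refilled/substituted/unresolved region with flanking
#' windows suitable for primer design.
#'
#' @param records correction records from [correct_errors()].
#' @param profile a `coverage_profile` (for the assembly length).
#' @param flank flank window size in bases (default 500).
#' @return data.frame: start, end, action, flank_left_start,
#'   flank_left_end, flank_right_start, flank_right_end, depth_before.
#' @export
flag_for_validation <- function(records, profile, flank = 500L) {
  L <- length(profile$depth)
  data.frame(
    start = records$start, end = records$end, action = records$action,
    flank_left_start = pmax(1L, records$start - flank),
    flank_left_end = pmax(1L, records$start - 1L),
    flank_right_start = pmin(L, records$end + 1L),
    flank_right_end = pmin(L, records$end + flank),
    depth_before = records$depth_before,
    stringsAsFactors = FALSE
  )
}

#' Write a coverage profile as bedGraph-style TSV
#'
#' @param profile a `coverage_profile`.
#' @param path output path.
#' @param seqname sequence name for column 1.
#' @return invisibly, `path`.
#' @export
write_coverage_tsv <- function(profile, path, seqname = "assembly") {
  r <- rle(profile$depth)
  ends <- cumsum(r$lengths)
  df <- data.frame(seq = seqname, start = ends - r$lengths, end = ends,
                   depth = r$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
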