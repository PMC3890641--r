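# Overlap-consensus gap filling.  A repository holds every read and its
# reverse complement as a linked pair; extension recruits active reads
# whose 30 bp window matches the terminal seed within a mismatch
# tolerance, records the base following each matched window, appends the
# majority base, consumes the contributing reads (and their complements),
# and repeats until the growing sequence reaches the head of the
# downstream contig.

#' Gap-filling parameters
#'
#' @param seed_length seed window length in bases (default 30).
#' @param max_seed_mismatches mismatches tolerated in seed and termination
#'   matching (default 2).
#' @param min_depth minimum number of recorded bases required to extend.
#' @param max_extension hard cap on extension length; `NULL` applies the
#'   per-gap rule `2 * gap_estimate + 500`.
#' @param termination_overlap bases of overlap with the downstream contig
#'   that close a gap (default 30).
#' @return a `gapfill_params` list.
#' @export
gapfill_params <- function(seed_length = 30L, max_seed_mismatches = 2L,
                           min_depth = 1L, max_extension = NULL,
                           termination_overlap = 30L) {
  stopifnot(seed_length > 0L, max_seed_mismatches >= 0L, min_depth >= 0L,
            termination_overlap > 0L)
  structure(list(seed_length = as.integer(seed_length),
                 max_seed_mismatches = as.integer(max_seed_mismatches),
                 min_depth = as.integer(min_depth),
                 max_extension = if (is.null(max_extension)) NULL
                 else as.integer(max_extension),
                 termination_overlap = as.integer(termination_overlap)),
            class = "gapfill_params")
}

#' Build a consumable read repository
#'
#' Enters every read and its reverse complement as a linked pair (a
#' palindromic read is stored once, self-paired) and indexes all
#' substrings for seed queries with mismatches.  Reads shorter than the
#' seed length are excluded, with the count recorded.
#'
#' @param reads a `read_set`, FASTQ path, or character vector of reads.
#' @param seed_length seed length the repository will serve (default 30).
#' @param max_seed_mismatches mismatch tolerance it must support.
#' @return a `read_repository` (stateful: extension consumes reads).
#' @export
build_repository <- function(reads, seed_length = 30L, max_seed_mismatches = 2L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  if (length(seqs) == 0L) stop("no reads supplied")
  short <- nchar(seqs) < seed_length
  n_excluded <- sum(short)
  seqs <- seqs[!short]
  if (length(seqs) == 0L) stop("all reads are shorter than the seed length")
  q <- max(1L, seed_length %/% (max_seed_mismatches + 1L))
  ptr <- repo_build_cpp(toupper(seqs), q)
  structure(list(ptr = ptr, n_reads = length(seqs),
                 n_excluded = as.integer(n_excluded), q = q,
                 seed_length = as.integer(seed_length)),
            class = "read_repository")
}

#' Repository status
#'
#' @param repo a `read_repository`.
#' @return list with `n_pairs`, `n_oriented`, `n_active` (oriented
#'   sequences still available).
#' @export
repository_status <- function(repo) {
  stopifnot(inherits(repo, "read_repository"))
  repo_status_cpp(repo$ptr)
}

#' @export
print.read_repository <- function(x, ...) {
  s <- repo_status_cpp(x$ptr)
  cat(sprintf("<read_repository> %d reads (%d oriented, %d active; %d excluded as short)\n",
              s$n_pairs, s$n_oriented, s$n_active, x$n_excluded))
  invisible(x)
}

#' Query the repository index
#'
#' Returns the (1-based) oriented-sequence indices of active entries
#' containing a window that matches `seed` with at most `max_mismatches`
#' mismatches.  Mainly used to verify the index against brute force.
#'
#' @param repo a `read_repository`.
#' @param seed query sequence (at least the repository seed length).
#' @param max_mismatches mismatch tolerance.
#' @return integer vector of oriented indices.
#' @export
query_repository <- function(repo, seed, max_mismatches = 2L) {
  stopifnot(inherits(repo, "read_repository"))
  repo_query_cpp(repo$ptr, toupper(seed), as.integer(max_mismatches))
}

# seed selection: terminal window, sliding inward past low-quality bases
# (quality is synthetic in testing; the slide trims the upstream tail so
# extension restarts from the chosen window)
choose_seed_offset <- function(upstream, quality = NULL, seed_length = 30L,
                               max_slide = 20L, min_q = 20L) {
  n <- nchar(upstream)
  if (is.null(quality)) return(0L)
  qv <- utf8ToInt(quality) - 33L
  for (s in 0:max_slide) {
    win <- (n - s - seed_length + 1L):(n - s)
    if (win[1L] < 1L) break
    if (all(qv[win] >= min_q)) return(s)
  }
  0L
}

#' Extend across a gap by overlap consensus
#'
#' Implements the extension loop: the seed is the terminal
#' `seed_length`-mer of the growing sequence (initially the upstream
#' contig's 3' end); every active repository sequence containing a window
#' matching the seed within `max_seed_mismatches` and having at least one
#' following base records that base; the strict-majority base is appended
#' and contributing reads (with their complements) are consumed; the gap
#' closes when the tail of the growing sequence matches the downstream
#' contig's head within the same tolerance, and the downstream contig's
#' bases win in the merged overlap.  Ties and read exhaustion abort with
#' the corresponding status.
#'
#' This call mutates `repo` (consumed reads stay consumed).
#'
#' @param upstream,downstream flanking sequences (A/C/G/T only).
#' @param repo a `read_repository`.
#' @param params a [gapfill_params()].
#' @param gap_estimate estimated gap length in bases (caps extension at
#'   `2 * gap_estimate + 500` unless `params$max_extension` is set).
#' @param upstream_quality optional quality string for seed selection.
#' @return a `gapfill_result`: `status` (`closed`, `no_reads`,
#'   `ambiguous_tie`, `cap_exceeded`), `extension` (bases appended),
#'   `filled_sequence` (net new sequence between the contigs after overlap
#'   merging), `upstream_trim`, `per_base_support`, `reads_consumed`, and
#'   on closure `join` (upstream + fill + downstream).
#' @export
extend_consensus <- function(upstream, downstream, repo, params = gapfill_params(),
                             gap_estimate = 0L, upstream_quality = NULL) {
  stopifnot(inherits(repo, "read_repository"))
  upstream <- toupper(upstream)
  downstream <- toupper(downstream)
  if (grepl("[^ACGT]", upstream) || grepl("[^ACGT]", downstream))
    stop("contig sequences must contain only A/C/G/T")
  slide <- choose_seed_offset(upstream, upstream_quality, params$seed_length)
  if (slide > 0L) upstream <- substr(upstream, 1L, nchar(upstream) - slide)
  cap <- if (is.null(params$max_extension))
    2L * as.integer(gap_estimate) + 500L else params$max_extension
  res <- repo_extend_cpp(repo$ptr, upstream, downstream,
                         params$seed_length, params$max_seed_mismatches,
                         params$min_depth, cap, params$termination_overlap)
  ext <- res$extension
  out <- list(status = res$status, extension = ext,
              per_base_support = res$support,
              reads_consumed = res$reads_consumed,
              seed_slide = slide, gap_estimate = as.integer(gap_estimate))
  if (res$status == "closed") {
    term <- params$termination_overlap
    grown <- paste0(upstream, ext)
    keep <- nchar(grown) - term
    out$filled_sequence <- if (nchar(ext) >= term)
      substr(ext, 1L, nchar(ext) - term) else ""
    out$upstream_trim <- max(0L, term - nchar(ext))
    out$join <- paste0(substr(grown, 1L, keep), downstream)
  } else {
    out$filled_sequence <- NA_character_
    out$upstream_trim <- 0L
    out$join <- NA_character_
  }
  class(out) <- "gapfill_result"
  out
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat(sprintf("<gapfill_result> status=%s, extension=%d bp, reads consumed=%d\n",
              x$status, nchar(x$extension), x$reads_consumed))
  invisible(x)
}

#' Fill every gap in a scaffold
#'
#' Processes gaps in scaffold order against a shared (consumable)
#' repository.  Closed gaps are merged into the growing assembly; unclosed
#' gaps are represented as a run of `N` of the estimated length.
#'
#' @param scaffold a `scaffold`.
#' @param contigs the `contig_set` (or named vector) the scaffold places.
#' @param repo a `read_repository` (mutated: reads are consumed).
#' @param params a [gapfill_params()].
#' @return list with `assembly` (an `assembled_genome`: `seq` plus the gap
#'   `report`) and `report` (one row per gap: gap_id, status,
#'   length_filled, reads_consumed, min_support).
#' @export
fill_all_gaps <- function(scaffold, contigs, repo, params = gapfill_params()) {
  stopifnot(inherits(scaffold, "scaffold"))
  seqs <- if (inherits(contigs, "contig_set")) contigs$contigs else contigs
  p <- scaffold$placements
  miss <- setdiff(p$contig_id, names(seqs))
  if (length(miss) > 0L)
    stop("scaffold places unknown contigs: ", paste(miss, collapse = ", "))

  oriented <- function(i) {
    s <- seqs[[p$contig_id[i]]]
    if (p$strand[i] == "-") s <- revcomp(s)
    substr(s, 1L + p$trim_left[i], nchar(s) - p$trim_right[i])
  }

  assembly <- oriented(1L)
  report <- list()
  for (i in seq_len(nrow(scaffold$gaps))) {
    g <- scaffold$gaps[i, ]
    down <- oriented(i + 1L)
    tail_len <- min(nchar(assembly), 2000L)
    up_tail <- substr(assembly, nchar(assembly) - tail_len + 1L, nchar(assembly))
    res <- extend_consensus(up_tail, down, repo, params,
                            gap_estimate = g$est_length)
    if (res$status == "closed") {
      prefix <- substr(assembly, 1L, nchar(assembly) - tail_len)
      assembly <- paste0(prefix, res$join)
      filled <- nchar(res$filled_sequence)
    } else {
      assembly <- paste0(assembly, strrep("N", max(1L, g$est_length)), down)
      filled <- NA_integer_
    }
    report[[i]] <- data.frame(
      gap_id = g$gap_id, status = res$status,
      length_filled = filled,
      extension_length = nchar(res$extension),
      reads_consumed = res$reads_consumed,
      min_support = if (length(res$per_base_support) > 0L)
        min(res$per_base_support) else NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  report <- if (length(report) > 0L) do.call(rbind, report) else
    data.frame(gap_id = character(0), status = character(0),
               length_filled = integer(0), extension_length = integer(0),
               reads_consumed = integer(0), min_support = integer(0))
  assembly_obj <- structure(list(seq = assembly, report = report),
                            class = "assembled_genome")
  list(assembly = assembly_obj, report = report)
}

#' @export
print.assembled_genome <- function(x, ...) {
  closed <- sum(x$report$status == "closed")
  cat(sprintf("<assembled_genome> %d bp; %d/%d gaps closed\n",
              nchar(x$seq), closed, nrow(x$report)))
  invisible(x)
}

#' Write the per-gap report
#'
#' @param report gap report data.frame from [fill_all_gaps()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_gap_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
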