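# Low-level sequence helpers shared across the pipeline.  Sequences are
# plain uppercase character scalars; Biostrings is used where its C code
# wins (reverse complement of large sets, sliding windows, translation
# tables).

BASES <- c("A", "C", "G", "T")

# bacterial/archaeal translation table, fetched once
genetic_code_11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

START_CODONS <- c("ATG", "GTG", "TTG", "ATT")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#'
#' @param x character scalar (A/C/G/T/N).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  revcomp_cpp(x)
}

#' G+C fraction of a DNA string
#'
#' @param x character scalar.
#' @return fraction in \[0, 1\]; `NaN` for an empty string.
#' @export
gc_fraction <- function(x) {
  if (nchar(x) == 0L) return(NaN)
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(x), baseOnly = TRUE)
  acgt <- sum(f[c("A", "C", "G", "T")])
  if (acgt == 0L) return(NaN)
  unname((f[["G"]] + f[["C"]]) / acgt)
}

# split a coding sequence into codons
codons_of <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

#' Translate a CDS under bacterial translation table 11
#'
#' The first codon is rendered as methionine when it is one of the
#' recognised initiation codons (ATG/GTG/TTG/ATT).
#'
#' @param x in-frame coding sequence (length divisible by 3).
#' @param as_start treat the first codon as an initiator.
#' @return amino-acid string; stops are `*`.
#' @export
translate11 <- function(x, as_start = TRUE) {
  cod <- codons_of(toupper(x))
  if (length(cod) == 0L) return("")
  aa <- unname(genetic_code_11()[cod])
  aa[is.na(aa)] <- "X"
  if (as_start && cod[1L] %in% START_CODONS) aa[1L] <- "M"
  paste(aa, collapse = "")
}

#' Locate homopolymer runs
#'
#' @param x DNA string.
#' @param min_len minimum run length reported.
#' @param bases which bases count (default A and T, the runs that matter in
#'   AT-rich genomes).
#' @return data.frame with `start`, `end` (1-based closed), `base`, `length`.
#' @export
homopolymer_runs <- function(x, min_len = 8L, bases = c("A", "T")) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len & r$values %in% bases
  data.frame(
    start = (ends - r$lengths + 1L)[keep],
    end = ends[keep],
    base = r$values[keep],
    length = r$lengths[keep],
    stringsAsFactors = FALSE
  )
}

# random DNA of length n with a target GC fraction
random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Sampling codons by rejection of stop codons enriches G+C slightly (the
# stops are AT-rich).  Solve for the per-base G+C probability whose
# post-rejection expectation hits the target.
solve_codon_gc <- function(target) {
  f <- function(p) {
    pa <- (1 - p) / 2
    pg <- p / 2
    p_taa <- pa^3
    p_tag <- pa^2 * pg
    p_stop <- p_taa + 2 * p_tag
    egc <- (3 * p - 2 * p_tag) / (1 - p_stop) / 3
    egc - target
  }
  uniroot(f, c(1e-4, 0.999), tol = 1e-9)$root
}

# n_codons random non-stop codons at an effective base composition
random_codons <- function(n_codons, p_gc) {
  if (n_codons <= 0L) return(character(0))
  out <- character(n_codons)
  need <- seq_len(n_codons)
  while (length(need) > 0L) {
    cand <- paste0(
      sample(BASES, length(need), TRUE, c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2)),
      sample(BASES, length(need), TRUE, c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2)),
      sample(BASES, length(need), TRUE, c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2))
    )
    ok <- !(cand %in% STOP_CODONS)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

# draw one element of x (safe for length-1 vectors, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

# substring replacement that tolerates insertions/deletions
splice_string <- function(x, start, end, replacement) {
  # replace x[start..end] (1-based closed; end = start-1 inserts before start)
  paste0(substr(x, 1L, start - 1L), replacement,
         substr(x, end + 1L, nchar(x)))
}
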