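# Read mapping, coverage accounting, and excise-and-refill correction.

test_that("mapper places exact and mutated reads per the mismatch cap", {
  st <- small_strain()
  g <- substr(st$seq, 1L, 5000L)
  exact <- substr(g, 1001L, 1036L)
  m <- map_reads(g, exact)
  expect_identical(m$mapping$pos, 1001L)
  expect_identical(m$mapping$mismatches, 0L)
  expect_true(m$mapping$forward)

  # reverse-complement read maps to the same interval on the minus strand
  m2 <- map_reads(g, revcomp(exact))
  expect_identical(m2$mapping$pos, 1001L)
  expect_false(m2$mapping$forward)

  # 4 substitutions exceed the <=3 rule
  r4 <- exact
  for (p in c(3L, 12L, 21L, 30L)) {
    old <- substr(r4, p, p)
    substr(r4, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  }
  m3 <- map_reads(g, r4)
  expect_true(is.na(m3$mapping$pos))
  r3 <- exact
  for (p in c(3L, 12L, 21L)) {
    old <- substr(r3, p, p)
    substr(r3, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  }
  expect_identical(map_reads(g, r3)$mapping$mismatches, 3L)
})

test_that("coverage sum rule holds exactly and empty input is fine", {
  st <- small_strain()
  g <- substr(st$seq, 1L, 5000L)
  reads <- simulate_reads(g, coverage = 30, error_rate = 0.01, seed = 3L,
                          circular = FALSE)
  m <- map_reads(g, reads)
  expect_identical(sum(m$profile$depth), as.integer(m$profile$mapped_bases))
  expect_identical(m$profile$mapped_bases, 36 * m$profile$n_mapped)
  m0 <- map_reads(g, character(0))
  expect_identical(sum(m0$profile$depth), 0L)
})

test_that("indexed mapper agrees with a Biostrings brute-force scanner", {
  st <- small_strain()
  g <- substr(st$seq, 2001L, 7000L)
  reads <- simulate_reads(g, coverage = 15, error_rate = 0.01, seed = 17L,
                          circular = FALSE)
  m <- map_reads(g, reads)
  gd <- Biostrings::DNAString(g)
  for (i in seq_along(reads$reads)) {
    r <- reads$reads[i]
    hits_f <- Biostrings::matchPattern(r, gd, max.mismatch = 3L)
    hits_r <- Biostrings::matchPattern(revcomp(r), gd, max.mismatch = 3L)
    mm_of <- function(hits, q) vapply(seq_along(hits), function(j)
      sum(strsplit(as.character(hits[[j]]), "")[[1L]] !=
            strsplit(q, "")[[1L]]), integer(1L))
    best <- Inf; starts <- integer(0)
    if (length(hits_f) > 0L) {
      mmf <- mm_of(hits_f, r)
      best <- min(best, min(mmf))
    }
    if (length(hits_r) > 0L) {
      mmr <- mm_of(hits_r, revcomp(r))
      best <- min(best, min(mmr))
    }
    if (is.infinite(best)) {
      expect_true(is.na(m$mapping$pos[i]))
    } else {
      if (length(hits_f) > 0L)
        starts <- c(starts, BiocGenerics::start(hits_f)[mmf == best])
      if (length(hits_r) > 0L)
        starts <- c(starts, BiocGenerics::start(hits_r)[mmr == best])
      expect_identical(m$mapping$mismatches[i], as.integer(best))
      expect_true(m$mapping$pos[i] %in% starts)
      expect_identical(m$mapping$n_best[i], length(unique(
        paste(starts, c(rep("f", sum(if (length(hits_f) > 0L) mmf == best else 0)),
                        rep("r", sum(if (length(hits_r) > 0L) mmr == best else 0)))))))
    }
  }
})

test_that("find_low_coverage returns padded maximal intervals", {
  prof <- c(30, 30, 5, 5, 30)
  r <- find_low_coverage(prof, threshold = 21, pad = 0L)
  expect_identical(r, data.frame(start = 3L, end = 4L))
  # padding merges nearby dips
  prof2 <- c(rep(30, 50), rep(5, 3), rep(30, 10), rep(5, 3), rep(30, 50))
  r2 <- find_low_coverage(prof2, threshold = 21, pad = 10L)
  expect_identical(nrow(r2), 1L)
  expect_identical(find_low_coverage(rep(200, 100), threshold = 21),
                   data.frame(start = integer(0), end = integer(0)))
})

test_that("excise-and-refill fixes a single-base homopolymer deletion", {
  st <- small_strain()
  runs <- homopolymer_runs(st$seq, min_len = 10L)
  runs <- runs[runs$start > 2000L & runs$end < nchar(st$seq) - 2000L, ]
  r <- runs[1L, ]
  broken <- endofinish:::splice_string(st$seq, r$start, r$start, "")
  reads <- simulate_reads(st, coverage = 200, error_rate = 0, seed = 5L)
  repo <- build_repository(reads)
  region <- data.frame(start = r$start - 30L, end = r$end + 30L)
  out <- correct_errors(broken, region, repo)
  expect_identical(out$assembly, st$seq)
  expect_identical(out$records$action, "refilled")

  # no low-coverage regions: assembly returned byte-identical
  out2 <- correct_errors(st$seq, data.frame(start = integer(0), end = integer(0)),
                         build_repository(reads))
  expect_identical(out2$assembly, st$seq)
  # region with zero matching reads -> unresolved, unchanged
  empty_repo <- build_repository("ACGTTGCAACGTTGCAACGTTGCAACGTTGCA")
  out3 <- correct_errors(st$seq, data.frame(start = 5000L, end = 5050L),
                         empty_repo)
  expect_identical(out3$records$action, "unresolved")
  expect_identical(out3$assembly, st$seq)
})

test_that("multi-base corruption is detected at <21x and repaired end to end", {
  st <- small_strain()
  runs <- homopolymer_runs(st$seq, min_len = 9L)
  runs <- runs[runs$start > 3000L & runs$end < nchar(st$seq) - 3000L, ]
  # corrupt two tracts the way a bad draft consensus would: garble the
  # run and its flanks so short reads cannot map across
  broken <- st$seq
  for (i in c(1L, 3L)) {
    r <- runs[i, ]
    set.seed(100L + i)
    garble <- endofinish:::random_dna(25L, 0.5)
    broken <- endofinish:::splice_string(broken, r$start - 5L, r$start + 19L,
                                         garble)
  }
  reads <- simulate_reads(st, coverage = 200, error_rate = 0, seed = 6L)
  res <- polish_assembly(broken, reads, threshold = 21, circular = TRUE)
  expect_identical(res$assembly, st$seq)
  expect_lte(res$rounds, 3L)
  expect_identical(nrow(res$remaining), 0L)
})

test_that("polishing a correct assembly is a no-op (idempotence)", {
  st <- small_strain()
  reads <- simulate_reads(st, coverage = 200, error_rate = 0, seed = 8L)
  res <- polish_assembly(st$seq, reads, threshold = 21, circular = TRUE)
  expect_identical(res$assembly, st$seq)
  expect_identical(res$rounds, 0L)
  expect_identical(nrow(res$records), 0L)
  # threshold 0: nothing is ever low-coverage
  expect_identical(nrow(find_low_coverage(res$profile, threshold = 0)), 0L)
})

test_that("validation report lists corrections with primer flanks", {
  prof <- structure(list(depth = rep(100L, 4000L)), class = "coverage_profile")
  recs <- data.frame(start = 1000L, end = 1050L, action = "unresolved",
                     before = "x", after = "x", depth_before = 3)
  v <- flag_for_validation(recs, prof)
  expect_identical(nrow(v), 1L)
  expect_identical(v$flank_left_start, 500L)
  expect_identical(v$flank_right_end, 1550L)
  v0 <- flag_for_validation(recs[0L, ], prof)
  expect_identical(nrow(v0), 0L)
  expect_true(all(c("start", "end", "action") %in% names(v0)))
})
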