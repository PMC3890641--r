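# Standard-format I/O.  FASTA/FASTQ go through Biostrings, GFF3 through
# rtracklayer; GenBank flat files get a minimal reader of our own (no
# installed R package parses them), covering LOCUS/FEATURES/ORIGIN with
# complement() and join() locations -- enough to ingest a deposited
# bacterial chromosome record.

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads of unexpected length are kept, with a warning naming how many
#' deviate (downstream stages that need a fixed read length will simply
#' skip reads too short to index).
#'
#' @param path file path.
#' @param expected_length optional read length to check against.
#' @return a `read_set`: list with `reads`, `ids`, `quality`.
#' @export
read_fastq <- function(path, expected_length = NULL) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  reads <- toupper(as.character(x))
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  ids <- sub("\\s.*$", "", names(x))
  if (!is.null(expected_length)) {
    off <- sum(nchar(reads) != expected_length)
    if (off > 0L)
      warning(sprintf("%d of %d reads differ from the expected length %d",
                      off, length(reads), expected_length))
  }
  structure(list(reads = unname(reads), ids = ids, quality = unname(qual),
                 read_length = as.integer(round(mean(nchar(reads))))),
            class = "read_set")
}

#' Write reads to FASTQ
#'
#' @param reads a `read_set` (from [simulate_reads()] or [read_fastq()]) or a
#'   character vector of read sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "read_set")) {
    seqs <- reads$reads
    qual <- reads$quality
    ids <- reads$ids
  } else {
    seqs <- reads
    qual <- NULL
    ids <- NULL
  }
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("read_%07d", seq_len(n))
  if (is.null(qual)) qual <- strrep("I", nchar(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities =
                                Biostrings::BStringSet(qual))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models <-> GFF3.  Models are data.frames with columns gene_id, start,
# end (1-based closed), strand, type, product, segment.  Dual reading-frame
# models occupy two rows sharing gene_id (segment 1 and 2) and are written
# as two CDS features with the same ID and a polyA_merge=true attribute.
# ---------------------------------------------------------------------------

empty_models <- function() {
  data.frame(gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), type = character(0),
             product = character(0), segment = integer(0),
             stringsAsFactors = FALSE)
}

check_models <- function(models) {
  need <- c("gene_id", "start", "end", "strand", "type")
  miss <- setdiff(need, names(models))
  if (length(miss) > 0L)
    stop("models lack required columns: ", paste(miss, collapse = ", "))
  if (is.null(models$product)) models$product <- ""
  if (is.null(models$segment)) models$segment <- 1L
  stopifnot(all(models$start <= models$end),
            all(models$strand %in% c("+", "-")))
  models
}

# per-row phase of CDS segments (relevant for segment 2 of merged models)
segment_phase <- function(models) {
  phase <- integer(nrow(models))
  for (g in unique(models$gene_id)) {
    i <- which(models$gene_id == g)
    if (length(i) < 2L) next
    i <- i[order(models$segment[i])]
    len1 <- models$end[i[1L]] - models$start[i[1L]] + 1L
    phase[i[2L]] <- (3L - (len1 %% 3L)) %% 3L
  }
  phase
}

#' Write gene models to GFF3
#'
#' @param models model data.frame (see [read_gff3()] for the schema).
#' @param path output path.
#' @param seqname sequence name for column 1.
#' @param seqlen optional sequence length for the region directive.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(models, path, seqname = "chr", seqlen = NULL) {
  models <- check_models(models)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(models$start, models$end),
    strand = models$strand
  )
  merged <- models$gene_id %in% models$gene_id[duplicated(models$gene_id)]
  S4Vectors::mcols(gr)$source <- "endofinish"
  S4Vectors::mcols(gr)$type <- models$type
  S4Vectors::mcols(gr)$phase <- ifelse(models$type == "CDS",
                                       segment_phase(models), NA_integer_)
  S4Vectors::mcols(gr)$ID <- models$gene_id
  S4Vectors::mcols(gr)$product <- ifelse(models$product == "",
                                         NA_character_, models$product)
  S4Vectors::mcols(gr)$polyA_merge <- ifelse(merged, "true", NA_character_)
  if (!is.null(seqlen))
    GenomeInfoDb::seqlengths(gr) <- setNames(as.integer(seqlen), seqname)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `start`, `end` (1-based
#'   closed), `strand`, `type`, `product`, `segment`; dual-frame models
#'   occupy two rows sharing `gene_id`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_models())
  mc <- S4Vectors::mcols(gr)
  ids <- if (!is.null(mc$ID)) as.character(mc$ID) else
    sprintf("feature_%05d", seq_along(gr))
  ids[is.na(ids)] <- sprintf("feature_%05d", which(is.na(ids)))
  product <- if (!is.null(mc$product)) as.character(mc$product) else
    rep(NA_character_, length(gr))
  product[is.na(product)] <- ""
  out <- data.frame(
    gene_id = ids,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(mc$type),
    product = product,
    segment = 1L,
    stringsAsFactors = FALSE
  )
  out <- out[out$type %in% c("CDS", "tRNA", "rRNA", "pseudogene"), , drop = FALSE]
  out$strand[!(out$strand %in% c("+", "-"))] <- "+"
  # number segments of multi-row models in reading order
  for (g in unique(out$gene_id[duplicated(out$gene_id)])) {
    i <- which(out$gene_id == g)
    ord <- order(out$start[i])
    if (out$strand[i[1L]] == "-") ord <- rev(ord)
    out$segment[i[ord]] <- seq_along(i)
  }
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# GenBank flat files (read-only)
# ---------------------------------------------------------------------------

parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$|^(\\d+)$", parts))
  seg <- lapply(m, function(g) {
    if (length(g) == 0L || g[1L] == "") return(NULL)
    if (g[4L] != "") c(as.integer(g[4L]), as.integer(g[4L]))
    else c(as.integer(g[2L]), as.integer(g[3L]))
  })
  if (any(vapply(seg, is.null, logical(1L)))) return(NULL)
  list(strand = strand,
       start = vapply(seg, `[`, integer(1L), 1L),
       end = vapply(seg, `[`, integer(1L), 2L))
}

#' Read a GenBank flat file
#'
#' Minimal reader for bacterial genome records: sequence from ORIGIN and
#' CDS/tRNA/rRNA features from the FEATURES table, including
#' `complement()` and two-segment `join()` locations.  Coordinates are kept
#' 1-based closed.
#'
#' @param path file path.
#' @return list with `name`, `seq` and a model data.frame `models`.
#' @export
read_genbank_flat <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[1L]))
    stop("not a GenBank flat file (no LOCUS line): ", path)
  name <- strsplit(trimws(sub("^LOCUS", "", lines[1L])), "\\s+")[[1L]][1L]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop("no ORIGIN section in ", path)
  ostart <- ostart[1L]

  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  models <- empty_models()
  if (length(fstart) > 0L) {
    flines <- lines[(fstart[1L] + 1L):(ostart - 1L)]
    # a feature starts with a key in column 6
    is_key <- grepl("^ {5}\\S", flines)
    idx <- which(is_key)
    recs <- list()
    for (j in seq_along(idx)) {
      from <- idx[j]
      to <- if (j < length(idx)) idx[j + 1L] - 1L else length(flines)
      block <- flines[from:to]
      key <- sub("^\\s+(\\S+).*$", "\\1", block[1L])
      if (!(key %in% c("CDS", "tRNA", "rRNA"))) next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^\\s+/", block)
      loc_end <- if (length(qual_at) > 0L) qual_at[1L] - 1L else length(block)
      loc <- paste(trimws(sub("^\\s+\\S+\\s*", "", block[1L])),
                   if (loc_end > 1L) paste(trimws(block[2:loc_end]), collapse = "") else "",
                   sep = "")
      loc <- gsub("\\s", "", loc)
      parsed <- parse_gb_location(loc)
      if (is.null(parsed))
        stop(sprintf("unparseable %s location near line %d: %s", key,
                     fstart[1L] + from, loc))
      qual_txt <- paste(trimws(block), collapse = " ")
      get_q <- function(q) {
        m <- regmatches(qual_txt, regexec(paste0("/", q, '="([^"]*)"'), qual_txt))[[1L]]
        if (length(m) >= 2L) m[2L] else ""
      }
      gene_id <- get_q("locus_tag")
      if (gene_id == "") gene_id <- get_q("gene")
      if (gene_id == "") gene_id <- sprintf("%s_%05d", key, j)
      pseudo <- grepl("/pseudo(\\s|$|=)", qual_txt)
      nseg <- length(parsed$start)
      segs <- seq_len(nseg)
      if (parsed$strand == "-") segs <- rev(segs)
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = gene_id,
        start = parsed$start, end = parsed$end,
        strand = parsed$strand,
        type = if (pseudo) "pseudogene" else key,
        product = get_q("product"),
        segment = segs,
        stringsAsFactors = FALSE
      )
    }
    if (length(recs) > 0L) models <- do.call(rbind, recs)
  }
  list(name = name, seq = seq, models = models)
}
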