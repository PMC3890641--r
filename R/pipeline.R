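# Pipeline orchestration: configuration, the synthetic four-strain demo
# run (simulate -> scaffold -> gap fill -> polish -> annotate -> compare),
# output bundling and a reproducibility manifest.  All randomness flows
# from one root seed, split deterministically per stage and strain.

#' Pipeline configuration
#'
#' Stage parameters default to the finishing recipe this pipeline
#' implements: 30 bp seed with 2 mismatches for gap filling, 3 mismatches
#' for read mapping, a 21x coverage threshold for excise-and-refill, and
#' a 10% length-deviation rule for curation.
#'
#' @param rng_seed root seed; every stage seed is derived from it.
#' @param n_strains number of strains in the synthetic demo.
#' @param spec a [genome_spec()] for the simulated reference.
#' @param n_snps,syn_fraction,n_indels per-strain divergence.
#' @param n_gaps,gap_length_range contig shredding parameters.
#' @param coverage,read_length,error_rate read simulation parameters.
#' @param seed_length,max_seed_mismatches,min_depth gap-fill parameters.
#' @param map_mismatches mapping mismatch cap.
#' @param coverage_threshold excise-and-refill threshold (fold).
#' @param curation_ratio length-deviation rule (fraction of reference
#'   length).
#' @param k anchor k-mer size for scaffolding and alignment.
#' @param output_dir where [run_pipeline()] writes results.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(rng_seed = 1L,
                            n_strains = 4L,
                            spec = genome_spec(chromosome_length = 60000L,
                                               n_genes = 54L,
                                               plasmid_specs = NULL),
                            n_snps = 60L, syn_fraction = 0.55, n_indels = 8L,
                            n_gaps = 8L, gap_length_range = c(50L, 300L),
                            coverage = 60, read_length = 36L, error_rate = 0,
                            seed_length = 30L, max_seed_mismatches = 2L,
                            min_depth = 1L,
                            map_mismatches = 3L, coverage_threshold = 21,
                            curation_ratio = 0.10, k = 17L,
                            output_dir = tempfile("endofinish_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write/read a pipeline configuration
#'
#' JSON round trip; the resolved configuration is written alongside every
#' run's outputs.
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `write_config`: invisibly, `path`; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$spec <- unclass(x$spec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- x$spec
  x$spec <- NULL
  cfg <- do.call(pipeline_config, x[setdiff(names(x), "spec")])
  args <- spec[!vapply(spec, is.null, logical(1L))]
  if (is.data.frame(args$plasmid_specs))   # jsonlite simplification
    args$plasmid_specs <- lapply(seq_len(nrow(args$plasmid_specs)),
                                 function(i) as.list(args$plasmid_specs[i, ]))
  if (length(spec$plasmid_specs) == 0L) args["plasmid_specs"] <- list(NULL)
  cfg$spec <- do.call(genome_spec, args)
  cfg
}

# deterministic per-stage seed derived from the root (kept below 2^31)
stage_seed <- function(root, stage, strain = 0L) {
  (as.integer(root) * 1009L + stage * 101L + strain) %% 1000000007L
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a reference genome and `n_strains` diverged strains; for each
#' strain, shreds the true genome into draft contigs, simulates reads,
#' scaffolds the contigs against the *reference* genome (the synteny
#' template), fills the gaps by overlap consensus, polishes by
#' excise-and-refill, and projects + curates the annotation; finally
#' compares all finished strains against the first (the designated
#' coordinate frame), producing pairwise SNP/indel and
#' synonymous/nonsynonymous matrices, runs tests, genome statistics and
#' an AT-frequency track.  All outputs are written under
#' `config$output_dir` together with the resolved configuration and a
#' digest manifest.
#'
#' @param config a [pipeline_config()].
#' @return a `run_manifest`: list with `outputs` (file digests), `summary`
#'   (per-strain gap/polish outcomes), `tables` (variant and effect
#'   matrices, runs tests, stats), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  ref <- simulate_reference(config$spec, seed = stage_seed(config$rng_seed, 1L))
  write_fasta(c(reference = ref$seq), file.path(config$output_dir, "reference.fasta"))
  write_gff3(ref$models, file.path(config$output_dir, "reference.gff3"),
             seqname = "reference", seqlen = nchar(ref$seq))

  params <- gapfill_params(config$seed_length, config$max_seed_mismatches,
                           config$min_depth)
  strains <- list()
  summary_rows <- list()
  for (si in seq_len(config$n_strains)) {
    sid <- sprintf("strain_%02d", si)
    strain <- mutate_strain(ref, n_snps = config$n_snps,
                            syn_fraction = config$syn_fraction,
                            n_indels = config$n_indels,
                            seed = stage_seed(config$rng_seed, 2L, si),
                            strain_id = sid)
    contigs <- shred_contigs(strain, n_gaps = config$n_gaps,
                             gap_length_range = config$gap_length_range,
                             seed = stage_seed(config$rng_seed, 3L, si))
    reads <- simulate_reads(strain, coverage = config$coverage,
                            read_length = config$read_length,
                            error_rate = config$error_rate,
                            seed = stage_seed(config$rng_seed, 4L, si))

    placements <- anchor_contigs(contigs, ref, k = config$k)
    scaf <- build_scaffold(placements, nchar(ref$seq))
    repo <- build_repository(reads, config$seed_length, config$max_seed_mismatches)
    filled <- fill_all_gaps(scaf, contigs, repo, params)
    pol <- polish_assembly(filled$assembly, reads,
                           threshold = config$coverage_threshold,
                           max_mismatches = config$map_mismatches,
                           params = params,
                           rng_seed = stage_seed(config$rng_seed, 5L, si),
                           circular = config$spec$circular)
    ann <- annotate_genome(ref, pol$assembly, k = config$k)

    write_fasta(setNames(pol$assembly, sid),
                file.path(config$output_dir, paste0(sid, ".fasta")))
    write_gff3(ann$models, file.path(config$output_dir, paste0(sid, ".gff3")),
               seqname = sid, seqlen = nchar(pol$assembly))
    write_gap_report(filled$report,
                     file.path(config$output_dir, paste0(sid, "_gaps.tsv")))

    strains[[sid]] <- list(assembly = pol$assembly, models = ann$models,
                           truth = strain$truth, polish = pol)
    summary_rows[[si]] <- data.frame(
      strain = sid,
      n_gaps = nrow(filled$report),
      gaps_closed = sum(filled$report$status == "closed"),
      polish_rounds = pol$rounds,
      low_cov_left = nrow(pol$remaining),
      assembly_matches_truth = identical(pol$assembly, strain$seq))
  }

  ids <- names(strains)
  genomes <- lapply(strains, `[[`, "assembly")
  var_matrix <- pairwise_variant_matrix(genomes, k = config$k)

  ref_strain <- ids[1L]
  eff_matrix <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  runs_results <- list()
  for (j in seq_along(ids)[-1L]) {
    cmp <- compare_genomes(genomes[[ref_strain]], genomes[[ids[j]]],
                           strains[[ref_strain]]$models, k = config$k)
    eff_matrix[1L, j] <- cmp$effects$totals[["nonsynonymous"]]
    eff_matrix[j, 1L] <- cmp$effects$totals[["synonymous"]]
    runs_results[[ids[j]]] <- tryCatch(runs_test(cmp$effects),
                                       error = function(e) NULL)
  }
  stats <- lapply(ids, function(s)
    genome_stats(genomes[[s]], strains[[s]]$models))
  names(stats) <- ids

  write.table(var_matrix, file.path(config$output_dir, "variant_matrix.tsv"),
              sep = "\t", quote = FALSE)
  write.table(eff_matrix, file.path(config$output_dir, "effect_matrix.tsv"),
              sep = "\t", quote = FALSE)
  stats_tbl <- do.call(rbind, lapply(ids, function(s)
    data.frame(strain = s, stats[[s]][setdiff(names(stats[[s]]), "at_track")])))
  write.table(stats_tbl, file.path(config$output_dir, "genome_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  at <- stats[[1L]]$at_track
  if (!is.null(at))
    write.table(data.frame(seq = ref_strain, start = at$pos - 1L,
                           end = at$pos - 1L + 100L, at = at$at),
                file.path(config$output_dir, "at_track.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  rt <- lapply(runs_results, function(r)
    if (is.null(r)) NULL else unclass(r))
  jsonlite::write_json(rt, file.path(config$output_dir, "runs_tests.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_config(config, file.path(config$output_dir, "config.json"))

  files <- sort(list.files(config$output_dir, full.names = TRUE))
  files <- files[!(basename(files) %in% "manifest.json")]
  manifest <- structure(list(
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE),
    summary = do.call(rbind, summary_rows),
    tables = list(variants = var_matrix, effects = eff_matrix,
                  runs_tests = runs_results, stats = stats_tbl),
    config = config,
    wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_manifest")
  jsonlite::write_json(
    list(files = manifest$outputs, wall_time = manifest$wall_time),
    file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d strains, %d output files, %.1f s\n",
              nrow(x$summary), nrow(x$outputs), x$wall_time))
  print(x$summary)
  invisible(x)
}
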