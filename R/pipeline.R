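#' Run configuration for the sequencing-analysis workflow
#'
#' Validates paths and parameters for [runPipeline()]. Every referenced file
#' must exist at load time; the seed and a configuration fingerprint are
#' recorded in the header of every output table.
#'
#' @param fastqR1,fastqR2 Paired FASTQ paths (gzip accepted).
#' @param referenceFasta Amplicon reference FASTA.
#' @param lociTsv Loci metadata TSV (see [writeLociTsv()]).
#' @param sampleSheet Sample sheet TSV.
#' @param outDir Output directory.
#' @param minOverlap,maxMismatchFrac Merge parameters (see [mergePairs()]).
#' @param maxPrimerMismatch Structure-filter budget (see [filterStructure()]).
#' @param windowHalfWidth Optional cut-site window for indel counting
#'   (`NULL` = whole-read, the default mode).
#' @param params Alignment parameters (see [alignParams()]).
#' @param seed Master seed recorded in outputs.
#' @return A validated list of class `"RunConfig"`.
#' @export
runConfig <- function(fastqR1, fastqR2, referenceFasta, lociTsv, sampleSheet,
                      outDir, minOverlap = 20L, maxMismatchFrac = 0.1,
                      maxPrimerMismatch = 1L, windowHalfWidth = NULL,
                      params = alignParams(), seed = 1L) {
  paths <- c(fastqR1 = fastqR1, fastqR2 = fastqR2,
             referenceFasta = referenceFasta, lociTsv = lociTsv,
             sampleSheet = sampleSheet)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("validation error: missing input file(s): ",
         paste(sprintf("%s=%s", names(missing), missing), collapse = ", "),
         call. = FALSE)
  cfg <- list(fastqR1 = fastqR1, fastqR2 = fastqR2,
              referenceFasta = referenceFasta, lociTsv = lociTsv,
              sampleSheet = sampleSheet, outDir = outDir,
              minOverlap = as.integer(minOverlap),
              maxMismatchFrac = maxMismatchFrac,
              maxPrimerMismatch = as.integer(maxPrimerMismatch),
              windowHalfWidth = windowHalfWidth, params = params,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a run configuration from YAML
#'
#' Keys mirror the [runConfig()] arguments; unknown keys raise a validation
#' error naming the field.
#'
#' @param path YAML file path.
#' @return A `RunConfig`.
#' @export
loadRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("validation error in config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(runConfig, y)
}

configFingerprint <- function(cfg) {
  flat <- unlist(cfg[setdiff(names(cfg), "outDir")])
  strFingerprint(paste(names(flat), flat, sep = "=", collapse = ";"))
}

writeResultTsv <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# AmpliCas %s%s", packageVersion("AmpliCas"),
                     if (is.null(cfg)) "" else
                       sprintf(" config=%s seed=%d", configFingerprint(cfg),
                               cfg$seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full amplicon editing-quantification workflow
#'
#' Executes merge -> structure filter -> demultiplex -> align -> indel call ->
#' editing summary -> specificity/dose-response, writes every stage's table
#' under `outDir`, and verifies the read-conservation identity (input pairs =
#' merge failures + structure rejects + unassigned + assigned).
#'
#' @param cfg A `RunConfig` from [runConfig()] or [loadRunConfig()].
#' @param verbose Print per-stage counts? Default `TRUE`.
#' @return A list: `counts` (named stage counts), `calls`, `summaries`,
#'   `doseResponse`, and `files` (paths written).
#' @export
runPipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  loci <- readLociTsv(cfg$lociTsv, cfg$referenceFasta)
  samples <- read.delim(cfg$sampleSheet, stringsAsFactors = FALSE,
                        colClasses = c(barcode = "character"))
  fq1 <- readFastq(cfg$fastqR1)
  fq2 <- readFastq(cfg$fastqR2)
  if (length(fq1$seq) != length(fq2$seq))
    stop("data error: R1/R2 read counts differ", call. = FALSE)
  nPairs <- length(fq1$seq)
  say <- function(...) if (verbose) message(sprintf(...))
  say("input pairs: %d", nPairs)

  counts <- c(input_pairs = nPairs, merged = 0L, merge_failed = 0L,
              structure_rejected = 0L, demultiplexed = 0L,
              assigned = 0L, unassigned = 0L)
  empty <- nPairs == 0L
  if (empty) {
    warning("empty FASTQ input: writing empty summaries", call. = FALSE)
    calls <- data.frame(id = character(0), sample_id = character(0),
                        locus = character(0), has_indel = logical(0))
    summaries <- data.frame(sample_id = character(0), locus = character(0),
                            reads_pass = integer(0),
                            reads_with_indel = integer(0),
                            pct_indels = numeric(0))
    dr <- data.frame()
  } else {
    merged <- mergePairs(fq1$seq, fq2$seq, fq1$qual, fq2$qual,
                         minOverlap = cfg$minOverlap,
                         maxMismatchFrac = cfg$maxMismatchFrac)
    counts["merged"] <- sum(merged$merged)
    counts["merge_failed"] <- sum(!merged$merged)
    say("merged: %d (failed: %d)", counts["merged"], counts["merge_failed"])

    fs <- filterStructure(merged, samples,
                          maxPrimerMismatch = cfg$maxPrimerMismatch)
    counts["structure_rejected"] <- nrow(fs$rejects)
    dmx <- demultiplex(fs$accepted)
    counts["demultiplexed"] <- nrow(fs$accepted)
    say("structure-accepted: %d (rejected: %d)", counts["demultiplexed"],
        counts["structure_rejected"])

    inserts <- setNames(fs$accepted$insert, fs$accepted$id)
    aln <- alignReads(inserts, loci, cfg$params)
    aln$sample_id <- fs$accepted$sample_id
    calls <- callIndels(aln, loci, windowHalfWidth = cfg$windowHalfWidth)
    counts["assigned"] <- sum(!is.na(calls$locus))
    counts["unassigned"] <- sum(is.na(calls$locus))
    say("assigned: %d (unassigned: %d)", counts["assigned"],
        counts["unassigned"])

    conserved <- counts["input_pairs"] ==
      counts["merge_failed"] + counts["structure_rejected"] +
      counts["unassigned"] + counts["assigned"]
    if (!conserved)
      stop("conservation check failed: stage counts do not add up",
           call. = FALSE)
    say("conservation check: OK")

    summaries <- editingSummary(calls)
    dr <- doseResponse(summaries, samples, loci)
  }

  files <- c(counts = file.path(cfg$outDir, "counts.tsv"),
             calls = file.path(cfg$outDir, "calls.tsv"),
             summaries = file.path(cfg$outDir, "summaries.tsv"),
             dose_response = file.path(cfg$outDir, "dose_response.tsv"))
  writeResultTsv(data.frame(stage = names(counts), n = unname(counts)),
                 files[["counts"]], cfg)
  callCols <- intersect(c("id", "sample_id", "locus", "ref_start", "cigar",
                          "score", "has_indel", "n_events"), names(calls))
  writeResultTsv(calls[, callCols, drop = FALSE], files[["calls"]], cfg)
  writeResultTsv(summaries, files[["summaries"]], cfg)
  writeResultTsv(dr, files[["dose_response"]], cfg)

  list(counts = counts, calls = calls, summaries = summaries,
       doseResponse = dr, files = files)
}

#' Simulate a run and write it to disk (simulate workflow entry point)
#'
#' Convenience wrapper chaining [makeLoci()], [makeSamples()] and
#' [writeRun()] under one master seed.
#'
#' @param outDir Output directory.
#' @param seed Master seed.
#' @param trueIndelRates Named per-locus truth rates; names must match the
#'   loci produced by [makeLoci()] (default on/off1/off2 rates 0.4/0.05/0.02).
#' @param nReplicates Replicates (default 3).
#' @param cfg A [SimulationConfig-class] (default `simulationConfig(seed = seed)`).
#' @param ... Passed to [makeLoci()].
#' @return List with `loci`, `samples`, and the file `manifest`.
#' @export
simulateRun <- function(outDir, seed = 1L,
                        trueIndelRates = c(on = 0.40, off1 = 0.05,
                                           off2 = 0.02),
                        nReplicates = 3L,
                        cfg = simulationConfig(seed = seed), ...) {
  loci <- makeLoci(seed, nOffTargets = length(trueIndelRates) - 1L, ...)
  samples <- makeSamples(loci, trueIndelRates, nReplicates = nReplicates,
                         seed = seed)
  manifest <- writeRun(loci, samples, cfg, outDir)
  list(loci = loci, samples = samples, manifest = manifest)
}
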