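#' AmpliconLocus: an on- or off-target amplicon reference
#'
#' One PCR amplicon spanning a Cas9 target site. The protospacer occupies a
#' 0-based half-open interval on the reference; the PAM sits in the 3 bases
#' immediately 3' of the protospacer on the protospacer strand; the blunt
#' Cas9 cut falls between protospacer positions 17 and 18 (3 bp from the
#' PAM-proximal end). `fwdPrimer` is the forward-primer annealing part (the
#' reference prefix, top strand); `revPrimer` is the reverse primer oligo
#' itself, 5'->3' (the reverse complement of the reference suffix).
#'
#' @slot name Locus name.
#' @slot role `"on_target"` or `"off_target"`.
#' @slot reference Amplicon sequence, 5'->3' top strand.
#' @slot protospacerStart,protospacerEnd 0-based half-open interval.
#' @slot protospacerStrand `"+"` or `"-"`.
#' @slot pam 3-nt PAM as read on the protospacer strand.
#' @slot cutPosition 0-based between-base index on the reference.
#' @slot fwdPrimer,revPrimer Primer annealing parts (see above).
#' @export
setClass("AmpliconLocus", representation(
  name = "character", role = "character", reference = "character",
  protospacerStart = "integer", protospacerEnd = "integer",
  protospacerStrand = "character", pam = "character",
  cutPosition = "integer", fwdPrimer = "character", revPrimer = "character"))

setValidity("AmpliconLocus", function(object) {
  msgs <- character(0)
  ref <- object@reference
  n <- nchar(ref)
  s <- object@protospacerStart; e <- object@protospacerEnd
  if (!grepl("^[ACGT]+$", ref)) msgs <- c(msgs, "reference must be A/C/G/T")
  if (!object@role %in% c("on_target", "off_target"))
    msgs <- c(msgs, "role must be on_target or off_target")
  if (e - s != 20L) msgs <- c(msgs, "protospacer interval must span 20 nt")
  if (s < 0L || e > n) msgs <- c(msgs, "protospacer interval outside reference")
  if (!object@protospacerStrand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (!grepl("^[ACGT]GG$", object@pam)) msgs <- c(msgs, "pam must match NGG")
  if (object@protospacerStrand == "+") {
    if (e + 3L > n || substr(ref, e + 1L, e + 3L) != object@pam)
      msgs <- c(msgs, "PAM must occupy the 3 bases 3' of the protospacer (+)")
    if (object@cutPosition != s + 17L)
      msgs <- c(msgs, "cut must fall between protospacer positions 17|18 (+)")
  } else {
    if (s - 3L < 0L || revComp(substr(ref, s - 2L, s)) != object@pam)
      msgs <- c(msgs, "PAM must occupy the 3 bases 3' of the protospacer (-)")
    if (object@cutPosition != s + 3L)
      msgs <- c(msgs, "cut must fall between protospacer positions 17|18 (-)")
  }
  if (nchar(object@fwdPrimer) > 0 &&
      substr(ref, 1L, nchar(object@fwdPrimer)) != object@fwdPrimer)
    msgs <- c(msgs, "fwdPrimer must be the reference prefix")
  if (nchar(object@revPrimer) > 0 &&
      substr(ref, n - nchar(object@revPrimer) + 1L, n) !=
        revComp(object@revPrimer))
    msgs <- c(msgs, "revPrimer must reverse-complement the reference suffix")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AmpliconLocus", function(object) {
  cat(sprintf("AmpliconLocus '%s' (%s): %d bp, protospacer [%d,%d) %s, PAM %s, cut %d\n",
              object@name, object@role, nchar(object@reference),
              object@protospacerStart, object@protospacerEnd,
              object@protospacerStrand, object@pam, object@cutPosition))
})

#' Construct an AmpliconLocus
#'
#' @param name Locus name.
#' @param role `"on_target"` or `"off_target"`.
#' @param reference Amplicon sequence (top strand, 5'->3').
#' @param protospacerStart 0-based start of the 20-nt protospacer interval.
#' @param protospacerStrand `"+"` or `"-"`.
#' @param fwdPrimerLen,revPrimerLen Primer annealing lengths at the two
#'   reference ends.
#' @return An [AmpliconLocus-class]. PAM and cut position are derived from the
#'   interval and strand.
#' @export
ampliconLocus <- function(name, role, reference, protospacerStart,
                          protospacerStrand = "+",
                          fwdPrimerLen = 20L, revPrimerLen = 20L) {
  reference <- toupper(reference)
  s <- as.integer(protospacerStart); e <- s + 20L
  n <- nchar(reference)
  if (protospacerStrand == "+") {
    pam <- substr(reference, e + 1L, e + 3L)
    cut <- s + 17L
  } else {
    pam <- revComp(substr(reference, s - 2L, s))
    cut <- s + 3L
  }
  new("AmpliconLocus", name = name, role = role, reference = reference,
      protospacerStart = s, protospacerEnd = e,
      protospacerStrand = protospacerStrand, pam = pam,
      cutPosition = as.integer(cut),
      fwdPrimer = substr(reference, 1L, fwdPrimerLen),
      revPrimer = revComp(substr(reference, n - revPrimerLen + 1L, n)))
}

#' @describeIn ampliconLocus Locus name accessor.
#' @param x An `AmpliconLocus`.
#' @export
locusName <- function(x) x@name

#' @describeIn ampliconLocus Reference sequence accessor.
#' @export
referenceSeq <- function(x) x@reference

#' @describeIn ampliconLocus Cut position accessor (0-based, between bases).
#' @export
cutPosition <- function(x) x@cutPosition

#' @describeIn ampliconLocus Protospacer as read 5'->3' on its strand.
#' @export
protospacerSeq <- function(x) {
  ps <- substr(x@reference, x@protospacerStart + 1L, x@protospacerEnd)
  if (x@protospacerStrand == "-") revComp(ps) else ps
}

#' SimulationConfig: parameters of the synthetic read generator
#'
#' The generator emulates barcoded paired-end amplicon sequencing of a pool of
#' Cas9-edited loci: each template is `barcode + amplicon`, an edited template
#' carries exactly one indel concentrated at the cut site, and 150-nt paired
#' reads are taken from the template ends with uniform substitution errors.
#'
#' @slot deletionFraction Probability an indel is a deletion (vs insertion).
#' @slot pLen Geometric parameter for indel length (support 1, 2, ...).
#' @slot maxIndelLen Length cap for simulated indels.
#' @slot jitter Indel positions drawn uniformly from cut +/- jitter.
#' @slot substitutionErrorRate Per-base substitution error probability.
#' @slot readLength Read length in nt (150 by default).
#' @slot nReads Read pairs per sample.
#' @slot baseQuality Constant Phred quality assigned to every base.
#' @slot seed Master seed.
#' @export
setClass("SimulationConfig", representation(
  deletionFraction = "numeric", pLen = "numeric", maxIndelLen = "integer",
  jitter = "integer", substitutionErrorRate = "numeric",
  readLength = "integer", nReads = "integer", baseQuality = "integer",
  seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  for (nm in c("deletionFraction", "pLen", "substitutionErrorRate")) {
    v <- slot(object, nm)
    if (length(v) != 1L || v < 0 || v > 1)
      msgs <- c(msgs, sprintf("%s must lie in [0,1]", nm))
  }
  if (object@readLength < 1L) msgs <- c(msgs, "readLength must be positive")
  if (object@nReads < 0L) msgs <- c(msgs, "nReads must be non-negative")
  if (object@jitter < 0L) msgs <- c(msgs, "jitter must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults encode the emulated study conditions: 150-nt paired-end reads,
#' one indel per edited template with geometric lengths (p = 0.3, cap 30)
#' centred on the cut site within +/- 2 nt, constant Q30 base qualities.
#'
#' @param nReads Read pairs per sample (default 2000).
#' @param substitutionErrorRate Per-base substitution error rate (default 0.001).
#' @param deletionFraction Fraction of indels that are deletions (default 0.7).
#' @param pLen Geometric length parameter (default 0.3).
#' @param maxIndelLen Indel length cap (default 30).
#' @param jitter Positional jitter around the cut (default 2).
#' @param readLength Read length (default 150).
#' @param baseQuality Constant Phred quality (default 30).
#' @param seed Master seed (default 1).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(nReads = 2000L, substitutionErrorRate = 0.001,
                             deletionFraction = 0.7, pLen = 0.3,
                             maxIndelLen = 30L, jitter = 2L,
                             readLength = 150L, baseQuality = 30L, seed = 1L) {
  new("SimulationConfig", deletionFraction = deletionFraction, pLen = pLen,
      maxIndelLen = as.integer(maxIndelLen), jitter = as.integer(jitter),
      substitutionErrorRate = substitutionErrorRate,
      readLength = as.integer(readLength), nReads = as.integer(nReads),
      baseQuality = as.integer(baseQuality), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d x %d-nt pairs/sample, error %.4g, ",
                     "del frac %.2f, pLen %.2f, jitter +/-%d, seed %d\n"),
              object@nReads, object@readLength, object@substitutionErrorRate,
              object@deletionFraction, object@pLen, object@jitter, object@seed))
})

# Embed a 20-nt protospacer + NGG PAM into a random amplicon.
makeOneLocus <- function(name, role, protospacer, ampliconLength, strand,
                         primerLen = 20L) {
  # place the protospacer so the cut site sits near the amplicon centre
  s <- as.integer(ampliconLength / 2) - 10L
  pamN <- sample(DNA_BASES_CHR, 1L)
  if (strand == "+") {
    left <- randomDna(s)
    right <- randomDna(ampliconLength - s - 23L)
    ref <- paste0(left, protospacer, pamN, "GG", right)
  } else {
    # protospacer read on the minus strand; on the top strand we embed its
    # reverse complement with the PAM's reverse complement (CCN) 5' of it
    left <- randomDna(s - 3L)
    right <- randomDna(ampliconLength - s - 20L)
    ref <- paste0(left, "CC", pamN, revComp(protospacer), right)
  }
  ampliconLocus(name, role, ref, s, strand,
                fwdPrimerLen = primerLen, revPrimerLen = primerLen)
}

#' Generate an on-target locus plus mismatched off-target loci
#'
#' Emulates a panel of one on-target site and `nOffTargets` previously
#' identified off-target sites whose protospacers differ from the on-target
#' protospacer at exactly `mismatchesPerOffTarget` positions, each embedded in
#' an otherwise unrelated random amplicon with a valid NGG PAM. Deterministic
#' given `seed`.
#'
#' @param seed Integer seed.
#' @param nOffTargets Number of off-target loci (default 2).
#' @param mismatchesPerOffTarget Protospacer mismatches per off-target
#'   (default 2).
#' @param ampliconLength Amplicon length in bp (default 240, so that 150-nt
#'   read pairs always overlap by at least 60 nt).
#' @param primerLen Primer annealing length at each amplicon end (default 20).
#' @return A named list of [AmpliconLocus-class] objects; the first is the
#'   on-target locus.
#' @export
makeLoci <- function(seed, nOffTargets = 2L, mismatchesPerOffTarget = 2L,
                     ampliconLength = 240L, primerLen = 20L) {
  if (mismatchesPerOffTarget < 0L || mismatchesPerOffTarget > 20L)
    stop("mismatchesPerOffTarget must lie in [0, 20]", call. = FALSE)
  if (nOffTargets < 0L) stop("nOffTargets must be >= 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    proto <- randomDna(20L)
    strands <- sample(c("+", "-"), nOffTargets + 1L, replace = TRUE)
    loci <- vector("list", nOffTargets + 1L)
    loci[[1]] <- makeOneLocus("on", "on_target", proto, ampliconLength,
                              strands[1], primerLen)
    for (i in seq_len(nOffTargets)) {
      pos <- sample.int(20L, mismatchesPerOffTarget)
      chars <- strsplit(proto, "")[[1]]
      for (p in pos) chars[p] <- sample(setdiff(DNA_BASES_CHR, chars[p]), 1L)
      loci[[i + 1]] <- makeOneLocus(sprintf("off%d", i), "off_target",
                                    paste(chars, collapse = ""),
                                    ampliconLength, strands[i + 1], primerLen)
    }
    names(loci) <- vapply(loci, locusName, character(1))
    loci
  })
}

#' Build a sample sheet for a simulated pool
#'
#' One sample per locus x replicate x condition, each with a unique 5-nt
#' barcode, mirroring pools where every sample is a unique combination of
#' sequencing barcode and amplified region.
#'
#' @param loci List of [AmpliconLocus-class] objects.
#' @param trueIndelRates Named numeric vector of per-locus truth editing
#'   rates (names matching locus names).
#' @param nReplicates Replicates per condition (default 3).
#' @param inhibitorKind Condition label (default `"none"`).
#' @param relativeConcentration Relative inhibitor concentration (default 0).
#' @param seed Seed for barcode assignment.
#' @return A `data.frame` with columns `sample_id, barcode, fwd_primer,
#'   rev_primer, locus, inhibitor_kind, relative_concentration, replicate,
#'   true_indel_rate`.
#' @export
makeSamples <- function(loci, trueIndelRates, nReplicates = 3L,
                        inhibitorKind = "none", relativeConcentration = 0,
                        seed = 1L) {
  stopifnot(all(names(loci) %in% names(trueIndelRates)))
  grid <- expand.grid(locus = names(loci), replicate = seq_len(nReplicates),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  barcodes <- withr::with_seed(as.integer(seed), {
    bc <- character(0)
    while (length(bc) < n)
      bc <- unique(c(bc, vapply(seq_len(n), function(i) randomDna(5L),
                                character(1))))
    bc[seq_len(n)]
  })
  data.frame(
    sample_id = sprintf("%s_%s_rep%d", grid$locus, inhibitorKind,
                        grid$replicate),
    barcode = barcodes,
    fwd_primer = vapply(loci[grid$locus], function(l) l@fwdPrimer, character(1)),
    rev_primer = vapply(loci[grid$locus], function(l) l@revPrimer, character(1)),
    locus = grid$locus,
    inhibitor_kind = inhibitorKind,
    relative_concentration = relativeConcentration,
    replicate = grid$replicate,
    true_indel_rate = unname(trueIndelRates[grid$locus]),
    stringsAsFactors = FALSE, row.names = NULL)
}

# Apply one indel to an amplicon around the cut site; returns the edited
# sequence plus the truth record fields (coordinates on the unedited amplicon).
applyIndel <- function(reference, cut, cfg) {
  len <- min(rgeom(1L, cfg@pLen) + 1L, cfg@maxIndelLen)
  pos <- cut + sample.int(2L * cfg@jitter + 1L, 1L) - cfg@jitter - 1L
  isDel <- runif(1L) < cfg@deletionFraction
  n <- nchar(reference)
  if (isDel) {
    pos <- max(1L, min(pos + 1L, n - len))    # leftmost deleted base, 1-based
    edited <- paste0(substr(reference, 1L, pos - 1L),
                     substr(reference, pos + len, n))
    list(seq = edited, type = "deletion", pos = pos - 1L, len = len)
  } else {
    pos <- max(0L, min(pos, n))               # between-base index, 0-based
    edited <- paste0(substr(reference, 1L, pos), randomDna(len),
                     substr(reference, pos + 1L, n))
    list(seq = edited, type = "insertion", pos = pos, len = len)
  }
}

# Inject uniform substitution errors into a character vector of sequences.
injectErrors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    chars <- strsplit(s, "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES_CHR, chars[p]), 1L)
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired-end reads for one sample
#'
#' Each template is `barcode + amplicon`; with probability
#' `sample$true_indel_rate` the amplicon carries exactly one indel at the cut
#' site (type, length and position drawn per the config). Read 1 is the first
#' `readLength` nt of the template; read 2 is the reverse complement of the
#' last `readLength` nt. Per-base substitution errors are applied
#' independently to both reads. Deterministic given `seed`.
#'
#' @param locus An [AmpliconLocus-class].
#' @param sample One row of a sample sheet (see [makeSamples()]).
#' @param cfg A [SimulationConfig-class].
#' @param seed Seed for this sample (default derived from `cfg@seed`).
#' @return A list with `r1`, `r2` (character vectors), `q1`, `q2` (quality
#'   strings), and `truth` (a `data.frame`: read_id, sample_id, locus, edited,
#'   indel_type, indel_len, indel_pos).
#' @export
simulateSample <- function(locus, sample, cfg,
                           seed = deriveSeed(cfg@seed, 1L)) {
  validObject(cfg)
  ref <- referenceSeq(locus)
  rate <- sample$true_indel_rate
  n <- cfg@nReads
  rl <- cfg@readLength
  withr::with_seed(as.integer(seed), {
    edited <- runif(n) < rate
    templates <- character(n)
    type <- rep(NA_character_, n); len <- rep(NA_integer_, n)
    pos <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (edited[i]) {
        ev <- applyIndel(ref, cutPosition(locus), cfg)
        templates[i] <- ev$seq
        type[i] <- ev$type; len[i] <- ev$len; pos[i] <- ev$pos
      } else {
        templates[i] <- ref
      }
    }
    templates <- paste0(sample$barcode, templates)
    tlen <- nchar(templates)
    if (any(tlen < rl))
      stop("template shorter than the read length; increase amplicon length ",
           "or lower maxIndelLen", call. = FALSE)
    r1 <- substr(templates, 1L, rl)
    r2 <- revComp(substring(templates, tlen - rl + 1L, tlen))
    r1 <- injectErrors(r1, cfg@substitutionErrorRate)
    r2 <- injectErrors(r2, cfg@substitutionErrorRate)
    q <- strrep(rawToChar(as.raw(cfg@baseQuality + 33L)), rl)
    ids <- sprintf("%s:%06d", sample$sample_id, seq_len(n))
    list(r1 = setNames(r1, ids), r2 = setNames(r2, ids),
         q1 = rep(q, n), q2 = rep(q, n),
         truth = data.frame(read_id = ids, sample_id = sample$sample_id,
                            locus = locusName(locus), edited = edited,
                            indel_type = type, indel_len = len,
                            indel_pos = pos, stringsAsFactors = FALSE))
  })
}

writeFastqGz <- function(seqs, quals, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (length(seqs)) {
    rec <- paste0("@", names(seqs), "\n", seqs, "\n+\n", quals)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Write a complete simulated sequencing run to disk
#'
#' Simulates every sample in the sheet against its locus and writes the
#' reference FASTA, a loci metadata TSV, the sample sheet TSV, pooled R1/R2
#' FASTQ (gzip, Phred+33), and the per-read truth TSV. Byte-identical across
#' reruns with the same inputs.
#'
#' @param loci Named list of [AmpliconLocus-class] objects.
#' @param samples Sample sheet `data.frame` (see [makeSamples()]).
#' @param cfg A [SimulationConfig-class]; `cfg@seed` drives all randomness.
#' @param outDir Output directory (created if missing).
#' @return Named character vector of the files written (the manifest).
#' @export
writeRun <- function(loci, samples, cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  r1 <- character(0); r2 <- character(0)
  q1 <- character(0); q2 <- character(0)
  truth <- list()
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    sim <- simulateSample(loci[[smp$locus]], smp, cfg,
                          seed = deriveSeed(cfg@seed, i))
    r1 <- c(r1, sim$r1); r2 <- c(r2, sim$r2)
    q1 <- c(q1, sim$q1); q2 <- c(q2, sim$q2)
    truth[[i]] <- sim$truth
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(truth)) rownames(truth) <- NULL
  manifest <- c(
    reference_fasta = file.path(outDir, "reference.fa"),
    loci_tsv = file.path(outDir, "loci.tsv"),
    sample_sheet = file.path(outDir, "samples.tsv"),
    fastq_r1 = file.path(outDir, "reads_R1.fastq.gz"),
    fastq_r2 = file.path(outDir, "reads_R2.fastq.gz"),
    truth_tsv = file.path(outDir, "truth.tsv"))
  refs <- Biostrings::DNAStringSet(vapply(loci, referenceSeq, character(1)))
  Biostrings::writeXStringSet(refs, manifest[["reference_fasta"]])
  writeLociTsv(loci, manifest[["loci_tsv"]])
  write.table(samples, manifest[["sample_sheet"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeFastqGz(r1, q1, manifest[["fastq_r1"]])
  writeFastqGz(r2, q2, manifest[["fastq_r2"]])
  if (is.null(truth))
    truth <- data.frame(read_id = character(0), sample_id = character(0),
                        locus = character(0), edited = logical(0),
                        indel_type = character(0), indel_len = integer(0),
                        indel_pos = integer(0))
  write.table(truth, manifest[["truth_tsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest
}

#' Write / read loci metadata as TSV
#'
#' @param loci Named list of [AmpliconLocus-class] objects.
#' @param path TSV path.
#' @return `writeLociTsv`: the path, invisibly. `readLociTsv`: a named list of
#'   [AmpliconLocus-class] objects (requires the reference FASTA alongside).
#' @export
writeLociTsv <- function(loci, path) {
  df <- do.call(rbind, lapply(loci, function(l) data.frame(
    name = l@name, role = l@role,
    protospacer_start = l@protospacerStart,
    protospacer_end = l@protospacerEnd,
    protospacer_strand = l@protospacerStrand,
    pam = l@pam, cut_position = l@cutPosition,
    fwd_primer = l@fwdPrimer, rev_primer = l@revPrimer,
    stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLociTsv
#' @param fastaPath Reference FASTA with one record per locus, names matching
#'   the TSV `name` column.
#' @export
readLociTsv <- function(path, fastaPath) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  refs <- Biostrings::readDNAStringSet(fastaPath)
  loci <- lapply(seq_len(nrow(df)), function(i) {
    nm <- df$name[i]
    if (!nm %in% names(refs))
      stop(sprintf("locus '%s' missing from reference FASTA", nm),
           call. = FALSE)
    ampliconLocus(nm, df$role[i], as.character(refs[[nm]]),
                  df$protospacer_start[i], df$protospacer_strand[i],
                  fwdPrimerLen = nchar(df$fwd_primer[i]),
                  revPrimerLen = nchar(df$rev_primer[i]))
  })
  names(loci) <- df$name
  loci
}

#' Read pooled FASTQ (optionally gzipped) into sequences and qualities
#'
#' @param path FASTQ path (plain or `.gz`).
#' @return A list with `seq` (named character vector) and `qual`.
#' @export
readFastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L)
    return(list(seq = setNames(character(0), character(0)),
                qual = character(0)))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4 (near record %d)",
                 path, length(lines), length(lines) %/% 4L + 1L), call. = FALSE)
  ids <- lines[seq(1L, length(lines), by = 4L)]
  bad <- !startsWith(ids, "@")
  if (any(bad))
    stop(sprintf("malformed FASTQ '%s': record %d does not start with '@'",
                 path, which(bad)[1]), call. = FALSE)
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  names(seqs) <- sub("^@", "", ids)
  list(seq = seqs, qual = quals)
}
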