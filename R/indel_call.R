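#' Alignment scoring parameters
#'
#' Affine-gap fit-alignment parameters for aligning reads (global) to amplicon
#' references (local). A gap of length L costs `gapOpening + L * gapExtension`.
#' Defaults (+2 match, -3 mismatch, open 8, extend 1) are chosen so isolated
#' Q30-level substitution errors do not open gaps.
#'
#' @param match Match reward (default 2).
#' @param mismatch Mismatch penalty, negative (default -3).
#' @param gapOpening Gap-opening cost, positive (default 8).
#' @param gapExtension Per-base gap-extension cost, positive (default 1).
#' @param minScoreFrac Minimum accepted score as a fraction of the read's
#'   maximum attainable score (`match * read length`); reads below are
#'   unassigned. Default 0.5.
#' @return A list of alignment parameters.
#' @export
alignParams <- function(match = 2, mismatch = -3, gapOpening = 8,
                        gapExtension = 1, minScoreFrac = 0.5) {
  list(match = match, mismatch = mismatch, gapOpening = gapOpening,
       gapExtension = gapExtension, minScoreFrac = minScoreFrac)
}

#' Align reads to pooled amplicon references and assign loci
#'
#' Computes a fit alignment (read global, reference local, affine gaps) of
#' every read against every candidate locus and assigns each read to its
#' best-scoring locus. Reads whose best score falls below
#' `minScoreFrac * match * read length`, or whose top two locus scores tie,
#' are left unassigned: a tie is never double-counted. This replaces
#' genome-wide mapping with alignment to the known amplicon panel.
#'
#' @param inserts Character vector of reads (barcode-trimmed inserts).
#' @param loci Named list of [AmpliconLocus-class] objects.
#' @param params See [alignParams()].
#' @return A `data.frame` with one row per read: `id, locus (NA when
#'   unassigned), ref_start` (0-based), `cigar, score, read`.
#' @export
alignReads <- function(inserts, loci, params = alignParams()) {
  stopifnot(length(loci) >= 1L)
  ids <- names(inserts)
  if (is.null(ids)) ids <- as.character(seq_along(inserts))
  n <- length(inserts)
  if (n == 0L)
    return(data.frame(id = character(0), locus = character(0),
                      ref_start = integer(0), cigar = character(0),
                      score = numeric(0), read = character(0),
                      stringsAsFactors = FALSE))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  pats <- Biostrings::DNAStringSet(unname(inserts))
  # pass 1: score-only against every locus to pick the assignment
  scores <- matrix(-Inf, nrow = n, ncol = length(loci))
  for (j in seq_along(loci)) {
    scores[, j] <- Biostrings::pairwiseAlignment(
      pats, Biostrings::DNAString(referenceSeq(loci[[j]])),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = params$gapOpening, gapExtension = params$gapExtension,
      scoreOnly = TRUE)
  }
  best <- max.col(scores, ties.method = "first")
  bestScore <- scores[cbind(seq_len(n), best)]
  tied <- vapply(seq_len(n), function(i)
    sum(scores[i, ] == bestScore[i]) > 1L, logical(1))
  minScore <- params$minScoreFrac * params$match * nchar(inserts)
  assigned <- !tied & bestScore >= minScore
  out <- data.frame(id = ids, locus = NA_character_,
                    ref_start = NA_integer_, cigar = NA_character_,
                    score = bestScore, read = unname(inserts),
                    stringsAsFactors = FALSE)
  # pass 2: full alignment only against the assigned locus
  for (j in seq_along(loci)) {
    sel <- which(assigned & best == j)
    if (!length(sel)) next
    aj <- Biostrings::pairwiseAlignment(
      pats[sel], Biostrings::DNAString(referenceSeq(loci[[j]])),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = params$gapOpening, gapExtension = params$gapExtension)
    out$locus[sel] <- names(loci)[j]
    out$ref_start[sel] <- Biostrings::start(Biostrings::subject(aj)) - 1L
    out$cigar[sel] <- cigarFromAlignment(aj, nchar(inserts[sel]))
  }
  out
}

# Build CIGAR strings from the insertion/deletion ranges of a
# PairwiseAlignments object. Biostrings reports both range sets in
# alignment-column coordinates, so the alignment spans
# read length + total deletion width columns; M runs fill the space
# between indel events.
cigarFromAlignment <- function(aln, readLens) {
  ind <- Biostrings::indel(aln)
  insS <- as.list(IRanges::start(Biostrings::insertion(ind)))
  insW <- as.list(IRanges::width(Biostrings::insertion(ind)))
  delS <- as.list(IRanges::start(Biostrings::deletion(ind)))
  delW <- as.list(IRanges::width(Biostrings::deletion(ind)))
  vapply(seq_along(readLens), function(i) {
    starts <- c(insS[[i]], delS[[i]])
    widths <- c(insW[[i]], delW[[i]])
    ops <- c(rep("I", length(insS[[i]])), rep("D", length(delS[[i]])))
    total <- readLens[i] + sum(delW[[i]])
    if (!length(starts)) return(sprintf("%dM", total))
    o <- order(starts)
    starts <- starts[o]; widths <- widths[o]; ops <- ops[o]
    cig <- character(0)
    col <- 1L
    for (k in seq_along(starts)) {
      if (starts[k] > col)
        cig <- c(cig, sprintf("%dM", starts[k] - col))
      cig <- c(cig, sprintf("%d%s", widths[k], ops[k]))
      col <- starts[k] + widths[k]
    }
    if (col <= total) cig <- c(cig, sprintf("%dM", total - col + 1L))
    paste(cig, collapse = "")
  }, character(1))
}

parseCigar <- function(cigar) {
  m <- gregexpr("\\d+[MID]", cigar)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar))
    stop(sprintf("malformed CIGAR '%s'", cigar), call. = FALSE)
  toks <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1]]
  ops <- substr(toks, nchar(toks), nchar(toks))
  lens <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  if (any(lens < 1L)) stop("zero-length CIGAR operation", call. = FALSE)
  if (any(ops[-1] == ops[-length(ops)]))
    stop("adjacent CIGAR operations of the same type", call. = FALSE)
  list(ops = ops, lens = lens)
}

#' Extract indel events from a CIGAR string
#'
#' Walks the CIGAR in reference coordinates: every `I`/`D` operation yields
#' one event; `M` (alignment match, covering substitutions) yields none.
#' Insertion positions are 0-based between-base indices; deletion positions
#' are the 0-based leftmost deleted base.
#'
#' @param cigar CIGAR string over `M`/`I`/`D`.
#' @param refStart 0-based reference start of the alignment.
#' @return A `data.frame` with columns `type` (`"insertion"`/`"deletion"`),
#'   `position` (0-based reference coordinate), `length`.
#' @examples
#' indelsFromCigar("20M2D58M", 0)   # deletion, position 20, length 2
#' indelsFromCigar("10M3I67M", 5)   # insertion, between-base position 15
#' @export
indelsFromCigar <- function(cigar, refStart = 0L) {
  pc <- parseCigar(cigar)
  pos <- as.integer(refStart)
  type <- character(0); where <- integer(0); len <- integer(0)
  for (k in seq_along(pc$ops)) {
    op <- pc$ops[k]; L <- pc$lens[k]
    if (op == "M") {
      pos <- pos + L
    } else if (op == "D") {
      type <- c(type, "deletion"); where <- c(where, pos); len <- c(len, L)
      pos <- pos + L
    } else {
      type <- c(type, "insertion"); where <- c(where, pos); len <- c(len, L)
    }
  }
  data.frame(type = type, position = where, length = len,
             stringsAsFactors = FALSE)
}

#' Does an alignment contain an indel?
#'
#' Whole-read by default, mirroring CIGAR-based counting of reads with
#' insertions or deletions; optionally restricted to a reference window
#' (e.g. around the cut site) for noise robustness.
#'
#' @param cigar CIGAR string.
#' @param refStart 0-based reference start.
#' @param window Optional length-2 numeric `c(lo, hi)`: count only events
#'   with `lo <= position <= hi`.
#' @param region Optional length-2 numeric `c(lo, hi)`: count only events
#'   inside this reference interval (used to mask primer-annealing flanks).
#' @return Logical scalar.
#' @export
readHasIndel <- function(cigar, refStart = 0L, window = NULL, region = NULL) {
  ev <- indelsFromCigar(cigar, refStart)
  if (nrow(ev) == 0L) return(FALSE)
  keep <- rep(TRUE, nrow(ev))
  if (!is.null(region))
    keep <- keep & ev$position >= region[1] & ev$position <= region[2]
  if (!is.null(window))
    keep <- keep & ev$position >= window[1] & ev$position <= window[2]
  any(keep)
}

#' Per-read indel calls for a batch of alignments
#'
#' Applies [readHasIndel()] to every assigned read. Events falling inside the
#' primer-annealing flanks of the locus are excluded, so sequencing errors in
#' primer regions never count as locus indels. With `windowHalfWidth` set,
#' only events within `cut +/- windowHalfWidth` count (off by default:
#' whole-read counting is the primary mode).
#'
#' @param alignments `data.frame` from [alignReads()].
#' @param loci Named list of [AmpliconLocus-class] objects.
#' @param windowHalfWidth Optional half-width of a cut-site window (e.g. 25).
#' @return The input with columns `has_indel` (logical; `NA` for unassigned
#'   reads) and `n_events` added.
#' @export
callIndels <- function(alignments, loci, windowHalfWidth = NULL) {
  out <- alignments
  out$has_indel <- NA
  out$n_events <- NA_integer_
  for (nm in names(loci)) {
    sel <- which(!is.na(out$locus) & out$locus == nm)
    if (!length(sel)) next
    loc <- loci[[nm]]
    refLen <- nchar(referenceSeq(loc))
    excl <- c(nchar(loc@fwdPrimer), refLen - nchar(loc@revPrimer) - 1L)
    win <- if (is.null(windowHalfWidth)) NULL else
      c(cutPosition(loc) - windowHalfWidth, cutPosition(loc) + windowHalfWidth)
    # fast path: a single-M CIGAR has no events
    plain <- grepl("^\\d+M$", out$cigar[sel])
    out$n_events[sel[plain]] <- 0L
    out$has_indel[sel[plain]] <- FALSE
    sel <- sel[!plain]
    for (i in sel) {
      ev <- indelsFromCigar(out$cigar[i], out$ref_start[i])
      keep <- ev$position >= excl[1] & ev$position <= excl[2]
      if (!is.null(win))
        keep <- keep & ev$position >= win[1] & ev$position <= win[2]
      out$n_events[i] <- sum(keep)
      out$has_indel[i] <- any(keep)
    }
  }
  out
}

#' Indel position and length spectra for one locus
#'
#' @param events `data.frame` of indel events (see [indelsFromCigar()]),
#'   all from the given locus.
#' @param locus An [AmpliconLocus-class]; positions are reported relative to
#'   its cut site.
#' @return A list with `position` (table keyed by position - cut) and
#'   `length` (table keyed by signed length: + insertion, - deletion). Totals
#'   equal the event count.
#' @export
indelSpectra <- function(events, locus) {
  if (nrow(events) == 0L)
    return(list(position = table(integer(0)), length = table(integer(0))))
  relPos <- events$position - cutPosition(locus)
  signedLen <- ifelse(events$type == "insertion", events$length,
                      -events$length)
  list(position = table(relPos), length = table(signedLen))
}
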