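#' Merge paired-end reads by overlap consensus
#'
#' For each pair, scans all overlaps of at least `minOverlap` nt between the
#' 3' end of read 1 and the 5' end of the reverse-complemented read 2, and
#' keeps the overlap with the smallest mismatch fraction (ties broken in
#' favour of the longer overlap). Within the overlap the consensus base is
#' the one with the higher quality (ties favour read 1). Pairs with no
#' overlap at or below `maxMismatchFrac` are reported unmerged.
#'
#' @param r1,r2 Character vectors of read sequences (read 2 as sequenced,
#'   i.e. reverse strand).
#' @param q1,q2 Phred+33 quality strings (defaults: constant high quality).
#' @param minOverlap Minimum overlap length (default 20).
#' @param maxMismatchFrac Maximum tolerated mismatch fraction in the overlap
#'   (default 0.1; must be < 0.5).
#' @return A `data.frame` with one row per pair: `id, merged, sequence,
#'   quality, overlap_len, mismatches`.
#' @examples
#' tpl <- strrep("ACGT", 50)                     # 200-nt template
#' r1 <- substr(tpl, 1, 150)
#' r2 <- revComp(substr(tpl, 51, 200))
#' mergePairs(r1, r2)$sequence == tpl
#' @export
mergePairs <- function(r1, r2, q1 = strrep("I", nchar(r1)),
                       q2 = strrep("I", nchar(r2)),
                       minOverlap = 20L, maxMismatchFrac = 0.1) {
  stopifnot(length(r1) == length(r2))
  if (maxMismatchFrac < 0 || maxMismatchFrac >= 0.5)
    stop("maxMismatchFrac must lie in [0, 0.5)", call. = FALSE)
  if (any(nchar(r1) == 0L) || any(nchar(r2) == 0L))
    stop("empty read in input", call. = FALSE)
  res <- .mergePairsCpp(unname(r1), unname(q1), unname(r2), unname(q2),
                        as.integer(minOverlap), maxMismatchFrac)
  ids <- names(r1)
  if (is.null(ids)) ids <- as.character(seq_along(r1))
  data.frame(id = ids, merged = res$merged, sequence = res$sequence,
             quality = res$quality, overlap_len = res$overlap_len,
             mismatches = res$mismatches, stringsAsFactors = FALSE)
}

#' Enforce the barcode + primer read structure and assign samples
#'
#' A merged read is accepted iff it starts with a known 5-nt barcode (exact
#' match), immediately followed by that sample's forward-primer annealing
#' part (at most `maxPrimerMismatch` substitutions), and ends with the
#' sample's reverse-primer annealing part (same budget). Accepted reads are
#' assigned to the barcode's sample; the barcode is trimmed from the emitted
#' insert while primer flanks are retained so that alignment stays anchored
#' at the amplicon ends.
#'
#' @param merged `data.frame` from [mergePairs()] (unmerged rows are ignored).
#' @param samples Sample sheet with columns `sample_id, barcode, fwd_primer,
#'   rev_primer` (see [makeSamples()]).
#' @param maxPrimerMismatch Substitution budget per primer (default 1).
#' @return A list with `accepted` (`data.frame`: id, sample_id, insert) and
#'   `rejects` (`data.frame`: id, reason in
#'   `no_barcode|fwd_primer|rev_primer`).
#' @export
filterStructure <- function(merged, samples, maxPrimerMismatch = 1L) {
  if (anyDuplicated(samples$barcode)) {
    dup <- samples$barcode[duplicated(samples$barcode)]
    stop(sprintf("duplicate barcode(s) in one pool: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (any(nchar(samples$barcode) != 5L))
    stop("barcodes must be exactly 5 nt", call. = FALSE)
  reads <- merged[merged$merged, , drop = FALSE]
  n <- nrow(reads)
  sampleIdx <- match(substr(reads$sequence, 1L, 5L), samples$barcode)
  reason <- rep(NA_character_, n)
  reason[is.na(sampleIdx)] <- "no_barcode"
  ok <- !is.na(sampleIdx)
  if (any(ok)) {
    idx <- which(ok)
    fwd <- samples$fwd_primer[sampleIdx[idx]]
    revSuffix <- revComp(samples$rev_primer[sampleIdx[idx]])
    seqs <- reads$sequence[idx]
    nc <- nchar(seqs)
    for (j in seq_along(idx)) {
      fl <- nchar(fwd[j]); rl <- nchar(revSuffix[j])
      if (nc[j] < 5L + fl + rl) { reason[idx[j]] <- "fwd_primer"; next }
      obsF <- substr(seqs[j], 6L, 5L + fl)
      if (hammingDist(obsF, fwd[j]) > maxPrimerMismatch) {
        reason[idx[j]] <- "fwd_primer"; next
      }
      obsR <- substr(seqs[j], nc[j] - rl + 1L, nc[j])
      if (hammingDist(obsR, revSuffix[j]) > maxPrimerMismatch)
        reason[idx[j]] <- "rev_primer"
    }
  }
  pass <- is.na(reason)
  accepted <- data.frame(
    id = reads$id[pass],
    sample_id = samples$sample_id[sampleIdx[pass]],
    insert = substring(reads$sequence[pass], 6L),
    stringsAsFactors = FALSE)
  rejects <- data.frame(id = reads$id[!pass], reason = reason[!pass],
                        stringsAsFactors = FALSE)
  list(accepted = accepted, rejects = rejects)
}

#' Split structure-accepted reads by sample
#'
#' @param accepted `data.frame` from [filterStructure()]`$accepted`.
#' @return A list with `bySample` (named list of `data.frame`s) and `counts`
#'   (`data.frame`: sample_id, n_reads; total equals the accepted total).
#' @export
demultiplex <- function(accepted) {
  bySample <- split(accepted, accepted$sample_id)
  counts <- data.frame(sample_id = names(bySample),
                       n_reads = vapply(bySample, nrow, integer(1)),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(bySample = bySample, counts = counts)
}
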