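#' GuideSpec: an SpCas9 guide specification
#'
#' Holds the DNA representation of a 20-nt spacer (5'->3') together with its
#' NGG protospacer-adjacent motif (PAM). The spacer is written as DNA even
#' though the guide itself is RNA: inhibitor oligos are designed against the
#' spacer-derived part of the guide, and all pairing arithmetic in this
#' package is done in DNA space.
#'
#' @slot spacer Character scalar, exactly 20 symbols over {A,C,G,T}, 5'->3'.
#' @slot pam Character scalar, 3 symbols matching N-G-G.
#' @export
setClass("GuideSpec", representation(spacer = "character", pam = "character"))

setValidity("GuideSpec", function(object) {
  msgs <- character(0)
  if (length(object@spacer) != 1L || nchar(object@spacer) != 20L)
    msgs <- c(msgs, "spacer must be a single 20-nt sequence")
  if (!grepl("^[ACGT]*$", object@spacer))
    msgs <- c(msgs, "spacer alphabet restricted to A/C/G/T")
  if (length(object@pam) != 1L || !grepl("^[ACGT]GG$", object@pam))
    msgs <- c(msgs, "pam must be 3 nt matching NGG over A/C/G/T")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GuideSpec
#'
#' @param spacer 20-nt spacer sequence, 5'->3', DNA alphabet.
#' @param pam 3-nt PAM matching NGG.
#' @return A [GuideSpec-class] object.
#' @examples
#' guideSpec("GGGCACTAGCTTACGGATCC", "TGG")
#' @export
guideSpec <- function(spacer, pam) {
  new("GuideSpec", spacer = toupper(spacer), pam = toupper(pam))
}

#' @describeIn guideSpec Spacer accessor.
#' @param x A `GuideSpec` or `InhibitorDesign`.
#' @export
spacer <- function(x) {
  if (is(x, "InhibitorDesign")) x@guide@spacer else x@spacer
}

#' @describeIn guideSpec PAM accessor.
#' @export
pam <- function(x) {
  if (is(x, "InhibitorDesign")) x@guide@pam else x@pam
}

setMethod("show", "GuideSpec", function(object) {
  cat("GuideSpec: 5'-", object@spacer, "-3' PAM:", object@pam, "\n")
})

#' InhibitorDesign: a guide-complementary inhibitor oligonucleotide
#'
#' A single-stranded DNA oligo complementary to the PAM-proximal,
#' spacer-derived part of a guide RNA. Plain designs (`L8`, `L20`) are the
#' reverse complement of the spacer's 3'-most `coreLength` nucleotides, i.e.
#' they carry the same sequence as the PAM-proximal part of the protospacer
#' (target strand). PAM-loop designs (`L8_PAM`, `L20_PAM`) add a 5' extension
#' `[PAM][loop][revcomp(PAM)]` that folds back onto itself to present a
#' double-stranded PAM to the Cas9 ribonucleoprotein. `SCRAMBLED` designs are
#' composition-preserving permutations used as sequence-specificity controls.
#'
#' @slot kind One of `"L20"`, `"L8"`, `"L20_PAM"`, `"L8_PAM"`, `"SCRAMBLED"`,
#'   or the generic `"L<n>"`/`"L<n>_PAM"` for other core lengths.
#' @slot coreLength Integer, length of the guide-complementary core.
#' @slot loop Character, the loop linker (PAM-loop kinds only; else "").
#' @slot sequence Character, the full oligo 5'->3'.
#' @slot guide The source [GuideSpec-class].
#' @slot seed Integer seed (scrambled designs only; otherwise `NA`).
#' @export
setClass("InhibitorDesign", representation(
  kind = "character", coreLength = "integer", loop = "character",
  sequence = "character", guide = "GuideSpec", seed = "integer"))

setValidity("InhibitorDesign", function(object) {
  msgs <- character(0)
  if (!grepl("^[ACGT]+$", object@sequence))
    msgs <- c(msgs, "sequence alphabet restricted to A/C/G/T")
  n <- nchar(object@sequence)
  if (grepl("_PAM$", object@kind)) {
    expect <- object@coreLength + 6L + nchar(object@loop)
    if (n != expect)
      msgs <- c(msgs, sprintf("PAM-loop design length %d != core + 6 + loop = %d",
                              n, expect))
  } else if (object@kind != "SCRAMBLED" && n != object@coreLength) {
    msgs <- c(msgs, "plain design length must equal coreLength")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "InhibitorDesign", function(object) {
  cat(sprintf("InhibitorDesign [%s] %d nt: 5'-%s-3'\n",
              object@kind, nchar(object@sequence), object@sequence))
  if (nzchar(object@loop))
    cat("  PAM arm:", substr(object@sequence, 1, 3),
        " loop:", object@loop, "\n")
  if (!is.na(object@seed)) cat("  scramble seed:", object@seed, "\n")
})

#' @describeIn designInhibitor Oligo sequence accessor.
#' @param x An `InhibitorDesign`.
#' @export
oligoSequence <- function(x) x@sequence

#' @describeIn designInhibitor Design kind accessor.
#' @export
designKind <- function(x) x@kind

#' Design a guide-complementary inhibitor oligo
#'
#' Builds the inhibitor core as the reverse complement of the PAM-proximal
#' (3'-most) `coreLength` nucleotides of the spacer, written 5'->3'.
#' With `pamLoop = TRUE` the oligo is extended at its 5' end with
#' `[PAM][loop][revcomp(PAM)]`, so the first three nucleotides fold back and
#' pair with the three immediately preceding the core, forming a 3-bp PAM
#' duplex.
#'
#' @param guide A [GuideSpec-class].
#' @param coreLength Integer in `[1, 20]`: length of the complementary core.
#'   The tested designs use 8 and 20.
#' @param pamLoop Logical: add the fold-back PAM extension?
#' @param loop Loop linker sequence (PAM-loop designs only). Default `"TTTT"`.
#' @return An [InhibitorDesign-class].
#' @examples
#' g <- guideSpec("GGGCACTAGCTTACGGATCC", "TGG")
#' designInhibitor(g, 20)                 # 20nt inhibitor
#' designInhibitor(g, 8, pamLoop = TRUE)  # 8nt+PAM inhibitor
#' @export
designInhibitor <- function(guide, coreLength, pamLoop = FALSE, loop = "TTTT") {
  stopifnot(is(guide, "GuideSpec"))
  validObject(guide)
  if (!is.numeric(coreLength) || length(coreLength) != 1L ||
      coreLength < 1 || coreLength > 20)
    stop("coreLength must lie in [1, 20]", call. = FALSE)
  coreLength <- as.integer(coreLength)
  sp <- spacer(guide)
  core <- revComp(substr(sp, 21L - coreLength, 20L))
  if (pamLoop) {
    if (!nzchar(loop)) stop("loop must be non-empty for PAM-loop designs",
                            call. = FALSE)
    loop <- toupper(loop)
    assertDna(loop, "loop")
    seqn <- paste0(pam(guide), loop, revComp(pam(guide)), core)
    kind <- sprintf("L%d_PAM", coreLength)
  } else {
    seqn <- core
    loop <- ""
    kind <- sprintf("L%d", coreLength)
  }
  new("InhibitorDesign", kind = kind, coreLength = coreLength, loop = loop,
      sequence = seqn, guide = guide, seed = NA_integer_)
}

# Longest run over which some substring of `a` is the reverse complement of a
# contiguous substring of `b` (exhaustive scan; sequences here are <= ~30 nt).
longestComplementRun <- function(a, b) {
  brc <- revComp(b)
  na <- nchar(a); nb <- nchar(brc)
  best <- 0L
  maxk <- min(na, nb)
  for (k in seq_len(maxk)) {
    subsA <- unique(substring(a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L))
    subsB <- substring(brc, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
    if (any(subsA %in% subsB)) best <- k else break
  }
  best
}

#' Scramble an inhibitor oligo as a sequence-specificity control
#'
#' Draws a seeded uniform permutation of the parent oligo's nucleotides,
#' re-drawing until the result (a) differs from the parent and (b) shares no
#' contiguous complementary match of at least `maxComplementRun` nucleotides
#' with the source spacer, so the control cannot hybridize productively with
#' the guide's seed region. Deterministic for a given seed.
#'
#' @param parent An [InhibitorDesign-class] with sequence length >= 2.
#' @param seed Integer seed for the permutation draw.
#' @param maxComplementRun Reject permutations sharing a complementary run of
#'   this length or more with the spacer. Default 8.
#' @return An [InhibitorDesign-class] of kind `"SCRAMBLED"`.
#' @examples
#' g <- guideSpec("GGGCACTAGCTTACGGATCC", "TGG")
#' scrambleOligo(designInhibitor(g, 20), seed = 7)
#' @export
scrambleOligo <- function(parent, seed, maxComplementRun = 8L) {
  stopifnot(is(parent, "InhibitorDesign"))
  s <- oligoSequence(parent)
  if (nchar(s) < 2L) stop("parent sequence must have length >= 2", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(unique(chars)) == 1L)
    stop("degenerate input: homopolymer has no distinct permutation",
         call. = FALSE)
  sp <- spacer(parent)
  perm <- withr::with_seed(as.integer(seed), {
    repeat {
      cand <- paste(sample(chars), collapse = "")
      if (cand == s) next
      if (longestComplementRun(cand, sp) >= maxComplementRun) next
      break
    }
    cand
  })
  new("InhibitorDesign", kind = "SCRAMBLED", coreLength = parent@coreLength,
      loop = "", sequence = perm, guide = parent@guide,
      seed = as.integer(seed))
}

#' Check the fold-back pairing of a PAM-loop design
#'
#' Verifies that the 5' arm (first 3 nt) and the pre-core segment (the 3 nt
#' immediately before the complementary core) are mutually reverse
#' complementary -- the intended 3-bp PAM duplex -- and scans the whole oligo
#' for unintended self-complementary runs of `minSelfRun` nucleotides or more
#' outside that duplex.
#'
#' @param design An [InhibitorDesign-class] of a `_PAM` kind.
#' @param minSelfRun Minimum run length reported as unintended pairing.
#'   Default 6.
#' @return A list with `pamDuplexOk` (logical), `unintendedPairing` (logical),
#'   and `longestUnintendedRun` (integer).
#' @export
hairpinCheck <- function(design, minSelfRun = 6L) {
  stopifnot(is(design, "InhibitorDesign"))
  if (!grepl("_PAM$", design@kind))
    stop("hairpinCheck applies only to PAM-loop (L<n>_PAM) designs",
         call. = FALSE)
  s <- oligoSequence(design)
  loopLen <- nchar(design@loop)
  arm <- substr(s, 1L, 3L)
  preCore <- substr(s, 4L + loopLen, 6L + loopLen)
  pamDuplexOk <- identical(arm, revComp(preCore))
  # scan for self-complementarity excluding the designed 3-bp duplex: mask the
  # 5' arm and ask whether the remainder still pairs with the full oligo
  rest <- substr(s, 4L, nchar(s))
  run <- longestComplementRun(rest, rest)
  list(pamDuplexOk = pamDuplexOk,
       unintendedPairing = run >= minSelfRun,
       longestUnintendedRun = as.integer(run))
}

#' Write inhibitor designs to FASTA
#'
#' One record per design; headers encode kind, core length and (for scrambled
#' controls) the seed, e.g. `inhibitor|L8_PAM|core=8` or
#' `inhibitor|SCRAMBLED|core=20|seed=7`.
#'
#' @param designs A list of [InhibitorDesign-class] objects.
#' @param file Output FASTA path.
#' @return The file path, invisibly.
#' @export
writeInhibitorFasta <- function(designs, file) {
  if (is(designs, "InhibitorDesign")) designs <- list(designs)
  hdr <- vapply(designs, function(d) {
    h <- sprintf("inhibitor|%s|core=%d", d@kind, d@coreLength)
    if (!is.na(d@seed)) h <- sprintf("%s|seed=%d", h, d@seed)
    h
  }, character(1))
  seqs <- Biostrings::DNAStringSet(vapply(designs, oligoSequence, character(1)))
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
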