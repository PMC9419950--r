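test_that("CIGAR parsing yields the hand-derived indel events", {
  expect_identical(nrow(indelsFromCigar("80M")), 0L)

  ev <- indelsFromCigar("20M2D58M", refStart = 0)
  expect_identical(ev$type, "deletion")
  expect_identical(ev$position, 20L)
  expect_identical(ev$length, 2L)

  ev <- indelsFromCigar("10M3I67M", refStart = 5)
  expect_identical(ev$type, "insertion")
  expect_identical(ev$position, 15L)
  expect_identical(ev$length, 3L)

  ev <- indelsFromCigar("5M1I4M2D6M", refStart = 10)
  expect_identical(ev$type, c("insertion", "deletion"))
  expect_identical(ev$position, c(15L, 19L))

  expect_error(indelsFromCigar("10M0D5M"), "zero-length")
  expect_error(indelsFromCigar("10M5M"), "adjacent")
  expect_error(indelsFromCigar("10X"), "malformed")
})

test_that("readHasIndel distinguishes whole-read and windowed counting", {
  expect_false(readHasIndel("150M"))
  expect_true(readHasIndel("70M2D78M", refStart = 0))
  expect_true(readHasIndel("70M2D78M", window = c(60, 80)))
  expect_false(readHasIndel("70M2D78M", window = c(100, 120)))
  # substitutions are represented inside M and are not indels
  expect_false(readHasIndel("40M"))
})

test_that("exact reference substrings align as a single match run", {
  loci <- makeLoci(seed = 41, nOffTargets = 0)
  ref <- referenceSeq(loci[[1]])
  read <- substr(ref, 21, 200)
  aln <- alignReads(c(r1 = read), loci)
  expect_identical(aln$locus, "on")
  expect_identical(aln$cigar, sprintf("%dM", nchar(read)))
  expect_identical(aln$ref_start, 20L)
  expect_identical(aln$score, 2 * nchar(read))
  expect_identical(nrow(indelsFromCigar(aln$cigar, aln$ref_start)), 0L)
})

test_that("a simulated clean deletion is recovered at the truth coordinates", {
  loci <- makeLoci(seed = 42, nOffTargets = 0)
  ref <- referenceSeq(loci[[1]])
  cut <- cutPosition(loci[[1]])
  # deletion of 2 nt at 0-based position cut (leftmost deleted base)
  read <- paste0(substr(ref, 1, cut), substr(ref, cut + 3, nchar(ref)))
  aln <- alignReads(c(r = read), loci)
  ev <- indelsFromCigar(aln$cigar, aln$ref_start)
  expect_identical(ev$type, "deletion")
  expect_identical(ev$length, 2L)
  expect_identical(ev$position, cut)
})

test_that("fit-alignment scores equal the exhaustive DP oracle on small instances", {
  set.seed(43)
  p <- alignParams()
  for (i in 1:100) {
    n <- sample(30:80, 1)
    ref <- rndDna(n)
    if (i %% 2 == 0) {
      m <- sample(10:min(40, n), 1)
      st <- sample(seq_len(n - m + 1), 1)
      read <- substr(ref, st, st + m - 1)
      ch <- strsplit(read, "")[[1]]
      nmut <- sample(0:3, 1)
      for (x in sample(m, min(m, nmut)))
        ch[x] <- sample(c("A", "C", "G", "T"), 1)
      if (m > 12 && runif(1) < 0.5)
        ch <- ch[-sample(3:(m - 2), sample(1:3, 1))]
      read <- paste(ch, collapse = "")
    } else {
      read <- rndDna(sample(8:40, 1))
    }
    mat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = TRUE)
    got <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(ref),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = p$gapOpening, gapExtension = p$gapExtension,
      scoreOnly = TRUE)
    expect_equal(got, fitScoreOracle(read, ref), tolerance = 1e-9)
  }

  # the same equivalence holds through the package surface on a short locus
  loci <- makeLoci(seed = 43, nOffTargets = 0, ampliconLength = 80,
                   primerLen = 5)
  ref <- referenceSeq(loci[[1]])
  reads <- vapply(1:10, function(i) {
    st <- sample(1:41, 1)
    read <- substr(ref, st, st + 39)
    ch <- strsplit(read, "")[[1]]
    if (i %% 2 == 0) ch <- ch[-sample(5:35, 2)]
    ch[sample(40 - 4, 1)] <- sample(c("A", "C", "G", "T"), 1)
    paste(ch, collapse = "")
  }, character(1))
  got <- alignReads(reads, loci)$score
  want <- vapply(reads, fitScoreOracle, numeric(1), ref = ref)
  expect_equal(got, unname(want), tolerance = 1e-9)
})

test_that("reads are assigned to their source locus and ties are dropped", {
  loci <- makeLoci(seed = 44, nOffTargets = 2, mismatchesPerOffTarget = 2)
  samples <- makeSamples(loci, c(on = 0.3, off1 = 0.3, off2 = 0.3),
                         nReplicates = 1, seed = 44)
  cfg <- simulationConfig(nReads = 200, substitutionErrorRate = 0.001,
                          seed = 44)
  d <- withr::local_tempdir()
  m <- writeRun(loci, samples, cfg, d)
  fq1 <- readFastq(m[["fastq_r1"]]); fq2 <- readFastq(m[["fastq_r2"]])
  merged <- mergePairs(fq1$seq, fq2$seq, fq1$qual, fq2$qual)
  fs <- filterStructure(merged, samples)
  aln <- alignReads(setNames(fs$accepted$insert, fs$accepted$id), loci)
  truthLocus <- samples$locus[match(fs$accepted$sample_id,
                                    samples$sample_id)]
  assigned <- !is.na(aln$locus)
  expect_gt(mean(assigned), 0.99)
  expect_gte(mean(aln$locus[assigned] == truthLocus[assigned]), 0.99)

  # two identical references always tie -> unassigned
  twin <- list(a = loci[[1]], b = loci[[1]])
  twin$b@name <- "b"
  read <- substr(referenceSeq(loci[[1]]), 31, 180)
  expect_true(is.na(alignReads(c(r = read), twin)$locus))
})

test_that("CIGAR round-trips reconstruct error-free reads from the reference", {
  loci <- makeLoci(seed = 45, nOffTargets = 0)
  ref <- referenceSeq(loci[[1]])
  samples <- makeSamples(loci, c(on = 1), nReplicates = 1, seed = 45)
  cfg <- simulationConfig(nReads = 60, substitutionErrorRate = 0, seed = 45)
  sim <- simulateSample(loci[[1]], samples[1, ], cfg)
  merged <- mergePairs(sim$r1, sim$r2, sim$q1, sim$q2)
  fs <- filterStructure(merged, samples)
  aln <- alignReads(setNames(fs$accepted$insert, fs$accepted$id), loci)
  for (i in which(!is.na(aln$locus))) {
    pc <- indelsFromCigar(aln$cigar[i], aln$ref_start[i])
    # rebuild the read: copy reference for M, skip for D, splice read bases for I
    toks <- regmatches(aln$cigar[i], gregexpr("\\d+[MID]", aln$cigar[i]))[[1]]
    ops <- substr(toks, nchar(toks), nchar(toks))
    lens <- as.integer(substr(toks, 1, nchar(toks) - 1))
    refPos <- aln$ref_start[i] + 1L; readPos <- 1L
    rebuilt <- character(0)
    for (k in seq_along(ops)) {
      if (ops[k] == "M") {
        rebuilt <- c(rebuilt, substr(ref, refPos, refPos + lens[k] - 1L))
        refPos <- refPos + lens[k]; readPos <- readPos + lens[k]
      } else if (ops[k] == "D") {
        refPos <- refPos + lens[k]
      } else {
        rebuilt <- c(rebuilt, substr(aln$read[i], readPos,
                                     readPos + lens[k] - 1L))
        readPos <- readPos + lens[k]
      }
    }
    expect_identical(paste(rebuilt, collapse = ""), aln$read[i])
    # reference- and read-consuming lengths add up
    expect_identical(sum(lens[ops != "D"]), nchar(aln$read[i]))
  }
})

test_that("CIGARs from indel ranges agree with gapped-string run-length encoding", {
  loci <- makeLoci(seed = 46, nOffTargets = 0)
  samples <- makeSamples(loci, c(on = 0.8), nReplicates = 1, seed = 46)
  cfg <- simulationConfig(nReads = 50, substitutionErrorRate = 0.002,
                          seed = 46)
  sim <- simulateSample(loci[[1]], samples[1, ], cfg)
  merged <- mergePairs(sim$r1, sim$r2, sim$q1, sim$q2)
  fs <- filterStructure(merged, samples)
  ins <- setNames(fs$accepted$insert, fs$accepted$id)
  mat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(unname(ins)),
    Biostrings::DNAString(referenceSeq(loci[[1]])),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 8, gapExtension = 1)
  viaStrings <- AmpliCas:::.cigarFromGappedCpp(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
  viaRanges <- AmpliCas:::cigarFromAlignment(aln, nchar(ins))
  expect_identical(viaRanges, unname(viaStrings))
})

test_that("indel spectra are keyed relative to the cut site", {
  loci <- makeLoci(seed = 47, nOffTargets = 0)
  loc <- loci[[1]]
  cut <- cutPosition(loc)
  ev <- data.frame(type = rep("deletion", 10), position = rep(cut, 10),
                   length = rep(2L, 10), stringsAsFactors = FALSE)
  sp <- indelSpectra(ev, loc)
  expect_identical(as.integer(sp$position["0"]), 10L)
  expect_identical(as.integer(sp$length["-2"]), 10L)
  expect_identical(sum(sp$position), nrow(ev))

  empty <- indelSpectra(ev[0, ], loc)
  expect_identical(length(empty$position), 0L)

  ins <- data.frame(type = "insertion", position = cut + 1L, length = 4L)
  expect_identical(as.integer(indelSpectra(ins, loc)$length["4"]), 1L)
})

test_that("with zero sequencing error the estimated indel fraction is exact", {
  loci <- makeLoci(seed = 48, nOffTargets = 0)
  samples <- makeSamples(loci, c(on = 0.35), nReplicates = 1, seed = 48)
  cfg <- simulationConfig(nReads = 400, substitutionErrorRate = 0, seed = 48)
  sim <- simulateSample(loci[[1]], samples[1, ], cfg)
  merged <- mergePairs(sim$r1, sim$r2, sim$q1, sim$q2)
  fs <- filterStructure(merged, samples)
  aln <- alignReads(setNames(fs$accepted$insert, fs$accepted$id), loci)
  aln$sample_id <- fs$accepted$sample_id
  calls <- callIndels(aln, loci)
  est <- editingSummary(calls)
  truthFrac <- mean(sim$truth$edited)
  expect_identical(est$reads_pass, 400L)
  expect_equal(est$pct_indels, 100 * truthFrac)
})
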