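test_that("merging a read with its own reverse complement returns the read", {
  set.seed(21)
  r1 <- rndDna(80)
  out <- mergePairs(r1, revComp(r1))
  expect_true(out$merged)
  expect_identical(out$sequence, r1)
  expect_identical(out$overlap_len, 80L)
  expect_identical(out$mismatches, 0L)
})

test_that("paired ends of a 200-nt template merge back to the template", {
  set.seed(22)
  tpl <- rndDna(200)
  r1 <- substr(tpl, 1, 150)
  r2 <- revComp(substr(tpl, 51, 200))
  out <- mergePairs(r1, r2)
  expect_identical(out$sequence, tpl)
  expect_identical(out$overlap_len, 100L)
})

test_that("unrelated reads fail to merge at the mismatch bound", {
  set.seed(23)
  for (i in 1:10) {
    r1 <- rndDna(150); r2 <- rndDna(150)
    oracle <- bruteMergeOracle(r1, r2, 20, 0.1)
    out <- mergePairs(r1, r2, minOverlap = 20, maxMismatchFrac = 0.1)
    expect_identical(out$merged, !is.null(oracle))
  }
})

test_that("consensus takes the higher-quality base in the overlap", {
  set.seed(25)
  tpl <- rndDna(120)
  r1 <- substr(tpl, 1, 80)
  r2seq <- substr(tpl, 41, 120)
  # corrupt r1's base 50 (overlap region) with low quality; r2 keeps truth
  wrong <- setdiff(c("A", "C", "G", "T"), substr(r1, 50, 50))[1]
  r1bad <- paste0(substr(r1, 1, 49), wrong, substr(r1, 51, 80))
  q1 <- paste0(strrep("I", 49), "#", strrep("I", 30))
  out <- mergePairs(r1bad, revComp(r2seq), q1, strrep("I", 80))
  expect_identical(out$sequence, tpl)
  expect_identical(out$mismatches, 1L)
})

test_that("merge equals the exhaustive overlap-search oracle on random small pairs", {
  set.seed(24)
  for (i in 1:200) {
    n <- sample(30:60, 1)
    tpl <- rndDna(n)
    rl <- sample(20:min(40, n), 1)
    r1 <- substr(tpl, 1, rl)
    r2 <- revComp(substr(tpl, n - rl + 1, n))
    # sprinkle substitution errors
    if (i %% 3 == 0) {
      ch <- strsplit(r1, "")[[1]]
      p <- sample(rl, 1)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      r1 <- paste(ch, collapse = "")
    }
    mo <- 10
    oracle <- bruteMergeOracle(r1, r2, mo, 0.1)
    got <- mergePairs(r1, r2, minOverlap = mo, maxMismatchFrac = 0.1)
    if (is.null(oracle)) {
      expect_false(got$merged)
    } else {
      expect_true(got$merged)
      expect_identical(got$overlap_len, as.integer(oracle$ov))
      expect_identical(got$mismatches, as.integer(oracle$mm))
      expect_identical(nchar(got$sequence), as.integer(oracle$len))
    }
  }
})

test_that("structure filter demands exact barcodes and tolerant primers", {
  loci <- makeLoci(seed = 31, nOffTargets = 0)
  samples <- makeSamples(loci, c(on = 0), nReplicates = 1, seed = 31)
  ref <- referenceSeq(loci[[1]])
  good <- paste0(samples$barcode[1], ref)
  merged <- data.frame(id = "r1", merged = TRUE, sequence = good,
                       quality = strrep("I", nchar(good)),
                       overlap_len = 60L, mismatches = 0L,
                       stringsAsFactors = FALSE)
  fs <- filterStructure(merged, samples)
  expect_identical(nrow(fs$accepted), 1L)
  expect_identical(fs$accepted$sample_id, samples$sample_id[1])
  expect_identical(fs$accepted$insert, ref)  # barcode trimmed, primers kept

  # one substitution in the barcode -> rejected (exact matching)
  bad_bc <- good
  substr(bad_bc, 2, 2) <- setdiff(c("A", "C", "G", "T"),
                                  substr(bad_bc, 2, 2))[1]
  merged$sequence <- bad_bc
  fs <- filterStructure(merged, samples)
  expect_identical(fs$rejects$reason, "no_barcode")

  # one substitution in the forward primer: accepted at budget 1, not at 0
  bad_fp <- good
  substr(bad_fp, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                                  substr(bad_fp, 8, 8))[1]
  merged$sequence <- bad_fp
  expect_identical(nrow(filterStructure(merged, samples,
                                        maxPrimerMismatch = 1)$accepted), 1L)
  expect_identical(filterStructure(merged, samples,
                                   maxPrimerMismatch = 0)$rejects$reason,
                   "fwd_primer")

  # corrupted reverse end
  bad_rp <- good
  n <- nchar(bad_rp)
  for (p in c(n - 1, n - 3)) {
    substr(bad_rp, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(bad_rp, p, p))[1]
  }
  merged$sequence <- bad_rp
  expect_identical(filterStructure(merged, samples,
                                   maxPrimerMismatch = 1)$rejects$reason,
                   "rev_primer")
})

test_that("duplicate barcodes in one pool are a configuration error", {
  loci <- makeLoci(seed = 32, nOffTargets = 0)
  samples <- makeSamples(loci, c(on = 0), nReplicates = 2, seed = 32)
  samples$barcode[2] <- samples$barcode[1]
  merged <- data.frame(id = "r", merged = TRUE, sequence = strrep("A", 100),
                       quality = strrep("I", 100), overlap_len = 50L,
                       mismatches = 0L, stringsAsFactors = FALSE)
  expect_error(filterStructure(merged, samples), "duplicate barcode")
})

test_that("demultiplex partitions reads conservatively", {
  accepted <- data.frame(
    id = sprintf("r%d", 1:300),
    sample_id = rep(c("s1", "s2", "s3"), each = 100),
    insert = strrep("A", 30), stringsAsFactors = FALSE)
  dmx <- demultiplex(accepted)
  expect_identical(sort(dmx$counts$sample_id), c("s1", "s2", "s3"))
  expect_true(all(dmx$counts$n_reads == 100L))
  expect_identical(sum(dmx$counts$n_reads), nrow(accepted))
  empty <- demultiplex(accepted[0, ])
  expect_identical(nrow(empty$counts), 0L)
})

test_that("a zero-error simulation yields zero structure rejects", {
  loci <- makeLoci(seed = 33, nOffTargets = 1)
  samples <- makeSamples(loci, c(on = 0.4, off1 = 0.05), nReplicates = 1,
                         seed = 33)
  cfg <- simulationConfig(nReads = 150, substitutionErrorRate = 0, seed = 33)
  d <- withr::local_tempdir()
  m <- writeRun(loci, samples, cfg, d)
  fq1 <- readFastq(m[["fastq_r1"]]); fq2 <- readFastq(m[["fastq_r2"]])
  merged <- mergePairs(fq1$seq, fq2$seq, fq1$qual, fq2$qual)
  expect_true(all(merged$merged))
  fs <- filterStructure(merged, samples)
  expect_identical(nrow(fs$rejects), 0L)
  expect_identical(nrow(fs$accepted), length(fq1$seq))
})
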