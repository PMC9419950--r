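# Independent oracles used by the test suite. These deliberately do not share
# code with the package implementation.

# Exhaustive affine-gap fit alignment (read global, reference local) by
# dynamic programming over explicit match/insert/delete state matrices.
# A gap of length L costs open + L * ext.
fitScoreOracle <- function(read, ref, match = 2, mismatch = -3,
                           open = 8, ext = 1) {
  p <- strsplit(read, "")[[1]]; s <- strsplit(ref, "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)  # gap in reference (insertion)
  Iy <- matrix(NEG, m + 1, n + 1)  # gap in read (deletion)
  M[1, ] <- 0                      # free start anywhere in the reference
  for (i in 2:(m + 1)) {
    Ix[i, 1] <- -(open + ext * (i - 1))
    for (j in 1:(n + 1)) {
      if (j > 1) {
        sc <- if (p[i - 1] == s[j - 1]) match else mismatch
        M[i, j] <- sc + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1])
      }
      Ix[i, j] <- max(Ix[i, j], M[i - 1, j] - open - ext,
                      Ix[i - 1, j] - ext, Iy[i - 1, j] - open - ext)
      if (j > 1) Iy[i, j] <- max(M[i, j - 1] - open - ext,
                                 Iy[i, j - 1] - ext,
                                 Ix[i, j - 1] - open - ext)
    }
  }
  max(M[m + 1, ], Ix[m + 1, ])
}

# Exhaustive overlap-merge oracle: try every overlap length, track the best
# (mismatch fraction, then longer overlap). Returns NULL on failure.
bruteMergeOracle <- function(r1, r2, minOverlap = 20, maxMismatchFrac = 0.1) {
  rc <- function(x) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  b <- rc(r2)
  na <- nchar(r1); nb <- nchar(b)
  best <- NULL
  for (ov in seq(minOverlap, min(na, nb))) {
    a1 <- substr(r1, na - ov + 1, na)
    b1 <- substr(b, 1, ov)
    mm <- sum(strsplit(a1, "")[[1]] != strsplit(b1, "")[[1]])
    frac <- mm / ov
    if (frac <= maxMismatchFrac &&
        (is.null(best) || frac < best$frac ||
         (frac == best$frac && ov > best$ov)))
      best <- list(ov = ov, mm = mm, frac = frac,
                   len = na + nb - ov)
  }
  best
}

# Random DNA string (test-local; independent of the package helper).
rndDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")

# Longest complementary run between two sequences by brute-force substring
# scan against the reverse complement.
bruteComplementRun <- function(a, b) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  brc <- rc(b)
  best <- 0
  for (k in seq_len(min(nchar(a), nchar(brc)))) {
    subsA <- substring(a, 1:(nchar(a) - k + 1), k:nchar(a))
    subsB <- substring(brc, 1:(nchar(brc) - k + 1), k:nchar(brc))
    if (any(subsA %in% subsB)) best <- k
  }
  best
}

# A fixed test guide used across files.
testGuide <- function() guideSpec("GGGCACTAGCTTACGGATCC", "TGG")
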