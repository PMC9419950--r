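---
title: "AmpliCas methods: editing quantification, inhibitor design, and the synthetic truth model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AmpliCas methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AmpliCas)
```

# Scope and model

AmpliCas quantifies Cas9-induced indels from barcoded paired-end amplicon
sequencing and designs guide-complementary DNA oligo inhibitors. This
vignette documents the methods, the parameters that matter, the numerical
choices, and what the synthetic-data validation does and does not show.

## Coordinate and orientation conventions

All sequences are DNA, written 5'->3'. The spacer is the 20-nt variable part
of the guide; "PAM-proximal" means the spacer's 3' end. The protospacer
occupies a 0-based half-open interval on the amplicon reference; on the `-`
strand the protospacer is the reverse complement of that reference slice and
the PAM sits immediately 5' of it on the top strand (reference coordinates).
The blunt Cas9 cut falls between protospacer positions 17|18, i.e. 3 bp from
the PAM-proximal boundary. Internally all coordinates are 0-based half-open;
only human-readable report columns are 1-based.

# Inhibitor oligo design

A plain inhibitor of core length $k$ is the reverse complement of the
spacer's 3'-most $k$ nucleotides, so the oligo carries the same sequence as
the PAM-proximal part of the protospacer (target strand) and can hybridize
with the spacer-derived part of the guide RNA. The tested lengths are 8 and
20; `designInhibitor()` accepts any $k \in [1, 20]$.

PAM-loop variants prepend `PAM + loop + revcomp(PAM)`, so the oligo's first
three bases fold back and pair with the three bases preceding the core,
presenting a 3-bp double-stranded PAM to the ribonucleoprotein. The loop
linker is not fixed by the design principle; the default `TTTT` was chosen
because oligo-T linkers are the standard inert spacer in hairpin
constructions, and it is fully configurable. `hairpinCheck()` verifies the
intended 3-bp duplex and scans the rest of the oligo (exhaustive substring
complement scan) for unintended self-complementary runs of >= 6 nt, since
such runs could compete with the designed fold-back. No thermodynamic
folding (free-energy) prediction is attempted: checks are exact
complementarity only.

Scrambled controls are seeded uniform permutations of the parent oligo,
re-drawn until they differ from the parent and share no contiguous
complementary run of >= 8 nt with the spacer. The 8-nt threshold is our own
guard — an 8-nt perfect hybrid at the PAM-proximal (seed) end is the shortest
design that measurably engages the guide, so a control containing one could
retain function; the threshold is configurable. Because the identity
permutation is excluded, the draw is uniform over the remaining distinct
permutations (the test suite verifies uniformity over the 11 non-parent
permutations of a 4-mer by chi-square at 10,000 seeds).

# The sequencing-analysis pipeline

## Merging read pairs

`mergePairs()` scans every overlap of length >= `minOverlap` (default 20)
between read 1's 3' end and the reverse-complemented read 2's 5' end, and
keeps the overlap minimizing the mismatch fraction, ties broken in favour of
the longer overlap; pairs whose best overlap exceeds `maxMismatchFrac`
(default 0.1) are reported unmerged. Consensus bases take the
higher-quality read, ties favouring read 1. The defaults are conservative
settings for 150-nt pairs over ~240-bp amplicons, where the true overlap is
>= 60 nt; the merge is implemented in C++ and verified against an exhaustive
overlap-search oracle.

## Read structure and demultiplexing

A merged read is accepted iff it starts with a known 5-nt barcode (exact
match), immediately followed by that sample's forward-primer annealing part
and ending with its reverse-primer annealing part, each tolerating at most
`maxPrimerMismatch` substitutions (default 1). Barcodes are matched exactly
because they carry sample identity — a 1-substitution tolerance could
cross-assign samples whose barcodes differ at two positions; primer parts
tolerate sequencing error because they carry no identity information.
Rejected reads are tallied by failing flag (`no_barcode`, `fwd_primer`,
`rev_primer`). The barcode is trimmed from the accepted insert; primer
flanks are retained through alignment so the fit alignment stays anchored at
the amplicon ends, and indel events falling inside the primer-annealing
regions are excluded at calling time instead, so primer-region sequencing
errors can never count as locus indels.

## Alignment and locus assignment

Each insert is aligned to every amplicon reference in the panel with a fit
alignment — global in the read, local in the reference — under affine gap
penalties (match +2, mismatch −3, gap open −8, gap extend −1; a gap of
length $L$ costs $8 + L$). The penalties are set so that isolated Q30-level
substitution errors are absorbed as mismatches rather than opening gaps: one
mismatch costs 5 relative to a match, while the cheapest gap pairing costs
at least 11. Alignment uses `Biostrings::pairwiseAlignment`; scores are
verified against an independent exhaustive dynamic-programming oracle in the
test suite.

A read is assigned to its best-scoring locus. Two guards produce
`unassigned` reads: a minimum score (fraction `minScoreFrac = 0.5` of the
read's maximum attainable score, i.e. half of `2 * length`) rejects reads
that resemble no panel member, and exact score ties between loci are dropped
rather than double-counted. Aligning to the known amplicon panel replaces
genome-wide mapping: the loci are few and known in this assay design, which
removes an external aligner and a whole-genome index; this is the one
intentional methodological substitution in the pipeline, and it is why
off-target loci must be supplied by the user rather than discovered.

## Indel calling

CIGAR strings over `M`/`I`/`D` are derived from the alignment's
insertion/deletion ranges; `M` covers both matches and substitutions. Every
`I`/`D` operation becomes one event: insertions at 0-based between-base
reference positions, deletions at the 0-based leftmost deleted base. A read
"has an indel" when at least one event survives the primer-region mask —
whole-read counting, mirroring CIGAR-based scoring of reads with insertions
or deletions. An optional cut-site window (`windowHalfWidth`, suggested 25)
restricts counting to events near the cut; it is off by default because
whole-read counting is the primary definition, but it reduces the residual
false-positive rate from rare error-induced gaps. Position and length
spectra (`indelSpectra()`) are keyed relative to the cut site, with signed
lengths (+insertion, −deletion).

## Editing frequency, specificity, statistics

`pct_indels = 100 * reads_with_indel / reads_pass`, where `reads_pass`
counts structure-accepted, locus-assigned reads — the denominator choice is
documented here because pipelines differ: unassigned and structure-rejected
reads are excluded from both numerator and denominator. A zero denominator
is an explicit error, never a silent 0.

Specificity is `100 * on / (on + sum(off))` over the per-locus `pct_indels`
of one condition replicate: the percentage of observed indels that happen
on-target, corrected for per-locus read depth. It is scale-invariant,
monotone increasing in the on-target rate and decreasing in each off-target
rate, and undefined (error) when all rates are zero — conditions with
essentially no indels are excluded rather than reported as a meaningless
number. The implementation accepts any number of off-target loci; the
three-locus form (one on-target, two off-targets) is the tested default.

`compareGroups()` runs the conventional chain for triplicate condition
comparisons: Shapiro–Wilk normality on the ANOVA residuals, Levene's test
for variance homogeneity (median-centred, i.e. the Brown–Forsythe variant,
matching the common scipy default), one-way ANOVA, then Tukey's range test
with one row per unordered pair and 0.05/0.01/0.001 significance tiers. The
Tukey family is all pairwise comparisons within one panel; no cross-panel
correction is applied.

# The synthetic truth model

`makeLoci()` builds one on-target locus plus off-target loci whose
protospacers differ at an exact, user-chosen number of positions (default 2),
embedded in otherwise unrelated random 240-bp amplicons with valid NGG PAMs
on a randomly chosen strand; 20-nt primer annealing parts are the amplicon
ends. 240 bp keeps every 150+150 pair overlapping by >= 60 nt.

`simulateSample()` emulates the amplicon library: each template is
`barcode + amplicon`; with probability `true_indel_rate` the amplicon
carries exactly one indel — deletions with probability `deletionFraction`
(default 0.7, reflecting the deletion-dominated repair spectrum typically
seen at Cas9 cuts), lengths geometric with `pLen = 0.3` capped at 30 nt
(most real indels are 1–5 nt with a long tail), positioned uniformly within
±2 nt of the cut. Reads are the template's first 150 nt and the reverse
complement of its last 150 nt, with independent per-base substitution errors
(default 0.001, i.e. Q30) and constant Q30 quality strings; qualities are
only consumed at merge consensus, so a flat quality model is sufficient.
Everything is deterministic given the master seed; per-sample seeds are
derived from it.

What the simulator does **not** emulate: PCR amplification bias and
chimeras, multiple indels per template, substitution-only editing outcomes,
homology-directed repair, quality degradation along the read, and the true
indel spectra of any particular locus. Passing end-to-end tests therefore
demonstrates that the pipeline's bookkeeping, alignment and counting are
correct under a realistic error model — not that any biological claim about
a particular locus is reproduced.

# Validation scales and numerical choices

The end-to-end recovery check simulates the three-locus design at truth
rates 0.40/0.05/0.02 with 2000 read pairs per locus per sample and three
replicates (18,000 pairs), at which size every per-sample estimate should
fall inside the truth rate's 99% binomial interval and mean specificity
within 2 points of the formula value 100·40/47 = 85.1. Oracle-equivalence
tests run 200 random merge instances and 100 random alignment instances at
read lengths <= 40 nt against references <= 80 nt, where exhaustive dynamic
programming is cheap. These sizes were chosen as the smallest at which the
binomial intervals are tight enough to catch systematic biases of a fraction
of a percentage point.

Degenerate inputs are errors, not silent defaults: homopolymer parents in
`scrambleOligo()` (no distinct permutation exists), zero-variance groups in
`compareGroups()`, zero read denominators, missing t0 lanes in gel series,
and all-zero specificity inputs. Negative % digestion (a lane brighter than
its t0, densitometry noise) is retained raw with a clamped display column,
so downstream summaries can choose either.

# Gel densitometry module

Band intensities are consumed as a TSV exported from any densitometry tool;
no image analysis is performed. Within each (assay, condition) series the
t0 lane defines `I_rel = I / I_t0`, `% digestion = (1 − I_rel) · 100`, and
time-lapse summaries report mean ± SD over replicates per delay (seconds).
`predictFragments()` returns the two cleavage fragment lengths
`(cut, length − cut)` for annotating gels of linear substrates.

# Known limitations

- Off-target loci are user-supplied; there is no discovery step.
- Indel calling reports insertions and deletions only — no substitution
  outcomes, no UMI deduplication, no HDR quantification.
- The fit-alignment substitution of genome-wide mapping assumes reads
  genuinely originate from the supplied panel; contaminating loci surface
  only as unassigned reads.
- Exact complementarity checks in the designer are not folding predictions;
  a passing `hairpinCheck()` does not guarantee the hairpin forms under
  assay conditions.
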