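---
title: "Methods: small RNA miRNA discovery, expression and degradome analysis"
author: "mirstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA miRNA discovery, expression and degradome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mirstalk re-implements, as transparent and testable R code, the
computational chain used in plant small-RNA sequencing studies of
hormone-responsive miRNAs: read filtering, exact genome mapping, known and
novel miRNA annotation with hairpin stability metrics, TPM-based
differential expression, complementarity-penalty target prediction, and
degradome (PARE) cleavage-site classification. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## Read filtering

Raw reads are trimmed at the first exact occurrence of a 3' adapter prefix
of at least `min_adapter_overlap` nt (default 8; reads without any such
occurrence are discarded as `no_adapter`). The surviving inserts must then
pass four rules, applied in a fixed order so rejection tallies are
reproducible:

1. length within 10–30 nt,
2. not beginning with a 5' adapter prefix (`adapter5` contaminant),
3. no single-nucleotide run longer than 10 nt,
4. at most 10% N (strict inequality on the fraction).

All four thresholds are exposed in `filter_params()`. Adapter matching is
exact; mismatch-tolerant trimming would make the pipeline depend on a
scoring scheme the decision rules never state, and at these overlap lengths
exact matching loses almost nothing. Quality-based filtering is available
as an optional mean-Phred threshold (`min_mean_quality`, off by default):
the pipeline's decision rules are defined on sequence content, and read
simulators and collapsed public data sets frequently carry uninformative
quality strings.

Filtering is idempotent, conserves reads (`kept + rejected = input`), and
`collapse_unique()` reduces each library to distinct sequences with counts,
ordered lexicographically in the C locale so outputs are byte-stable across
platforms.

## Exact mapping and annotation

Clean reads are mapped to the genome with **zero mismatches** on both
strands. Because the criterion is exact identity, the mapper is a
seed-hash lookup (10-nt seed, the minimum read length) followed by
full-length string verification; its output is by construction the complete
set of exact occurrences, and the test suite checks it against a
position-by-position brute-force scan. Coordinates are 0-based half-open
internally; GFF3 export converts to 1-based inclusive.

A read is annotated as a **known miRNA** iff it is identical to a reference
mature sequence *and* that mature is a forward substring of its hairpin
record (ids are matched after stripping a `-5p`/`-3p` arm suffix). All
other mapped reads are classified by exact substring membership against
user-supplied per-class reference sets in a fixed hierarchy (rRNA, tRNA,
snRNA, snoRNA, scRNA, repeat, nat-siRNA, exon, intron — whichever sets are
provided), each read receiving exactly one class; what remains is a
`novel_candidate`, and unmapped reads are `other`. Multi-locus reads are
counted once per read (not split across loci): mature-sequence-centric
counting is the convention for miRNA expression, and the class hierarchy
resolves cross-class conflicts deterministically.

## Hairpin folding and stability metrics

Secondary structure comes from a deterministic maximum-weighted
base-pairing dynamic program (Nussinov-style): pair weights GC = 3,
AU = 2, GU = 1, minimum hairpin loop 3 nt, and a traceback that prefers
pairing, then an unpaired 5' base, then an unpaired 3' base, then the
leftmost bifurcation. The DP maximum is verified against exhaustive
enumeration for all test sequences up to 18 nt. The folder's score is
reported as a *pseudo-energy* (−total pair weight). Thermodynamic minimum
folding free energies in kcal/mol are not recomputable from printed data
without binding to a specific external folding engine, so wherever MFEI is
computed a real MFE can be supplied as an input column
(`precursor_metrics(sequence, mfe = ...)`); published table values are
reproduced exactly from their printed MFE/LP/GC inputs.

The stability index is

$$\mathrm{MFEI} = \frac{|\mathrm{MFE}|/L_P \times 100}{\mathrm{GC\%}}$$

with GC% computed over non-N positions (N excluded from numerator and
denominator — the neutral choice for masked bases). Display rounding is
half-up to 2 decimals, as precursor tables conventionally print; full
precision is kept internally.

## Novel miRNA discovery

Candidate loci are read *stacks*: collapsed sequences whose best
single-library count reaches `min_stack_count` (default 10 reads — below
that, star-arm evidence and duplex geometry are not meaningfully testable,
and degradation background floods the candidate list). Stacks on the same
scaffold and strand within a 292-nt span (the largest precursor the
pipeline accepts) are paired into mature/star duplex candidates, the more
abundant stack taken as the mature. Orphan stacks are folded inside
one-sided windows of increasing extension (mature at the window edge, the
geometry of real precursor arms), up to a 70-nt flank.

Before any fold, a candidate must contain an 11-nt reverse-complement
match to the mature (a star arm carries such a match by definition of
pairing); after folding, the mature must lie on a stem arm: at least 60%
of its bases paired, partners forming a contiguous interval disjoint from
the mature, and at least half of the mature in one uninterrupted helix.
Random sequence pairs diffusely under a maximum-pairing folder and fails
the helix-run requirement, which is what keeps degradation background out
of the candidate list.

The two acceptance rules are then applied exactly as printed:

* **(i) star-supported**: star reads present and the star interval equals
  the pairing partner of the mature shifted to leave 2-nt 3' overhangs on
  both duplex ends (`p(m2−2) = s1`, `p(m1) = s2−2`, tolerance ±1 nt — the
  Dicer-processing signature; the tolerance absorbs single-nucleotide
  register ambiguity in maximum-weight folds);
* **(ii) multi-library**: without read-covered star support the candidate
  must be detected in at least 2 distinct libraries (replicates count as
  independent libraries, matching the 18-library design).

A duplex is reported once: any candidate whose mature sequence is the
star sequence of another candidate is dropped as a passenger-strand
duplicate (abundant stars can seed their own stacks, occasionally at a
secondary exact-match locus).

## Quantification and differential expression

Expression is normalised as TPM = reads / total clean reads × 10⁶, using
the library's total *clean* reads (the printed definition), not the
miRNA-assigned total. Differential expression per miRNA between two
groups of libraries uses:

* `log2FC = log2((mean TPM_B + 1) / (mean TPM_A + 1))` — a 1-TPM
  pseudocount handles zeros and is recorded in the output;
* a Wald statistic with negative-binomial variance
  `Var(count) = μs + φ(μs)²`, where `s` is the library size factor
  (clean reads / 10⁶) and the dispersion `φ` is a per-miRNA method-of-
  moments estimate pooled across both groups, moderated toward the
  across-miRNA median with a prior weight of `prior_df = 10`
  pseudo-samples and floored at 10⁻⁸ — with three replicates per group
  the raw moment estimator is far too noisy to use per-gene, and
  moderation toward a shared central value is the standard remedy in
  count-based expression analysis;
* a *t* reference with `n_A + n_B − 2` degrees of freedom (a small-sample
  guard: with three replicates per group the moment dispersion estimate is
  noisy, and the normal reference is anti-conservative);
* Benjamini–Hochberg adjustment (`stats::p.adjust`), the standard meaning
  of "adjusted p-value" in this literature.

The decision rule is the printed one: significant iff |log2FC| ≥ 1 and
adjusted p ≤ 0.05. The test is antisymmetric under group swap, and
miRNAs with zero counts throughout both groups are dropped. Comparison
summaries report per-contrast up/down tallies and all Venn regions for up
to three contrasts. RT-qPCR relative expression is the standard
2^−ΔΔCt computation.

## Target prediction and degradome classification

Target sites are scored on ungapped antiparallel alignments (miRNA
position *i* faces site position *L−i+1*): Watson–Crick pairs cost 0, G:U
wobbles 0.5, other mismatches 0.5, penalties doubled at miRNA positions
2–13, and sites pass at a total score ≤ 4 (inclusive — the cutoff is read
as the maximal admissible score, the TargetFinder convention). The 0.5
mismatch penalty differs from TargetFinder's canonical 1.0; it is
implemented as printed and exposed in `penalty_params()`. Gapped/bulged
sites are out of scope: the printed scheme defines no gap penalty, and
inventing one would change the decision boundary silently.

Degradome reads mark cleavage products: each read's first 20 nt
(configurable; tolerates 3' quality decay) is matched exactly against the
transcript set and increments a 5'-end counter at the match start,
multi-transcript hits incrementing each hit. The expected cleavage
position of a site is the transcript base pairing miRNA position 10
(`window_start + L − 10`). Sites with degradome evidence are categorised
with explicit precedence:

| precedence | condition at the site | category |
|---|---|---|
| 1 | exactly one read | 5 |
| 2 | unique maximum on the transcript | 1 |
| 3 | tied maximum | 2 |
| 4 | ≥ median | 3 |
| 5 | < median | 4 |

The single-read test precedes categories 1–4 because a transcript whose
only signal is one read at the site would otherwise be ambiguous between
categories 1 and 5; the median is computed over positions with at least
one read (the CleaveLand convention). Both choices are visible in the
documentation and the category function is total over sites with ≥ 1 read.

## The synthetic-data generator

`sim_config()` defaults define the study conditions the package is tested
under: 18 libraries (stem/root × control, short-term, long-term treatment
× 3 replicates), 10⁶ raw reads per library, negative-binomial counts with
dispersion 0.05, twenty planted 4-fold changes (ten up, ten down) in the
stem short-term contrast, and read lengths dominated by 24- then 21-nt
tags. Each library is 40% planted miRNA reads, 15% genome-derived
background fragments, ~40% unmappable clean tags, and ~4% reads destined
for each filter (no adapter, 5' contaminant, length, homopolymer, N-rich),
so clean-read fractions land near the high-90s% and roughly half of the
filtered tags map — the shape of real deep-sequencing summary tables.
Background fragments are drawn from a fixed pool with exponential
abundance weights shared across libraries (degradation products recur
across libraries in real data); pool fragments identical to a planted
mature or star are resampled so planted counts remain exactly recoverable
at the default error rate of 0.

Planted precursors are `mature + loop + reverse complement of the mature`
with 2-nt 3' overhangs on both duplex ends. The loop is all-C and the
terminal characters of the mature are constrained (last four nt `AACC`,
first two never containing both U and G) so that the duplex anchor pairs
are unambiguous under maximum-weight folding — without these constraints
the open duplex end can form a spurious terminal pair that shifts the
fold register by 2 nt and breaks the overhang test for a perfectly real
hairpin. The first nucleotide remains U-biased (48.5%), the reported
tendency for AGO1-loaded miRNAs. Each generator stage draws from its own
seed substream, so adding a stage never perturbs another stage's output,
and a fixed seed yields byte-identical FASTA/FASTQ.

Degradome truth plants one perfect-complement site per transcript and
engineers the 5'-end profile so each intended category is achievable by
construction (unique maximum for category 1, tied maximum for 2, and so
on), with twenty transcripts of 600 nt and four sites per category.

What passing these tests shows: the pipeline's decision rules recover
planted signal exactly under their own assumptions, with zero decoy
acceptance, ≥ 95% hairpin recovery, DE sensitivity ≥ 0.9 at observed
FDR ≤ 0.1, and correct degradome categories. What it does not show:
robustness to sequencing error, adapter mismatches, bulged duplexes,
repeat-rich genomes, or thermodynamic folding differences — real data
contain all of these, and the corresponding parameters (`error rate`,
adapter overlap, penalty weights, folding MFE source) are exposed
precisely so users can tighten or relax them.

## Problem sizes and determinism

The recovery study runs at the full design (18 × 10⁶ reads, ~2 GB of
FASTQ) in well under an hour on one core; unit tests use a 1/50-depth
configuration that exercises identical code paths in seconds. All
randomness flows from a single integer seed; the pipeline itself is a pure
function of its inputs and parameters, and every report bundle carries a
JSON manifest with parameters, seed and md5 checksums so any bundle can be
reproduced exactly.

## Known limitations

* The folder maximises pair weight, not free energy; pseudo-energies are
  suitable for structure and duplex geometry, not for comparing against
  published kcal/mol values (supply an MFE table for that).
* Exact adapter and reference matching: a single sequencing error in an
  adapter or mature read drops that read from the corresponding tally.
* Ungapped target model only.
* The multi-library rule treats any two libraries as independent evidence;
  it does not model batch structure.
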