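---
title: "Methods: template-bias analysis and CPO complexity estimation for randomized peptide libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-bias analysis and CPO complexity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overflapr)
```

## The problem

A randomized peptide expression library is built by replacing a template
CDS (here a 39-nt, 13-residue peptide between the last codon of a
secretion signal and the stop codon) with a designed 54-nt fully
degenerate (NNN) region, amplifying the whole plasmid, re-circularizing,
and transforming. Deep amplicon sequencing of the randomized region then
serves as quality control. Three questions matter:

* What fraction of the library still resembles the template
  (insufficient randomization caused by preferential primer annealing)?
* How skewed are variant abundances (PCR jackpot effects)?
* How many distinct variants does the library actually contain, given
  that the number of transformed colonies — not the number of distinct
  reads — bounds the molecules captured?

`overflapr` answers these from a FASTQ of single-end amplicon reads, a
template specification, and the observed colony count.

## Pipeline model and assumptions

**Anchored extraction.** The randomized region is located by finding the
two constant sequences that surround it. The search is semi-global under
unit-cost edits (substitutions and indels): the whole anchor must align
within the read, and a hit is accepted when its edit distance is at most
`floor(rate × anchor length)` with `rate = 0.1` by default — the
conventional adapter-trimming tolerance; the exact tolerance used
upstream of published datasets is typically unreported, so the rate is a
configuration value recorded with every run. Ties are resolved
deterministically (lowest distance, then leftmost start, then shortest
span) so fail-reason tallies are reproducible. Anchors overlapping the
read ends only partially are rejected: extracting truncated regions from
clipped reads would contaminate the length distribution.

The extracted region is the sequence strictly between the anchors: left
flank codon + insert + stop codon. Retention filters apply in a fixed
order — empty region, ambiguous base, flank mismatch, length not a
multiple of three — and the first failure is recorded. Flank matching is
exact: flank identity is a hard retention criterion, not something to be
error-corrected, because the flanks double as a frame check. Reads with
IUPAC ambiguity codes in the region are discarded (a codon containing N
cannot be assigned a peptide); both orientations are searched and, when
both yield anchors, the orientation with the smaller total anchor edit
distance wins (ties go to forward).

**Template-bias classification.** Each retained region is globally
aligned (Needleman–Wunsch, linear gaps) against the reference = left
flank + template insert + right flank — the flanks are included because
the extracted region contains them, and a template read-through matches
the full 45-nt reference exactly. A region is *insufficiently
randomized* when `n_mismatches < 10` and `n_gap_columns < 3`.

Three conventions here were genuinely open and are worth stating:

* *Scoring:* match +1 / mismatch −1 / gap −1. The classification consumes
  only mismatch and gap counts, which are robust to the exact scheme; the
  scores are configurable and logged.
* *Strict vs inclusive bounds:* "fewer than ten mismatches and three
  gaps" is read as strict bounds on both quantities. The inclusive
  reading is available as `classifier_params(inclusive_bounds = TRUE)`.
* *Gap columns vs gap openings:* gaps are counted per alignment column.
  With a bound of 3 the distinction matters; column counting is the
  stricter and simpler convention.

Because co-optimal alignments can differ in their mismatch/gap split, the
traceback is deterministic (diagonal > up > left), and the reported
counts are defined as those of that traceback. A useful geometric
consequence: any global alignment of a 60-nt region against the 45-nt
reference has at least 15 gap columns, so a full-length random insert can
*never* be classified as template-biased — misclassification in that
direction is structurally impossible, not just unlikely.

**Peptide quantification.** Regions translate in frame 0 with the
standard genetic code; the stored peptide is flank residue + insert
peptide + terminal `*`. Internal stops are kept as `*` by default
(`internal_stop_policy = "keep_symbol"`): sub-full-length peptides in the
length distribution are attributed to nucleotide-level deletions, not to
nonsense codons, and truncation would silently merge distinct DNA
variants. `truncate_at_stop` is available for users modelling expressed
products. Variant identity is at the peptide level — synonymous reads
are summed — with nucleotide-level collapse available for diagnostics.
Reads are classified individually and each peptide takes the majority
class of its supporting reads (ties go conservatively to
`insufficiently_randomized`); collapsing before classification would
instead assign each peptide the alignment of an arbitrary representative
read. The peptide length distribution excludes the terminal `*`, so a
full designed insert has length 19 (flank residue + 18 insert residues).

**CPO complexity estimation.** Fractions are computed over *passed*
reads, never raw reads — this is forced by the estimator's anchor
identity: `Σ_i CPO_i = Σ_i f_i N_c = N_c`, which only holds if the
fractions sum to one over the peptide-coding reads. CPO is computed over
all variants jointly; class-level CPO sums are then partitioned, which
preserves the additive structure (per-class quantities sum to overall
ones). The estimate is

`N̂ = |{CPO ≥ 1}| + round(Σ_{CPO<1} CPO)`,

with the boundary CPO = 1 counted in the first group and
half-away-from-zero rounding — the everyday convention; banker's
rounding would surprise non-programmers and differs only at exact .5.
`N̂` can exceed the colony count by at most one.

**Composition.** Per-position amino-acid frequencies over the insert
positions (flank residue excluded) are compared with the uniform-NNN
expectation (codon multiplicity / 64, stop included at 3/64). The
default weighting is by read, matching a read-level average; by-variant
weighting is offered because post-CPO diversity claims are variant-level.
Divergence is summarized as total-variation distance — the simplest
bounded summary, 0 iff the distributions coincide — with a per-position
chi-square statistic as a secondary, descriptive column (no multiplicity
correction: the table is exploratory, not inferential). Sequences
shorter than a position drop out of that position's denominator, keeping
every row normalized. Only plain NNN randomization is modelled; NNK/NNS
schemes would need a different theoretical vector and are an extension
hook, not a default.

## The synthetic generator

The generator emulates the statistical structure of the three library
archetypes so the pipeline can be exercised end to end without any
download:

| preset | bias fraction | template variants | skew (σ) | aberration rate | colonies |
|---|---|---|---|---|---|
| `wpa` | 0.50 | 8 | 2.5 | 0.02 | 3802 |
| `overflap` | 3e-5 | 1 | 1.2 | 0.01 | 4534 |
| `overflap-asym` | 0 | 0 | 0.8 | 0.005 | 4865 |

Template-like inserts are the template CDS with i.i.d. substitutions at
rate 0.02 per base (≈0.8 expected substitutions over 39 nt — far below
the 10-mismatch classification bound, so template-like reads classify as
biased with near certainty). Random inserts are uniform 54-mers;
abundances are log-normal(0, σ) normalized so the template-like pool's
mass equals the bias fraction exactly. Jackpot skew is modelled
phenomenologically by the log-normal rather than by a mechanistic
cycle-by-cycle PCR simulator, which would be speculative. Insert-length
aberrations (whole-codon changes with probability 0.8, frame-breaking
otherwise; deletion or duplication of a contiguous segment) produce both
short-but-in-frame peptides and filter-failing reads. Sequencing errors
are i.i.d. substitutions (0.005/base) plus single-base indels in
homopolymer runs of length ≥ 3 (0.01/run), the dominant artefact class
of semiconductor sequencing; anchors receive the same error process. No
quantitative aberration or error rates accompany published libraries of
this kind, so these defaults are order-of-magnitude choices, fixed once.
Roughly half of the reads are emitted reverse-complemented; quality
strings are constant placeholders. A single master seed derives
per-stage substreams, so truth tables and read sets are byte-reproducible.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: position-dependent base-calling error profiles,
read-length truncation, chimeric reads, primer-dimer contamination,
plasmid copy-number variation between cells, and colony-size effects on
read sampling. The colony count is a free parameter of the truth,
deliberately decoupled from the number of true variants, so estimator
behaviour under miscounted colonies is testable.

## Numerical choices and degenerate inputs

* Alignment scores are small integer-valued doubles; traceback
  comparisons use an absolute tolerance of 1e-9.
* The CPO identity `Σ CPO = N_c` is asserted to 1e-9 relative tolerance.
* Empty inputs are first-class: an empty FASTQ yields an empty read
  table; a run in which no read passes completes with a warning and an
  empty summary (estimate 0), not an error.
* Percentages are reported at two decimals, except that values rounding
  to 0 or 100 keep one significant figure of their distance from the
  boundary (0.003, 99.997) — matching how such tables are conventionally
  printed.

## Problem sizes used by the test suite

The suite validates the aligner and anchor scan against independent
oracles (recursive score enumeration on 500 random pairs of length ≤ 12;
a vectorized DP oracle on 10,000 random anchor/sequence cases, plus
brute-force substring enumeration with tie-break checks on 400 cases),
classification geometry on 10,000 random inserts, bias recovery on a
50,000-read simulated biased library (recovered template share within
0.50 ± 0.01), complexity recovery on a uniform 200-variant library at
100,000 error-free reads (estimate within ±10%), and composition on a
100,000-read unbiased simulation (per-position TV distance < 0.02, the
binomial sampling envelope at that depth). These sizes keep the full
suite under a minute on one CPU while leaving each check's statistical
power intact. All stochastic tests run under a single fixed master seed
(101), chosen as suite policy.

## Known limitations

The CPO estimator inherits the accuracy of the colony count: imaging
typically under-segments dense plates, and the estimate scales linearly
with `N_c`. Unequal plasmid copy numbers and growth-rate differences
between clones distort read fractions away from colony probabilities; no
correction is applied because none is well-identified from the data the
pipeline sees. Richer species-richness estimators (Chao1, rarefaction)
are intentionally not part of the default output — the package's purpose
is the CPO construction itself — though the variant table exposes
everything needed to compute them externally. Alignment is
nucleotide-level with linear gaps; affine-gap or protein-level alignment
is out of scope, as are paired-end logic, base-quality recalibration and
demultiplexing.
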