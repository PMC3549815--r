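---
title: "The correction model behind kcorrect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The correction model behind kcorrect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcorrect)
```

## The problem and the generative model

Reads from single-cell (MDA-amplified) libraries cover the genome with
weights spanning orders of magnitude, so the usual k-mer-multiplicity
histogram has no valley separating errors from signal. `kcorrect`
therefore never applies a coverage cutoff. Instead it models each k-mer
position independently: a base call at position `j` of k-mer `x` is wrong
with probability `q_x[j]`, and when the same k-mer is observed several
times the evidence multiplies — a multiset of occurrences that agree on
nucleotide `j` is jointly erroneous there with probability equal to the
product of the individual error probabilities. Phred qualities supply
those probabilities (`q = 10^(-Q/10)`), which is also the model's central
assumption: **quality strings are taken at face value as calibrated error
probabilities**. Miscalibrated qualities degrade the method in the
obvious direction (overconfident qualities make bad k-mers look solid;
underconfident ones suppress correction).

The likelihood that k-mer `x` arose from a true center `c` is

```
L(x | c) = prod over j with x[j] != c[j] of q_x[j]
         * prod over j with x[j] == c[j] of (1 - q_x[j])
```

and the maximum-likelihood center of a cluster is its
multiplicity-weighted consensus string. A single-parameter variant with a
fixed per-position error rate `epsilon` (default 0.01) is kept as
`hammer_likelihood()` for the emulation mode (`hammer_emulate = TRUE`),
which reduces the algorithm to one consensus center per Hamming
component and lets users quantify what the Bayesian refinement adds.
Errors are substitutions only — distances are Hamming distances, and
indels are out of scope by construction.

## Stage by stage

**k-mer statistics.** One pass over the reads collects, per distinct
k-mer, its multiplicity and the per-position log-sums of base error
probabilities. k-mers containing `N` are discarded — this is the only
masking rule, and the FASTQ reader funnels every non-ACGT base into `N`
to keep it that way. A disk-bucketed counter (`bucketed_count()`, hash
into spill files, sort each lexicographically, aggregate equal runs)
reproduces the in-memory result for inputs whose k-mer set would not fit
in RAM; a property test asserts the two paths agree.

**Hamming components.** Edges join k-mers at distance at most `tau`. If
two k-mers are within distance `tau` and the index set `{0..k-1}` is
split into `tau + 1` parts, at least one part carries zero mismatches, so
equality blocks under each part are a complete candidate-pair cover. Two
partition families are used: contiguous runs first, then strided
(congruence classes mod `tau + 1`) for blocks above `max_quadratic`
members; every resulting block is processed pairwise into a union–find
structure. Two levels suffice because the two families are the ones with
a worst-case guarantee here; oversized second-level blocks are simply
processed pairwise, which preserves exactness at worst-case cost. When
`tau + 1` does not divide `k` the parts differ in size by one, which
leaves the pigeonhole argument untouched. Components are
provably identical to the brute-force all-pairs graph — the test suite
checks this against an independent oracle on hundreds of random sets —
and independent of input order and of `max_quadratic`.

**Subclustering.** Components can merge distinct true centers: diverged
repeat copies, or unrelated k-mers chained by intermediate vertices. Each
component is re-clustered by m-means under Hamming distance for
`m = 1, 2, 3, ...`, scored by `2 log L_m - (3km + m - 1) log N`, stopping
at the first non-improvement (the likelihood term alone would always
prefer more clusters; the BIC penalty charges `km` parameters for
centers, `2km` for conditional substitution probabilities and `m - 1` for
mixture proportions). Initial centers are the `m` members with the
highest probability of being error-free — high-multiplicity, high-quality
k-mers — so on well-separated components the first assignment is already
the answer.

**Solid selection and expansion.** `p_x = prod_j (1 - q_x[j])` is the
probability k-mer `x` is error-free; `p_C = 1 - prod_{x in C} (1 - p_x)`
the probability a cluster holds at least one correct k-mer. Cluster
centers with `p_C` above the solid threshold are trusted. Singletons are
deliberately not special-cased: a chance cluster of several junk k-mers
is *more* likely than a junk singleton of the same total multiplicity, so
both face the same bar. Reads completely covered by solid occurrences
then donate all their k-mers to the solid set, iterated to a fixed point;
the fixed point is monotone in the starting set and independent of read
order (each pass judges coverage against the pass-start snapshot).
Coverage must come from *observed* occurrences: a consensus center that
never occurs in a read can vote during correction but cannot cover.

**Correction.** Per read position, solid k-mers vote their own letter and
non-solid k-mers with solid centers vote the center's aligned letter; the
majority wins. Ties keep the original base when it is among the leaders
(stability), otherwise the fixed order A &lt; C &lt; G &lt; T applies —
both rules exist purely to make output deterministic. Zero-vote positions
are never touched, read length is preserved, and corrected bases keep
their original quality characters so the FASTQ fields stay aligned.

## Tunables

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 21 | k-mer length; long enough to be near-unique in bacterial genomes, short enough that 100 bp reads carry ~80 k-mers. Larger k showed no benefit in the regime this method targets. |
| `tau` | 1 | Hamming edge threshold. 1 is the cheapest sound choice (each extra unit multiplies candidate blocks); 2 is supported and tested. |
| `solid_threshold` | 0.999 | Strict by design: admitting a wrong center corrupts reads, while a missed true center usually gets rescued by expansion. |
| `epsilon` | 0.01 | Fixed error rate of the single-parameter likelihood (emulation mode only). |
| `max_quadratic` | 1000 | Block size above which the strided re-split kicks in; caps pairwise work per block at ~5·10^5 comparisons. Result-invariant. |
| `max_iterations`, `change_fraction_stop` | 3, 0.002 | "Keep iterating while a substantial amount changes": the fraction is not canonical, so both knobs are exposed. In practice iteration 1 does almost all the work. |
| `phred_offset` | 33 | 64 available for legacy Illumina FASTQ. |
| `canonical` | off | Strand merging (`min(x, revcomp(x))`); off because the substitution model treats strands independently. |
| `bic_distinct` | off | Reads the BIC observation count `N` as distinct k-mers instead of total multiplicity. The default (multiset size) matches the likelihood, which multiplies one term per occurrence. |

Error probabilities are clamped to `[1e-10, 1 - 1e-10]` before any
product: the statistics multiply probabilities across occurrences, and an
exact 0 or 1 would be absorbing. All products are accumulated in
log-space; with default clamping the per-position products underflow a
double around multiplicity 150, which real MDA peaks exceed easily.

## What the simulator emulates — and what it does not

`make_genome()` / `make_reads()` generate the regime the pipeline is
designed for: i.i.d. genomes (optionally with planted repeat pairs at a
stated Hamming divergence, to exercise subclustering), lognormal
per-locus amplification weights (`sigma_coverage` = sdlog; 1.5 gives the
orders-of-magnitude spread typical of MDA, 0 gives uniform multi-cell
coverage), both strands, and substitution errors injected with *exactly*
the probability the emitted quality encodes. Calibration is tested: per
quality value, the realized error frequency sits in the binomial 3-sigma
band of `10^(-Q/10)`.

Passing tests on this simulator therefore demonstrate the algorithm under
its own assumptions. Real data violate them in known ways the simulator
deliberately omits: quality miscalibration, sequence-context error bias,
indels, chimeric MDA artefacts and foreign-DNA contamination. Results
here say nothing about those failure modes; the simulator's role is
correctness and sensitivity analysis, not benchmarking against real
libraries.

## Numerical and degenerate-case choices

* Natural logarithms everywhere (BIC convention).
* m-means ties: members go to the lowest-indexed nearest center; consensus
  ties resolve A &lt; C &lt; G &lt; T; empty clusters are reseeded with
  the member farthest from its assigned center; iteration caps at 100
  rounds (assignments almost always stabilise in 2–3).
* Initial m-means centers tie-break by higher multiplicity, then
  lexicographic order — determinism again.
* A component of one k-mer returns immediately with `m = 1`.
* Unobserved consensus centers receive a synthetic `p_x` built from the
  members' per-position error products at center-agreeing positions (at
  every position some member agrees, since the center is the consensus).
* Empty inputs (no reads, reads shorter than k, all-N windows) flow
  through every stage as empty tables rather than errors.
* The m-sweep compares `ℓ_m` values that all include their penalty term;
  with `N = 1` the penalty vanishes identically, reproducing the
  closed-form worked examples in the tests.

## Problem sizes used by the shipped checks

The test suite and the acceptance script size their simulations to the
reference study conditions — a 10 kb genome at ~30× mean coverage (3,000
× 100 bp reads, ~1% error) for end-to-end checks, with smaller genomes
for per-stage properties — which keeps the full suite in the low minutes
on a single core while still exercising tens of thousands of distinct
k-mers per run.

## Known limitations

* **Substitutions only.** Indel errors shift every downstream k-mer and
  are invisible to the Hamming model.
* **Low-coverage near-duplicates.** If a k-mer lies within distance `tau`
  of a much better covered variant — diverged repeat copies, or the rarer
  case of a read's k-mer being one mismatch from its own reverse
  complement at a near-palindromic locus — and its own multiplicity is
  too small for the BIC to justify a second cluster, it is absorbed and
  its reads are "corrected" toward the majority variant. This is the
  intended trade-off at multiplicity 1–2 (an error is the likelier
  explanation), but it means idempotence on error-free reads is a
  property of adequate coverage, not an unconditional guarantee; at the
  ~30× study conditions it holds in the shipped checks.
* **Quality trust.** Everything downstream of the Phred decode inherits
  whatever miscalibration the sequencer introduced.
* **No contamination or chimera handling**, and paired-end structure is
  ignored (mates are corrected as independent reads).
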