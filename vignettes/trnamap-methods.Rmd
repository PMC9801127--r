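---
title: "Mutational profiling of tRNA modification enzymes with trnamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational profiling of tRNA modification enzymes with trnamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnamap)
```

# The measurement model

Watson–Crick-face methylations such as m¹A and m¹G interfere with base
pairing during reverse transcription.  A processive RT (TGIRT-class
enzymes in particular) either reads through the lesion and records a
non-templated base in the cDNA — a *misincorporation* — or terminates,
truncating the cDNA.  Sequencing the cDNA therefore converts a chemical
modification into a statistical signal: the per-position *mutation rate*,

$$
r_{p} \;=\; \frac{\text{mutated reads at } p}{\text{reads covering } p},
$$

which rises from the sequencing-error floor (~10⁻³) to values as high as
~0.8 at a strongly modified site.  Because the untreated transcript pool
shares every other source of mismatch (sequencing error, alignment
artifacts), the modification level is estimated by the background-subtracted
rate, clamped at zero:

$$
r^{\mathrm{sub}}_{p} = \max\!\left(0,\; r^{\mathrm{treated}}_{p}
 - r^{\mathrm{untreated}}_{p}\right).
$$

`trnamap` implements this measurement twice, deliberately:

1. **Alignment-based profiling** (`assignReads()` + `buildProfile()`):
   each read is aligned semi-globally against every reference in the
   pool, the best reference wins, and mismatches/deletions are tallied
   per position.  This is the right tool for a *diverse* pool
   (e.g. ~59 tRNA species).
2. **Exact-sequence-match counting** (`buildVariantQueries()` +
   `countExact()` + `computeMRate()`): for a *single-point variant
   library* the reads are nearly identical and alignment cannot
   attribute a read to its variant reliably, so we instead count reads
   containing each of four exact full-length sequences that differ only
   at the monitored target position.  The per-variant statistic is

   $$
   M_{\mathrm{rate}} = \frac{\mathrm{Read}_{\mathrm{Mutant}}}
                            {\mathrm{Read}_{\mathrm{Total}}},
   $$

   with the same untreated subtraction.

Both routes are kept as independent code paths; their agreement on a
common simulated pool (r² ≥ 0.99) is one of the package's standing
validation checks.

# Study conditions emulated by the simulator

The synthetic-data module generates the data the analysis assumes, with
the following defaults chosen once to match the experimental system a
user of this workflow works in:

* **Pool**: ~20–59 tRNA-like references of 70–90 nt (the natural length
  range), optionally with skewed abundances.  `syntheticTRNAPool()`
  forces a G start, a CCA end and an A at the monitored position
  (label "22"), mirroring the m¹A22 system the package is organized
  around.
* **Signature**: a saturated m¹A-type site uses a misincorporation rate
  of 0.79 — the level observed for the best substrates of an m¹A22
  methyltransferase — with a substitution spectrum uniform over the
  three non-templated bases.  The true spectrum of m¹A under TGIRT is
  not well characterized; the spectrum is configurable and none of the
  downstream statistics depend on it (only the non-reference mass
  matters).
* **RT stops**: modeled as truncation retaining the tRNA 3′ side,
  because cDNA synthesis primes from the 3′ adapter.  This reproduces
  the qualitative missing-data pattern of real tRNA libraries, where
  D-arm positions drop below the depth floor for poorly reverse-transcribed
  species.  When `stopRate > 0` the truth table's expected rates ignore
  the (small) correlation between stopping and modification status at
  the same position; the convergence tests therefore use `stopRate = 0`.
* **Sequencing error**: uniform substitutions at a configurable per-base
  rate (default 0.001, an Illumina-class figure).  Indel errors are not
  modeled: the statistic is substitution-based and the exact-match
  counter would simply drop indel reads from `Read_Total` without
  biasing the rate.
* **Adapter and qualities**: the standard small-RNA 3′ ligation adapter
  `CTGTAGGCACCATCAAT` is appended to every read; qualities are constant
  Q37 because no quality-based filtering is part of the statistic.
* **Orientation**: reads are emitted in tRNA sense.  The profiler can
  additionally try the reverse complement (`tryReverseComplement`),
  which should be enabled for real libraries of unknown orientation and
  left off for simulator output.

What passing tests on these simulations *do* show: the estimators are
unbiased, converge at the binomial rate, agree across the two
quantification routes, and recover designated truth exactly when the
error rate is zero.  What they do *not* show: robustness to RT
sequence-context biases, ligation bias, PCR duplicates, or
multinucleotide mutation clusters — none of which the simulator
attempts to emulate.

# Library design and transcription cassettes

`designPointVariantLibrary()` enumerates, for each mutable position, all
three base substitutions (3 × |positions| variants), ordered by position
then by base (A < C < G < U) so outputs are diff-stable, and named in
RNA bases (`U8A`).  The monitored target position is never mutable: its
base is the readout and mutating it would destroy the signal's
interpretability.  By default every label is mutable except the target
and — when the tRNA ends in CCA — the three CCA labels, which the RT
primer anchors; an 84-label tRNA thus yields the canonical 240-variant
screen (80 positions × 3).  Which positions beyond these to exclude is
an experimental choice, so the designer takes an explicit label list.

Position labels are free-form strings supplied by the annotation
(Sprinzl-style, insertion labels like `20a` or `45b` allowed) rather
than computed: automatic Sprinzl alignment is a hard problem of its own
and non-standard variable-arm labels are common, so the mapping is left
to the curator.

`buildT7Cassette()` embeds the (DNA-encoded) tRNA between the T7
promoter `GCGTAATACGACTCACTATA` and the constant 38-nt tail carrying the
BsaI site.  An extra G is prepended when the tRNA does not begin with
one (T7 initiates poorly otherwise) and CCA is appended when absent;
run-off transcription of the BsaI-digested template then always yields
a G-starting, CCA-ending transcript — `predictedTranscript()` returns
exactly that, and a property test enforces it for arbitrary input.

# Numerical choices

* **Alignment scoring**: match +1, mismatch −1, linear gap −2 per gap
  position, read aligned end-to-end with free reference end-gaps.  The
  real pipeline this emulates delegates alignment to a dedicated
  mutational-profiling aligner; these are conventional short-read
  values, exposed as configuration.  A read is unassigned when its best
  score ties a second reference (ambiguity must not leak into rates) or
  falls below 0.6 × the maximum attainable score.  The inner dynamic
  program is implemented in C++ (as every alignment tool does); an
  exact-equality fast path skips the DP only when no reference contains
  another, so the tie rule is unaffected.  `Biostrings::pairwiseAlignment`
  serves as an independent oracle for the scores in the tests.
* **Mutation events**: mismatches and deletions count toward the rate;
  insertions are tracked but excluded from the numerator by default,
  since the headline signals are misincorporations.  A flag
  (`countInsertions`) includes them.
* **Depth floor**: positions with fewer than 1000 covering reads are
  flagged missing (the standard MaP depth requirement); the floor is
  per position, so partially covered references yield partial profiles,
  and references missing everywhere are reported "not analyzable".
* **Thresholds**: a modified position is called at subtracted rate
  strictly > 0.01; a variant has lost activity at subtracted
  M_rate strictly < 0.05; both boundaries are exercised by tests.
  `Read_Total` below 100 flags an M_rate undefined rather than
  reporting a noisy ratio.
* **Exact matching**: default mode is substring containment of the
  full-length variant sequence (reads still carry adapters); full-length
  equality mode is available for trimmed data.  A read with any error
  inside the query region matches nothing and drops out of
  `Read_Total` — this thins counts without biasing M_rate because
  errors are position-independent.  Window-restricted queries were
  considered and rejected as a default: the full-length query keeps the
  per-variant query sets provably disjoint.
* **Michaelis–Menten fitting**: Levenberg–Marquardt nonlinear least
  squares with positivity bounds; initialization `Vmax₀ = max(v)`,
  `Km₀ = S` at the velocity closest to `Vmax₀/2`.  No Lineweaver–Burk
  linearization is used anywhere (reciprocal transforms bias the
  estimates).  Negative velocities are clipped to 0 with a warning.
  Unidentifiable designs — velocities flat across concentrations, i.e.
  only the saturated regime observed — are flagged (`converged(fit) ==
  FALSE`) rather than raised, with Km standard error > 10 × Km or a Km
  at the box bound as the flag criterion.  A brute-force grid search
  over (Km, Vmax) confirms the optimizer's minimum in the tests.
* **Group comparison**: Welch's two-sided t-test on replicate rates,
  the standard choice for n = 3 groups with unequal variances; a
  permutation test bounds it in the test suite.  Degenerate zero-variance
  input returns p = 1 (equal means) or 0.
* **Determinism**: every random draw flows from one integer seed;
  module-level sub-seeds are derived by a fixed affine map kept below
  2³¹.  With a fixed seed the simulator's FASTQ output is byte-identical
  across runs.

# Problem sizes used in the standing validation

The validation suite regenerates everything from code: the
method-agreement check simulates 20 references × 50,000 reads per
sample (treated and untreated) at error 0.001 and requires r² ≥ 0.99
between the two quantification routes; the variant-screen recovery uses
a 33-variant library (11 positions) at 4000 reads per variant with a
designated zero-efficiency set and requires exact recovery of the lost
set at error 0; kinetic refits use 6 concentrations × 3 replicates with
3% multiplicative noise and require Km within 15% (noiseless refits to
at least 4 significant digits).  The smaller unit tests use pools of
1–8 references and a few thousand reads with binomial (3–4 SD)
tolerances.

# Known limitations

* The profiler is a simplified stand-in for a full mutational-profiling
  aligner: no ambiguity re-alignment, no quality trimming, no
  multinucleotide-mutation merging.  Whether indels should count toward
  the rate is exposed as a flag because conventions differ.
* Exact-match counting requires error-free reads across the whole query;
  at high error rates or long references `Read_Total` shrinks
  accordingly (unbiased but noisier).  The optional relaxation of one
  mismatch outside the target region is deliberately not implemented:
  it would break the disjointness guarantee that makes the counts
  unambiguous.
* The simulator draws reads independently; no PCR duplication,
  circularization artifacts or index hopping.
* Kinetic fits treat velocities in whatever units they are supplied;
  no volume/enzyme normalization is attempted.
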