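---
title: "Models and methods behind bisamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bisamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisamp)
library(tibble)
```

# The assay and what the package computes

Multiplex bisulphite PCR sequencing (MBPS) amplifies a panel of short
(~100–150 bp) target regions from bisulphite-converted DNA in a single
multiplex reaction and sequences the amplicons deeply. After
conversion, unmethylated cytosines read as T while 5-methylcytosines
remain C, so the per-CpG *beta* value — the fraction of reads carrying
C at a CpG — estimates the methylated-molecule fraction. `bisamp`
implements the computational chain of such an assay: panel definition,
read preprocessing and bisulphite-aware assignment, per-CpG
quantification, coverage QC, PCR-bias calibration, sensitivity
analysis and read-level epiallele summaries, together with a simulator
whose ground truth makes every stage testable without any external
data.

# Panel model

A panel row carries the genomic interval (0-based half-open, BED
native), the amplicon reference insert, primer lengths and the offsets
of every literal `CG` dinucleotide. Two representation choices matter:

- **Primer-overlapped CpGs are non-callable.** Primer bases are
  chemically synthesised; where a primer covers a CpG the assay orders
  a degenerate Y/R base there, so the sequenced base reports primer
  synthesis, not genomic methylation. Such CpGs keep their offsets but
  are flagged `callable = FALSE` and excluded from methylation calling.
  (Reported CpG counts can therefore be computed under either
  convention — with or without primer CpGs.)
- **Degenerate bases never define a CpG and never count as
  mismatches.** `Y` matches C/T and `R` matches G/A during assignment.

`bis_reference()` gives the expected post-conversion sequence: on the
original-top (OT) strand every non-CpG C reads T and CpG Cs are
ambiguous (`Y`); the original-bottom (OB) strand is reported in
forward orientation with non-CpG G as A and CpG Gs ambiguous (`R`).
Genome build is a label only; nothing is downloaded.

# Read simulator

The simulator emulates, per amplicon:

1. **Coverage** — reads drawn negative-binomially (`mean_coverage`,
   `dispersion`; variance $\mu + \mu^2\phi$). The default
   $\phi = 0.2$ reproduces the visibly uneven coverage of real
   multiplex panels while keeping most amplicons within a few-fold of
   the mean; $\phi = 0$ gives exact depth for controlled experiments.
2. **Molecule methylation** — all-or-none (each molecule fully
   methylated with probability `level`, the appropriate model for
   mixtures of fully methylated and unmethylated control DNA), per-CpG
   Bernoulli (mosaic epialleles), or an explicit pattern distribution.
3. **PCR bias** — molecules are sampled for sequencing with weight
   $b^f$, where $f$ is the molecule's methylated-CpG fraction. For
   all-or-none methylation at level $E$ this yields an observed
   methylated-read fraction $bE/(bE + 1 - E) = bE/(1+(b-1)E)$ —
   exactly the single-parameter law the calibration module fits, so
   forward simulation and correction are mutually checkable. A
   composition-dependent sampling weight was chosen over per-cycle
   branching because it is analytically transparent while reproducing
   the same observed/expected relation.
4. **Bisulphite conversion** — unmethylated C reads T with probability
   `conversion_rate` (default 0.995, matching routinely observed
   rates above 99.4%); methylated C reads T with probability
   `inappropriate` (default 0).
5. **Sequencing error** — per-base substitutions at `seq_error`
   (default 0.001) with constant Q40 qualities; sequencers for this
   assay publish no error model, so these are conventional,
   configurable values. An optional two-state degradation model drops
   a read tail to Q2 to exercise trimming.

Reads span the full amplicon insert — the targets are shorter than
typical read lengths — so there is no fragmentation model, and
paired-end merging, adapters and primer dimers are out of scope. Every
emitted read is recorded in a truth table (molecule pattern, apparent
post-conversion pattern, conversion and error event counts), enabling
exact-recovery tests. A fixed seed makes FASTQ and truth output
byte-identical.

For deep-coverage power experiments, `simulate_calls()` runs the same
molecule → bias → conversion chain but stops at per-read CpG calls
without rendering sequences. With no sequencing error the full
trim/assign/call pipeline provably recovers exactly those calls (the
test suite asserts byte-level identity of recovered and simulated
patterns), so the two routes are interchangeable there; the call-level
route keeps 50-repetition, 100,000-read experiments tractable.

# Trimming and bisulphite-aware assignment

Trimming follows the assay's standard recipe: clip 1 bp from both
ends, trim the 3' end while the terminal base quality is below 30,
discard below 20 bp (a read of exactly 20 bp is kept). Clipping is a
one-shot operation on raw reads; the quality trim and length filter by
themselves are idempotent.

Assignment replaces genome alignment with a bespoke ungapped matcher
over the panel: targets are short, pre-defined and fully spanned by
the reads, so indels are out of model. Each read is scored at every
feasible offset against both bisulphite strands of every amplicon. The
match rule treats every original-C position (OT) as the ambiguity
class {C,T} — a read T there is a conversion event and a read C a
retained cytosine, neither a mismatch — and symmetrically {G,A} for OB
(reads are reverse-complemented into forward orientation first).
Everything else that differs is a *non-bisulphite mismatch*; the best
placement wins if it has at most 1 such mismatch (configurable).
Tie-breaks are deterministic and documented: within an amplicon, the
lowest offset and OT before OB; across amplicons, an exact tie is
`AMBIGUOUS` and the read is dropped from all counts — the simplest
defensible rule, rather than fractional weighting. The test suite
checks the matcher against an exhaustive brute-force scorer on
randomised panels.

Methylation is read out at callable CpGs (C → methylated, T →
unmethylated, anything else → `N`; `N` counts toward neither allele).
The bisulphite conversion rate is estimated from non-CpG cytosines:
converted/(converted + retained) over all assigned reads.

# Coverage QC and rebalancing

An amplicon–sample pair below 100 reads is a dropout (strictly below:
100 passes) and is removed from the methylation table; an amplicon is
a panel-level dropout when its *median* coverage across samples falls
below the threshold — the median is robust to single failed samples.
The rebalancing plan operationalises post-sequencing panel rescue:
relative to the panel median, amplicons below 0.5× are suggested a
doubled primer concentration, above 2× a halved one, and dropouts move
to a separate sub-panel at 3× concentration. The 0.5×/2× cutoffs are
package choices (the decision is made by eye from boxplots at the
bench) and are configurable.

# PCR-bias calibration

Post-conversion, methylated (C-rich) and unmethylated (T-rich)
templates can amplify at different efficiencies, biasing the observed
beta. Calibration uses a gradient of methylated-control mixtures
(default design 0/10/25/50/75/90/100%) per amplicon. The default
model is the single-parameter hyperbola

$$O = \frac{bE}{1 + (b-1)E},$$

fitted by bounded 1-D least squares over $b \in [0.01, 100]$
(`stats::optimize`, tolerance $10^{-9}$). It fixes 0 and 1, is
monotone, and inverts in closed form,
$\hat E = O/(b - (b-1)O)$, so correction is exact — the round trip
holds to $10^{-12}$ across the $E \times b$ grid. A cubic polynomial
regression of expected on observed is available as an alternative
correction curve for amplicons whose bias is not well described by a
single coefficient; it is evaluated and clamped to $[0,1]$ (clamping
is reported). The `needs_correction` flag is $|b - 1| > 0.1$ in both
modes — a configurable package choice, since the assay literature
reports how many amplicons were corrected but not the criterion — and
the amplicon-level $b$ is applied at per-CpG resolution, with amplicon
means recomputed afterwards.

# Sensitivity analysis

How much coverage is needed to distinguish a small methylation
increase from the unmethylated control? The experiment mirrors the
bench design: replicate control samples at 0%, 1% and 5% across
independent runs, downsampled to each coverage in
$\{100, 1000, 10^4, 10^5\}$, per-amplicon mean betas compared by a
one-sided (greater) Welch t-test against the 0% group, with the star
scheme ns / * / ** / *** (and **** below $10^{-4}$). Choices made
where the convention is unstated:

- **Welch across replicates** matches the replicate structure of the
  design and is robust to unequal variances (the spike-in group has
  molecule-sampling variance the 0% group lacks); a pooled-count
  one-sided proportion test is available as an alternative.
- **No multiple-testing correction by default** — reports are
  per-amplicon stars; Benjamini–Hochberg is available via
  `p_adjust = "BH"`.
- **Downsampling is without replacement** (subsampling the observed
  read pool); a bootstrap option exists.
- **Zero-variance groups yield `NA`**, not a fabricated p-value
  (possible at 0% under perfect conversion).

At the defaults — conversion 0.995, three replicates, two
representative amplicons with 4 and 6 CpGs — the modal smallest level
distinguishable from 0% at 1000x is 1%, and the modal lowest coverage
at which 1% is significant is 1000x, with detection power
non-decreasing in coverage; `scripts/acceptance.R` recomputes exactly
these quantities over 50 seeded repetitions (pools of 10,000 reads for
the 1000x experiment and 100,000 for the down-sampling grid — sizes
chosen so the deepest grid point is fully populated), taking the mode
over repetition × amplicon outcomes.

# Epiallele patterns and cross-platform comparison

The pattern matrix tabulates distinct per-read methylation strings per
(sample, amplicon) with counts and frequencies. Frequency is defined
as count over N-free assigned reads; patterns containing `N` are
reported but excluded from normalisation (published pattern figures
are ambiguous about the denominator — this one guarantees frequencies
sum to 1 and a minimum nonzero frequency of 1/reads). The
pattern-weighted mean methylation equals the mean per-CpG beta exactly
when every read covers every CpG without `N` — an identity the tests
assert.

`platform_compare()` correlates two per-CpG beta tables (e.g. this
assay against whole-genome bisulphite sequencing) over shared keys,
either absolutely per sample or as per-amplicon methylation
differences between a sample pair, which typically agrees better
across platforms than absolute values. It requires at least 3 shared
sites and reports Pearson r with its p-value.

# What the simulations do and do not establish

Passing the simulation-based suite shows the pipeline is
self-consistent: assignments are provably optimal under the stated
match rule, calling recovers simulated truth exactly in the noiseless
limit, the bias model round-trips, and the sensitivity claims hold
under the stated noise model. Real data add effects the generator does
not model — indels and chimeric reads, context-dependent conversion
failure, primer-dimer artefacts, strand-asymmetric methylation, SNPs
under primers or at CpGs — so concordance with an orthogonal platform
on real samples remains the decisive validation, and the
cross-platform operation exists precisely for that.

# Limitations

- Ungapped matching: reads with indels are unassigned rather than
  rescued.
- One bias coefficient per amplicon; per-CpG bias is not modelled.
- Single-end, full-insert reads; no paired-end merging.
- No SNP-aware calling.
- Genome build is metadata; exported coordinates are 0-based (BED)
  with an opt-in 1-based flag.
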