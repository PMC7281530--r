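---
title: "Methods: simulating and analysing pooled shRNA drop-out screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing pooled shRNA drop-out screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The screen being modelled

A pooled shRNA drop-out (viability) screen transduces a cell population
with a library of hairpins — here modelled on a boutique library of
4020 hairpins targeting 1677 genes (about 2.4 hairpins per gene) —
selects, treats replicate flasks with a drug at a low-inhibition dose
(EC10) or leaves them untreated, and after several weeks of culture
reads hairpin representation by amplicon sequencing of genomic DNA.
Hairpins whose representation falls under treatment mark "rescuer"
genes: genes whose silencing removes drug resistance. The package
implements every computational stage of this design — read simulation
and counting, representation (sampling-error) analysis, depletion /
enrichment / loss calling with cross-drug overlaps, and the
dose–response and drug-combination synergy analyses used to pick
screen doses and validate combination partners.

Because raw screen sequencing data of this kind are rarely deposited,
the package pairs every analysis step with a synthetic-data generator
whose ground truth is returned alongside the data. All conclusions the
test suite draws are therefore statements about recovery of known
truth under a controlled noise model, not about any particular
biological dataset.

## Synthetic data: what is emulated, and what is not

**Library and abundance.** `generate_library()` draws unique hairpin
sequences (default 21 nt) with a configurable gene/hairpin structure;
`generate_abundance()` models the skewed representation left by
transduction and expansion as a log-normal profile: weights
$\exp(\mathcal N(0, \sigma^2))$, normalised to sum to one. For a large
library the coefficient of variation of the profile approaches
$\sqrt{e^{\sigma^2}-1}$, which the tests verify. Log-normal was chosen
as the simplest heavy-tailed, one-parameter family; real post-selection
profiles also contain dropout and multimodality that this does not
attempt to capture.

**Amplicon reads.** `amplicon_model()` describes the sequenced PCR
product as three fixed segments — forward primer (53 nt), vector
insert carrying the hairpin at a fixed offset (513 nt), reverse
segment (68 nt, of which 30 nt adaptor and 9 nt sample barcode) — for
a 634 nt product, sequenced as full-length single-end reads.
`generate_reads()` draws hairpins multinomially from the abundance
profile and splices them into this scaffold; sequencing noise is
restricted to uniform base substitutions (no indels), which is enough
to exercise mismatch-tolerant matching without modelling
platform-specific homopolymer error. Quality strings are constant; PCR
amplification bias and duplicate reads are deliberately out of scope.
The exact per-hairpin tally used is always returned, so recovery tests
never re-infer truth from reads.

**Planted effects.** `effect_spec()` plants treatment ground truth as
per-hairpin abundance multipliers (depletion < 1, enrichment > 1) or
outright loss (probability forced to zero). `simulate_screen_counts()`
draws replicate count matrices directly at the count level — untreated
arms from the base profile, treated arms from the effect-adjusted
profile — with optional extra between-replicate noise: each
replicate's expected profile is perturbed log-normally so counts carry
a chosen additional CV on top of multinomial sampling. Defaults follow
the triplicate design (3 treated vs 3 untreated flasks) at a depth of
$10^6$ reads per sample, a typical depth for a ~4000-hairpin pool.

**Dose matrices.** `generate_dose_matrix()` builds combination
surfaces from two four-parameter Hill curves under probabilistic
independence, $y_1 + y_2 - y_1 y_2$, plus a constant interaction
offset $\delta$ on interior cells and optional Gaussian noise, clipped
to $[0,1]$. $\delta = 0$ with no noise is an exact zero-interaction
surface, the calibration point for synergy scoring.

## Hairpin counting

`count_hairpins()` demultiplexes by the barcode at its fixed offset
(the last 9 nt of the read under the default model) and identifies the
hairpin by extracting the fixed-offset hairpin window and matching it
against the library — exact hash first, then Hamming distance for the
remainder. Offsets are deterministic in this amplicon design, so
alignment would add cost without information. Policy decisions, all
surfaced as parameters:

* default tolerances: 1 barcode mismatch, 2 hairpin mismatches;
* barcode maps must be separable — pairwise Hamming distance strictly
  greater than twice the barcode tolerance — or counting refuses to
  start;
* ties at the same best distance are counted ambiguous, never
  assigned, avoiding silent misassignment;
* reads shorter than the model, or matching nothing within tolerance,
  are reported as unassigned; the report categories always partition
  the reads seen;
* zero-count hairpins are kept as explicit matrix rows so that "lost"
  classification downstream is well defined.

## Sampling-error simulation

`simulate_sampling()` models passaging bottlenecks as multinomial
draws (sampling with replacement from a large pool) and summarises the
per-hairpin CV of counts across replicates. For probability $p$ and
$n$ draws the CV follows $\sqrt{(1-p)/(np)}$; at $10^6$ draws from a
uniform 4020-hairpin pool the per-hairpin mean is ~248.8 counts and
the CV ~0.063, and the probability of missing any hairpin entirely is
$\approx e^{-248.8}$, i.e. full representation. The relative-error
metric is the CV across replicates; a hypergeometric refinement
(sampling without replacement from a finite flask) was considered and
rejected since the cell pool is much larger than the sample.

## Hit calling

`call_hits()` implements the screen statistic as a per-hairpin
pipeline over a `screen_counts` object:

1. **Normalisation** to reads per million (each sample scaled to
   $10^6$), preserving within-sample ratios; a median-of-ratios option
   exists for screens dominated by a few hairpins.
2. **Abundance filter**: only hairpins whose *mean raw* count across
   untreated control replicates strictly exceeds `min_raw = 100` are
   tested; the rest are carried forward as `filtered`. The mean (rather
   than requiring every replicate to pass) is the least brittle reading
   of a control-abundance rule.
3. **Loss detection**, before any ratio: a kept hairpin whose raw
   treated counts are all zero is `lost` — the count-matrix analogue
   of points plotted on the axis of a drop-out scatterplot. Loss takes
   precedence over the fold/p rule.
4. **Test and ratio**: a two-sided classical equal-variance Student
   t-test on normalised counts (treated vs control; Welch available as
   an option), and
   $\log_2\!\frac{\bar{x}_T + c}{\bar{x}_C + c}$ with pseudocount
   $c = 0.5$ normalised units keeping depleted-but-nonzero hairpins
   finite.
5. **Classification**: `depleted` if $\log_2$ ratio $\le -1$ and
   $p < 0.01$; `enriched` symmetrically; otherwise `unchanged`. The
   five classes partition the library exactly. Benjamini–Hochberg
   adjusted p-values are reported for context, but calling uses the
   raw p-value with the two-fold rule, matching the primary-hit
   convention of drop-out screens; the symmetric treatment of
   enrichment is an assumption.

Degenerate inputs are defined rather than accidental: zero variance in
both arms with equal means gives $t = 0$, $p = 1$ (unchanged); zero
pooled variance with unequal means gives $p$ at the smallest positive
double; fewer than two replicates per arm is an error.

`intersect_hits()` intersects one class across contrasts at hairpin
level and maps the result through the library to genes; `lost`
hairpins count as depleted by default, being depletion's extreme.

### Calibration and power

With no planted effects the fraction of kept hairpins at $p < 0.01$
sits at ~1% (the suite pools 50 null triplicate screens of 2000
hairpins). Power depends strongly on the between-replicate CV because
a 3-vs-3 equal-variance t-test estimates the pooled variance with only
4 degrees of freedom: at 8× planted depletion the suite and the
acceptance script measure ~100% recall at 5–10% CV but ~93% at 20%
CV, essentially independent of sequencing depth once counts are in the
hundreds. This is a property of the linear-scale Student t itself —
log-scale testing would be more powerful at high CV, but linear
normalised counts are what this pipeline tests by design.

## Dose–response fitting and ECx

`fit_hill()` fits
$y(d) = e_{\min} + (e_{\max}-e_{\min})\,\frac{d^h}{\mathrm{EC}_{50}^h + d^h}$
by Levenberg–Marquardt least squares (`minpack.lm::nls.lm` on the
residual function directly), with box constraints
$e_{\min}, e_{\max} \in [0,1]$, $\mathrm{EC}_{50} > 0$,
$h \in [0.05, 20]$, start values taken from the data range and the
first dose crossing the half response, and tight tolerances
(`ftol = ptol = 1e-15`, 500 iterations) so that noiseless curves are
recovered to $10^{-6}$. A fitted span $e_{\max}-e_{\min} < 0.01$ is
flagged flat rather than silently inverted. `estimate_ecx()` inverts
the curve in closed form,
$\mathrm{EC}_x = \mathrm{EC}_{50}\,(f/(1-f))^{1/h}$ with
$f = (x/100 - e_{\min})/(e_{\max}-e_{\min})$, and refuses targets
outside the achievable span — this is how an EC10 screening dose is
derived from a monotherapy curve.

## ZIP synergy scoring

`zip_delta()` follows the zero-interaction-potency convention:

* monotherapy Hill curves are fitted to the dose-0 margins;
* the null expectation at each combination cell is the independence
  combination $y_A + y_B - y_A y_B$ of the monotherapy predictions;
* the observed surface is smoothed by conditional potency-shifted
  fits: along each row (drug A varying at fixed B) and each column,
  a four-parameter Hill curve is fitted to the interior cells with a
  free baseline — under independence the conditional response is
  exactly a Hill curve with baseline $y_B$, so the free-baseline fit
  nests the null. The two directional fits are averaged. A line with
  fewer than four interior doses, or a failed fit, falls back to the
  raw observed values and is logged;
* the delta surface is $100\times(\text{fitted} - \text{expected})$
  in percentage points; the **overall** score is its mean over
  combination cells and the **most synergistic area** (MSA) is the
  maximum mean over any contiguous 3×3 dose window (the conventional
  window size; configurable).

On exact zero-interaction surfaces the delta is numerically zero, and
a planted constant offset $\delta$ is recovered as $100\,\delta$
points. One caveat found while validating: "MSA ≥ overall" is not a
theorem for arbitrary matrices (a surface concentrated on the corners
of a 4×4 grid defeats it, because 3×3 windows under-weight corners);
it does hold on the spatially coherent surfaces that ZIP fitting
produces, and the tests check it there, alongside agreement of the MSA
search with a brute-force all-windows scan.

Viability readouts are reduced to vehicle-normalised inhibition
fractions; `read_dose_matrix()` also accepts raw fluorescence via
$1 - (v - \text{blank})/(v_{\text{vehicle}} - \text{blank})$ and clips
negative inhibition to zero with a message.

## Problem sizes and reproducibility

The test suite and the acceptance script run at the scale of the
design they model: 500–4020-hairpin libraries, $10^5$ reads per
counting check, $10^6$ multinomial draws × 100 replicates for the
sampling analysis, 50 null + 10 planted triplicate screens of 2000
hairpins at $10^6$ reads per sample, 6×6 dose matrices, and 100 random
synergy surfaces. Every stochastic step takes an explicit integer
seed, restores the caller's RNG state, and is bit-reproducible under a
fixed seed. `scripts/acceptance.R --seed <int> --out <path>` recomputes
the headline quantities from scratch through the installed package.

## Known limitations

* The abundance model is log-normal by choice; real library profiles
  are not guaranteed to follow it.
* Sequencing noise is substitution-only; indel-rich platforms would
  need indel-tolerant matching that this package deliberately omits.
* Hit calling is per-hairpin; gene-level aggregation statistics (RRA
  and similar) and pathway enrichment are out of scope.
* Synergy scoring implements the ZIP model only (no Loewe, HSA, or
  Bliss-only modes, no bootstrap confidence intervals), and published
  overall/MSA synergy scores from other studies are not reproducible
  without their raw viability matrices.
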