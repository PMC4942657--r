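---
title: "Single-marker quantification of multicomponent HPLC assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification of multicomponent HPLC assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qams)
```

## The problem

Quality control of a herbal drug such as *Fructus Corni* (the fruit of
*Cornus officinalis*) should track many active components at once — iridoid
glycosides (morroniside, loganin, sweroside, cornin, cornuside, the
7-*O*-methyl- and 7-*O*-ethylmorroniside epimer pairs) together with organic
acids (gallic acid, 5-hydroxymethyl-2-furfural). The classical external
standard method (ESM) needs a calibrated reference substance for every
analyte on every run, but several of these compounds are expensive or not
commercially available at all.

*Quantitative analysis of multicomponents by single marker* (QAMS) removes
that requirement. One abundant, stable, cheap compound — here loganin — is
calibrated as the **internal reference substance**; every other analyte is
quantified through a fixed **relative correction factor** (RCF) established
once during method development. This package implements the complete QAMS
workflow for peak-table data: calibration, RCF estimation and ruggedness
testing, peak identification by relative retention time, quantification by
both routes, method-validation statistics, and a ground-truthed simulator so
that every stage is testable without instruments.

## The model

Each compound $i$ is assumed to respond linearly over its validated range,

$$A_i = k_i C_i + b_i,$$

with $A$ the integrated peak area (arbitrary detector units), $C$ the
solution concentration (µg/mL). Only ratios of areas enter the single-marker
formulas, so the area unit never matters. The response factor of $i$ is
$f_i = C_i / A_i$, and the RCF of $i$ against the reference $s$ is

$$f_{is} = \frac{f_i}{f_s} = \frac{C_i \, A_s}{C_s \, A_i}.$$

Given a located sample run, the reference concentration $C_s$ comes from
inverting loganin's own calibration curve, and every target is

$$C_i = f_{is} \cdot A_i \cdot \frac{C_s}{A_s},$$

using the compound's *mean* RCF — the method's premise is precisely that
$f_{is}$ is a constant of proportionality, so per-run factors are never
substituted. Solution concentrations convert to herb contents via the
preparation record ($m$ g of powder, $V$ mL extraction volume, dilution $d$):

$$\text{content (mg/g)} = \frac{C \cdot V \cdot d}{1000 \, m},$$

2 g / 50 mL / no dilution by default. With that preparation the loganin
concentrations of typical samples (≈250–350 µg/mL) fall inside its
calibrated range, which is what fixes the mg/g unit interpretation of the
bundled content table.

Two exact identities are worth knowing (both are enforced by tests):

* when every intercept is zero and the RCFs equal the calibration slope
  ratios $k_s/k_i$, QAMS and ESM coincide algebraically for *any* areas;
* the RCF is invariant under a common rescaling of all areas (detector
  gain). Absolute QAMS contents are gain-invariant only end-to-end — the
  gain must also act on the calibration standards so the fitted slope
  absorbs it; with a frozen curve only the concentration *ratios* to the
  anchor are invariant, because the anchor concentration is inverted from
  the gained area. This distinction is easy to get wrong and is the reason
  the invariance tests rescale the curve together with the run.

## Peak identification by relative retention time

QAMS runs carry no standard for most analytes, so peaks are identified by
their **relative retention time** (RRT), $t_i / t_s$. The reference peak
itself is anchored first: the largest-area peak within ±5% of the expected
anchor retention time. Area, not proximity, breaks ties because the internal
reference is chosen to be abundant; absolute anchor positions are
system-specific configuration, not published constants.

Every other compound then receives candidate peaks whose observed RRT
deviates from its expected RRT by at most a tolerance (default 5%,
per-compound overrides allowed since observed RRT dispersions range roughly
1–5% across instruments and columns). Candidate (compound, peak) pairs are
assigned greedily in order of ascending relative deviation with per-peak
exclusivity. Compounds left without a peak are reported *not detected* — an
explicit state, never a zero. Two compounds claiming one peak at exactly
equal deviation raise an ambiguity error rather than guessing: with epimer
pairs sitting 0.01 RRT apart, silent misassignment is worse than a failure.
Global nearest-deviation order (rather than processing compounds strictly by
expected RRT) matters for merged peaks: a co-eluting cornin/sweroside peak
lies relatively closer to sweroside's expectation, so sweroside wins the
peak and cornin is flagged — matching what an analyst reports when those two
fail to separate at 35 °C.

## Validation statistics

All dispersion reporting uses $\mathrm{RSD} = 100 \, s / \bar x$ with the
*sample* (n−1) standard deviation; that convention reproduces the bundled
replicate-RCF dispersion rows, the population form does not. Spike recovery
is $100 (\text{detected} - \text{original}) / \text{added}$; the alternative
$\text{detected}/(\text{original}+\text{added})$ form fails to reproduce the
bundled loganin and morroniside recovery rows and was rejected. Precision,
repeatability and stability reports accept either peak areas or computed
contents (labeled), apply a 5% RSD pass threshold by default, and skip
single-measurement groups with a warning.

Method agreement (`compare_methods`) pairs contents on (sample, compound),
drops not-detected pairs, and reports per-compound mean and maximum relative
differences plus a paired two-sided t-test (Wilcoxon signed-rank as an
option). Degenerate inputs are handled explicitly: identical pairs (to
floating-point noise) give p = 1; a constant nonzero shift gives p = 0. Note
that with ~30 paired samples the t-test resolves systematic offsets well
below 1%, so "statistically significant" and "practically different" part
ways quickly; the per-compound relative differences are the quantities to
read alongside the flag.

## The synthetic study generator

`generator_config()` describes one simulated HPLC system; from it,
`generate_standard_series()`, `generate_sample_batch()` and
`generate_condition_panel()` produce ground-truthed injections, and
`simulate_study()` writes a complete study (six-level calibration series,
21 crude + 10 processed samples, a multi-condition panel, and the generating
truth) as plain-text files. Identical seeds reproduce identical bytes, and
every source of randomness requires an explicit seed.

What the generator emulates:

* linear detector response per compound on the scale of the bundled
  calibration slopes, with multiplicative lognormal area noise (default CV
  2%, the low-percent repeatability of a well-behaved system);
* retention positions at the bundled mean RRTs, anchored at a configurable
  loganin retention time (31 min default, inside a 50-minute gradient; the
  generated run window is 55 min so late peaks survive drift);
* the crude/processed composition pattern: crude samples lack
  5-hydroxymethyl-2-furfural and both *O*-ethylmorronisides;
* condition panels in which RCFs stay within the 5% ruggedness band, and a
  35 °C failure mode where cornin and sweroside are emitted as one merged
  peak (summed area, area-weighted retention time).

Four modeling choices deserve their rationale:

**True intercepts default to zero.** The bundled fitted curves keep their
intercepts for fixture replay, but the generator's true response is
proportional. Fitted intercepts are calibration artifacts of the measured
range; extrapolating them to trace-level concentrations far below that range
(the 7α-*O*-methylmorroniside contents correspond to ~0.4 µg/mL, where the
fitted intercept would be ~60% of the signal) produces nonphysical areas and
breaks every recovery guarantee for reasons that have nothing to do with the
method under study.

**A per-configuration response gain stands in for RCF drift.** Each
compound's realized slope differs from the bundled reference slope by a
fixed gain drawn once per configuration (uniform ±5%, reference fixed at 1),
so the simulated system's true RCFs are reference slope ratios perturbed by
up to 5%. The gain is shared by standards and samples of that system — as a
real detector's response is. Applying such a perturbation to samples only
would shift QAMS and ESM identically and produce no method offsets at all
(both estimates are scaled by the same factor, as the zero-intercept algebra
above shows); what actually makes externally sourced RCFs disagree with
same-system calibration is response drift *between* systems, which is what
this models.

**Retention drift is correlated, not independent.** Run-to-run drift
(default CV 1%) is shared by all peaks of a run and cancels in RRT;
independent per-peak jitter is tiny (default CV 0.05%, about a second at
mid-run). Condition-to-condition selectivity changes are a monotone stretch
of retention relative to the anchor (default CV 0.5%), so neighboring peaks
move together and elution order is preserved across conditions. Independent
per-peak drift of ~1% would swap the epimer pairs (0.01 RRT apart) in a
substantial fraction of runs — but the real assay resolved and assigned
those pairs on every instrument, column and sample, so such a generator
would emulate a different, worse instrument than the one being modeled.

**Sample contents are uniform over the observed ranges.** Per-compound
ranges span the bundled 31-sample content table (e.g. loganin 6.2–8.7 mg/g);
preparation is fixed at 2 g / 50 mL.

What the generator does *not* emulate: raw detector signal and peak
integration, physical retention modeling from the gradient program, detector
saturation or nonlinearity, carry-over, and correlated noise between
compounds. Passing tests therefore demonstrate the correctness of the
*computations* under realistic magnitudes of noise and drift — not the
chromatographic fitness of any particular instrument method.

## Checks the test-suite runs, and how they are read

Replays of the bundled reference tables assert printed means at their
printed rounding, with one systematic allowance: transcribed cells are
themselves rounded, so a mean of six 3-decimal cells is compared within
0.001, and published dispersions (computed before rounding) are compared
relatively. With only two or three 2-decimal cells, a published RSD of order
0.2–3% is simply not recoverable from the printed table — three cells of
0.93 recompute to an RSD of exactly 0 whatever the unrounded values were —
and the corresponding assertions document that irreducible gap rather than
hide it.

End-to-end recovery on the simulated study is asserted per compound: the
mean QAMS content over a 31-sample batch must land within 3× the area CV of
the generating truth for every detected compound. Per-injection bounds at
that multiple would be a ~2σ statement that any 300-measurement batch
violates a handful of times by construction; the per-compound mean is the
estimate the method actually reports. One instructive pattern the simulation
exposes: for trace components quantified near or below the bottom of their
calibrated range, ESM inversion inherits the full uncertainty of the fitted
intercept, while the ratio-based QAMS route does not — so QAMS-vs-ESM
comparisons are read only where ESM is itself in range, and the two trace
epimers show exactly the large relative discrepancies at 0.01–0.09 mg/g that
the bundled sample table also shows.

Problem sizes used by the default tests and the acceptance script: a
six-level calibration series (stock/1 … stock/32, matching the bundled
linearity ranges), 31-sample batches, and 4–9-condition panels with three
dilution levels each — the scale of the study the package models.

## Numerical and degenerate-input policy

* Out-of-range and negative inverted concentrations are returned flagged
  (`below_range`/`above_range`/`negative`), never rejected: contents near
  range edges must remain computable.
* Not-detected is an explicit state distinct from zero everywhere: missing
  ruggedness cells are excluded from means, never imputed; not-detected
  pairs are dropped from method comparison.
* Calibration requires three distinct concentrations (the mathematical
  floor) and warns below six (the customary design).
* One RCF observation per injection run; observations are never averaged
  before aggregation.
* All RNG use is seeded explicitly, and package functions restore the
  caller's RNG state.

## Limitations

The package processes peak tables; it does not integrate raw signal or read
vendor formats. Absolute retention times are configuration, so anchoring
depends on a sensible expected anchor position per system — if the reference
peak is absent, the largest in-window peak wins, and on a pathological run
that can be a neighbor (the abundance tie-break makes this unlikely, not
impossible). RCF constancy is an assumption to be *verified* by the
ruggedness tools, not a law; the package detects violations against a
threshold and deliberately does not model why a column or temperature shifts
a factor.
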