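---
title: "Methods: serine flux, incorporation and labeling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serine flux, incorporation and labeling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serflux)
```

This vignette is the package's own account of the models and estimators it
implements, the parameters that matter, the numerical choices behind them,
and what the synthetic-data generators do and do not emulate.

## Constraint-based model and flux variability

A metabolic model is the linear system of a stoichiometric matrix $S$
(metabolites × reactions) with flux bounds: the feasible flux space is the
polytope $\{v : S v = 0,\ lb \le v \le ub\}$, fluxes in
mmol·gDW⁻¹·h⁻¹. Exchange reactions are single-metabolite boundary
reactions with coefficient $-1$; by the standard sign convention a negative
exchange flux is uptake and a positive one secretion, and all user-facing
uptake arguments are nonnegative magnitudes converted internally. The
biomass drain is structurally a boundary reaction too, but it is never
treated as an exchange.

Flux balance analysis (FBA) maximizes the biomass flux over the polytope.
Flux variability analysis (FVA) then adds the floor
$v_{\mathrm{biomass}} \ge f \cdot z^\*$ — the default fraction of optimum
$f = 0.99$ keeps every reported envelope inside the space supporting 99% of
maximal growth — and minimizes and maximizes each target. Targets may be
single reactions or named linear combinations; composite targets (such as
the net serine production of the synthesis branch plus the Shm route) are
optimized *directly* as one objective. Summing per-reaction envelopes
instead would overstate the range, because the per-reaction extremes are
generally attained at different flux states.

`uptake_scan()` fixes the scanned exchange at each grid value
(`mode = "fixed"`; `mode = "max"` only relaxes the lower bound), then
**re-maximizes biomass at that point** before applying the fraction floor.
The re-optimization is essential: judged against the unconstrained optimum,
every low-uptake point would be spuriously infeasible. Infeasible grid
points are flagged and the scan continues.

### Gene rules, deletions, media

Gene–protein–reaction rules are boolean expressions over gene ids with
`and`/`or` and parentheses (case-insensitive); the empty rule means
unconditionally available. Deletions are purely on/off: a reaction whose
rule evaluates false has both bounds set to zero, and no isozyme flux
splitting is attempted — deletions only ever knock reactions out, so richer
semantics would have nothing to act on. Deleting an unknown gene warns and
does nothing; deletion is monotone (a superset of deletions never
re-enables a reaction).

Media are named maps from exchange ids to maximum uptake rates. The
shipped YAML presets (`inst/extdata/media/media.yaml`) encode a synthetic
complete (SDC) and a rich (YPD) medium with a documented default of
10 mmol·gDW⁻¹·h⁻¹ for glucose and 1 for each amino acid and nucleobase
(the rich preset opens all 20 amino acids and 4 nucleobases). These
defaults are deliberately editable configuration, not constants baked into
code: per-nutrient uptake limits are rarely published with a model, and
any quantitative use should replace them with measured values. The
`sey6210_deletions()` preset lists the auxotrophy markers of the SEY6210
laboratory strain (LEU2, URA3, HIS3, TRP1, LYS2, SUC2) to be applied
before a scan when mimicking that background.

### The LP core and its verification

No linear-programming backend is assumed: the engine carries a dense
two-phase bounded-variable primal simplex with Bland's anti-cycling rule
(entering variable = smallest improving index; leaving variable = smallest
index among minimal ratios; variables with equal bounds are never chosen to
enter, which also protects phase 2 from pivoting on its pinned
artificials). Feasibility and optimality are tested at $10^{-9}$;
envelope comparisons use $10^{-6}$, a comfortable margin over
double-precision LP noise. Every optimal flux vector returned satisfies
$\|S v\|_\infty < 10^{-8}$. Only envelope bounds are contractual — the
flux vector attaining them is one of possibly many alternate optima, so
tie-breaking among optima is irrelevant by construction. Targets that are
genuinely unbounded (possible only when a user model carries infinite
bounds) are reported at ±1000, the conventional big bound, and flagged.

Correctness is established against an independent oracle,
`fva_brute_force()`: every vertex of the flux polytope is enumerated by
solving all basis/bound assignments (rank-reduced rows, all $2^{n-r}$
bound patterns per nonsingular basis), and envelopes are read off the
vertex set. A linear objective attains its extrema at vertices of a
bounded polytope, so the oracle is exact; its combinatorial cost restricts
it to networks of ≲10 reactions, which is why the random test networks are
capped at 8 reactions. The test suite additionally cross-checks the FBA
optimum against `boot::simplex`, a simplex implementation written
independently of this package.

### The serine toy model

`serine_toy_model()` is a fixed 11-reaction, 8-metabolite caricature of
the serine economy: glucose → 3-phosphoglycerate (lumped glycolysis,
2 pg3 per glucose), a serine-synthesis branch (gated by `SER1 and SER2`),
a reversible Shm route serine ⇌ glycine + one-carbon unit (`SHM1 or
SHM2`), lumped fatty-acid synthesis, SPT (`LCB1 and LCB2`), a protein
drain, and a biomass reaction consuming protein, long-chain base and
glycine (1 : 0.1 : 0.5). Glucose uptake is capped at 2. With these
coefficients the serine balance gives the net production of the synthesis
plus Shm routes as $0.6\,v_{\mathrm{biomass}} - u$ at serine uptake $u$,
so the envelope is strictly positive at $u = 0$, crosses zero near
$u = 2$, and is strictly negative beyond — the qualitative crossover the
scan is designed to exhibit — while the SPT envelope maximum
($0.1\,v_{\mathrm{biomass}}$) grows monotonically with uptake. The model
is a didactic substrate for the engine, not a fitted reconstruction; on a
genome-scale model the same functions apply unchanged, with the serine
reaction panel assembled by `serine_reaction_panel()` from the serine
species of every compartment of interest.

## SILAC incorporation

Only peptides with exactly one serine and a finite positive heavy/light
ratio are informative, and `filter_single_serine()` keeps exactly those.
Per peptide, incorporation is computed from the ratio $r$ by the formula
$1 - 1/(r - 1)$ (default). This expression is kept as the primary formula
for fidelity to its source, although typographically it is ambiguous and
algebraically it is undefined at $r = 1$ (such records are flagged and
excluded); the standard incorporation-check identity $r/(r+1)$ is provided
as `formula = "ratio-over-ratio-plus-one"`. Both formulas are strictly
increasing with limit 1, so the estimator below is monotone-invariant to
the choice; the simulators invert whichever formula the estimator will
apply.

The strain-level **incorporation level** is the location of the maximum of
a Gaussian kernel density over the per-peptide values — a mode estimator,
chosen over the mean or median because the per-peptide distribution is a
sharp peak at the true level contaminated by outliers (mis-assigned
ratios, partially labeled pools) that would bias moment statistics.
Bandwidth is Silverman's rule (`bw.nrd0`, overridable), the grid has 512
points spanning the data ± 3 bandwidths, ties resolve to the lowest grid
point and are flagged, and at least 10 finite values are required (below
that the density maximum is unstable). Because the level lies on the
grid, recovered levels are accurate to the grid spacing (well under 0.01
on typical data). Whether a headline per-strain percentage should be a
density maximum or a share of labeled peptides is a genuine ambiguity;
the density maximum is the default and the share of peptides with
incorporation above one half is reported alongside as
`labeled_fraction`.

**Intensity-dependent outliers** in protein-level SILAC ratios are called
by a binned robust-z approach: proteins are sorted into equal-count
intensity bins (default 300 per bin), the spread on each side of the bin
median is estimated from the 15.87/84.13 percentile distances (one-sided
robust standard deviations, immune to the outliers being hunted), and
two-sided normal tail p-values are assigned with tiers at $10^{-11}$,
$10^{-4}$ and $0.05$. The binning absorbs the strong variance–intensity
dependence of ratio measurements; the exact test behind such tiered
volcano displays is conventionally unstated, and the binned robust-z is
this package's documented choice, with bin size and percentile constants
exposed as arguments. Under a log-normal null the p < 0.05 tier captures
≈5% of proteins, which the suite verifies.

## Tracer quantification

All tracer operations are deliberately plain arithmetic on integrated
quantities — no peak picking, isotope-pattern deconvolution or spectral
processing, which belong to instrument software upstream.

* **Uptake**: per-time transport is
  $\max(\mathrm{counts} - \mathrm{background}, 0) / \mathrm{specific\ activity} / \mathrm{protein}$
  (nmol/mg). Negative background-subtracted counts clamp to zero with a
  warning (transport is physically nonnegative). The initial rate defaults
  to the 5-minute point — the conventional early-uptake comparison time —
  with a through-origin linear fit over all time points as an option.
  The specific activity of the label mix is a required input column, never
  an assumed constant. Replicates aggregate as mean ± sd with n.
* **Amino acids**: concentration = (peak area / norleucine area) ×
  calibration factor / cell count, in nmol per 10⁸ cells; calibration
  factors come from a standard mixture and are required per analyte.
  Two-condition comparisons use Welch's t-test (robust to unequal
  variances, the safer reading of an unspecified "t-test") plus the
  percent change of means.
* **Lipid labeling**: mol% of a (class, channel) cell is 100 × its summed
  amount over the sample's total; the cells of a sample partition to 100
  by construction, and an absent cell is a measured zero, not missing
  data.
* **Long-chain bases**: pmol/mg = intensity / internal-standard intensity
  × spiked pmol / protein mg, fold changes relative to a named reference
  sample; a zero reference amount leaves the fold change `NA` with a
  warning rather than an infinity.

Percent changes follow two fixed conventions: `percent_reduction(t, r)` =
$100(r - t)/r$ (a decrease is positive) and `percent_change(t, r)` =
$100(t - r)/r$ (an increase is positive). The reduction is not
antisymmetric under swapping arguments — only the sign of the difference
flips, not the magnitude — which the suite asserts explicitly.

## Screen mining

Interaction records (gene, epsilon, p) become a volcano table with
$-\log_{10} p$ and a `negative_significant` flag for aggravating
interactions (epsilon < 0) below the threshold (default raw p < 0.05).
Raw p-values drive the call because interaction screens are conventionally
displayed and thresholded that way; a Benjamini–Hochberg column is emitted
alongside for transparency. Ranking is ascending p with ties broken by
descending |epsilon| — a total order, so `top_interactions()` is stable
across runs.

## Synthetic data: what it does and does not show

Every generator is deterministic under a fixed seed, draws from its own
random stream (derived from the seed plus the generator's name, so adding
a generator never perturbs another's fixtures), restores the caller's RNG
state, and can write its table with a `.truth.json` sidecar consumed by
recovery tests.

The generators' default parameters encode the study conditions the
analyses are meant to resolve: per-strain incorporation levels of 93.8%
(wild type), 92.7% (serine auxotroph), 59% (gnp1), 90.8% (agp1) and an
81% decrease for the double permease deletion; uptake rates of 10
nmol/mg/min for wild type with 65% and 34% reductions for the single
deletions; serine-labeled IPC fractions at 36% and 27% of wild type (64%
and 73% decreases) with the auxotroph in the wild-type range; and a screen
with two planted aggravating hits over a calibrated Gaussian null of 4000
genes. Where no magnitude is dictated by those conditions the defaults
are one-time choices at realistic scales — peptide tables of 2000 rows
with noise sd 0.03, 10% outliers and 5% missingness; three uptake
replicates at 5/15/30 min with a background of 200 counts; duplicate
lipidomes totalling 1000 pmol; intensities log-normal.

What passing these tests shows is that the estimators are correct and
calibrated on data matching their assumptions: unimodal incorporation
peaks with symmetric noise, strictly linear early uptake, exactly
partitioned lipid classes, independent null interactions. Real tables
violate these in ways the generators do not emulate — ratio compression
and shared-peptide dependence in SILAC, transporter saturation bending the
time course, correlated lipid classes, batch structure — so recovery here
bounds estimator error, not measurement error. The uptake generator is
linear by design (matching the quantification model); saturation is a
known, deliberate omission.

## Problem sizes and runtime choices

The shipped verification uses 200 random networks of 4–8 reactions for
the oracle comparison (the vertex oracle is exponential in network size),
a 40-point uptake grid for scans, and simulated tables of 2000 peptides /
3000 proteins / 4000 genes — sizes at which the whole suite and the
acceptance script each run in well under a minute on a single core while
still exercising every code path at realistic data volumes. Genome-scale
models load through the same SBML-FBC reader and run through the same
engine; they are simply not bundled, as reconstructions are distributed
upstream.

## Known limitations

* No parsimonious FBA, loopless FVA, flux sampling, or integer
  constraints; no thermodynamic or enzyme-capacity extensions; no model
  curation or gap-filling.
* The dense simplex targets small-to-medium models; genome-scale FVA
  works but a sparse factorized solver would be faster.
* Dialects are SBML L3+FBC and the JSON toy format only (no MAT/Excel
  models); tabular inputs are TSV/CSV.
* The exact mapping of named enzymes (Ser2, Shm1/2, SPT) to reaction ids
  in any particular genome-scale reconstruction is annotation-dependent
  and is left to configuration rather than hard-coded.
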