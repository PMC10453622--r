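---
title: "Semi-rational thermostability design analysis with thermorank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-rational thermostability design analysis with thermorank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermorank)
```

## The design loop

Semi-rational thermostability engineering nominates mutation sites from
structural flexibility, proposes substitutions from homolog sequence
statistics, measures the resulting mutants, and combines the best ones. This
package implements the desk side of that loop for a subtilisin-family serine
protease (PB92, 269 residues), with every wet-lab quantity entering strictly
as data, never computed.

### 1. Flexible-site nomination

Per-residue flexibility is proxied by the crystallographic B-factor of the
C-alpha atom. `read_calpha_bfactors()` extracts one record per residue from a
PDB file and `nominate_flexible_sites()` selects residues with B-factor
strictly greater than a cutoff — default 21.0 Å², an absolute threshold on
raw (unnormalized) B-factors. Strict `>` and the raw scale are deliberate:
the cutoff is stated as an absolute value, and normalization would silently
change its meaning across structures. A z-score option (`normalize = TRUE`)
exists for comparing structures refined at different resolutions, but is off
by default.

Parsing follows standard crystallographic practice where the format leaves
room: only the first MODEL of a multi-model file is read, HETATM records are
skipped, and when a CA has alternate locations the highest-occupancy copy
wins (ties to the first encountered). Published analyses also reject
individual high-B sites for structural reasons that resist formalization
(e.g. a site dismissed as "C-terminal" although it sits at residue 153 of
269). We therefore expose exclusions as explicit, user-supplied predicates —
a residue list, a coil-label filter, a terminus margin — rather than
guessing a hard-coded rule.

### 2. Substitution proposals from alignment columns

`column_frequencies()` computes the residue spectrum of the alignment column
under each query position (query included in the counts; with ~150 homologs
its inclusion moves frequencies by <1%). Gaps are excluded from the
denominator by default — a column's evidence is the residues actually
observed there — with `include_gaps = TRUE` as the alternative convention.

`propose_candidates()` applies the consensus rule: the union of the top-2
residues by frequency and every residue at ≥10% frequency, minus the
wild-type residue. The threshold comparison is inclusive (`>=`), configurable
via `inclusive = FALSE`, since "more than 10%" in prose rarely survives
contact with percentages that are themselves rounded. Ties — both at the
top-k boundary and in output ordering — break alphabetically so results are
deterministic. Column indices are 1-based, as is everything in R.

### 3. Inactivation kinetics

Residual-activity decay during isothermal incubation is modelled as
first-order: $A(t) = A_0 e^{-kt}$, half-life $t_{1/2} = \ln 2 / k$. This is
the standard single-step irreversible inactivation model; multi-phase and
Lumry–Eyring kinetics are out of scope. Two estimators are provided:

* `method = "nls"` (default): nonlinear least squares on the percent scale,
  assuming homoscedastic residuals there;
* `method = "loglinear"`: regression of $\ln A$ on $t$ over positive
  residuals — fast, and the starting value for the nls route.

$A_0$ is fitted freely by default. The rationale is empirical: in the
bundled measurement table the wild type retains 36.59% activity at 30 min
while its reported half-life is 23.14 min, which is inconsistent with a
strict $A_0 = 100$ first-order curve (that would imply ~20.7 min); a free
amplitude absorbs the early-time offset such series show. `fix_A0 = TRUE`
pins the amplitude at 100 when the normalization is trusted. $R^2$ is always
computed on the original percent scale and clamped to $[0, 1]$.

`t_half_interpolated()` provides a model-free cross-check (linear
interpolation of the first 50% crossing), and `optimal_temperature()` reads
the optimum off an activity–temperature table, with ties resolved to the
lowest temperature (the conservative choice for an enzyme run hot).

### 4. Scoring and combination planning

Activity and thermostability are put on a common point scale: the wild type
scores 100 on each, and every 1% change scores one point, so

$$AS = \text{relative activity (\%)}, \qquad
  TS = 100 \cdot \frac{t_{1/2}}{t_{1/2}^{WT}}.$$

The composite score is the exponent-weighted product
$CS = TS^{w_T} \cdot AS^{w_A}$, default $w_T = w_A = 1$. A product — not a
weighted sum — is the only reading under which "both weights are 1" and
"wild type = 10,000" hold at once, and exponent weights keep the wild-type
reference at 10,000 for any weight pair. Scores are computed from unrounded
inputs; rounding happens only at output.

`select_per_site_best()` picks the top composite scorer per site (ties:
higher thermostability score, then alphabetical). A winner is *advanced*
into combination planning only if its composite exceeds the wild type's by
`advance_min_ratio` (default 1.2). The margin operationalizes "meaningful
improvement": measured activities and half-lives carry several percent of
assay error, and a composite a few percent above 10,000 is not evidence the
site helps. In the bundled data the margin cleanly separates the halted
sites (best composites 1.10x and 0.50x wild type) from the advanced ones
(1.46x and up); any value in that wide gap gives the same selection.

`propose_combinations()` treats a contiguous loop as one structural unit:
the non-loop winners form a fixed base, and the plan is the base alone, the
base plus each loop winner, and the base plus the whole loop — for a loop of
size $g \ge 2$, $g + 2$ proposals, identifiers encoding the substitution
count (`M2`, `M3-1` ... `M6`). With a single-member loop the joint proposal
would duplicate the single addition and is emitted once.

### 5. Property profiles

`windowed_profile()` computes unweighted centered sliding-window means of a
per-residue scale, window 9 by default — the common choice for surface
properties. Edge positions without a full window carry no score rather than
a shrunken-window score, so every emitted value has identical semantics. Two
scales are bundled: Kyte–Doolittle hydropathy and the Bhaskaran–Ponnuswamy
average flexibility index; this pair, with a 9-residue uniform window,
reproduces all ten published before/after site shifts the package's
acceptance checks assert (to 0.001 — the printed values are themselves
rounded to 3 d.p.). `mutation_delta()` exploits linearity: a point
substitution shifts the profile by exactly $(\text{scale}_{new} -
\text{scale}_{wt})/w$ at every position whose window covers the site, and
nowhere else.

## What the synthetic generators emulate — and what they do not

* `synth_pdb()`: a poly-alanine CA trace whose B-factor column is Gaussian
  baseline (default mean 12 Å², sd 2 Å², typical for a well-ordered
  mesophilic enzyme core) with exact target values at designated flexible
  sites. It emulates the *B-factor column*, not crystallography: no
  anisotropy, no correlation along the chain, no refinement artifacts.
* `synth_msa()`: alignment columns hit requested residue compositions by
  largest-remainder quota, deterministically — frequency-rule tests are
  exact, not probabilistic. Columns are independent; real homolog sets have
  phylogenetic correlation, so realized candidate lists on real alignments
  will be noisier than on these fixtures.
* `synth_timecourses()`: first-order decay with multiplicative Gaussian
  noise (default sigma 2%, typical colorimetric-assay precision), clipped at
  zero, $t=0$ forced to 100. Real series can show lag phases or biphasic
  decay that this generator deliberately does not produce.

Passing tests on these fixtures therefore demonstrate correctness of the
computations, not robustness to every pathology of real data.

## Numerical choices and problem sizes

Noiseless decay fits are checked to 1e-6 min; the nls route is cross-checked
against an independent zooming grid search. Parameter-recovery ensembles use
half-lives of 20–700 min sampled over ~1.5 half-lives at 7 points, 40
replicates per condition (and 100 replicates for the 2%-noise recovery
check), all under fixed seeds — sizes chosen to make median-error assertions
stable at a few seconds' runtime. Property-based tests for nominations,
frequency rules and profiles use 20–200-unit random fixtures against
brute-force oracles.

## Known limitations

* mmCIF, anisotropic B-factors and per-atom (non-CA) analysis are not
  supported.
* The package does not build alignments or homology models, and does not
  predict combination-mutant properties — no additivity or epistasis model;
  planning is combinatorial bookkeeping over measured winners.
* Published score tables occasionally disagree with their own inputs
  (decimal-shifted thermostability scores, one internally inconsistent
  half-life/fold pair, one activity-score discrepancy). The bundled fixture
  keeps the printed values verbatim in `*_reported` columns and the
  recomputation tests tolerate exactly these documented rows.
* Reproducing *absolute* windowed profile values at specific sites requires
  the mature enzyme sequence, which must be fetched from the PDB; only
  sequence-context-free shifts are verified offline.
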