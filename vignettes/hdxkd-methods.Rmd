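---
title: "Determining apparent dissociation constants from HDX-MS titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining apparent dissociation constants from HDX-MS titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxkd)
library(dplyr)
```

## The model

Hydrogen–deuterium exchange mass spectrometry (HDX-MS) reads out the
solvent exchange of backbone amide hydrogens as a mass increase. When a
small molecule binds, amides at and around the binding site are protected;
at a fixed labeling time the protection relative to the apo state is

$$\Delta D = D_{\mathrm{apo}} - D_{\mathrm{bound}}.$$

Under EX2 exchange with a rapid binding pre-equilibrium, and assuming
negligible ligand depletion (free ligand $[L] \approx [L_0]$), the
protection tracks fractional occupancy, so titrating the ligand and
fitting

$$\Delta D(L) = \Delta D_{max}\,\frac{[L]}{K_D + [L]}$$

yields an apparent dissociation constant $K_D^{app}$ per peptide, and —
through electron-capture-dissociation (ECD) c/z fragment ladders — per
residue. `hdxkd` implements the full workflow: uptake-table ingestion,
differential analysis with a hybrid significance criterion, bounded
nonlinear least-squares fitting with acceptance rules, global aggregation,
residue-level ladder algebra with scrambling QC, and a forward simulator
that generates ground-truth data for every stage.

## Assumptions, and when they fail

The Langmuir fit is exact only when $\Delta D$ is *linear* in occupancy.
That holds when bound and free molecules exchange as two independent
populations over the labeling window (the `slow_mixture` regime of
`site_uptake()`). Under fast interconversion (`fast_exchange`) the amide
exchanges at the occupancy-averaged rate
$k_{obs} = k_{int}(\theta/P_{bound} + (1-\theta)/P_{free})$, and uptake is
exponential — not linear — in $\theta$. The fitted $K_D^{app}$ is then
biased upward, increasingly so at long exposures where the apo and bound
uptake curves converge; as the exposure shortens into the initial-rate
regime the bias vanishes. Both regimes are implemented precisely so this
labeling-time caveat is a testable property rather than folklore: the test
suite and the acceptance script verify that the bias falls monotonically
over exposures $\{0.05, 0.5, 5, 50\}$ min, using a site with
$k_{int} = 5\,\mathrm{min}^{-1}$, $P_{free} = 25$, $P_{bound} = 2500$ and
$K_D = 5\,\mu M$ — chosen so the apo half-time ($\sim$3.5 min) sits inside
the exposure ladder, the 50 min point is near apo saturation (converged
curves), and the 3 s point is deep in the initial-rate regime.

The no-depletion idealization is quantified rather than assumed:
`ligand_depletion()` solves the exact 1:1 quadratic equilibrium. At the
standard design's lowest point (1 µM protein, 0.95 µM ligand,
$K_D = 4.8\,\mu M$) about 15% of the ligand is protein-bound — the
titration's bottom anchor is the weakest link of the approximation.

```{r depletion}
ligand_depletion(1, 0.95, 4.8)
```

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `d_frac` | 0.894 | mole fraction | final D2O content of the standard 3 + 57 µL labeling mix |
| ligand series | `final_ligand_conc(2^(0:7))` | µM | nominal 1–128 µM two-fold series, ×57/60 on dilution (top ≈ 120 µM) |
| exposure | 5 | min | maximizes the number of peptides with large measurable protection |
| `n_replicates` | 3 | — | standard titration replication |
| significance | >5% and >0.5 Da and p < 0.05 | — | hybrid criterion; both magnitude legs must clear and a two-sided Welch test must pass |
| acceptance | $\Delta D_{max} \ge 20\%$, CV < 20% | — | rejects fits whose plateau is small or poorly determined |
| fit bounds | $K_D \in [10^{-3}, 10^5]$ µM, $\Delta D_{max} \in [0, 150]$% | — | physical territory with room for noise overshoot |
| `noise_sd_da` | 0.05 | Da | replicate noise of a well-behaved bottom-up experiment |

Design choices where the field convention is not unique:

* **Observable amides.** `max_exchangeable_amides()` uses $N - 2 - P$:
  residue 1 has no measured backbone amide, residue 2 back-exchanges too
  fast, and prolines from position 3 on have none. The N-terminal
  exclusion width is configurable.
* **Percent basis.** The ">5%" significance leg and all `delta_pct`
  values are percentages of the theoretical maximum uptake,
  $n_{exch} \times d_{frac}$; percent-of-apo is available via
  `percent_of = "apo_uptake"`.
* **"Student t-test".** Implemented as Welch's unequal-variance test by
  default (replicate variances differ between states at $n = 3$);
  `pooled_var = TRUE` gives the classical pooled test. No
  multiple-testing correction by default, matching the per-peptide hybrid
  criterion; Benjamini–Hochberg is available via `p_adjust = "BH"`.
* **Standard errors and CV.** From the RSS-scaled Gauss–Newton covariance
  at the optimum; the CV of $\Delta D_{max}$ is
  $100 \times \mathrm{SE}(\Delta D_{max}) / \Delta D_{max}$.
* **Weighting.** Unweighted least squares by default; `1/sd²` weighting
  via `weighting = "1/sd2"`.
* **Global aggregation.** `global_kd()` averages accepted fits either over
  all peptides (maximal) or over a greedy weighted set cover (minimal):
  iteratively the accepted peptide covering the most not-yet-covered
  residues, ties broken by lower CV then lower start. Greedy cover is
  deterministic and reproducible where a manual choice is not. The
  summary SD is the sample SD ($n - 1$).
* **Replicability metric.** `replicability()` is the mean replicate SD as
  a percentage of theoretical maximum uptake. There is no single
  field-standard formula for a "replicability" percentage; this
  interpretation is labeled as such and should only be compared against
  itself across runs.

## Fragment-ladder bookkeeping

The single correctness-critical convention in the MS/MS path is which
fragment carries which amide. `hdxkd` assigns the amide hydrogen of
residue $j$ to $c_j$ (not $c_{j-1}$), and $z_k$ carries the amides of the
C-terminal $k$ residues, prolines excepted:

```
peptide:   L  E  K  Q  Q  S  A  W  P  F  L  K  P  V  S  L    (n = 16)
           1  2  3  4  5  6  7  8  9 10 11 12 13 14 15 16
c series:  d(c_j) = sum of amide D over observable residues 1..j
z series:  d(z_k) = sum over observable residues n-k+1..n
resolved:  residue j     = d(c_j) - d(c_{j-1})
           residue n-k+1 = d(z_k) - d(z_{k-1})
```

Gaps in a series yield segment-level values over the unresolved amides
(resolved amides inside a gap span are subtracted out, and segments are
chosen greedily smallest-first so the emitted spans are disjoint). When
both series resolve a residue, the inverse-variance-weighted mean is
reported with a 3σ conflict flag. A span whose only observable amide is a
single residue — for example a $c_7 \to c_9$ gap across a proline — still
resolves that residue, because the proline contributes no amide deuterium.
On noiseless data the emitted resolved + segment partition conserves the
precursor deuterium exactly; that conservation is asserted in the tests.

```{r ladder}
site_d <- c(0, 0, 0.4, 0.7, 0.2, 0.5, 0.3, 0.8, 0, 0.6, 0.4, 0.5, 0, 0.3, 0.2, 0.6)
lad <- simulate_ladder("LEKQQSAWPFLKPVSL", site_d, c_indices = c(3:7, 9:11),
                       z_indices = 9:13)
ladder_to_residues(lad) |> head(10)
```

## Scrambling quality control

Electron-based fragmentation preserves positional deuterium only when the
activation does not scramble hydrogens across the ion. Two controls are
implemented. The selectively-labeled-standard method (`scrambling_p1()`)
places each fragment's observed deuterium between a no-scrambling
prediction (sum of the site model over the fragment) and a full-scrambling
prediction (precursor deuterium distributed proportionally to
labile-hydrogen counts, side chains included, from a fixed internal
table); the averaged position is the percent scrambling, and the metric is
affine in the true scrambled fraction by construction. The ammonia-loss
method (`ammonia_loss_check()`) flags deuterium loss coincident with NH3
loss on a charge-reduced species pair. Default flags — 10% for the
standard method, 0.1 Da or 3σ for ammonia loss — are package choices; no
universal numeric threshold exists.

## What the simulator emulates — and what it does not

`simulate_titration()` generates peptide-level uptake tables under the
standard design: per-amide intrinsic rates (user-specified or log-normal,
median 10 min⁻¹, σ(log10) = 1), protection factors for free and bound
states, occupancy from the isotherm (optionally with exact depletion),
additive Gaussian replicate noise, and deterministic output for a fixed
seed. Fragment ladders come from partial sums over sites; isotope
envelopes from the envelope module (fixed isotope tables, Poisson-binomial
deuterium distribution, H→D mass difference 1.006277 Da, proton mass
1.007276 Da for m/z).

It deliberately does not model: sequence-dependent intrinsic rates (a
hook exists for a future rate table; sampled rates are sufficient to
validate the fitting machinery), back-exchange during quench/LC (exposed
only as a multiplicative retention factor, matching uncorrected "relative
uptake" practice), chromatography, peak shapes, pepsin cleavage
specificity, or EX1 deconvolution — the simulator can *produce* bimodal
envelopes in the slow regime, and their centroid is the
population-weighted mean (what a centroid pipeline would measure), but
separating the two populations is out of scope. Passing tests therefore
demonstrate the correctness of the analysis chain under its stated
assumptions, not robustness to every pathology of real instrument data.

## Numerical choices

* Fitting uses bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  `ftol = ptol = 1e-14`, initialized at $\Delta D_{max,0} = \max \Delta D$
  and $K_{D,0}$ log-interpolated at the half-saturation crossing — robust
  for 8-point two-fold designs. Every fit in the test suite is
  cross-checked against an independent 400 × 400 grid search.
* Series with no positive protection return a flagged
  `"no protection"` failure; non-convergence returns a diagnostic reason.
  Nothing is dropped silently, and negative $\Delta D$ points are retained
  in fits rather than clipped.
* Envelope convolution aggregates by nucleon number, tracking
  intensity-weighted mean masses, and truncates at cumulative intensity
  0.9999 (centroid perturbation < 1e-3 Da for peptides ≤ 30 residues,
  asserted against the untruncated computation).
* CSV readers use base R's exactly-rounded double parser so that
  write→read round-trips are bit-identical.
* Zero variance in both replicate groups with a nonzero difference yields
  p = 0 with a degenerate-variance interpretation; fewer than two
  replicates per state makes the verdict "untestable" (`NA`).

## Problem sizes

The shipped validation uses a 50-residue synthetic construct with five
10-mers (peptide level), the 16-mer proline-containing worked-example
peptide (residue level), a 200-seed recovery study at the standard
design ($K_D$ log-uniform 0.5–50 µM, $\Delta D_{max}$ 20–60%, replicate
noise 1 percentage point, $n = 3$), 25-seed residue-level recovery, and
40-seed end-to-end runs at σ = 0.05 Da. These sizes give stable
Monte-Carlo estimates (coverage SE ≈ 2.3 percentage points at 200 seeds)
while keeping the suite fast enough to run on every change.

## A worked example

```{r worked}
construct <- protein_construct("demo", strrep("GASTLIVEKR", 5))
sites <- exchange_site_models(construct, binding_site = 21:30, seed = 7)
starts <- seq(1, 41, by = 10)
peptides <- data.frame(start = starts, end = starts + 9,
                       sequence = substring(construct$sequence, starts, starts + 9))
sim <- simulate_titration(construct, peptides, sites,
                          sim_protocol(kd_true_uM = 5, noise_sd_da = 0.02, seed = 1))
fits <- sim$uptake |>
  delta_uptake() |>
  fit_all_titrations()
fits |> select(target_id, kd_uM, kd_se_uM, dmax_pct, cv_pct, accepted, reason)
```

The peptide spanning the planted binding site recovers the true
$K_D = 5\,\mu M$; peptides with no protection fail with an explicit
reason. On the published bromodomain peptide table:

```{r table2}
t2 <- example_peptide_kd() |> mutate(accepted = TRUE)
glance(global_kd(t2, "maximal"))
kd_extremes(t2)$max$kd_uM
```

## Known limitations

* $K_D^{app}$ is apparent: indirect (allosterically propagated)
  protection, residues exchanging outside the kinetic window of the
  chosen exposure, and interconversion-regime violations all move
  per-peptide values away from the thermodynamic constant. The spread of
  accepted per-peptide values is information, not noise.
* The minimal-set mean depends on the cover heuristic; a manually curated
  set can differ from the greedy one while covering the same residues.
* Scrambling percentages assume the fixed labile-hydrogen table; charge
  states and pH shift true side-chain exchangeability.
* The residue-level path consumes fragment *centroids*; envelope fitting
  of individual fragment ions is out of scope.
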