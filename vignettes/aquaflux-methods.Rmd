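---
title: "Models and methods behind aquaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aquaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

# Scope

`aquaflux` characterizes aquaporin water channels expressed in an
aquaporin-null yeast host along two axes: osmotic water-transport kinetics
measured by stopped-flow fluorescence, and sequence-level annotation of the
motifs and selectivity residues that predict what a channel may conduct.
This vignette explains the models, the tunable parameters, the synthetic
data that stands in for instrument traces and cloned cDNAs, and the
numerical decisions — including the places where the design was genuinely
open and the package had to choose.

# The osmometer model

A yeast cell in suspension is treated as an ideal two-compartment
osmometer. Only a fraction of the initial volume $V_0$ exchanges water; the
remainder $V_b = \beta V_0$ (solids, bound water) is osmotically inert.
After rapid mixing into a hyperosmotic medium, volume obeys

$$\frac{dV}{dt} = -P_f\, A\, V_w \left( \mathrm{osm}_{out}
  - \mathrm{osm}_{in,0} \frac{V_0 - V_b}{V - V_b} \right),$$

with $P_f$ the osmotic water permeability (cm s$^{-1}$), $A$ the membrane
area (cm$^2$), $V_w = 18$ cm$^3$ mol$^{-1}$ the molar volume of water, and
osmolarities in mol cm$^{-3}$ internally (molar at the interface). The
equilibrium volume is the van't Hoff limit
$V_{eq} = V_b + (V_0 - V_b)\,\mathrm{osm}_{in,0}/\mathrm{osm}_{out}$.
Assumptions: ideal dilute (van't Hoff) osmotic pressure, constant membrane
area, no solute permeation and no active volume regulation on the assay
time scale.

Defaults in `cell_model()`: a sphere of radius 2.5 µm ($V_0/A = r/3$),
$\beta = 0.5$, and the standard shock protocol — cells equilibrated in
1.4 M sorbitol mixed with an equal volume of 2.1 M sorbitol, so
$\mathrm{osm}_{out} = 1.75$ M and the shock ratio is 1.25. Geometry and
$\beta$ are configuration, not constants; all recovery results in the test
suite are round trips that do not depend on the particular default.

The ODE is integrated with `deSolve::ode` (LSODA, `rtol = 1e-10`, absolute
tolerance scaled to $V_0$). Parameter sets that would drive the osmotic
volume to zero raise an error naming the offending quantities rather than
returning a nonphysical trajectory.

# From trace to permeability

Fluorescence is an affine function of volume ($F = c_0 + c_1 V$), so the
relaxation rate is invariant under instrument gain and offset — a property
the tests check explicitly. Each trace is fitted with
$F(t) = b + a\,e^{-kt}$ on $t \ge$ `dead_time` by Levenberg–Marquardt
(`minpack.lm::nlsLM`). Start values: $b_0$ is the mean of the last 10% of
points; $k_0$ and $a_0$ come from a log-linear regression of $F - b_0$ over
the first 80% of the retained points; on non-convergence the fit restarts
once at $2 k_0$. A trace whose optimum has $k \le 0$, or whose signal never
rises above numerical noise, is flagged as having no relaxation; ensemble
estimators exclude such traces with a warning and fail only when every
trace fails. The default dead time of 5 ms removes the mixing artifact;
it is configurable because instruments differ.

## Why the conversion is calibrated

Linearizing the ODE at equilibrium gives
$k_{lin} = P_f \frac{A}{V_0(1-\beta)} \frac{V_w\,
\mathrm{osm}_{out}^2}{\mathrm{osm}_{in,0}}$, and hence the closed-form
conversion $P_f = k\,(V_0(1-\beta)/A)\,\mathrm{osm}_{in,0}/(V_w\,
\mathrm{osm}_{out}^2)$ (`method = "linearized"`). But a finite shock is not
in the linear regime: the local relaxation rate drifts from
$k_{lin} \cdot \mathrm{osm}_{in,0}/\mathrm{osm}_{out}$ at $t=0$ up to
$k_{lin}$ near equilibrium, so a single-exponential fit of the full decay
lands in between — 11–19% below $k_{lin}$ at the standard 1.25 shock ratio,
the exact figure depending on the acquisition window. Any fixed constant
therefore carries a shock-size bias.

The default `method = "calibrated"` removes it by self-consistency: it
solves $k_{model}(P_f) = \hat{k}$, where $k_{model}$ is obtained by
simulating the declared osmometer model on the trace's own time grid and
fitting it with the same exponential routine. The fixed point is found by
the iteration $P_f \leftarrow P_f\, \hat{k}/k_{model}(P_f)$ (start: the
linearized constant; relative tolerance $10^{-6}$, at most 12 iterations —
2–4 suffice in practice because $k_{model}$ is nearly proportional to
$P_f$). For model-generated data this is exact by construction at any shock
size, and it reduces to the linearized constant as the shock vanishes. The
trade-off is honest and documented: the estimate is only as good as the
osmometer model itself, which is why the conversion method is recorded on
every result.

# Activation energy and inhibition

`estimate_ea()` is ordinary least squares of $\ln P_f$ on $1/T$;
$E_a = -\mathrm{slope} \times R$ with $R = 1.987 \times 10^{-3}$
kcal mol$^{-1}$ K$^{-1}$, reported with its standard error and $r^2$.
Duplicate temperatures are averaged before the regression; fewer than three
distinct temperatures is an error. The conventional reading: $E_a$ below
roughly 6–10 kcal mol$^{-1}$ indicates channel-mediated flux, higher values
indicate lipid-dominated diffusion.

Mercurial inhibition is the percent Pf reduction of a treated ensemble
relative to the untreated ensemble of the same strain, with a two-sided
pooled-variance Student's t test on the per-trace Pf sets (degenerate
zero-variance inputs return $p = 1$ for equal means, $p = 0$ otherwise).
Apparent stimulation (treated above control) is returned as a negative
percentage with a warning rather than suppressed. Reports annotate
significance at 0.05 / 0.01 / 0.001.

# The synthetic generators

`gen_trace()` integrates the osmometer ODE, normalizes fluorescence to
$F(0) = 1$ and adds i.i.d. Gaussian noise whose SD is expressed as a
fraction of the total signal amplitude (default 0.02, a plausible
fractional noise level for stopped-flow records; real instruments publish
no standard figure, so this is asserted, not inferred). Defaults: 400
samples, 5 ms dead time. With zero noise the output equals the ODE plus the
linear map exactly, and identical spec + seed gives bit-identical traces —
both are tested invariants. Study-level generation scales the acquisition
window with the expected relaxation (duration $= 6/k_{lin}$), as an
operator would configure the instrument; a fixed window would truncate slow
relaxations at 9 °C.

`gen_temperature_series()` applies the Arrhenius law with multiplicative
log-normal noise. The fixture grid is 9, 16, 23, 30, 37 °C with Pf
replicated at a 23 °C reference, mirroring the reference experimental
design (ten traces at 23 °C, five per other temperature).

`gen_aquaporin_set()` derives sequences from three synthetic templates
(PIP1-like 286 aa, PIP2-like 284 aa, TIP-like 251 aa — the published
lengths) with six 23-residue hydrophobic blocks, hydrophilic loops, both
NPA motifs, the water signature spanning the second NPA, the nine
selectivity columns and the subfamily regulatory sites, all at plausible
but synthetic offsets. Random substitutions (uniform positions outside the
reserved motif columns, uniform replacement among the 19 other residues)
create controlled divergence; reserved columns are never mutated, so the
planted selectivity profile always survives. What these fixtures do *not*
emulate: real alignment columns, insertions/deletions, composition bias, or
the true residue numbering of any protein — tests passing on them validate
the pipeline's logic, not any structural claim.

# Selectivity classification

The nine diagnostic residues — ar/R filter (TMH2, TMH5, LE1, LE2) and
P1–P5 — are matched against per-position allowed-residue sets for NH₃,
boron, CO₂, H₂O₂ and urea, shipped as a JSON data file and replaceable by
the user. The score is the count of matching positions (0–9); a substrate
is assigned at score ≥ 7.

The threshold was a genuinely open design point. Strict 9/9 matching cannot
reproduce the published assignments: the TIP tuples carry Val at P4 where
the ammonia rule lists Tyr, yet ammonia is assigned to all three TIPs in
the published table. Enumerating all 30 protein × substrate pairs shows
that threshold 7 reproduces the published table exactly — 12 PIP and 9 TIP
assignments, zero extras — while 8 would drop the TIP1;1 ammonia call and 6
would add false boron calls. The enumeration ships as a test; the threshold
remains configuration. Score-based matching is the package's
reconstruction of a procedure the source material describes only as
residue comparison; profiles are putative by nature and establish no
transport phenotype.

# Identity, distances and trees

Percent identity counts matching columns over columns where neither
sequence is gapped (terminal gaps treated like internal ones), which makes
the substitution-count arithmetic exact for equal-length pairs:
one substitution in 251 columns is 99.6%, and $(100 - \mathrm{id})/100$
equals the p-distance on gap-free alignments. Values are returned
unrounded; rounding to one decimal happens at the reporting layer.

Neighbor joining uses the classic Saitou–Nei agglomeration via `ape::nj`;
negative branch lengths are clamped to zero with a message (the common
phylogenetics-package convention). Bootstrap support resamples alignment
columns, rebuilds each tree and reports per-split percentages via
`ape::prop.clades`; the test default is 50–100 replicates to keep runtime
low, with 1000 available through the argument. When a study mixes
subfamilies of different lengths the records are padded with terminal gaps
before distance computation — a deliberately crude device adequate for
synthetic clade fixtures, with a message directing users to supply a real
alignment for real data; the package computes no multiple sequence
alignment.

# Degenerate inputs and tie-breaks

* Iso-osmotic model: simulation returns a constant volume; trace fitting
  then reports no relaxation.
* Zero permeability: a flat trace by construction.
* Flat or failed traces inside an ensemble: excluded with a warning,
  `n_traces` decremented; only all-failure errors.
* Zero-variance t-test inputs: $p = 1$ or $p = 0$ by mean equality.
* Single-record sequence study: a 1×1 identity matrix of 100, no tree,
  a warning.
* Empty rule file: empty profiles, a warning, normal completion.
* Position map past the sequence end, or a gap at a mapped column: errors
  naming the column.

# Problem sizes

The test suite and the acceptance script run at desk scale by choice: 7
strains × 10 replicate traces for Pf recovery, 5 temperatures (×5
replicates in the study composer) for $E_a$, 20 seeds for the noisy-Ea
recovery study, 10⁴ null simulations for the t-test calibration, 100-seed
ensembles for fit-dispersion checks, 5–8-leaf trees for NJ correctness and
six-record fixtures for the clade split. These sizes give stable Monte
Carlo margins (e.g. a binomial SD of ~0.002 on the type-I rate) while the
whole suite completes in well under a minute of compute per module.

# Known limitations

* Absolute Pf accuracy on real instrument data depends on the osmometer
  model's assumptions (ideal osmometer, known geometry, no solute flux);
  the calibrated inversion removes model-internal bias, not model error.
* No dead-time deconvolution, and single-exponential fits only — no
  double- or stretched-exponential relaxations.
* The hydropathy scanner is a surrogate for dedicated topology predictors
  and is tuned (window 19, threshold 1.6, minimum run 12) to the synthetic
  templates' block structure.
* Position maps for real sequences must be supplied from an external
  structural alignment.
* Signature matching predicts candidacy, not conductance.
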