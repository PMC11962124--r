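---
title: "Methods: the mitotic-entry model and the prolonged-prophase analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mitotic-entry model and the prolonged-prophase analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The mitotic-entry network

At the G2/M transition, cdk1-cyclin B is held inactive by inhibitory
Thr14/Tyr15 phosphorylation placed by wee1/myt1 and removed by cdc25
phosphatases. Two positive feedback loops — cdk1 activates cdc25 and
inhibits wee1 — together with mutual antagonism between cdk1 and the
counteracting phosphatase PP2A-B55 make activation bistable and
switch-like. PLK1 (polo-like kinase 1) feeds into this switch as an
activator of cdc25 downstream of cdk2-cyclin A; inhibiting it (as BI 2536
does) removes one of the routes by which cdc25 is turned on, and the
package exists to quantify the consequences: delayed, highly variable
nuclear envelope breakdown (NEBD), and a prolonged prophase-like state with
slowly rising cdk1 activity.

`propro` models this with six states: unphosphorylated cdc25 (`cdc25`),
active bi-phosphorylated cdc25 (`cdc25pp`, with the mono-phosphorylated
form implicit through conservation
$[Cdc25p] = [Cdc25_{Tot}] - [Cdc25] - [Cdc25pp]$), active cdk1-cyclin B
(`cycbcdk1`), active wee1/myt1 (`wee1`), active PP2A-B55 (`pp2ab55`) and a
generic phosphorylated cdk1 substrate (`subp`). The cdc25 cycle is

$$\frac{d[Cdc25]}{dt} = (k_{PPX,Y15} + k_{B55,Cdc25}[PP2AB55])[Cdc25p]
  - (k_{Cdk1,Cdc25}V_{Cdk1} + k_{Plk1,Cdc25}[Plk1])[Cdc25]$$
$$\frac{d[Cdc25pp]}{dt} = -(k_{PPX,Y15} + k_{B55,Cdc25}[PP2AB55])[Cdc25pp]
  + (k_{Cdk1,Cdc25}V_{Cdk1} + k_{Plk1,Cdc25}[Plk1])[Cdc25p]$$

with $V_{Cdk1} = [CycBCdk1]$ and $[Plk1] = f_{Plk1}\,[CycACdk2_{Tot}]$:
PLK1 activity is an algebraic input proportional to cdk2-cyclin A activity,
scaled by the inhibition parameter $f_{Plk1} \in [0, 1]$ (1 = fully active,
0 = complete inhibition). The substrate obeys

$$\frac{d[Subp]}{dt} = k_{Cdk1,Sub}V_{Cdk1}([Sub_{Tot}] - [Subp])
  - k_{B55,Sub}[PP2AB55][Subp],$$

and NEBD is declared the first time $[Subp]/[Sub_{Tot}]$ reaches 30%
(`nebd_threshold = 0.30`), linearly interpolated between output samples.

## The auxiliary submodel

Only the cdc25 and substrate equations above are constrained exactly; the
rest of the network is a deliberately minimal mass-action reconstruction of
the canonical wiring, with every constant exposed in
`default_auxiliary_params()`:

* cdk1-cyclin B is activated (Tyr15-dephosphorylated) at rate
  $k_{cdc25,basal} + k_{cdc25,act}[Cdc25pp]$ — the small basal term
  represents cdc25pp-independent phosphatase activity and prevents an
  unphysical absorbing state at zero — and inactivated at rate
  $k_{wee1,basal} + k_{wee1,inact}[Wee1]$.
* wee1 is reactivated at rate $k_{wee1,act} + k_{b55,wee1}[PP2AB55]$ and
  inactivated by cdk1 ($k_{cdk1,wee1}V_{Cdk1}$, the second feedback loop)
  and by cdk2-cyclin A ($k_{cdk2,wee1}[CycACdk2_{Tot}]$). The latter is the
  PLK1-independent entry route: it is why complete PLK1 inhibition delays
  but does not permanently block mitotic entry.
* PP2A-B55 is inactivated downstream of cdk1 ($k_{cdk1,b55}V_{Cdk1}$), the
  greatwall/ENSA limb collapsed into a single inhibitory step, and recovers
  at $k_{b55,act}$.

A clamped *reduced mode* (`network_rhs(..., reduced = TRUE)`) freezes
$V_{Cdk1}$ and $[PP2AB55]$ at supplied constants so the two printed
equations can be tested in isolation against closed forms: with
$k_{B55,Sub} = 0$ and clamped $V_{Cdk1} = v$ the substrate is exactly
$[Sub_{Tot}](1 - e^{-k_{Cdk1,Sub} v t})$, and the clamped cdc25 cycle is a
linear three-state system solved by a matrix exponential. The test suite
holds the implementation to these oracles at relative error $10^{-6}$ and
$10^{-8}$ respectively.

## Calibration and units

Time is in hours, all pools are scaled to 1 a.u., and cdk2-cyclin A
activity after G2 entry defaults to 4 a.u. G2 entry is a step of
$[CycACdk2_{Tot}]$ from 0 at $t = 0$; the initial condition is the
interphase fixed point at zero cdk2-cyclin A (computed, not hard-coded),
with cdc25 fully unphosphorylated and no substrate phosphorylation.
Residual S-phase after a thymidine-release-style synchronisation is
neglected. The shipped rate constants were calibrated once, against the
qualitative targets that define the biology (uninhibited NEBD within
0.5–2 h of G2 entry; several hours of delay at complete inhibition;
bistability preserved at all doses), and give:

* $f_{Plk1} = 1$: NEBD 0.86 h after G2 entry,
* $f_{Plk1} = 0.5 / 0.1 / 0$: 1.23 / 3.17 / 12.2 h,
* upper saddle-node threshold 0.52 a.u. ($f_{Plk1}=1$) vs 3.42 a.u.
  ($f_{Plk1}=0$).

Integration uses `deSolve::lsoda` (stiff-capable) at `rtol = 1e-8`,
`atol = 1e-10`, with a 0.01 h output grid; population sweeps use
`lsodar`'s root finding to stop each cell at its NEBD event.

# Steady states and saddle nodes

At a fixed point, every state is an explicit function of the active
cdk1-cyclin B level $v$: PP2A-B55 and wee1 balance their on/off fluxes, the
cdc25 cycle settles to the geometric ladder set by the ratio
$r = \mathrm{kinase}/\mathrm{phosphatase}$ (so
$[Cdc25pp] = [Cdc25_{Tot}]\,r^2/(1 + r + r^2)$), and the substrate follows.
The fixed-point condition therefore reduces *exactly* to one scalar
equation $g(v) = 0$ on $[0, [CycBCdk1_{Tot}]]$. `steady_states()` scans
$g$ on a dense lattice (2000 intervals), refines every bracketed root by
bisection (`uniroot`), verifies each candidate against the full
`network_rhs` (residual $< 10^{-8}$), and classifies stability by the
eigenvalues of a finite-difference Jacobian of the full six-state system.
We chose this reduction over multi-start Newton iteration in the full state
space, and over pseudo-arclength continuation, because on a
one-dimensional scan no branch can be missed and every step is
deterministically reproducible; the design trade-off is that it exploits
the network's specific structure and would need rework if the wiring
changed. Fixed points closer than $10^{-6}$ (relative, on $v$) are
de-duplicated; eigenvalues with $|\mathrm{Re}\,\lambda| < 10^{-9}$ are
reported as `indeterminate` rather than silently classified.

`find_saddle_nodes()` locates the cdk2-cyclin A activities where the count
of stable fixed points changes, by an 80-point coarse scan of the bounds
plus bisection to $10^{-3}$ of the bounds width. `sn_upper` — the activity
above which only the high-cdk1 state exists — is the quantity PLK1
inhibition moves: the package's central bifurcation statement is
`sn_upper(f=0) > sn_upper(f=1)`. A monostable parameterisation returns an
explicit no-bistability marker, not an error.

# Population simulation

Cell-to-cell variability enters solely through the cdk2-cyclin A activity:
each cell draws one value and keeps it across all inhibition doses
(`simulate_population()`), mirroring a dose-response experiment on one
heterogeneous population. The default doses `c(1, 0.5, 0.1, 0)` are 0, 50,
90 and 100% PLK1 inhibition; the default horizon is 24 h (a typical
overnight imaging window) with censoring beyond it; the default population
is 400 cells.

Because delay diverges as a cell's activity approaches the saddle-node
threshold from above, small differences in activity map onto entry delays
from minutes to "never within the experiment" — which is the model's
explanation for the seemingly inconsistent penetrance of PLK1 inhibition.
Three shipped presets (`scenario_presets()`, stored in
`inst/extdata/scenarios.json`, not in code) realise the three regimes this
produces. Their parameters were fixed once from the model's saddle-node
map (the 24 h entry threshold at complete inhibition sits at
$\approx 3.6$ a.u.):

| preset      | mean | sd  | regime                                             |
|-------------|------|-----|----------------------------------------------------|
| `narrow`    | 5.0  | 0.1 | synchronous entry; doses only shift the entry time |
| `broad`     | 5.0  | 1.0 | dose-dependent delay plus broadening               |
| `broad_low` | 3.4  | 1.0 | majority of cells censored at full inhibition      |

The default sampling family is a zero-truncated normal (negative draws
redrawn); lognormal and uniform families are available behind the same
scenario interface since the true distribution of activities is not
observable.

# Imaging metrics

The quantification functions consume label images and intensity frames;
segmentation and tracking are deliberately out of scope (they are the
province of dedicated, published tools) and enter only as inputs. The
conventions that matter:

* **Condensation score** — population SD (divide by $N$) of a nucleus'
  pixels over its background-corrected mean. The ratio form makes the
  score invariant to multiplicative bleaching, so no separate bleaching
  fit is applied; the sample-vs-population SD choice is documented because
  the score's absolute value depends on it (for nuclei of thousands of
  pixels the difference is negligible).
* **N/C ratio** — the cytoplasm is the ring from dilating the nuclear
  label by a 10 px disk, clipped to the nucleus' Voronoi territory
  (nearest-nucleus-pixel assignment, ties to the lower label id) and to
  unlabelled pixels. Background is an input everywhere: the package does
  not guess it, and the generator records the value it painted.
* **Eccentricity** — from the second-moments ellipse of the mask;
  normalised to the mean of the frames within 10 min after NEBD (2 frames
  at the 5-min default interval). A near-circular normalisation window
  (mean eccentricity $< 10^{-6}$) returns the raw series with an explicit
  `unnormalized` status instead of dividing by noise.
* **z-centroid** — intensity-weighted mean plane index (1-based, in
  z-step units); time courses are normalised to the mean of the first 5
  frames, as are cytoplasmic-intensity courses.
* **Focus counting** — local maxima inside the mask with topographic
  prominence above the threshold (default 100), computed by a persistence
  sweep over pixels in decreasing intensity with 8-connected union-find;
  plateau maxima count once; the surviving global maximum takes its
  prominence relative to the lowest masked intensity.
* Frames are matrices with a top-left origin; indices are 1-based in R and
  in all exports.

# Phosphoproteomics pipeline

The experimental design the pipeline serves compares four states in a
2×2 factorial: treatment (DMSO vs BI 2536) crossed with fraction
(attached = pre-NEBD vs suspended = post-NEBD shake-off), so that
G2 = DMSO·attached, Prometaphase = DMSO·suspended, Prolonged Prophase
(ProPro) = BI2536·attached and *Polo* = BI2536·suspended, with three
biological replicates spread over three TMT sixplex labelling batches
(each batch: one replicate of every state plus pooled reference channels).

Stages, in order, each exposed as its own function:

1. **Site filtering** — drop contaminants, reversed decoys and sites with
   phosphogroup localization probability below 0.75 (the boundary value is
   kept; the rule removes "< 0.75").
2. **Valid-value rule** — per labelling batch, a site with fewer than 70%
   valid intensities among that batch's quantification channels is masked
   as not quantified there; sites quantified nowhere are dropped.
   Reference channels do not count toward the fraction (switchable).
3. **Imputation** — missing values are drawn per column from
   $\mathcal N(\mu_j - 1.8\,\sigma_j,\ (0.3\,\sigma_j)^2)$ with
   $\mu_j, \sigma_j$ the column's observed log2 moments: the downshifted,
   narrowed Gaussian that models missing-not-at-random low-abundance
   dropout. Width and downshift are in column-SD units.
4. **Normalisation** — Tukey median polish per batch; the fitted column
   effects, plus each batch's overall level relative to the grand level,
   are subtracted; row (site) effects are retained. Removing the
   batch-overall term matters: without it, batch offsets cancel in every
   contrast but inflate residual variances, which silently deflates all
   test statistics. Reference-channel alignment (per-batch subtraction of
   the pooled-reference profile per site) is implemented but off by
   default: with two reference channels the subtraction injects
   within-batch-correlated noise worth half a within-group variance into
   the residuals while contributing nothing to the contrasts, measurably
   over-conservative on synthetic data; enable it when site-specific batch
   effects are expected to dominate that cost.
5. **Model** — per site, least-squares cell means of the four groups;
   residual variance on 8 df in the full design.
6. **Moderation** — empirical-Bayes shrinkage: a scaled-F prior fitted by
   matching the mean and variance of $\log s^2$ to their theoretical
   digamma/trigamma moments (Newton inversion of the trigamma function),
   giving prior df $d_0$ and prior variance $s_0^2$;
   $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and moderated t on
   $d + d_0$ df. Homoscedastic inputs take the explicit $d_0 = \infty$
   branch. The implementation agrees with the reference empirical-Bayes
   implementation in `limma` to $10^{-6}$ on shared data, which the test
   suite asserts.
7. **Contrasts** — the interaction
   $([\mathrm{BI.att}] - [\mathrm{BI.susp}]) - ([\mathrm{DMSO.att}] -
   [\mathrm{DMSO.susp}])$ isolates phosphosites specific to prolonged
   prophase (PLK1-inhibition-responsive *and* pre-NEBD; effects shared by
   both inhibited states or by both pre-NEBD states cancel), plus the four
   pairwise edges of the factorial square. Two-sided moderated-t p-values,
   Benjamini-Hochberg adjustment within each contrast, significance at
   adjusted p < 0.05; hit direction by fold-change sign, with an optional
   |log2 FC| > 0.5 volcano threshold.

# Synthetic data

`generate_phospho()` builds log2 intensities additively — site baseline
$\mathcal N(20, 1.5)$, batch offsets (sd 0.3, column-level), channel
offsets (sd 0.1), optional per-site main effects, a fixed-size interaction
effect on a seeded subset of sites, within-group noise (sd 0.25) — then
applies logistic missing-not-at-random dropout with midpoint at the 15th
intensity percentile and slope 2 per log2 unit. It emulates the moments and
missingness structure the pipeline assumes; it does not emulate
peptide-level correlation between sites of one protein, reporter-ion
interference or co-isolation, so passing tests speak to the statistics, not
to mass-spectrometric artefacts.

`generate_movie()` paints non-overlapping disk nuclei with
Gaussian-textured interiors whose relative SD follows a per-frame schedule
(the condensation ramp), an optional surrounding cytoplasm disk for
translocation metrics, global exponential bleaching and a flat background;
label images are exact by construction and NEBD is label disappearance.
There is no point-spread function or camera-noise model: the metrics under
test are statistics of labelled regions, not detection.

Both generators are pure functions of their specification (seed included).

# Problem sizes and numerical choices

The shipped test-suite sizes were chosen as the smallest that exercise
each property decisively: 2000 sites for distribution-level statistics
(Kolmogorov-Smirnov under the null at $\alpha = 0.01$), $10^5$ observed /
$10^4$ imputed values for the Monte-Carlo imputation moments, 400 cells per
scenario for the population regimes, 128 px movies with 4–8 frames for the
imaging metrics. Saddle-node resolution is $10^{-3}$ of the scan width;
median polish is driven to residual row/column medians below $10^{-3}$
(alternating median sweeps over even-width tables plateau around
$10^{-4}$, which is four orders below the data scale).

# Known limitations

* The model is deterministic and non-spatial: no stochastic kinetics, no
  nuclear import of cyclin B, no compartments — so it cannot express the
  contribution of cyclin B nuclear accumulation to the final switch.
* The auxiliary submodel is a reconstruction constrained only by topology
  and qualitative behaviour; its constants are not measurements.
* A statistical note on the factorial design: with 3 replicates per group,
  the interaction contrast has standard error
  $\sigma\sqrt{4/3} \approx 1.15\,\sigma$, so interaction effects near
  $4\sigma$ (e.g. 1.0 log2 units at $\sigma = 0.25$) sit at moderated
  $t \approx 3.5$ — detectably above null, but below the level that
  Benjamini-Hochberg selection at 0.05 over thousands of sites recovers
  with high sensitivity. Effects of $6\sigma$ are recovered essentially
  completely. This is a property of the design, shared by any
  moderated-t analysis of it.
* Synthetic movies and tables validate the metrics' definitions, not their
  robustness to segmentation errors, tracking errors or optical artefacts,
  which the package deliberately does not model.
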