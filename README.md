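# propro

Modelling and quantification of PLK1-inhibited mitotic entry.

Inhibiting polo-like kinase 1 (PLK1, e.g. with BI 2536) delays the
prophase-to-prometaphase transition — nuclear envelope breakdown (NEBD) —
to a strikingly variable extent: within one cell population, some cells
enter mitosis almost on time while others stall for many hours or never
enter during an overnight experiment. `propro` provides the computational
toolkit for studying this behaviour and the "prolonged prophase" state it
creates, for cell-cycle modellers and for analysts of the accompanying
live-imaging and phosphoproteomics read-outs.

## What is inside

**The bistable mitotic-entry model.** A six-state ODE network of
cdk1-cyclin B activation: a two-step cdc25 phosphorylation cycle opposed by
PP2A-B55 and a constitutive phosphatase, wee1/myt1 inhibition of cdk1 with
double-negative feedback, PP2A-B55 inactivation downstream of cdk1, and a
generic cdk1 substrate whose phosphorylation fraction is the NEBD read-out.
PLK1 enters as an activator of cdc25 with activity
$[Plk1] = f_{Plk1}\,[CycACdk2_{Tot}]$, where $f_{Plk1} \in [0,1]$ scales
from fully active (1) to completely inhibited (0):

$$\frac{d[Cdc25]}{dt} = (k_{PPX,Y15} + k_{B55,Cdc25}[PP2AB55])[Cdc25p]
  - (k_{Cdk1,Cdc25}V_{Cdk1} + k_{Plk1,Cdc25}[Plk1])[Cdc25]$$

NEBD is declared when substrate phosphorylation reaches 30%. Cells are
simulated from G2 entry (a step of cdk2-cyclin A activity at $t = 0$) with
a stiff ODE solver; populations draw per-cell cdk2-cyclin A activities
from configurable scenarios and are summarised as cumulative entry curves.
Steady-state and saddle-node analysis shows how PLK1 inhibition shifts the
cdk2-cyclin A threshold above which only the high-cdk1 state exists —
the mechanism behind the variable delay.

**Imaging metrics.** The per-nucleus quantifications used on label +
intensity movies: chromosome-condensation score (intensity SD over
background-corrected mean), nuclear/cytoplasmic ratio with Voronoi-clipped
dilation rings, FRET ratio, mask eccentricity with post-NEBD
normalisation, intensity-weighted z-centroid, prominence-based focus
counting, and cumulative NEBD percentages. Segmentation/tracking results
are consumed, not computed.

**Phosphoproteomics statistics.** The full site-level pipeline for a 2×2
factorial TMT design (±PLK1 inhibition × pre/post NEBD, three sixplex
batches with pooled references): localization/decoy filtering, per-batch
valid-value rule, downshifted-Gaussian imputation of
missing-not-at-random values, per-batch median-polish normalisation,
moderated t statistics with empirical-Bayes variance shrinkage, the
interaction contrast that defines prolonged-prophase-specific
phosphosites, four pairwise contrasts, Benjamini-Hochberg adjustment and
hit classification.

**Synthetic data.** Seeded generators for phosphosite tables (with batch
structure, spiked interaction effects and intensity-dependent dropout) and
for labelled movies (textured nuclei with a condensation ramp, bleaching,
NEBD events), so every stage is testable without any external data.

## Worked example

Simulate one PLK1-inhibited cell and inspect its entry delay:

```r
library(propro)

p <- default_params(f_plk1 = 0, cyca_cdk2_tot = 4)  # complete inhibition
tr <- simulate_cell(p)
tr
#> <cell_trajectory>
#>   2401 samples over [0, 24] h
#>   NEBD at 12.213 h
```

With full PLK1 activity the same cell enters at 0.86 h; the 12-hour delay
arises because inhibition moves the saddle-node threshold of cdk2-cyclin A
activity from 0.52 up to 3.42 a.u. — close beneath this cell's activity
of 4:

```r
find_saddle_nodes(default_params(f_plk1 = 0), bounds = c(0.01, 8))$sn_upper
#> [1] 3.420011
```

A heterogeneous population shows the characteristic partial penetrance —
every cell enters without inhibitor, 92.5% enter within 24 h at complete
inhibition:

```r
sc <- population_scenario(mean = 5, sd = 1, n_cells = 40, name = "demo")
tab <- simulate_population(sc, doses = c(1, 0), horizon = 24, seed = 1)
fraction_entered(tab, 24)
#>   scenario f_plk1 fraction
#> 1     demo      1    1.000
#> 2     demo      0    0.925
```

And the phosphoproteomics pipeline runs end-to-end on generated data:

```r
g <- generate_phospho(phospho_sim_spec(n_sites = 1000, seed = 1))
res <- phospho_pipeline(g$table, seed = 1)
res$table
#> <phosphosite_table> 876 sites x 18 samples (3 batches), log2
head(res$interaction[order(res$interaction$p), ])
```

`res$interaction` holds the prolonged-prophase-specific contrast
(log2 fold change, moderated t, raw and BH-adjusted p, up/down/ns class);
`res$pairwise` the four edges of the factorial square. On this null
generator specification (no spiked effects) no site is significant, as it
should be.

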