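# cryptsim

Stochastic crypt-lattice simulation and clonal analysis of intestinal
cell-fate proportions.

## The problem

Colonic crypts maintain a precise 1:3 ratio of mucus-secreting goblet
cells to absorptive enterocytes, yet the fate decisions are made early —
at the exit from a compartment of only ~8 Lgr5⁺ stem cells, *before*
transit-amplifying (TA) expansion. Early commitment by a pool of n cells
with secretory probability p, amplified a-fold, produces
`a·Binomial(n, p)` secretory output: mean `a n p`, SD `a √(n p (1−p))`,
so the coefficient of variation `√((1−p)/(n p))` is set by the *small*
pool (CV ≈ 0.61 for n = 8, p = 0.25) and is untouched by amplification,
whereas late commitment by 80 independent cells would give CV ≈ 0.19.
`cryptsim` is for quantitative biologists who want to simulate this
trade-off and the homeostatic mechanisms that resolve it:

* an event-driven simulator of the crypt as a cylindrical hexagonal
  lattice (22 rows × 16 columns; 8 stem cells + 8 niche cells, 6 TA rows,
  15 post-mitotic rows; division every 2.5 days; movement by mitotic
  pressure with column pushing and apical extrusion; stem-cell neutral
  drift);
* three commitment rules — **early** (at TA entry), **late** (at entry to
  the differentiated compartment), and **cz**: Delta–Notch lateral
  inhibition confined to a two-row commitment zone, where the 1:4
  secretory fraction emerges from the lattice geometry with no tuned
  probability;
* dispersive goblet-cell migration ("mixing"), clonal division
  synchronization, slower goblet cycling, stem-cell-number variability,
  and mosaic Notch hyperactivation (NICD) perturbations;
* inter-crypt variability statistics (CV of goblet proportions in sampled
  20–100-cell epithelial patches, neighbour-pair profiles, dwell times,
  flux amplification, noise-reduction percentages);
* the lineage-tracing pipeline: clone uniformity classification, a 10⁶-
  randomization null model for late commitment, bootstrap errors,
  Kruskal–Wallis/Welch clone-group comparisons, neutral-drift
  division-rate inference on the stem-cell ring, and matching synthetic
  data generators.

## Worked example

```r
library(cryptsim)
set.seed(42)

# the analytic trade-off
stats <- binomial_commitment_stats(8, 0.25, amplification = 10)
#> early commitment: 20 +/- 12.2 secretory cells per SC division time (CV 0.61)

# simulate replicate crypts under early vs zone-confined commitment
early <- simulate_crypts(sim_config(commitment_mode = "early"), 100, duration = 50)
czon  <- simulate_crypts(sim_config(commitment_mode = "cz"),    100, duration = 50)
sample_patch_proportions(early)
#> <proportion_sample> 100 patches of 55 cells (simulation): mean 0.223, CV 0.532
sample_patch_proportions(czon)
#> <proportion_sample> 100 patches of 61 cells (simulation): mean 0.256, CV 0.391
#> noise reduction by zone-confined lateral inhibition: 26%

# clone pipeline on synthetic lineage-tracing data
clones <- gen_clone_table(synth_spec(commitment_regime = "early", n_clones = 119))
cl <- classify_clones(clones)
#> <clone_classification> 119 clones (0 excluded as Lgr5+)
#>   uniform fraction among 119 multi-cell clones: 1.000
late_commitment_null(cl$clones$n_cells[cl$clones$n_cells >= 2],
                     observed_uniform_fraction = cl$uniform_fraction,
                     freq_secretory = 0.24, n_rand = 1e5)
#> late-commitment null: 0.38 +/- 0.041 uniform expected; observed 1.00 (z = 15.0, P = 2.3e-51)

# neutral-drift rate recovery from ring-clone sizes over chase times
fit <- fit_neutral_drift_rate(gen_lineage_truth(rate = 0.27, n_clones = 300),
                              n_boot = 100)
#> neutral-drift replacement rate: 0.29/day (95% CI 0.22-0.33)
```

Reading the output: under early commitment the goblet proportion of a
sampled epithelial patch swings by more than half of its mean from crypt
to crypt (CV 0.53), while confining lateral inhibition to the commitment
zone holds the mean at 0.26 and cuts the CV to 0.39. An all-uniform clone
table sits 15 standard deviations above the late-commitment null (which
expects only 38% uniform clones at these clone sizes), and the drift fit
recovers the generating replacement rate within its bootstrap CI.

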