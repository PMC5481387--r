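# bayesclust3d

Model-based Bayesian cluster analysis for 3D single-molecule localization
microscopy (SMLM) point clouds.

3D SMLM techniques such as iPALM output a table with one row per detected
fluorophore: coordinates (x, y, z) in nm plus per-dimension localization
precisions (σx, σy, σz). `bayesclust3d` decides which localizations form
nanoscale clusters without user-tuned analysis parameters, taking every
point's individual precision into account, and reports the descriptors cell
biologists actually compare between conditions: the number of clusters per
ROI, the percentage of localizations in clusters, the localizations per
cluster, the cluster radii, and how all of this varies with depth z.

## The method

For each localization *j* within an ROI of volume *V*, a localized,
linearised 3D Ripley's L statistic

L<sub>3D</sub>(r)<sub>j</sub> = ( 3V / (4(n−1)π) · Σ<sub>i≠j</sub> δ<sub>ij</sub> )<sup>1/3</sup>,

with δ<sub>ij</sub> = 1 when the toroidal distance between *i* and *j* is
below *r*, measures local density in length units (its expected scale under
complete spatial randomness is *r* itself). Points whose neighbour count
exceeds the CSR mean plus one standard deviation (exactly
Binomial(n−1, 4πr³/3V) on the torus) are eligible; eligible points hill-climb
the L field to local maxima, and maxima are pruned by topographic prominence
with threshold *T* — modes less prominent than *T* merge into their higher
neighbour across the connecting saddle, and shallow isolated modes are
dropped. Each (r, T) pair yields one cluster proposal; sweeping a grid
(default 19 radii × 21 thresholds) enumerates the hypothesis space.

Every distinct proposal is then scored under one generative model: clusters
are spherical Gaussians with unknown centre (integrated exactly in closed
form) and unknown radius (summed over a histogram prior); each point
contributes through its own variance s² + σ²; the background is uniform in
x/y with a per-ROI maximum-likelihood Beta distribution over z/Lz capturing
membrane-proximal pile-up; labelling follows a Bernoulli background prior
(default 50%) and a Chinese-restaurant-process partition prior. The
highest-scoring (maximum a posteriori) proposal is retained.

A ground-truth simulation engine reproduces the published validation
conditions (the "Standard Condition": 3000×3000×600 nm, 10 Gaussian clusters
of radius 30 nm × 50 molecules over an equal uniform background, Gamma
mean-30 nm precisions — plus CSR controls, Beta(2,5)/Beta(2,20) axial
backgrounds, hard-edge spheres and (1,1,2) ellipsoids), so every recovery
claim is testable from code alone.

## Worked example

Simulate one Standard Condition ROI and analyse it with all defaults:

```r
library(bayesclust3d)

sim <- simulate_roi(standard_condition(seed = 42))
fit <- bayes_cluster(sim$locs, roi(3000, 3000, 600))
fit
#> <bayes_cluster3d>
#>   n = 1000 localizations in 3000 x 3000 x 600 nm ROI
#>   MAP proposal: r = 100 nm, T = 180 nm, log score = -21023.44
#>   9 cluster(s), 50.7% of localizations clustered
#>   mean 56.3 localizations/cluster, mean radius 34.4 nm
```

The fit is a broom-style object: `glance()` gives the per-ROI descriptor
row, `tidy()` the per-cluster table, `augment()` the input points with
cluster labels and L values, and `autoplot()` a cluster map.

```r
head(tidy(fit), 5)
#> # A tibble: 5 x 7
#>   cluster n_points     x     y     z map_radius rms_radius
#>     <int>    <int> <dbl> <dbl> <dbl>      <dbl>      <dbl>
#> 1       1       49 2669. 1381.  462.         30       39.2
#> 2       2       52 2731. 2119.  157.         30       41.5
#> 3       3       50  893. 2728.  514.         30       39.8
#> 4       4       52 2416.  821.  475.         35       47.8
#> 5       5      101 1925. 1407.  199.         55       65.7
```

Nine clusters are detected for ten simulated: two overlapping true clusters
were merged (the 101-point cluster with a 55 nm radius); the remaining
clusters recover the simulated 50 molecules and 30 nm radius almost
exactly, and 50.7% of localizations are labelled clustered versus 50%
simulated. `map_radius` is the model's Gaussian standard deviation estimate
after subtracting each point's localization error, which is why it sits at
30 nm while the raw RMS spread of the noisy points is ~40 nm.
`recovery_metrics(sim, fit)` scores detected-versus-true descriptors, and
`z_profile(fit)` gives the 30 nm-binned axial profiles.

Batch work uses the same verbs: `analyze_roi()` writes per-point, per-cluster
and summary files; `batch_summary()` aggregates glance rows across ROIs with
SEM; `evaluate_recovery()` compares batches against simulation truth. A thin
command-line front end (`inst/scripts/bayesclust3d.R`) wraps simulate /
analyze / evaluate for shell pipelines.

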