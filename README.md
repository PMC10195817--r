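# smquant

Quantitative analysis of single-molecule experiments on nuclear proteins —
the kind of multi-modal campaign used to characterise how an autophagy
receptor such as NDP52 organises and behaves inside the nucleus.  One
package covers the five measurement modalities such a study combines,
each as a small, testable pipeline with a synthetic-data generator that
provides exact ground truth:

| Modality | What is measured | Core functions |
|---|---|---|
| SMLM (STORM) point patterns | clustering vs randomness; cluster size, area, occupancy | `ripley_l_minus_r()`, `cluster_dbscan()`, `cluster_metrics()` |
| Two-channel SMLM | per-molecule degree of colocalization (DoC) and colocalized-cluster statistics | `doc_scores()`, `coloc_cluster_summary()` |
| 3D single-particle tracking | diffusion coefficient D, anomalous exponent α, static/slow/diffuse composition | `track_msd()`, `fit_anomalous()`, `fit_tracks()`, `cell_summary()` |
| FRAP | recovery half-time and mobile fraction | `normalize_frap()`, `fit_recovery()` |
| Equilibrium titrations | dissociation constant under ligand depletion | `eq1_bound()`, `eq2_signal()`, `fit_kd()` |
| AFM height maps | grain masking, bounding sizes, KDE modes, DNA binding position, compaction | `mask_grains()`, `grain_bounds()`, `kde_mode()`, `dna_binding_position()`, `compaction_stats()` |

## The statistics at the core

* **Linearised Ripley's K** with guard-band edge handling for free-hand
  polygonal ROIs: `L(r) − r = sqrt(K̂(r)/π) − r`, zero under complete
  spatial randomness, positive under clustering.
* **DBSCAN** cluster maps at the field's settings (minimum 5 molecules,
  ε = mean localization precision), with convex-hull cluster areas.
* **DoC scores**: Spearman rank correlation of two channels' local density
  gradients `N(r)/r²` across a radius ladder, damped by `exp(−d/r_max)`;
  +1 = perfect colocalization, −1 = segregation, threshold 0.4.
* **Anomalous diffusion**: per-track time-averaged MSD fitted as
  `log MSD = log(2·dims·D) + α·log t` over the first lags; classes
  static (D < 0.1), slow (0.1 ≤ D ≤ 1), diffuse (D > 1 µm²/s).
* **FRAP**: double + full-scale normalization, then
  `I(t) = M(1 − e^{−kt})`, `t½ = ln2/k`, plateau M = mobile fraction.
* **Tight binding**: `[PD] = (S − sqrt(S² − 4·P·D))/2`, `S = P + D + K_d`,
  in a cancellation-safe form; MST-style self-association treats the
  labelled species (50 nM) as the fixed partner.
* **AFM grains**: threshold at `mean + k·SD`, 4-connected components,
  border/size/median filters, rotating-caliper bounding sizes, KDE
  mode ± SD summaries.

Every estimator above is checked against an independent brute-force
oracle in the test suite, and every generator returns ground truth so the
full pipelines are scored end to end.

## Worked example

Simulate a two-channel clustered nuclear scene, map clusters, and score
colocalization; then fit a FRAP trace and a self-association titration:

```r
library(smquant)

scene <- simulate_clustered_channels(cluster_scene_params(
  roi = square_roi(5000), n_clusters = 20, molecules_per_cluster = 44,
  cluster_sd = 25, background_fraction = 0.2, coloc_fraction = 0.5,
  seed = 42))

scene$channelA
#> <localization_table> 1111 localizations, mean precision 20.0 nm, ROI area 2.5e+07 nm^2

clus <- cluster_dbscan(scene$channelA)   # eps = mean precision, min_pts = 5
clus
#> <cluster_result> 1111 points, 25 clusters, 68.9% clustered (eps = 20 nm, min_pts = 5)
str(clus$summary)
#> List of 9
#>  $ n_points     : int 1111
#>  $ n_clusters   : int 25
#>  $ pct_clustered: num 68.9
#>  $ mean_area_nm2: num 3528
#>  $ sem_area_nm2 : num 353
#>  $ mean_members : num 30.6
#>  $ sem_members  : num 2.77
#>  $ mean_density : num 0.0109
#>  $ n_zero_area  : int 0

doc_scores(scene$channelA, scene$channelB)
#> <doc_result> 1111 + 1144 points, threshold 0.40: 48.9% / 47.6% colocalized

tr <- simulate_frap(t_half = 7.5, mobile_fraction = 0.65,
                    noise_sd = 0.02, seed = 42)
fit_recovery(normalize_frap(tr))
#> <frap_fit> t1/2 = 7.89 s, mobile fraction = 0.633

tc <- simulate_titration(kd = 0.21, noise_sd = 0.02, n_replicates = 3,
                         seed = 42)
fit_kd(tc)
#> <binding_fit> eq1: Kd = 0.2014 uM (SE 0.0093)
#>   replicates: mean 0.2016 +/- 0.0054 (SEM, n = 3)
```

Reading the output: about 69% of channel-A molecules sit in 25 clusters of
~31 molecules and ~3500 nm² each (the scene was generated with half the
cluster centres shared between channels, hence roughly half the molecules
scoring above the 0.4 DoC threshold).  The FRAP and titration fits recover
the generating parameters (t½ = 7.5 s, mobile fraction 0.65, K_d =
0.21 µM) within the noise of a single simulated experiment.

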