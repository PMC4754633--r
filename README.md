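# chronodiff

Differential daily-rhythmicity analysis for two-condition omics time
courses.

Peripheral organs such as the liver express thousands of genes and
metabolites with daily (diurnal) oscillations, and perturbations — for
example raising animals germ-free (GF) instead of specific pathogen-free
(SPF) — can change *which* features oscillate, their acrophase (peak time)
and their period. `chronodiff` implements the full analysis such a study
needs, for designs of the form *2 conditions × a few Zeitgeber times (ZT)
× a few replicates* (the canonical design is ZT 0/6/12/18 with n = 5 per
condition and time point):

- **Rhythm detection** (`jtk_scan()`): each feature is compared against
  cosine reference waveforms on a period/phase grid via Kendall's
  S = Σ<sub>i&lt;j</sub> sgn(x<sub>j</sub>−x<sub>i</sub>)·sgn(r<sub>j</sub>−r<sub>i</sub>),
  with an **exact permutation null** computed by dynamic programming over
  the tie structures of both the data and the reference (the JTK_Cycle
  scheme). Per-feature p-values are Bonferroni-adjusted over the
  non-redundant (period, phase) hypotheses and Benjamini–Hochberg q-values
  are taken across features; q &lt; 0.05 flags a feature rhythmic.
- **Six-class differential rhythmicity** (`classify_rhythms()`): from the
  two per-condition scans each feature is labelled
  1 = rhythmic in both with identical parameters, 2 = phase shift,
  3 = period change, 4 = rhythmic in condition A only, 5 = B only,
  6 = arrhythmic in both.
- **Differential expression and clustering** (`moderated_f_test()`,
  `ward_cluster()`, `cluster_profile_summary()`): per-feature F test
  across the (condition × ZT) cells with empirical-Bayes variance
  moderation, BH at 1 %, then hierarchical clustering with
  d = 1 − Pearson r and Ward's criterion, per-cluster mean Z-score
  profiles with 95 % CIs, and hypergeometric gene-set enrichment.
- **Seed-gene correlation networks** (`seed_network()`,
  `network_retention()`): the 50 features most correlated (|r|) with a
  seed, all pairwise edges tested by the t transform with Bonferroni
  adjustment over the displayed pairs, and cross-condition retention of
  the significant partners.
- **Metabolomics chemometrics** (`osc_filter()`, `pareto_scale()`,
  `plsda_fit()`, `q2_crossval()`, `vip_scores()`,
  `permutation_validation()`, `select_discriminant()`): orthogonal signal
  correction with the time classes as correction factor, Pareto scaling,
  NIPALS PLS-DA, 7-fold Q², a 200-iteration permutation test, and
  discriminant-bucket selection by VIP &gt; 1.5 plus Kruskal–Wallis
  p &lt; 0.05.
- **Ground-truth simulators** (`sim_rhythmic()`, `sim_network()`,
  `sim_buckets()`) emulating the design above, so every stage is testable
  without external data, and a deterministic orchestrator
  (`run_pipeline()`) that writes TSV outputs with a checksum manifest.

## Worked example

```r
library(chronodiff)

sim <- sim_rhythmic(n_features = 60, sigma = 0, seed = 3)
scan <- jtk_scan(sim$tcm, "SPF")
scan
#> Rhythm scan (SPF): 60 features, 40 rhythmic at q < 0.05
#>       feature period lag    S tau           p        adj_p            q
#> f0001   f0001     24   0  125   1 4.29567e-08 1.288701e-07 1.933051e-07
#> f0002   f0002     24  18 -125  -1 4.29567e-08 1.288701e-07 1.933051e-07
#> ...

cls <- classify_rhythms(scan, jtk_scan(sim$tcm, "GF"))
table(truth = sim$truth$class, estimated = cls$class)
#>      estimated
#> truth  1  2  3  4  5  6
#>     1 10  0  0  0  0  0
#>     2  0 10  0  0  0  0
#>     3  0  0 10  0  0  0
#>     4  0  0  0 10  0  0
#>     5  0  0  0  0 10  0
#>     6  0  0  0  0  0 10
```

On noiseless data every planted rhythmic feature is recovered
(q ≈ 2 × 10⁻⁷ at n = 20), `period`/`lag` equal the planted period and
acrophase (a negative S simply reports the antiphase lag, here 18 h for a
feature peaking at ZT18), and all six planted differential-rhythmicity
classes are recovered exactly.

A full run with all stages:

```r
res <- run_pipeline(default_config(seed = 1), "out/")
res$manifest          # every output file with its MD5 checksum
```

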