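---
title: "Methods and design choices in chronodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in chronodiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronodiff)
```

`chronodiff` analyses daily rhythms in feature-by-sample time courses
collected under two conditions. This vignette documents the statistical
models, the parameters that matter, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The design

The canonical design is two conditions (e.g. specific pathogen-free, SPF,
versus germ-free, GF, animals) sampled at Zeitgeber times ZT0, ZT6, ZT12
and ZT18 (hours after lights-on) with 5 replicates per condition and time
point — 40 samples in all. All methods accept other grids, but the
defaults assume one sample cycle per 24 h day and a 6 h spacing.
Missing values are rejected rather than imputed: the exact rhythm null
below assumes a complete design, and an incomplete sheet is more often an
input error than a fact about the biology.

## Rhythm detection: cosine references, Kendall's S, exact nulls

For each feature and each candidate (period $\tau$, lag $\phi$) on a grid,
the reference waveform $r_i = \cos(2\pi (t_i - \phi)/\tau)$ is evaluated at
each sample's ZT, and the concordance between the data and the reference is
summarised by Kendall's
$S = \sum_{i<j} \mathrm{sgn}(x_j - x_i)\,\mathrm{sgn}(r_j - r_i)$.
Replicates at one ZT share a reference value, so the reference is heavily
tied; tied data values (exact ties only) contribute zero.

The two-sided p-value is $P(|S| \ge |s|)$ under the exact permutation null:
all distinct assignments of the data values to the sample positions,
equally likely. `exact_null_distribution()` computes this null by a
convolution dynamic programme over *both* tie structures: data tie blocks
are inserted in increasing value order into the reference tie groups, each
placement contributing its concordant-minus-discordant increment with a
multinomial-coefficient multiplicity. For every design with up to 8
observations the DP is verified against exhaustive enumeration in the test
suite; for the 4 ZT × 5 replicate design the null has support −150…150 and
is computed once and cached per (data ties, reference ties) signature, so a
matrix scan pays the DP cost once.

One subtlety is worth recording: when **both** rankings are tied, the null
distribution depends on the value-ordered sequence of tie-block sizes and
need not be symmetric about zero (data blocks (1,1,2) against reference
blocks (1,1,2) have support −4…5). The package therefore never collapses
tie sequences to multisets. Reversing either ranking leaves $P(|S| \ge a)$
unchanged, so two-sided p-values — and the antiphase collapsing below —
are unaffected.

**Grid.** The default periods are {12, 24} h with the phase step equal to
the 6 h sampling interval: four time points over one cycle cannot resolve
finer structure, and both are configurable. A lag $\phi$ and its antiphase
partner $\phi + \tau/2$ induce negated orderings, so only lags below
$\tau/2$ are scanned and a negative $S$ reports the antiphase acrophase.
This leaves 3 non-redundant hypotheses on the default grid; the reported
`adj_p` is the minimum p times this count (capped at 1), a within-feature
Bonferroni factor that can be switched off. Across features,
Benjamini–Hochberg q-values are computed per scan and `q < 0.05` flags a
feature rhythmic. Constant series carry no ordering information and are
reported with `period = 0`, `p = 1`, never as an error.

## Six-class differential rhythmicity

Each feature's two per-condition scans are reduced to a class:
both rhythmic with equal period and acrophase (1); equal period, shifted
acrophase (2); changed period (3); rhythmic in the first (4) or second (5)
condition only; arrhythmic in both (6). Significance is `q < 0.05` within
each condition's own BH family. Equality tolerances default to half the
grid steps — grid-identical estimates compare equal, neighbouring grid
points differ — because the discrete scan defines parameter resolution;
acrophases are compared circularly modulo the period. The classification
is exhaustive and mutually exclusive, and swapping the condition labels
exchanges classes 4 and 5 while fixing the rest (a property the tests
check exactly).

## Differential expression, clustering, profiles, enrichment

The differential-expression flag uses a one-way F test across the 8
(condition × ZT) cells — "any difference" — with BH at 1 %. The exact
contrast set behind the original analysis is not recoverable; the 8-cell F
is the documented stand-in and yields a superset suitable as clustering
input. Variances are moderated by default: residual variances are shrunk
toward a prior fitted by moments on the log variances (digamma/trigamma
identities of the scaled chi-square, with a Newton inversion of the
trigamma function), the F denominator becomes the posterior variance and
its degrees of freedom gain the prior df. With prior df 0 the moderated F
equals the ordinary F; the fit agrees with `limma::squeezeVar` to
numerical precision (checked in a test against that independent
implementation).

Clustering uses $d = 1 - r$ (Pearson) with Ward's criterion in the
squared-distance (`ward.D2`) convention — the historical Ward.D/Ward.D2
ambiguity is resolved to D2 and recorded in the result object. The default
is k = 9 feature clusters; the sample-axis dendrogram is used for ordering
only. Constant rows have no defined correlation and are rejected by name.
Merge order and leaf order come from `stats::hclust` and are a
deterministic function of the input order; heatmap matrices inherit those
orders. Cluster profiles are per-feature Z-scores (each feature centred
and scaled across *all* samples — whether the original scaling was within
condition is not stated, and across-all-samples is the default), averaged
over replicates, averaged over the cluster, and offset so the reference
cell (first condition at the earliest ZT) is zero; the 95 % CI is across
the cluster's features. Gene-set enrichment is a plain hypergeometric
upper tail per (cluster, set) with BH within each cluster; conditional
(DAG-aware) testing is out of scope.

## Seed correlation networks

A seed network keeps the k = 50 partners with the highest |Pearson r| to
the seed (ties broken lexicographically for determinism) and tests all
$\binom{k+1}{2}$ pairwise correlations via
$t = r\sqrt{n-2}/\sqrt{1-r^2}$. The Bonferroni family is the displayed
pairs, matching the figure-level rule of the emulated analysis; a raw-p
mode for the partner flags is available because the original text is
ambiguous about the partner-list threshold. Retention re-evaluates the
same partner list, family and rule on the second condition's samples and
counts the initially significant partners that remain significant;
density is significant edges over tested pairs in both cases.

## Chemometrics for bucket tables

Buckets (integrated NMR spectral regions) arrive as a samples × buckets
matrix with ZT as the class factor, one model per condition. The stage
follows the classical sequence:

1. **OSC** (default 1 component; the original count is unstated, so it is
   a recorded parameter): the dominant principal direction is
   orthogonalised against the class-indicator column space, weights are
   recomputed by regression on that score, the score is re-orthogonalised
   and the component removed — every removed score is exactly orthogonal
   to every class column.
2. **Pareto scaling**: centre, divide by $\sqrt{\mathrm{sd}}$;
   zero-variance buckets are centred only and flagged.
3. **PLS-DA by NIPALS** on the centred class-indicator matrix, converging
   each score to $10^{-10}$ relative change, recording per-component
   explained Y sum-of-squares $\|t\|^2\|c\|^2$ and cumulative R²X/R²Y.
4. **7-fold Q²**, stratified so every training fold keeps all classes;
   $Q^2(a) = 1 - \mathrm{PRESS}(a)/\mathrm{SS}$. The component count
   follows a sequential rule — keep adding while the increment is at
   least 0.01 — approximating the undocumented commercial rule; a fixed
   count can be forced. The conventional validity heuristic (R² > 50 %,
   Q² > 0.4) is reported as a flag.
5. **Permutation validation** (default 200 relabellings):
   $p = (1 + \#\{Q^2_{perm} \ge Q^2\})/(n+1)$, likewise for R².
6. **VIP**, $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{aj}^2 /
   \sum_a \mathrm{SSY}_a}$, so $\sum_j \mathrm{VIP}_j^2 = p$; buckets with
   VIP strictly above 1.5 *and* Kruskal–Wallis p < 0.05 across the ZT
   classes are selected as discriminant.

Hotelling's 95 % ellipse for score plots uses semi-axes
$\sqrt{\mathrm{var}(t_i)\, \tfrac{2(n-1)}{n-2} F_{0.95}(2, n-2)}$.

## Synthetic data: what it emulates, what it does not

`sim_rhythmic()` draws features from
$y = m + A\cos(2\pi(t-\phi)/\tau) + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$, on an implicit log2 abundance scale
(mesor 10, amplitudes 0.5–2, $\sigma = 0.25$ by default — typical
magnitudes for normalised array signals). Classes are planted by the rules
above, with the class-2 phase shift defaulting to 6 h and the class-3
alternative period to 12 h so both are resolvable on the 6 h grid;
acrophases are drawn from the sampling grid so noiseless parameters are
exactly recoverable. Replicates are i.i.d. — no animal-level random
effect — and there are no probe-level artefacts, heteroscedasticity or
missingness, so passing tests demonstrate algorithmic correctness under
the design, not robustness to everything real arrays do.
`sim_network()` plants a latent driver with partner loadings in one
condition and independent partners in the other; `sim_buckets()` plants
ZT-dependent cosine mean shifts plus a shared confounder that is
*exactly* class-orthogonal by construction (residualised against the ZT
means), which is precisely the variation OSC is meant to remove.
Generators are deterministic functions of their seed and never disturb
the caller's RNG stream.

## Reproducibility and problem sizes

`run_pipeline()` derives each stage's seed from the global seed by fixed
offsets, so stage-level reruns reproduce pipeline-level results; outputs
are TSVs with a provenance header (version, seed, config hash) and a
manifest of MD5 checksums, and two runs with the same config and seed are
byte-identical. The test suite and the acceptance script run on sizes of
roughly 50–2 000 features, 40 samples, and 120-bucket tables — large
enough to exercise every code path and the FDR/recovery properties while
keeping a full run in well under a minute per stage. The enumeration
oracle for the exact null covers every tie design with up to 8
observations; larger designs rely on the DP, whose agreement with
enumeration is exact wherever enumeration is feasible.

## Known limitations

- The rhythm grid cannot estimate amplitude and does not interpolate
  phases between grid points; cosinor regression or Lomb–Scargle are
  out of scope by design.
- The DE flag is an omnibus 8-cell F; per-cell contrasts are available
  but not part of the headline flag.
- Plain hypergeometric enrichment ignores gene-set overlap structure.
- OSC here is sequential signal correction before PLS, not an integrated
  orthogonal PLS variant.
- Exact Kruskal–Wallis enumeration is limited to total n ≤ 10; larger
  designs use the chi-square approximation.
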