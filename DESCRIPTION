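Package: chronodiff
Title: Differential Daily Rhythmicity Analysis for Two-Condition Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of daily (diurnal) rhythms in feature-by-sample time-course
    data collected under two conditions, such as germ-free versus specific
    pathogen-free animals sampled around the clock. Implements nonparametric
    rhythm detection by scanning cosine reference waveforms with Kendall's S
    and an exact permutation null over tied designs (the JTK_Cycle scheme), a
    six-class differential-rhythmicity classifier, differential-expression
    selection with empirical-Bayes variance moderation, hierarchical clustering
    on 1-Pearson distances with Ward agglomeration and per-cluster Z-score
    profiles, hypergeometric gene-set enrichment, seed-gene correlation
    networks with Bonferroni edge significance and cross-condition retention,
    and a chemometrics stage for metabolite bucket tables (orthogonal signal
    correction, Pareto scaling, NIPALS PLS-DA, seven-fold Q2 cross-validation,
    permutation validation, and VIP-based discriminant bucket selection).
    A synthetic-data generator with known ground truth emulates the
    two-condition, four-time-point, five-replicate design so that every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
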