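# clustergrow

Iterative cluster-based annotation of image feature sets.

Large plankton-imaging campaigns (and many other single-object imaging
pipelines) produce millions of images that need class labels. Labeling each
image is hopeless at that scale, and a classifier with a fixed class list
cannot discover anything new. `clustergrow` implements the cluster-centric
alternative: objects live as deep feature vectors (D = 32 by default), and an
annotator — human at a console, or a ground-truth-backed oracle in tests and
benchmarks — makes a small number of high-leverage decisions:

1. **Seed.** HDBSCAN\* (neighborhood size k = 1, minimum cluster size *m*)
   extracts the densest regions of the unassigned pool as *cluster seeds*,
   rejecting most objects as noise. The schedule *m* = 128, 64, 32, 16, 8, 4
   finds the largest coherent groups first and increasingly smaller classes
   in later iterations.
2. **Validate.** Each seed is accepted iff sufficiently homogeneous
   (oracle: modal-label fraction ≥ 0.90); rejected seeds dissolve back into
   the pool.
3. **Grow.** Candidates are ranked by distance to the seed centroid and cut
   into pages of 50; galloping probes (pages 1, 2, 4, 8, …) followed by
   binary search find the last fully matching page *b* in O(log P)
   judgments, and pages 1..*b* join the cluster. A *turtle mode* switches to
   per-object review when the border page is only partially foreign.
4. **Name.** Validated clusters are arranged by UPGMA (average-linkage)
   clustering of their centroids; leaves and branches are named, merged and
   rearranged, and `flatten_labels()` turns the tree into an object-level
   label table.

Evaluation tools implement the standard consistency metrics: per-class
precision Pr\_c = TP\_c / (TP\_c + FP\_c) from sampled review (up to 500
objects per class), macro precision P̄r (unweighted mean over classes), the
10th-percentile precision Pr10, the relative overlap (Jaccard index)
|A∩B| / |A∪B| between classes of two labelings, predominant-class agreement,
session-split throughput (objects/hour), and class-recovery reports. A
synthetic generator produces long-tailed Gaussian-mixture benchmarks
(power-law class sizes, uniform background noise, small held-out *indicator*
classes) with complete ground truth, so the entire loop is testable without
any real image set.

## Worked example

```r
library(clustergrow)

d <- generate_dataset(synth_config(n_classes = 8, total_objects = 3000, dim = 16,
                                   separation = 10, noise_fraction = 0.02,
                                   indicator_class_count = 1, rng_seed = 42))
annotator <- oracle_annotator(d$labels)          # simulated human, purity 0.90
run <- run_full(d$features, annotator, m_schedule = c(64, 32, 16, 8, 4))
run
#> <annotation_run> 3000 objects -> 8 clusters, 8 named classes, 43 residual (1.4%)

glance(run)
#> # A tibble: 1 × 5
#>   n_objects n_clusters n_named_classes n_residual residual_fraction
#>       <int>      <int>           <int>      <int>             <dbl>
#> 1      3000          8               8         43            0.0143

rec <- recovery_report(run, d$labels, d$indicator_classes)
rec
#> # A tibble: 8 × 6
#>   label         size n_assigned retrieved first_seed_iteration indicator
#>   <chr>        <int>      <int> <lgl>                    <int> <lgl>
#> 1 class_01      1770       1770 TRUE                         1 FALSE
#> 2 class_02       508        508 TRUE                         1 FALSE
#> 3 class_03       245        245 TRUE                         1 FALSE
#> 4 class_04       146        146 TRUE                         2 FALSE
#> 5 class_05        98         98 TRUE                         2 FALSE
#> 6 class_06        70         70 TRUE                         1 FALSE
#> 7 class_07        53         53 TRUE                         2 FALSE
#> 8 indicator_01    50         50 TRUE                         2 TRUE

glance(precision_by_review(run$labels, annotator, cap = 500, rng_seed = 1))
#> # A tibble: 1 × 3
#>   macro_precision  pr10 n_classes
#>             <dbl> <dbl>     <int>
#> 1           0.983 0.963         8
```

All eight ground-truth classes — including the 50-object held-out indicator
class, which no iteration-1 seed could contain — come back as named classes;
the 43 residual objects are essentially the 2% uniform noise; the rank
correlation between class size and discovery iteration is negative
(−0.655 here): larger classes are found earlier, as the shrinking-*m*
schedule intends. `autoplot(run)`, `plot_recovery(rec)` and
`autoplot(correspondence(...))` provide the matching diagnostics plots.

A thin CLI mirrors the stages (`synth`, `cluster`, `grow`, `tree`, `run`,
`evaluate`) with JSON state files between them:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "clustergrow", package = "clustergrow"))')
Rscript $CLI synth --out-features f.tsv --out-labels truth.tsv --classes 8 \
    --objects 3000 --dim 16 --seed 42
Rscript $CLI run --features f.tsv --truth truth.tsv --out-labels out.tsv \
    --out-newick tree.nwk --log events.jsonl
Rscript $CLI evaluate --labels-a truth.tsv --labels-b out.tsv --out report.json
```

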