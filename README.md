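# brainblocks

Virtual neuropathologic sampling of brain volumes: how precise and how
accurate is the standard autopsy practice of cutting a brain into 4 mm
coronal slabs and sampling a 3.8 cm x 3.2 cm tissue block from a slab
chosen by anatomical landmarks — and how much does neuroimaging guidance
improve it?

`brainblocks` is for neuropathologists and neuroimaging researchers who
want to simulate and quantify block sampling protocols on volumetric
(NIfTI-1) data. It implements:

* a **virtual slicing model**: coronal slab stacks as half-open world
  intervals `[origin + i·t, origin + (i+1)·t)`, blocks as axis-aligned
  boxes placed by landmark + offset rules (`make_slice_stack()`,
  `place_block()`, `landmark_anchored_block()`);
* **precision** surfaces: per-voxel counts of how many subjects' blocks
  cover each template voxel, with overlap-degree histograms
  (`overlap_count_map()`, `overlap_histogram()`, `max_overlap_summary()`);
* **accuracy**: percent overlap of a sampled block with the registered
  reference block, `100 · |S ∩ R| / |R|` (Dice, union and sample
  denominators available), plus two corrections — the whole-slab
  anterior-posterior search (*guided*, `ap_slab_search()`) and the full
  6-parameter rigid-body overlap maximization (*optimal*,
  `rigid_overlap_optimize()`). By construction,
  subject-specific ≤ guided ≤ optimal;
* **inference**: exact/approximate Wilcoxon matched-pairs signed-rank
  test, Poisson regression of overlap counts with cluster-robust
  (sandwich) standard errors, and a sign-flip permutation test with
  empirical top/bottom 5% thresholds (`wilcoxon_signed_rank()`,
  `poisson_robust()`, `sign_flip_null()`);
* **seed-based functional connectivity**: Pearson correlation of a
  block's mean BOLD timeseries to each region of a region set, and the
  per-region comparison of subject-specific vs reference sampling
  (`fc_profile()`, `fc_discrepancy_analysis()`, `run_connectivity()`);
* a fully **synthetic phantom cohort** with known ground truth —
  ellipsoid brain, true rigid + smooth nonlinear deformations, jittered
  anterior-commissure-like landmark, planted BOLD network communities —
  so the whole pipeline is testable without any external data
  (`make_template()`, `make_subject()`, `simulate_bold()`,
  `make_cohort()`).

## Worked example

```r
library(brainblocks)

cohort <- make_cohort(n = 10, seed = 1)   # phantom cohort, ~15 s
acc <- run_accuracy(cohort, optimal = FALSE)
acc$table$summary
#>   roi_label           method  n  mean    sd median   iqr
#> 1       IPL           guided 10 59.79 16.16  62.94 24.68
#> 2       MFG           guided 10 54.14 14.65  51.99 15.58
#> 3      MSTG           guided 10 65.91 16.49  62.06 22.79
#> 4        V1           guided 10 57.50 11.07  60.20 17.47
#> 5       IPL subject_specific 10 18.29 25.56   3.47 32.87
#> 6       MFG subject_specific 10 18.53 22.75   5.50 36.94
#> 7      MSTG subject_specific 10 11.08 23.38   0.00  1.03
#> 8        V1 subject_specific 10 15.74 22.35   4.29 22.88

acc$wilcoxon
#>   roi_label                 comparison  W   p_value n_used  mode
#> 1       MFG guided vs subject_specific 28 0.0156250      7 exact
#> 2      MSTG guided vs subject_specific 36 0.0078125      8 exact
#> 3       IPL guided vs subject_specific 36 0.0078125      8 exact
#> 4        V1 guided vs subject_specific 36 0.0078125      8 exact
```

Landmark-placed blocks overlap their intended reference region by only
~11-19% on average (the anterior-posterior landmark jitter usually puts
the block on the wrong slab), while re-choosing the slab with imaging
guidance raises overlap to ~54-66%; the paired Wilcoxon test is
significant in every region. This mirrors, on synthetic ground truth, the
qualitative finding that motivated the framework.

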