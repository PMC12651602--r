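# picscore

Rare-event detection and contact-interface scoring for enrichment-free
liquid-biopsy slide images.

In enrichment-free liquid biopsy, every nucleated cell from a blood draw is
plated and imaged; circulating tumor cells (CTCs) and large extracellular
vesicles (LEVs) are found by rule-based thresholds on multiplexed
immunofluorescence (DAPI, cytokeratin/CK, CD45, brightfield). Some tumor
events physically contact white blood cells (WBCs), and a subset of those
contacts — *physiologically interacting clusters* (PICs) — shows elevated
CD45 at the contact interface with circumferential asymmetry toward the
tumor event, the signature of active engagement rather than random
co-location. `picscore` implements the full analysis chain for researchers
working on tumor–immune interactions in liquid biopsy, exercised end to end
on synthetic slides with planted ground truth.

The package covers:

* **Synthetic slides** (`sim_config()`, `generate_slide()`): multichannel
  16-bit images with planted WBCs, epi./im. CTCs, LEVs, debris, and
  tumor–WBC pairs in `pic` / `overlap` / `gap` relationships, plus exact
  ground-truth tables. Deterministic given a seed.
* **Event detection** (`detect_events()`): nuclear segmentation (Gaussian
  smoothing, Otsu, watershed; Voronoi propagation to cell bodies), the
  platform's filters — exclude DAPI < mean − 3 SD, call CTCs above
  CK mean + 6 SD of all segmented cells, LEVs ≥ 2.5 µm equivalent diameter
  with low DAPI and a brightfield membrane ring — and CD45 phenotyping
  anchored on the detected leukocyte distribution.
* **Neighbor analysis** (`find_neighbors()`): tumor–immune pairs whose
  masks overlap or share an 8-connected boundary, abundance per 10⁶ cells,
  and a random-overlap null expectation.
* **PIC scoring** (`score_pic_pair()`): ordered WBC perimeter traces,
  contact/non-contact partition, the contact-interface fold change
  (mean contact ÷ mean non-contact membrane intensity), a resultant-vector
  asymmetry score, and Mann–Whitney U comparison with rank effect size
  `r = |z|/√N`.
* **Phenotype profiling** (`hierarchical_cluster()`,
  `gate_immune_subtype()`, `fisher_enrichment()`): log(1+x) ion counts,
  Ward clustering, immune gating, IF↔IMC coordinate matching, Fisher
  enrichment of in-contact events, differential marker tests.
* **Cohort statistics** (`per_ml()`, `summarize_patient()`,
  `summarize_cohort()`): per-mL extrapolation and patient/cohort
  summaries, with a bundled per-mL enumeration table for eight
  LEV-evaluable patients.

## Worked example

```r
library(picscore)

# a synthetic slide: 504 WBCs, rare tumor events, planted pairs
sim <- generate_slide(sim_config(seed = 101))
det <- detect_events(sim$image)
det$thresholds$ck_threshold
#> [1] 19394.61
table(det$cells$phenotype[det$cells$retained])
#>  epi  im  wbc
#>    4   4  503

# score a planted interacting pair from the noisy CD45 channel
d <- simulate_pair_folds(1, "pic", fold = 2, seed = 90)
d[, c("fold_measured", "asymmetry", "class")]
#>   fold_measured  asymmetry class
#> 1      1.733249 0.09183548   pic

# the scaled group comparison: 93 interacting vs 16 overlap profiles
pic <- simulate_pair_folds(93, "pic", fold = 2, seed = 81)
ovl <- simulate_pair_folds(16, "overlap", seed = 82)
mann_whitney(pic$fold_measured, ovl$fold_measured)
#> Mann-Whitney U test (normal approximation)
#>   n1 = 93, n2 = 16, U = 1488.0, z = 6.370
#>   two-sided p = 1.94e-10, effect size r = 0.610 (rank-biserial -1.000)
```

The detection table reads: on this slide the CK threshold (mean + 6 SD over
all segmented cells) lands at ~19,400 intensity units; 8 cells exceed it —
4 epithelial (the standalone epi.CTCs plus the overlap- and gap-pair
partners) and 4 immune-like (the standalone im.CTCs plus the
interacting-pair partners) — and 503 of 504 WBCs are retained. The planted
fold-2 pair is recovered with a measured contact-interface fold of 1.73 and
classified `pic`; the 93-vs-16 group comparison separates interacting from
passive-overlap profiles at p ≈ 2×10⁻¹⁰ with effect size r ≈ 0.61.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that re-run the whole
study on synthetic material, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_slides.R    # slides + ground truth
Rscript analysis/02_detect_events.R      # detection + per-class precision/recall
Rscript analysis/03_neighbors_and_pics.R # neighbors, fold recovery, group test
Rscript analysis/04_phenotype.R          # clustering, gating, Fisher enrichment
Rscript analysis/05_cohort.R             # per-patient and cohort summaries
```

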