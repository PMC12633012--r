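# alveoniche

Analysis toolkit for single-nucleus and targeted spatial transcriptomics
of the early postnatal human lung, built around the two mutually
exclusive transcriptional states of alveolar type 2 (AT2) cells — a
lipid-metabolic state marked by *FMO5* and an inflammatory-responsive
state marked by *CFTR* — and their spatial pairing with distinct alveolar
fibroblast subtypes (AF-c1/2 vs the CCL2+ AF-c3).

It is intended for computational biologists who want a tested, seeded,
file-format-standard implementation of this analysis family:

* **QC + normalization** — feature/molecule/mito/ribo filters with the
  printed boundary semantics; `ln(1 + 10^4 · count/total)` normalization.
* **Markers and signatures** — Wilcoxon rank-sum marker detection with
  percent-expressed (≥ 25%) and |log2FC| (> 0.25) filters, Bonferroni over
  the gene universe; top-N signatures (50 for AT2 states, 100 for
  maturation sets).
* **Module scoring** — the binned-control method: each module gene is
  scored against 100 control genes drawn from its expression bin; the
  per-cell score is mean(module) − mean(pooled controls).
* **Specimen stratification + equal-weight composition** — specimens
  classed FMO5-enriched / CFTR-enriched / mixed by their AT2-state
  fraction; cells weighted `1/(G·N_g)` so each class contributes equally;
  rank-sum tests on per-specimen proportions.
* **Spatial niches** — k-means (K = 4) on each cell's k = 20
  nearest-neighbour label composition, per section; cross-section
  alignment by Pearson correlation of niche compositions with
  average-linkage clustering; Welch's t-test on composition with sections
  as replicates.
* **Colocalization statistics** — symmetric mean nearest-neighbor
  distance `d_sym(A,B) = (d(A→B) + d(B→A))/2` with one-way ANOVA + Tukey
  HSD; distance-band join counts `J = Σ_edges x_i x_j` over radii
  10–30 µm with analytic (random-labeling moments) and permutation nulls.
* **Maturation scoring** — per-type "on"/"off" gene sets from postnatal
  vs fetal contrasts; module scores benchmark developmental progress and
  expose arrested maturation.
* **Synthetic data** — a seeded generator for multi-specimen cohorts,
  staged fetal→postnatal series (with disease-arrest specimens) and
  multi-section spatial maps with known ground truth.

The methods vignette (`vignettes/alveoniche-methods.Rmd`) documents every
model, default and ambiguity resolution.

## Worked example

```r
library(alveoniche)

# simulate a cohort of 9 specimens in 3 AT2-state abundance classes
cohort <- generate_expression_cohort(cohort_config(seed = 1))
cohort <- apply_qc_filters(cohort)
norm   <- normalize_counts(cohort)

# AT2-state signatures from the AT2 cells
truth   <- cohort$truth$cells
at2     <- !is.na(truth$at2_state)
markers <- rank_markers(norm$values[, at2], truth$at2_state[at2],
                        "FMO5", "CFTR")
fmo5_sig <- build_signature(markers, 50, "up",   name = "FMO5")
cftr_sig <- build_signature(markers, 50, "down", name = "CFTR")
sum(grepl("^FMO5S", fmo5_sig$genes))
#> 50          # all 50 planted FMO5-state genes recovered in the top 50

# score-based state assignment and specimen classification
state  <- assign_at2_state(
  structure(list(values = norm$values[, at2]), class = "normalized_matrix"),
  fmo5_sig, cftr_sig, mode = "score", seed = 1)
groups <- classify_specimens_by_at2_state(
  data.frame(specimen = truth$specimen[at2],
             at2_state = sub("\\+$", "", state)))
table(groups$class)
#> CFTR_enriched FMO5_enriched         mixed
#>             3             3             3    # planted classes recovered

# spatial niches on a synthetic section
sp    <- generate_spatial_sections(spatial_config(n_sections = 2, seed = 1))
s1    <- sp$sections[[1]]
model <- fit_niches(neighborhood_profiles(s1, k = 20), K = 4, seed = 1)
adjusted_rand_index(model$assignment, s1$cells$region)
#> 0.905       # niches recover the planted anatomical regions

# colocalization: FMO5+ AT2 sits near AF-c1/2, far from AF-c3
symmetric_mean_nn_distance(s1, "AT2_FMO5", "AF_c1_2")$d_sym  #> 33.2 um
symmetric_mean_nn_distance(s1, "AT2_FMO5", "AF_c3")$d_sym    #> 61.1 um

# CFTR+ AT2 self-association by join counts (AT2-state cells only)
at2_map <- structure(list(section_id = "S01",
  cells = s1$cells[s1$cells$label %in% c("AT2_FMO5", "AT2_CFTR"), ],
  panel_counts = NULL), class = "spatial_map")
joincount_profile(at2_map, "AT2_CFTR", radii = c(15, 20, 25))
#>  radius J_obs       EJ        Z            p
#>      15    33 11.82987 7.368250 1.728821e-13
#>      20    53 24.34224 7.108475 1.173324e-12
#>      25    90 39.35707 9.546629 1.339857e-21
```

`J_obs` is the observed number of same-label neighbour pairs within the
radius, `EJ` its expectation under random labeling, and `Z`/`p` the
standardized deviate and two-sided p-value: CFTR+ AT2 cells self-associate
far beyond chance at every tested radius, as planted.

## Full pipeline and CLI

```r
report <- run_pipeline(default_pipeline_config(seed = 1), "out/")
```

or from the shell (config in YAML, every parameter optional):

```sh
Rscript inst/cli/alveoniche.R run --config cfg.yaml --out out/ --seed 1
```

Artifacts are standard formats (Matrix Market + TSV/CSV, GMT signatures,
JSON report) and are byte-identical across reruns with the same
config + seed.

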