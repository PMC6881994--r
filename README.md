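# papmeth

DNA methylation marker discovery and ovarian-cancer risk scoring from
Pap-test cervical scrapings.

Ovarian carcinoma is usually found late because early disease is nearly
symptomless and no accepted screening tool exists. Tumor cells and
cellular debris, however, reach the endocervical canal, so the DNA in a
routine cervical scraping carries a readable trace of the tumor's
methylome. `papmeth` implements the full computational pipeline for
turning that observation into a test:

* **Discovery** of highly differentially methylated (HDM) genes across
  three heterogeneous case/control methylome datasets — MBD-seq tissue
  read counts quantified in TSS ± 1000 bp promoter windows, 450K-style
  beta-value arrays with probe QC and promoter-level aggregation, and a
  pooled-scraping array screen — intersected at the gene level.
* **Candidate selection** by complete-linkage hierarchical clustering of
  the intersection and a top-10%-per-cluster rule.
* **Verification** of candidates in equal-mass 5-specimen DNA pools by
  qMSP, where the methylation readout is
  ΔCp = Cp(gene) − Cp(COL2A1) and lower ΔCp means more methylation.
* **Validation and risk modeling**: per-gene ROC analysis with
  closest-to-top-left cutoffs and 200-iteration stratified bootstrap
  intervals, and an **OC-risk score**
  ε + Σᵢ βᵢ·ΔCpᵢ fitted by logistic regression under 10-fold
  cross-validation repeated 200 times, frozen on the training set and
  applied to a held-out testing set. The published three-gene model
  (AMPD3, NRN1, TBX15; cutoff 0.73) ships frozen as
  `published_model()`.

A synthetic-cohort generator (`sim_params()`, `generate_*()`) builds
every pipeline input with planted markers and known ground truth, so the
whole pipeline is testable end to end without clinical data.

## Worked example

Scoring two specimens with the published risk equation:

```r
library(papmeth)
m <- published_model()
#> Ovarian-cancer risk model
#>   score = 6.38 + (-0.47) x dCp[AMPD3] + (-0.41) x dCp[NRN1] + (-0.57) x dCp[TBX15]
#>   cutoff: 0.73 (score >= cutoff classifies as OC)

dcp <- rbind(
  patient_A = c(AMPD3 = 2.0, NRN1 = 0.4, TBX15 = 4.9),
  patient_B = c(AMPD3 = 3.6, NRN1 = 4.2, TBX15 = 7.6)
)
risk_score(m, dcp)
#> patient_A patient_B
#>     2.483    -1.366
classify_risk(m, delta_cp = dcp)
#> patient_A patient_B
#>      "OC"  "normal"
```

Patient A's low ΔCp values (heavily methylated panel genes) put the
score well above the 0.73 cutoff; patient B's unmethylated profile lands
below it.

A full synthetic run — discovery over three study-scale cohorts
(50 vs 6 tissue, 79 vs 6 array, 3 vs 2 scraping pools; 500 genes, 10
planted markers), then validation on 31+31 / 21+21 qMSP cohorts:

```r
p   <- sim_params(seed = 7)
run <- run_discovery(
  generate_tissue_readset(p),
  generate_array_dataset(p, "case_control"),
  generate_array_dataset(p, "pooled")
)
length(run$intersection)        # 9 genes survive all three datasets
#> [1] 9                         # 9 of the 10 planted markers, 0 false positives

val <- run_validation(
  generate_qmsp_cohort(p, set = "training")$measurements,
  generate_qmsp_cohort(p, set = "testing")$measurements,
  panel = c("AMPD3", "NRN1", "TBX15"), seed = 7
)
val$roc_table[, c("gene_set", "cutoff", "train_auc", "test_sens", "test_spec", "test_auc")]
#>          gene_set cutoff train_auc test_sens test_spec test_auc
#>             AMPD3  4.100     0.704     0.857     0.429    0.687
#>              NRN1  0.882     0.857     0.476     1.000    0.961
#>             TBX15  6.172     0.906     0.905     0.762    0.923
#>  AMPD3+NRN1+TBX15 -0.199     0.956     1.000     0.952    0.998
```

Single genes trade sensitivity against specificity at their frozen
training cutoffs; the cross-validated three-gene combination dominates
both on the held-out testing set.

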