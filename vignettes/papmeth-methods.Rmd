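---
title: "Methods: marker discovery and risk scoring in papmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker discovery and risk scoring in papmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papmeth)
```

# The problem

Ovarian carcinoma sheds cells and cellular debris into the endocervical
canal, so DNA collected by a routine Pap-test cervical scraping carries a
trace of the tumor's epigenome. `papmeth` implements a complete pipeline
for exploiting that trace: discover genes hypermethylated specifically in
ovarian cancer across several methylome platforms, verify them cheaply in
pooled DNA by quantitative methylation-specific PCR (qMSP), and combine
the survivors into a logistic risk score that classifies a scraping as
cancer-suspicious or not.

The pipeline has four stages, each usable on its own:

1. **Discovery** across three case/control datasets — an MBD-seq tissue
   methylome, a 450K-style array tissue methylome, and a pooled-scraping
   array methylome — intersected at the gene level.
2. **Candidate selection** by hierarchical clustering of the
   intersection's methylation profiles and a top-10%-per-cluster rule.
3. **Verification** of candidates in equal-mass DNA pools by qMSP.
4. **Validation and risk modeling** on individually assayed training and
   testing cohorts.

# Discovery stage

## Tissue MBD-seq quantification

Methylated DNA captured by the methyl-CpG-binding domain protein and
sequenced gives read density proportional to methylation. For each
coding gene we count uniquely mapped read *starts* inside the promoter
window spanning 1000 bp upstream and downstream of the transcription
start site (2000 bp total), and divide by the sample's total mapped
reads. Coordinates are 0-based half-open throughout; a read start
exactly at the window end is outside. Genes on sex chromosomes and
non-NM (non-coding) RefSeq accessions are excluded. The read-in-window
rule uses the start position only: it is deterministic and independent
of read length, which the platform does not control tightly.

Raw per-sample fractions are of order $10^{-6}$, so a fixed
differential-methylation threshold stated on a $[0,1]$ scale cannot act
on them directly. `scale_levels()` therefore rescales each gene across
samples before calling; the default `per_gene_minmax` maps each gene's
range onto $[0,1]$ (a constant gene maps to all zeros), and a
rank-based alternative `(rank - 0.5)/n` is available. The scaling is
recorded in the result object: it is the one genuinely under-determined
step of this stage, and different choices change what the "HDM level"
threshold means.

A gene is called **highly differentially methylated (HDM)** when all of
the following hold, with the difference oriented so only
hypermethylation in cases can pass:

* two-sided Mann–Whitney $P < 0.01$;
* HDM level (case median minus control median of the scaled level)
  $> 0.2$;
* AUC $> 0.85$, where AUC is the probability that a random case
  outranks a random control.

The Mann–Whitney implementation uses the exact null distribution when
both groups have at most 8 observations and no ties, and the normal
approximation with continuity and tie correction otherwise; midranks
handle ties in both the test and the AUC.

## Array stages

For 450K-style beta matrices, probe QC removes probes failing detection
($P > 0.01$ in any sample by default; an all-samples rule is available),
probes with annotated SNPs (≥ 1 by default — retaining SNP-laden probes
contradicts standard array QC, so the count threshold is configurable
but exclusion is the default), non-NM genes, and sex chromosomes.

The case/control array stage calls HDM probes at median beta difference
$> 0.15$, Mann–Whitney $P < 0.05$, AUC $> 0.75$, and promotes a gene
when at least 3 of its promoter probes pass. The promoter region is the
same TSS ± 1000 bp window as the MBD-seq stage, keeping the gene-level
unit consistent across platforms.

The pooled-scraping stage has too few samples for hypothesis testing
(pools of 5 specimens, a handful per group), so a probe passes when the
mean case-pool beta exceeds the mean control-pool beta by more than
0.015, again with the ≥ 3 promoter-probe gene rule. Means rather than
medians are used here because equal-mass pooling itself is an averaging
operation.

## Intersection, clustering, selection

Genes passing all three stages form the intersection. Their tissue
methylation profiles (all samples, both groups — matching how such
heatmaps are drawn) are clustered by agglomerative hierarchical
clustering with complete linkage on Euclidean distance, cut to $k = 4$
clusters. Cluster labels are canonicalized by each cluster's
lexicographically smallest gene id, so row order cannot change the
result. Missing values are imputed by the gene median; a
row-standardization flag exists but the default clusters raw levels.

Within each cluster of more than 5 genes, the top
$\lceil 0.10 \times \text{size} \rceil$ genes by HDM level are marked
selected; smaller clusters keep everything. Ceiling rounding is used
because a 10% rule yielding 2–3 picks from clusters of a ~150-gene
intersection is only consistent with rounding up. Literature-novelty
triage is deliberately **not** automated: the candidate table carries
ranks, and the final shortlist is a human or configuration decision.

# Verification stage (pooled qMSP)

qMSP on bisulfite-converted DNA reports a crossing point Cp; the
methylation readout is
$\Delta C_p = C_p(\text{gene}) - C_p(\text{COL2A1})$, where the
unmethylated reference gene COL2A1 normalizes DNA input. Lower
$\Delta C_p$ means more methylated template. A reference Cp above 36
cycles marks absent template DNA and invalidates the measurement. An
undetected target with a valid reference is censored at
$\Delta C_p = 12$ cycles — above the largest group median seen in
practice — which preserves rank order without fabricating precision.
Duplicate reactions are averaged over their valid replicates.

A candidate passes pooled verification when its $\Delta C_p$ is lower in
carcinoma pools than in normal pools, in **at least one** tissue pool
and in **all** scraping pools. "Lower than the normal controls" is
judged against the minimum of the normal pools (the strictest reading;
a mean-of-normals option exists because the comparison baseline is not
uniquely determined). From the verified genes, up to two per cluster are
kept, ranked by the normal-minus-carcinoma pooled $\Delta C_p$ gap.
Assay instability (a gene whose qMSP chemistry misbehaves on individual
samples) is modeled as an input QC flag, not inferred.

# Validation and risk modeling

Training and testing cohorts are structurally separate inputs, and every
training-derived quantity — per-gene cutoffs, the AUC gate, the fitted
model and its cutoff — is frozen before the testing data are touched.
Perturbing the testing file provably leaves the fitted model
bit-identical (this is tested).

Per gene, both sets get group medians with stratified-bootstrap 95%
intervals and Mann–Whitney p-values. ROC cutoffs are chosen by the
closest-to-top-left criterion, minimizing
$(1-\text{sensitivity})^2 + (1-\text{specificity})^2$ over midpoint
thresholds, ties resolved toward higher sensitivity and then the lower
cutoff. For $\Delta C_p$ the disease-positive side is *below* the
cutoff; the direction convention is explicit in every function signature
because a silent sign flip would invert every ROC. Confidence intervals
use 200 stratified bootstrap iterations (resampling within class keeps
both classes present; plain resampling could produce degenerate
replicates at these sample sizes).

Genes exceeding a training AUC of 0.7 enter the combination model. The
**OC-risk score** is
$\varepsilon + \sum_i \beta_i \, \Delta C_{p,i}$
over the panel genes, fitted by logistic regression with stratified
10-fold cross-validation repeated 200 times: each training fold
contributes one maximum-likelihood fit, and the final coefficients are
the mean over all 2000 fits (the median is stored alongside; the mean is
the default because neither aggregate is canonically superior and the
mean has the smaller Monte-Carlo error). Fits that separate fall back to
a ridge penalty of $10^{-6}$ and are counted in the model's provenance.
The classification cutoff of a fitted model is closest-to-top-left on
its in-sample scores; a score at or above the cutoff classifies as
carcinoma (the boundary counts as positive — arbitrary, but fixed and
tested). The published model
$(-0.47)\,\Delta C_p(\text{AMPD3}) + (-0.41)\,\Delta C_p(\text{NRN1})
+ (-0.57)\,\Delta C_p(\text{TBX15}) + 6.38$, cutoff $0.73$, is
available frozen via `published_model()`; its intercept is treated as a
fitted intercept like any other, even though intercepts of such scores
are sometimes described as nuisance terms expected to vanish.

## Sample-size planning

`auc_sample_size()` solves the smallest per-group $n$ with
$z_{1-\alpha/2}\sqrt{V(\theta_0,n)} + z_{\text{power}}\sqrt{V(\theta_1,n)}
\le \theta_1 - \theta_0$ under the Hanley–McNeil variance
$V(\theta, n) = [\theta(1-\theta) + (n-1)(Q_1-\theta^2) +
(nr-1)(Q_2-\theta^2)]/(n^2 r)$, $Q_1 = \theta/(2-\theta)$,
$Q_2 = 2\theta^2/(1+\theta)$. At $\theta_1 = 0.75$ versus
$\theta_0 = 0.5$ with $\alpha = 0.05$, power 0.8 and a 1:1 ratio this
gives $n = 20$ per group. Planning tools built on other variance
approximations give 19 for the same inputs; `plan_study()` therefore
takes the base $n$ as an argument and derives enrolled sizes as
test $= n + 2$ and train $= \text{round-half-up}(1.5 n) + 2$ per group
(base 19 yields the familiar 62 training + 42 testing enrollment).
Both values of $n$ are honest answers; the discrepancy is documented
rather than resolved by guessing which variance formula the original
calculator used.

# The synthetic cohort generator

No clinical data ship with the package; `sim_params()` and the
`generate_*` functions build all pipeline inputs with known ground
truth. The generator's central design choice is a **shared latent
methylation fraction** per gene: marker genes get their latent
methylation raised by a per-dataset effect size in the case group, and
every platform observes the same latent variable through its own noise
channel. This mirrors the biological premise that the same genes are
hypermethylated in tumor tissue and in tumor-derived material in
scrapings, and it is what makes the cross-dataset intersection a
meaningful recovery target.

Defaults reproduce the cohort shape the pipeline targets: 500 genes with 10 planted markers;
50 vs 6 tissue MBD-seq samples at effect 0.3; 79 vs 6 array samples at
effect 0.2; 3 carcinoma vs 2 normal scraping pools (5 specimens each)
at effect 0.05; 31+31 training and 21+21 testing qMSP cohorts. Baseline
gene methylation is uniform on 0.1–0.4 with per-sample jitter of 0.02.

Channel models, chosen once as field-plausible since no distributional
model is prescribed by the design:

* **MBD-seq**: the read count in a gene's promoter window is Poisson
  with mean `total_reads × window_rate × latent` (window rate 5 × 10⁻⁵
  per unit methylation; depth 10⁶ with ±10% per-sample variation), and
  read starts are uniform within the window. Only promoter-proximal
  reads are materialized — reads elsewhere in the genome never touch a
  TSS window — while the total mapped reads used for normalization are
  carried as per-sample metadata.
* **Array**: probe betas are Beta-distributed around the latent fraction
  with concentration 300 (sd ≈ 0.02 at beta 0.2, the tight end of what
  such arrays deliver); each gene gets 4 + Poisson(2) probes, 10% of
  probes sit outside the promoter, 2% carry SNP annotations, 0.5% fail
  detection in one sample, and sex-chromosome/non-coding decoy genes are
  present so QC always has work to do.
* **Pooling**: a pool's latent methylation is the arithmetic mean of its
  members' fractions (equal DNA mass mixes fractions linearly), while Cp
  values pool as $-\log_2(\text{mean}(2^{-C_p}))$, because equal-mass
  mixing averages template quantities, which are exponential in Cp.
* **qMSP**: the target Cp decreases linearly in latent methylation at 5
  cycles per unit — qPCR template-doubling arithmetic, spanning the
  0–8 cycle range of observed group medians — with 1.5 cycles of
  per-sample noise, 0.15 cycles of replicate noise, and a reference Cp
  around 28 ± 0.25 cycles. Per-gene baselines are solved from target
  group medians (the published per-gene medians by default), so
  realized cohorts land on the published $\Delta C_p$ scale. 2% of
  samples get a failed reference (Cp > 36) to exercise validity QC.

What the generator does **not** emulate: bisulfite chemistry, probe
hybridization physics, batch and plate effects, inter-gene correlation
beyond the shared latent variable, age or histology dependence of
methylation, and assay-instability failure modes. Tests passing on this
generator demonstrate that the pipeline's logic is correct and
well-calibrated under its stated model — not that the clinical
performance figures would reproduce on new specimens.

# Problem sizes and numerical choices

The test suite and the acceptance script run discovery at 500 genes
over 5–10 generator seeds, validation CV at 10 folds × 200 replications
over up to 50 seeds, and oracle comparisons (pair-counting AUC,
exhaustive cutoff scans, exact rank-sum enumeration) over 1000 random
instances — sizes at which every stochastic check is stable while the
whole suite completes in minutes on one core. Degenerate inputs are
handled explicitly rather than by crash: empty groups error, constant
genes scale to zero, all-missing probes are dropped with a warning,
one-class cohorts flag the undefined metric as `NA`, windows clamp at
coordinate zero with a warning, and separation in logistic fits falls
back to the tiny ridge.

# Known limitations

* The scaled "HDM level" threshold for MBD-seq is only meaningful
  relative to the chosen scaling; results report the scaling mode.
* The pooled-scraping stage has no error control (by design — it is a
  screen), so its gene set is the noisiest of the three; the
  intersection is what controls false positives.
* The risk model assumes complete-case gene panels; specimens with an
  invalid reference for any panel gene are excluded from combination
  scoring rather than imputed.
* Bootstrap percentile intervals at n ≈ 20 per group are approximate;
  exact binomial intervals for sensitivity/specificity at a fixed
  cutoff would be a straightforward extension.
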