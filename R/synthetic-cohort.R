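#' Simulation parameters for the synthetic three-dataset study
#'
#' Bundles and validates every knob of the synthetic-cohort generators.
#' The defaults reproduce the cohort shape the pipeline targets: a tissue
#' MBD-seq cohort of 50 ovarian carcinomas vs 6 normal ovarian
#' epithelia, a public 450K-style tissue cohort of 79 carcinomas vs 6
#' normal tubal epithelia, a pooled cervical-scraping 450K stage of 3
#' carcinoma pools vs 2 normal pools (5 specimens per pool), and qMSP
#' validation cohorts of 31+31 (training) and 21+21 (testing)
#' scrapings. A shared latent methylation fraction per gene drives all
#' platforms, so markers planted once are recoverable in every dataset.
#'
#' @param n_genes Number of genes in the universe (default 500),
#'   including `n_sex_genes` on chrX/chrY and `n_non_nm` with non-coding
#'   accessions to exercise annotation QC.
#' @param n_markers Number of planted hypermethylated marker genes
#'   (default 10); markers are always autosomal NM genes.
#' @param n_sex_genes,n_non_nm Decoy genes removed by QC (defaults 10
#'   each).
#' @param tissue,array,pooled,qmsp Per-dataset settings; any supplied
#'   element overrides the default (see Details).
#' @param probes_per_gene List `min`, `lambda`: probes per gene are
#'   `min + rpois(lambda)` (defaults 4 and 2).
#' @param base_meth_range Range of per-gene baseline methylation
#'   fractions (default 0.1-0.4).
#' @param latent_sd Per-sample jitter of the latent methylation fraction
#'   (default 0.02).
#' @param snp_frac Fraction of probes carrying annotated SNPs (default
#'   0.02).
#' @param detp_fail_frac Fraction of probes with a failed detection
#'   p-value in one sample (default 0.005).
#' @param off_promoter_frac Fraction of probes placed outside the
#'   promoter window (default 0.1).
#' @param seed Integer seed; the gene universe and every generator are
#'   deterministic given the seed.
#'
#' @details Dataset settings and defaults: `tissue` has `n_case` 50,
#' `n_control` 6, `effect` 0.3 (beta-scale shift of the marker latent),
#' `read_depth` 1e6 total mapped reads, `window_rate` 5e-5 (expected
#' in-window read fraction per unit methylation); `array` has `n_case`
#' 79, `n_control` 6, `effect` 0.2, `concentration` 300 (Beta
#' distribution precision of probe measurements); `pooled` has
#' `n_case_pools` 3, `n_control_pools` 2, `pool_size` 5, `effect` 0.05,
#' `concentration` 300; `qmsp` has `cp_slope` 5 cycles per unit
#' methylated fraction, `cp_noise_sd` 1.5 cycles, `ref_cp_mean` 28
#' cycles, `ref_sd` 0.25, `replicate_sd` 0.15, `ref_fail_frac` 0.02
#' (samples with absent template, reference Cp > 36), `n_train`
#' c(31, 31) and `n_test` c(21, 21) as case/control sizes.
#'
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 500L, n_markers = 10L,
                       n_sex_genes = 10L, n_non_nm = 10L,
                       tissue = list(), array = list(), pooled = list(),
                       qmsp = list(),
                       probes_per_gene = list(min = 4L, lambda = 2),
                       base_meth_range = c(0.1, 0.4),
                       latent_sd = 0.02,
                       snp_frac = 0.02, detp_fail_frac = 0.005,
                       off_promoter_frac = 0.1,
                       seed = 1L) {
  merge_defaults <- function(user, def) {
    def[names(user)] <- user
    def
  }
  p <- list(
    n_genes = as.integer(n_genes), n_markers = as.integer(n_markers),
    n_sex_genes = as.integer(n_sex_genes), n_non_nm = as.integer(n_non_nm),
    tissue = merge_defaults(tissue, list(
      n_case = 50L, n_control = 6L, effect = 0.3,
      read_depth = 1e6, window_rate = 5e-5
    )),
    array = merge_defaults(array, list(
      n_case = 79L, n_control = 6L, effect = 0.2, concentration = 300
    )),
    pooled = merge_defaults(pooled, list(
      n_case_pools = 3L, n_control_pools = 2L, pool_size = 5L,
      effect = 0.05, concentration = 300
    )),
    qmsp = merge_defaults(qmsp, list(
      n_train = c(case = 31L, control = 31L),
      n_test = c(case = 21L, control = 21L),
      cp_slope = 5, cp_noise_sd = 1.5, ref_cp_mean = 28,
      ref_sd = 0.25, replicate_sd = 0.15, ref_fail_frac = 0.02
    )),
    probes_per_gene = probes_per_gene,
    base_meth_range = base_meth_range,
    latent_sd = latent_sd,
    snp_frac = snp_frac, detp_fail_frac = detp_fail_frac,
    off_promoter_frac = off_promoter_frac,
    seed = as.integer(seed)
  )
  effects <- c(p$tissue$effect, p$array$effect, p$pooled$effect)
  if (any(effects < 0 | effects >= 1)) stop("effect sizes must lie in [0, 1)")
  sizes <- c(
    p$tissue$n_case, p$tissue$n_control, p$array$n_case, p$array$n_control,
    p$pooled$n_case_pools, p$pooled$n_control_pools, p$pooled$pool_size,
    p$qmsp$n_train, p$qmsp$n_test
  )
  if (any(sizes < 1)) stop("all group sizes must be >= 1")
  if (p$qmsp$cp_slope <= 0) stop("cp_slope must be > 0")
  if (p$tissue$read_depth <= 0) stop("read_depth must be > 0")
  if (p$n_markers + p$n_sex_genes + p$n_non_nm > p$n_genes) {
    stop("n_genes too small for the requested marker/decoy counts")
  }
  class(p) <- "sim_params"
  p
}

# Deterministic gene universe shared by all generators: ids, genomic
# placement, accession type, per-gene baseline methylation, marker flag.
.gene_universe <- function(params) {
  set.seed(params$seed)
  n <- params$n_genes
  gene_id <- sprintf("G%04d", seq_len(n))
  chrom <- rep(paste0("chr", 1:22), length.out = n)
  accession <- sprintf("NM_%06d", seq_len(n))
  # decoys at the tail: sex-chromosome genes, then non-coding accessions
  if (params$n_sex_genes > 0L) {
    idx <- (n - params$n_sex_genes + 1L):n
    chrom[idx] <- rep(c("chrX", "chrY"), length.out = params$n_sex_genes)
  }
  if (params$n_non_nm > 0L) {
    idx <- (n - params$n_sex_genes - params$n_non_nm + 1L):(n - params$n_sex_genes)
    accession[idx] <- sprintf("NR_%06d", idx)
  }
  tss <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    tss[i] <- 100000L + (seq_along(i) - 1L) * 10000L
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  base_meth <- stats::runif(n, params$base_meth_range[1], params$base_meth_range[2])
  is_marker <- rep(FALSE, n)
  is_marker[seq_len(params$n_markers)] <- TRUE
  data.frame(
    gene_id = gene_id, chrom = chrom, tss = tss, strand = strand,
    accession = accession, base_meth = base_meth, is_marker = is_marker,
    stringsAsFactors = FALSE
  )
}

# Latent methylation fractions, genes x samples. Markers get +effect in
# the case group; every sample adds a small jitter.
.latent_matrix <- function(universe, n_case, n_control, effect, latent_sd,
                           sample_names) {
  n_genes <- nrow(universe)
  n <- n_case + n_control
  shift <- outer(
    ifelse(universe$is_marker, effect, 0),
    c(rep(1, n_case), rep(0, n_control))
  )
  lat <- universe$base_meth + shift +
    matrix(stats::rnorm(n_genes * n, sd = latent_sd), n_genes, n)
  lat <- pmin(pmax(lat, 0.01), 0.99)
  dimnames(lat) <- list(universe$gene_id, sample_names)
  lat
}

#' Generate a synthetic MBD-seq tissue cohort
#'
#' Emulates the tissue discovery stage: per sample, the read count
#' inside each gene's promoter window is Poisson with mean
#' `total_reads x window_rate x latent methylation`, and read start
#' coordinates are placed uniformly within the window (only
#' promoter-proximal reads are materialized; the per-sample total mapped
#' reads are carried as metadata). Marker genes have their latent
#' methylation elevated by the tissue effect size in the case group.
#'
#' @param params A [sim_params()] object.
#' @return List with `reads` (named list of per-sample data frames with
#'   `chrom`, `start` in 0-based coordinates), `annotation` (gene TSS
#'   table), `totals` (total mapped reads per sample), `labels`
#'   (`"OC"`/`"normal"`), and `truth` (marker set, effect size, latent
#'   methylation matrix).
#' @export
generate_tissue_readset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  universe <- .gene_universe(params)
  set.seed(params$seed + 101L)
  ts <- params$tissue
  samples <- c(
    sprintf("T_OC%02d", seq_len(ts$n_case)),
    sprintf("T_N%02d", seq_len(ts$n_control))
  )
  labels <- c(rep("OC", ts$n_case), rep("normal", ts$n_control))
  totals <- stats::setNames(
    round(ts$read_depth * stats::runif(length(samples), 0.9, 1.1)), samples
  )
  latent <- .latent_matrix(universe, ts$n_case, ts$n_control, ts$effect,
                           params$latent_sd, samples)
  win_start <- universe$tss - 1000L # symmetric span on both strands
  reads <- lapply(samples, function(s) {
    counts <- stats::rpois(nrow(universe), totals[s] * ts$window_rate * latent[, s])
    gene_idx <- rep.int(seq_len(nrow(universe)), counts)
    start <- win_start[gene_idx] + floor(stats::runif(length(gene_idx)) * 2000)
    df <- data.frame(
      chrom = universe$chrom[gene_idx], start = as.integer(start),
      stringsAsFactors = FALSE
    )
    df[order(df$chrom, df$start), , drop = FALSE]
  })
  names(reads) <- samples
  list(
    reads = reads,
    annotation = universe[, c("gene_id", "chrom", "tss", "strand", "accession")],
    totals = totals,
    labels = labels,
    truth = list(
      marker_genes = universe$gene_id[universe$is_marker],
      effect = ts$effect, latent = latent
    )
  )
}

# Probe manifest for the array platforms: >= `min` promoter probes per
# gene, a fraction placed off-promoter, SNP annotations on a fraction.
.probe_manifest <- function(params, universe) {
  k <- params$probes_per_gene$min +
    stats::rpois(nrow(universe), params$probes_per_gene$lambda)
  gene_idx <- rep.int(seq_len(nrow(universe)), k)
  n_probes <- length(gene_idx)
  off <- stats::runif(n_probes) < params$off_promoter_frac
  offset <- ifelse(off,
    3000L + sample.int(2000L, n_probes, replace = TRUE),
    sample.int(1999L, n_probes, replace = TRUE) - 1000L
  )
  n_snp <- ifelse(stats::runif(n_probes) < params$snp_frac,
                  sample(1:2, n_probes, replace = TRUE), 0L)
  data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chrom = universe$chrom[gene_idx],
    position = universe$tss[gene_idx] + offset,
    closest_gene = universe$gene_id[gene_idx],
    distance_to_tss = abs(offset),
    in_promoter = !off,
    n_snp = as.integer(n_snp),
    accession = universe$accession[gene_idx],
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic 450K-style beta-value dataset
#'
#' Emulates either the case/control array tissue stage
#' (`design = "case_control"`, 79 vs 6 by default) or the
#' pooled-scraping stage (`design = "pooled"`, 3 carcinoma pools vs 2
#' normal pools of 5 specimens each). Every gene gets at least
#' `probes_per_gene$min` promoter probes; probe betas follow a Beta
#' distribution centered on the sample's (or pool's) latent methylation;
#' a configurable fraction of probes carry SNP annotations or a failed
#' detection p-value, and sex-chromosome genes are present, so that
#' probe QC has something to remove.
#'
#' @param params A [sim_params()] object.
#' @param design `"case_control"` or `"pooled"`.
#' @return List with `probes` (manifest), `betas` (probes x samples),
#'   `detection_p` (same shape), `labels`, and `truth` (markers, effect,
#'   latent matrix; for pools also the specimen-to-pool map).
#' @export
generate_array_dataset <- function(params, design = c("case_control", "pooled")) {
  stopifnot(inherits(params, "sim_params"))
  design <- match.arg(design)
  universe <- .gene_universe(params)
  set.seed(params$seed + if (design == "case_control") 202L else 303L)
  probes <- .probe_manifest(params, universe)

  if (design == "case_control") {
    ar <- params$array
    samples <- c(
      sprintf("A_OC%02d", seq_len(ar$n_case)),
      sprintf("A_N%02d", seq_len(ar$n_control))
    )
    labels <- c(rep("OC", ar$n_case), rep("normal", ar$n_control))
    latent <- .latent_matrix(universe, ar$n_case, ar$n_control, ar$effect,
                             params$latent_sd, samples)
    conc <- ar$concentration
    truth_extra <- NULL
  } else {
    po <- params$pooled
    n_pools <- po$n_case_pools + po$n_control_pools
    n_spec <- n_pools * po$pool_size
    spec_names <- sprintf("S%03d", seq_len(n_spec))
    n_case_spec <- po$n_case_pools * po$pool_size
    spec_latent <- .latent_matrix(universe, n_case_spec,
                                  n_spec - n_case_spec, po$effect,
                                  params$latent_sd, spec_names)
    samples <- c(
      sprintf("P_OC%d", seq_len(po$n_case_pools)),
      sprintf("P_N%d", seq_len(po$n_control_pools))
    )
    labels <- c(rep("OC", po$n_case_pools), rep("normal", po$n_control_pools))
    pool_of <- rep(samples, each = po$pool_size)
    # equal-mass DNA mixing averages the member methylation fractions
    latent <- vapply(samples, function(pl) {
      rowMeans(spec_latent[, pool_of == pl, drop = FALSE])
    }, numeric(nrow(universe)))
    conc <- po$concentration
    truth_extra <- stats::setNames(pool_of, spec_names)
  }

  gene_idx <- match(probes$closest_gene, universe$gene_id)
  mu <- latent[gene_idx, , drop = FALSE]
  betas <- matrix(
    stats::rbeta(length(mu), c(mu) * conc, (1 - c(mu)) * conc),
    nrow = nrow(mu),
    dimnames = list(probes$probe_id, colnames(latent))
  )
  detection_p <- matrix(
    stats::runif(length(betas), 0, 0.005),
    nrow = nrow(betas), dimnames = dimnames(betas)
  )
  fail <- which(stats::runif(nrow(betas)) < params$detp_fail_frac)
  if (length(fail) > 0L) {
    cols <- sample.int(ncol(betas), length(fail), replace = TRUE)
    detection_p[cbind(fail, cols)] <- stats::runif(length(fail), 0.02, 0.2)
  }
  truth <- list(
    marker_genes = universe$gene_id[universe$is_marker],
    effect = if (design == "case_control") params$array$effect else params$pooled$effect,
    latent = latent
  )
  if (!is.null(truth_extra)) truth$pool_membership <- truth_extra
  list(
    probes = probes, betas = betas, detection_p = detection_p,
    labels = labels, truth = truth
  )
}

#' Pool specimen-level measurements into one pooled value
#'
#' Equal-quantity mixing of 5-specimen DNA pools. On the beta
#' (methylation fraction) scale, mixing equal DNA masses averages the
#' fractions arithmetically. On the Cp scale, equal-mass mixing averages
#' template quantities, which are exponential in Cp, so the pooled value
#' is `-log2(mean(2^-Cp_i))`.
#'
#' @param member_values Numeric vector of member methylation fractions
#'   or Cp values (nonempty).
#' @param mode `"beta"` or `"cp"`.
#' @return The pooled value (always between the member extremes).
#' @examples
#' pool_specimens(c(0.2, 0.4), "beta") # 0.3
#' pool_specimens(c(30, 32), "cp")     # ~30.678
#' @export
pool_specimens <- function(member_values, mode = c("beta", "cp")) {
  mode <- match.arg(mode)
  if (length(member_values) == 0L) stop("need at least one member")
  switch(mode,
    beta = mean(member_values),
    cp = -log2(mean(2^(-member_values)))
  )
}

#' Published per-gene delta-Cp group medians
#'
#' The group medians (cycles) of the five validated candidate genes in
#' the training and testing cervical-scraping cohorts, used as
#' calibration targets by [generate_qmsp_cohort()] so that synthetic
#' group medians land on the reported scale. `MEGF11` was not carried
#' into the testing set.
#'
#' @return Data frame with columns `gene`, `set`
#'   (`"training"`/`"testing"`), `group` (`"OC"`/`"normal"`), `median`.
#' @export
published_delta_cp_medians <- function() {
  data.frame(
    gene = rep(c("AMPD3", "AOX1", "MEGF11", "NRN1", "TBX15",
                 "AMPD3", "AOX1", "NRN1", "TBX15"), each = 2L),
    set = rep(c("training", "testing"), c(10L, 8L)),
    group = rep(c("normal", "OC"), 9L),
    median = c(
      3.8, 2.7, 2.0, 1.0, 5.8, 4.4, 2.3, 0.1, 7.6, 5.1, # training
      3.6, 2.0, 2.8, 0.9, 4.2, 0.4, 7.6, 4.9            # testing
    ),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic qMSP validation cohort
#'
#' Produces duplicate Cp measurements per sample and panel gene, with
#' case/control labels and clinical covariates. The target gene's Cp
#' decreases linearly with the latent methylated fraction
#' (`cp_slope` cycles per unit), per-gene baselines are chosen so the
#' group delta-Cp medians land on the supplied targets (published group
#' medians by default), the COL2A1 reference Cp is drawn around
#' `ref_cp_mean`, and a configurable fraction of samples has absent
#' template DNA (reference Cp > 36) to exercise QC.
#'
#' @param params A [sim_params()] object.
#' @param gene_panel Character vector of panel genes (nonempty).
#' @param set `"training"` or `"testing"` (chooses cohort size and
#'   default targets).
#' @param target_medians Optional data frame `gene`, `group`
#'   (`"OC"`/`"normal"`), `median` overriding the published targets.
#' @param seed_offset Internal offset added to `params$seed` so the
#'   training and testing cohorts are independent draws.
#' @return List with `measurements` (long data frame: `sample_id`,
#'   `group`, `gene`, `replicate`, `cp_gene`, `cp_ref`), `covariates`
#'   (age, FIGO stage, grading, histology per sample), and `truth`
#'   (per-gene generating effects in cycles, latent matrix, QC-failed
#'   samples).
#' @export
generate_qmsp_cohort <- function(params, gene_panel = c("AMPD3", "NRN1", "TBX15"),
                                 set = c("training", "testing"),
                                 target_medians = NULL,
                                 seed_offset = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set <- match.arg(set)
  if (length(gene_panel) == 0L) stop("gene_panel must be nonempty")
  q <- params$qmsp
  if (is.null(target_medians)) {
    pm <- published_delta_cp_medians()
    target_medians <- pm[pm$set == set & pm$gene %in% gene_panel,
                         c("gene", "group", "median")]
  }
  missing_tm <- setdiff(gene_panel, target_medians$gene)
  if (length(missing_tm) > 0L) {
    stop("no target medians for gene(s): ", paste(missing_tm, collapse = ", "))
  }
  if (is.null(seed_offset)) seed_offset <- if (set == "training") 404L else 505L
  set.seed(params$seed + seed_offset)

  sizes <- if (set == "training") q$n_train else q$n_test
  tag <- if (set == "training") "TR" else "TE"
  samples <- c(
    sprintf("Q_%s_OC%02d", tag, seq_len(sizes[["case"]])),
    sprintf("Q_%s_N%02d", tag, seq_len(sizes[["control"]]))
  )
  group <- c(rep("OC", sizes[["case"]]), rep("normal", sizes[["control"]]))
  n <- length(samples)

  tm <- function(g, grp) {
    target_medians$median[target_medians$gene == g & target_medians$group == grp]
  }
  base_latent <- 0.2
  failed <- stats::runif(n) < q$ref_fail_frac
  rows <- list()
  latent_all <- matrix(NA_real_, nrow = length(gene_panel), ncol = n,
                       dimnames = list(gene_panel, samples))
  for (g in gene_panel) {
    med_n <- tm(g, "normal")
    med_oc <- tm(g, "OC")
    effect_frac <- (med_n - med_oc) / q$cp_slope
    baseline <- med_n + q$cp_slope * base_latent
    latent <- pmin(pmax(
      base_latent + effect_frac * (group == "OC") +
        stats::rnorm(n, sd = params$latent_sd), 0
    ), 1)
    latent_all[g, ] <- latent
    sample_noise <- stats::rnorm(n, sd = q$cp_noise_sd)
    for (rep_i in 1:2) {
      cp_gene <- q$ref_cp_mean + baseline - q$cp_slope * latent +
        sample_noise + stats::rnorm(n, sd = q$replicate_sd)
      cp_ref <- stats::rnorm(n, q$ref_cp_mean, q$ref_sd)
      cp_ref[failed] <- stats::runif(sum(failed), 36.5, 40)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples, group = group, gene = g, replicate = rep_i,
        cp_gene = cp_gene, cp_ref = cp_ref, stringsAsFactors = FALSE
      )
    }
  }
  measurements <- do.call(rbind, rows)
  measurements <- measurements[order(measurements$sample_id, measurements$gene,
                                     measurements$replicate), , drop = FALSE]
  rownames(measurements) <- NULL

  is_oc <- group == "OC"
  covariates <- data.frame(
    sample_id = samples, group = group,
    age = round(stats::rnorm(n, mean = ifelse(is_oc, 52, 43), sd = 13)),
    figo_stage = ifelse(is_oc,
      sample(c("I", "II", "III", "IV"), n, replace = TRUE,
             prob = c(0.35, 0.13, 0.4, 0.12)), NA),
    grading = ifelse(is_oc,
      sample(c("G1", "G2", "G3"), n, replace = TRUE, prob = c(0.15, 0.15, 0.7)),
      NA),
    histology = ifelse(is_oc,
      sample(c("Ser", "En", "Mu", "CC"), n, replace = TRUE,
             prob = c(0.55, 0.08, 0.17, 0.2)), NA),
    stringsAsFactors = FALSE
  )
  effects <- vapply(gene_panel, function(g) tm(g, "normal") - tm(g, "OC"),
                    numeric(1))
  list(
    measurements = measurements,
    covariates = covariates,
    truth = list(
      gene_panel = gene_panel,
      effect_cycles = effects,
      target_medians = target_medians,
      latent = latent_all,
      ref_failed_samples = samples[failed]
    )
  )
}

#' Generate delta-Cp data from an explicit logistic model
#'
#' For parameter-recovery checks: draws per-gene delta-Cp covariates
#' from independent normals and labels from
#' `Bernoulli(plogis(epsilon + X beta))`, so the generating coefficients
#' are known exactly.
#'
#' @param beta Named numeric vector of generating coefficients (score
#'   per cycle).
#' @param epsilon Generating intercept.
#' @param n Number of samples.
#' @param dcp_mean,dcp_sd Mean and sd of each gene's delta-Cp covariate
#'   (recycled across genes).
#' @param seed Optional integer seed.
#' @return List with `delta_cp` (n x genes matrix), `labels` (logical,
#'   TRUE = case), `beta`, `epsilon`.
#' @export
generate_logistic_cohort <- function(beta, epsilon, n, dcp_mean = 3,
                                     dcp_sd = 1.5, seed = NULL) {
  if (is.null(names(beta))) stop("beta must be named by gene")
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta)
  dcp_mean <- rep_len(dcp_mean, p)
  dcp_sd <- rep_len(dcp_sd, p)
  x <- vapply(seq_len(p), function(j) stats::rnorm(n, dcp_mean[j], dcp_sd[j]),
              numeric(n))
  colnames(x) <- names(beta)
  prob <- stats::plogis(epsilon + drop(x %*% beta))
  list(
    delta_cp = x,
    labels = stats::runif(n) < prob,
    beta = beta, epsilon = epsilon
  )
}
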