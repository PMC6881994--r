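#' Default thresholds of the discovery pipeline
#'
#' Per-dataset criteria for calling highly differentially methylated
#' features: the tissue MBD-seq stage (Mann-Whitney p < 0.01, HDM level
#' > 0.2 on the scaled \[0, 1\] level, AUC > 0.85), the case/control
#' array stage (probe beta difference > 0.15, p < 0.05, AUC > 0.75,
#' >= 3 passing promoter probes), and the pooled-scraping stage (probe
#' mean difference > 0.015, >= 3 passing promoter probes).
#'
#' @return Nested list of thresholds, suitable for the `thresholds`
#'   argument of [run_discovery()].
#' @export
discovery_thresholds <- function() {
  list(
    tissue = list(hdm_min = 0.2, p_max = 0.01, auc_min = 0.85),
    array = list(delta_min = 0.15, p_max = 0.05, auc_min = 0.75, min_probes = 3L),
    pooled = list(delta_min = 0.015, min_probes = 3L)
  )
}

#' Run the three-dataset marker discovery stage
#'
#' Executes the full discovery flow: promoter-window quantification and
#' HDM-gene calling on the tissue MBD-seq cohort; probe QC, HDM-probe
#' calling and promoter aggregation on the case/control array cohort;
#' the no-test pooled rule on the pooled-scraping cohort; intersection
#' of the three gene sets; complete-linkage hierarchical clustering of
#' the intersection's tissue methylation profiles; and top-fraction
#' candidate selection per cluster. The stage is fully deterministic in
#' its inputs (no random numbers are drawn).
#'
#' @param tissue List with `reads`, `annotation`, `totals`, `labels`
#'   (as produced by [generate_tissue_readset()]).
#' @param array450k List with `probes`, `betas`, `detection_p`, `labels`
#'   (as produced by [generate_array_dataset()]).
#' @param pooled List with `probes`, `betas`, `detection_p`, `labels`
#'   (pooled design).
#' @param thresholds Nested threshold list (default
#'   [discovery_thresholds()]); partial overrides are merged over the
#'   defaults.
#' @param scaling Scaling of tissue window levels (default
#'   `"per_gene_minmax"`; see [scale_levels()]).
#' @param k Number of clusters (default 4; reduced with a warning when
#'   the intersection is smaller).
#' @param fraction,min_cluster_to_apply Candidate selection rule (see
#'   [select_top_candidates()]).
#' @return An object of class `discovery_run`: list with `gene_sets`
#'   (per dataset), `intersection`, `tissue_results`, `probe_results`,
#'   `clusters`, `candidates`, and the `thresholds` used.
#' @export
run_discovery <- function(tissue, array450k, pooled,
                          thresholds = discovery_thresholds(),
                          scaling = "per_gene_minmax", k = 4L,
                          fraction = 0.10, min_cluster_to_apply = 5L) {
  def <- discovery_thresholds()
  for (nm in names(def)) {
    if (!is.null(thresholds[[nm]])) def[[nm]][names(thresholds[[nm]])] <- thresholds[[nm]]
  }
  thresholds <- def

  # tissue MBD-seq stage
  windows <- make_tss_windows(tissue$annotation)
  wm <- quantify_windows(tissue$reads, windows, tissue$totals)
  scaled <- scale_levels(wm, method = scaling)
  tissue_results <- call_hdm_genes(
    scaled, tissue$labels,
    hdm_min = thresholds$tissue$hdm_min,
    p_max = thresholds$tissue$p_max,
    auc_min = thresholds$tissue$auc_min
  )
  set_tissue <- sort(tissue_results$gene[tissue_results$pass])

  # case/control array stage
  qc_a <- qc_filter_probes(array450k$probes, array450k$betas,
                           array450k$detection_p)
  probe_results <- call_hdm_probes(
    qc_a$betas, array450k$labels,
    delta_min = thresholds$array$delta_min,
    p_max = thresholds$array$p_max,
    auc_min = thresholds$array$auc_min
  )
  set_array <- aggregate_promoter(probe_results, qc_a$probes,
                                  min_probes = thresholds$array$min_probes)

  # pooled-scraping stage
  qc_p <- qc_filter_probes(pooled$probes, pooled$betas, pooled$detection_p)
  set_pooled <- call_pooled_hdm(
    qc_p$betas, pooled$labels, qc_p$probes,
    delta_min = thresholds$pooled$delta_min,
    min_probes = thresholds$pooled$min_probes
  )

  intersection <- intersect_gene_sets(set_tissue, set_array, set_pooled)

  clusters <- NULL
  candidates <- NULL
  if (length(intersection) == 0L) {
    warning("empty intersection: no candidate genes")
  } else {
    k_eff <- min(k, length(intersection))
    if (k_eff < k) {
      warning(sprintf("intersection has only %d gene(s); using k = %d",
                      length(intersection), k_eff))
    }
    profiles <- scaled$levels[intersection, , drop = FALSE]
    clusters <- cluster_genes(profiles, k = k_eff)
    hdm_lv <- stats::setNames(tissue_results$hdm_level, tissue_results$gene)
    candidates <- select_top_candidates(
      clusters, hdm_lv,
      fraction = fraction, min_cluster_to_apply = min_cluster_to_apply
    )
  }

  structure(
    list(
      gene_sets = list(tissue = set_tissue, array = set_array,
                       pooled = set_pooled),
      intersection = intersection,
      tissue_results = tissue_results,
      probe_results = probe_results,
      clusters = clusters,
      candidates = candidates,
      thresholds = thresholds
    ),
    class = "discovery_run"
  )
}

#' Write the discovery-stage result files
#'
#' Gene sets (one gene per line), the per-gene and per-probe result
#' tables (TSV), and the candidate table (CSV).
#'
#' @param run A `discovery_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_discovery_results <- function(run, dir) {
  stopifnot(inherits(run, "discovery_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tissue = file.path(dir, "hdm_genes_tissue.txt"),
    array = file.path(dir, "hdm_genes_array.txt"),
    pooled = file.path(dir, "hdm_genes_pooled.txt"),
    intersection = file.path(dir, "intersection.txt"),
    tissue_results = file.path(dir, "tissue_hdm_results.tsv"),
    probe_results = file.path(dir, "array_probe_results.tsv"),
    candidates = file.path(dir, "candidates.csv")
  )
  write_gene_set(run$gene_sets$tissue, paths[["tissue"]])
  write_gene_set(run$gene_sets$array, paths[["array"]])
  write_gene_set(run$gene_sets$pooled, paths[["pooled"]])
  write_gene_set(run$intersection, paths[["intersection"]])
  utils::write.table(run$tissue_results, paths[["tissue_results"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$probe_results, paths[["probe_results"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$candidates)) {
    utils::write.csv(run$candidates, paths[["candidates"]], row.names = FALSE)
  } else {
    utils::write.csv(
      data.frame(gene = character(0), cluster = integer(0),
                 hdm_level = numeric(0), rank = integer(0),
                 selected = logical(0)),
      paths[["candidates"]], row.names = FALSE
    )
  }
  invisible(paths)
}

#' Delta-Cp sample-by-gene matrix from raw qMSP measurements
#'
#' Computes per-replicate delta-Cp with reference QC, averages the
#' valid duplicates per sample and gene, and pivots to a samples x
#' genes matrix. Samples whose reference failed in every replicate of a
#' gene get `NA` for that gene.
#'
#' @param measurements Long data frame with `sample_id`, `group`,
#'   `gene`, `replicate`, `cp_gene`, `cp_ref`.
#' @param ref_max,censor_ceiling See [compute_delta_cp()].
#' @return List with `delta_cp` (matrix), `labels` (named character,
#'   per sample), `n_invalid` (count of invalid sample-gene cells).
#' @export
delta_cp_matrix <- function(measurements, ref_max = 36, censor_ceiling = 12) {
  need <- c("sample_id", "group", "gene", "replicate", "cp_gene", "cp_ref")
  stopifnot(all(need %in% names(measurements)))
  dc <- compute_delta_cp(measurements$cp_gene, measurements$cp_ref,
                         ref_max = ref_max, censor_ceiling = censor_ceiling)
  measurements$delta_cp <- dc$delta_cp
  measurements$valid <- dc$valid
  samples <- unique(measurements$sample_id)
  genes <- unique(measurements$gene)
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  n_invalid <- 0L
  for (s in samples) {
    for (g in genes) {
      rows <- measurements$sample_id == s & measurements$gene == g
      agg <- aggregate_duplicates(measurements$delta_cp[rows],
                                  measurements$valid[rows])
      if (agg$valid) m[s, g] <- agg$delta_cp else n_invalid <- n_invalid + 1L
    }
  }
  labels <- stats::setNames(
    measurements$group[match(samples, measurements$sample_id)], samples
  )
  list(delta_cp = m, labels = labels, n_invalid = n_invalid)
}

# Per-gene two-set summary block used by run_validation: group medians
# with bootstrap CIs and the Mann-Whitney p-value.
.gene_summary <- function(values, labels, gene, set_name, B, seed) {
  pos <- .as_case_logical(labels, "OC")
  keep <- !is.na(values)
  v <- values[keep]
  pos_k <- pos[keep]
  med_fn <- function(vv, ll) stats::median(vv[.as_case_logical(ll, "OC")])
  med_fn_n <- function(vv, ll) stats::median(vv[!.as_case_logical(ll, "OC")])
  ci_oc <- bootstrap_ci(v, ifelse(pos_k, "OC", "normal"), med_fn, B = B, seed = seed)
  ci_n <- bootstrap_ci(v, ifelse(pos_k, "OC", "normal"), med_fn_n, B = B, seed = seed + 1L)
  data.frame(
    set = set_name, gene = gene,
    n_oc = sum(pos_k), n_normal = sum(!pos_k),
    median_oc = stats::median(v[pos_k]),
    median_oc_lo = ci_oc[1], median_oc_hi = ci_oc[2],
    median_normal = stats::median(v[!pos_k]),
    median_normal_lo = ci_n[1], median_normal_hi = ci_n[2],
    p_value = mann_whitney_two_tailed(v[pos_k], v[!pos_k])$p_value,
    stringsAsFactors = FALSE
  )
}

#' Run the training/testing validation stage
#'
#' Computes per-gene delta-Cp summaries in both sets, per-gene ROC
#' performance with cutoffs frozen on the training set, gates genes on
#' training AUC, fits the cross-validated logistic risk model on the
#' gated panel, and evaluates the frozen model on the testing set.
#' Training-derived quantities (cutoffs, model, gate) never see the
#' testing data.
#'
#' @param train,test Long qMSP measurement tables (see
#'   [delta_cp_matrix()]); their sample ids must not overlap.
#' @param panel Character vector of candidate genes to validate.
#' @param gate_auc Genes must exceed this training AUC to enter the
#'   combination model (default 0.7).
#' @param folds,replications,aggregation Passed to [fit_cv_model()].
#' @param seed Integer seed for the CV splits and bootstraps.
#' @param B Bootstrap iterations for CIs (default 200).
#' @param ref_max,censor_ceiling qMSP QC settings (see
#'   [compute_delta_cp()]).
#' @return List with `per_gene` (group-median summary rows for both
#'   sets), `roc_table` (per-gene and panel cutoff/sens/spec/AUC rows
#'   for both sets), `model` (the fitted `risk_model`), `panel_genes`
#'   (the gated panel), `train_metrics`, `test_metrics`, and `qc`
#'   (invalid-measurement counts).
#' @export
run_validation <- function(train, test, panel, gate_auc = 0.7,
                           folds = 10L, replications = 200L,
                           aggregation = "mean", seed = NULL, B = 200L,
                           ref_max = 36, censor_ceiling = 12) {
  overlap <- intersect(unique(train$sample_id), unique(test$sample_id))
  if (length(overlap) > 0L) {
    stop("sample id(s) present in both training and testing sets: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  }
  for (g in panel) {
    if (!g %in% train$gene) stop("panel gene missing from training set: ", g)
    if (!g %in% test$gene) stop("panel gene missing from testing set: ", g)
  }
  if (is.null(seed)) seed <- 1L
  dtr <- delta_cp_matrix(train, ref_max = ref_max, censor_ceiling = censor_ceiling)
  dte <- delta_cp_matrix(test, ref_max = ref_max, censor_ceiling = censor_ceiling)

  per_gene <- list()
  roc_rows <- list()
  train_auc <- stats::setNames(numeric(length(panel)), panel)
  for (i in seq_along(panel)) {
    g <- panel[i]
    v_tr <- dtr$delta_cp[, g]
    v_te <- dte$delta_cp[, g]
    per_gene[[length(per_gene) + 1L]] <-
      .gene_summary(v_tr, dtr$labels, g, "training", B, seed + 10L * i)
    per_gene[[length(per_gene) + 1L]] <-
      .gene_summary(v_te, dte$labels, g, "testing", B, seed + 10L * i + 5L)

    keep_tr <- !is.na(v_tr)
    pos_tr <- .as_case_logical(dtr$labels, "OC")[keep_tr]
    ct <- closest_topleft_cutoff(v_tr[keep_tr], pos_tr,
                                 direction = "lower_is_positive")
    auc_tr <- roc_auc(v_tr[keep_tr], pos_tr, direction = "lower_is_positive")
    auc_tr_ci <- bootstrap_ci(
      v_tr[keep_tr], pos_tr,
      function(v, l) roc_auc(v, l, direction = "lower_is_positive"),
      B = B, seed = seed + 100L + i
    )
    train_auc[g] <- auc_tr

    keep_te <- !is.na(v_te)
    pos_te <- .as_case_logical(dte$labels, "OC")[keep_te]
    called_te <- v_te[keep_te] <= ct$cutoff
    auc_te <- roc_auc(v_te[keep_te], pos_te, direction = "lower_is_positive")
    auc_te_ci <- bootstrap_ci(
      v_te[keep_te], pos_te,
      function(v, l) roc_auc(v, l, direction = "lower_is_positive"),
      B = B, seed = seed + 200L + i
    )
    roc_rows[[length(roc_rows) + 1L]] <- data.frame(
      gene_set = g, cutoff = ct$cutoff,
      train_sens = ct$sensitivity, train_spec = ct$specificity,
      train_auc = auc_tr, train_auc_lo = auc_tr_ci[1], train_auc_hi = auc_tr_ci[2],
      test_sens = mean(called_te[pos_te]),
      test_spec = mean(!called_te[!pos_te]),
      test_auc = auc_te, test_auc_lo = auc_te_ci[1], test_auc_hi = auc_te_ci[2],
      stringsAsFactors = FALSE
    )
  }

  panel_genes <- panel[train_auc > gate_auc]
  model <- NULL
  train_metrics <- NULL
  test_metrics <- NULL
  if (length(panel_genes) >= 1L) {
    x_tr <- dtr$delta_cp[, panel_genes, drop = FALSE]
    cc_tr <- stats::complete.cases(x_tr)
    model <- fit_cv_model(
      x_tr[cc_tr, , drop = FALSE], dtr$labels[cc_tr],
      folds = folds, replications = replications,
      seed = seed, aggregation = aggregation, positive = "OC"
    )
    train_metrics <- evaluate_risk_model(
      model, x_tr[cc_tr, , drop = FALSE], dtr$labels[cc_tr],
      B = B, seed = seed + 300L, positive = "OC"
    )
    x_te <- dte$delta_cp[, panel_genes, drop = FALSE]
    cc_te <- stats::complete.cases(x_te)
    test_metrics <- evaluate_risk_model(
      model, x_te[cc_te, , drop = FALSE], dte$labels[cc_te],
      B = B, seed = seed + 400L, positive = "OC"
    )
    roc_rows[[length(roc_rows) + 1L]] <- data.frame(
      gene_set = paste(panel_genes, collapse = "+"),
      cutoff = model$cutoff,
      train_sens = train_metrics$sensitivity,
      train_spec = train_metrics$specificity,
      train_auc = train_metrics$auc,
      train_auc_lo = train_metrics$auc_ci[1],
      train_auc_hi = train_metrics$auc_ci[2],
      test_sens = test_metrics$sensitivity,
      test_spec = test_metrics$specificity,
      test_auc = test_metrics$auc,
      test_auc_lo = test_metrics$auc_ci[1],
      test_auc_hi = test_metrics$auc_ci[2],
      stringsAsFactors = FALSE
    )
  } else {
    warning("no gene passed the training AUC gate; no combination model fitted")
  }

  list(
    per_gene = do.call(rbind, per_gene),
    roc_table = do.call(rbind, roc_rows),
    model = model,
    panel_genes = panel_genes,
    train_metrics = train_metrics,
    test_metrics = test_metrics,
    qc = list(train_invalid = dtr$n_invalid, test_invalid = dte$n_invalid)
  )
}
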