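#' Probe-level quality control for 450K-style beta matrices
#'
#' Removes probes that fail detection (detection p above
#' `max_detection_p` in any sample by default, or in all samples with
#' `detection_rule = "all"`), probes carrying annotated SNPs (at least
#' `snp_min` of them) when `snp_exclude`, probes of genes without
#' NM-type RefSeq accessions when `nm_only`, and probes on sex
#' chromosomes when `drop_sex`.
#'
#' @param probes Data frame with columns `probe_id`, `chrom`,
#'   `closest_gene`, `n_snp`, and optionally `accession`; `probe_id`
#'   values must be unique.
#' @param betas Numeric matrix, probes x samples, rows named by probe id.
#' @param detection_p Optional matrix of per-probe, per-sample detection
#'   p-values (same shape as `betas`); `NULL` skips the detection filter.
#' @param max_detection_p Detection threshold (default 0.01).
#' @param detection_rule `"any"` (default: one failing sample removes the
#'   probe) or `"all"` (removed only when failing in every sample).
#' @param snp_exclude Drop SNP-carrying probes (default TRUE).
#' @param snp_min Minimum annotated-SNP count that triggers exclusion
#'   (default 1).
#' @param nm_only,drop_sex Annotation filters (defaults TRUE).
#' @return List with filtered `probes` and `betas` (and `detection_p`
#'   when supplied). Warns instead of failing when nothing survives.
#' @export
qc_filter_probes <- function(probes, betas, detection_p = NULL,
                             max_detection_p = 0.01,
                             detection_rule = c("any", "all"),
                             snp_exclude = TRUE, snp_min = 1L,
                             nm_only = TRUE, drop_sex = TRUE) {
  detection_rule <- match.arg(detection_rule)
  stopifnot(!anyDuplicated(probes$probe_id))
  betas <- as.matrix(betas)
  keep <- rep(TRUE, nrow(probes))
  if (!is.null(detection_p)) {
    dp <- as.matrix(detection_p)[probes$probe_id, , drop = FALSE]
    fail <- dp > max_detection_p
    keep <- keep & !(if (detection_rule == "any") apply(fail, 1L, any) else apply(fail, 1L, all))
  }
  if (snp_exclude) keep <- keep & probes$n_snp < snp_min
  if (nm_only && "accession" %in% names(probes)) {
    keep <- keep & startsWith(as.character(probes$accession), "NM_")
  }
  if (drop_sex) keep <- keep & !(probes$chrom %in% c("chrX", "chrY", "X", "Y"))
  if (!any(keep)) warning("no probes pass QC")
  out <- list(
    probes = probes[keep, , drop = FALSE],
    betas = betas[probes$probe_id[keep], , drop = FALSE]
  )
  if (!is.null(detection_p)) {
    out$detection_p <- as.matrix(detection_p)[probes$probe_id[keep], , drop = FALSE]
  }
  out
}

#' Call highly differentially methylated probes
#'
#' Per-probe case/control comparison on beta values with the array-stage
#' criteria: median beta difference (case - control) above `delta_min`,
#' two-sided Mann-Whitney p below `p_max`, and AUC above `auc_min`.
#' Missing betas are handled probe-wise complete-case; probes with an
#' entirely missing group are excluded with a warning.
#'
#' @param betas Probes x samples beta matrix in \[0, 1\].
#' @param labels Case/control labels per sample column.
#' @param delta_min,p_max,auc_min Thresholds (defaults 0.15, 0.05, 0.75).
#' @param positive Case level when `labels` is not logical.
#' @return Data frame with `probe_id`, `hdm_level`, `p_value`, `auc`,
#'   `pass`.
#' @export
call_hdm_probes <- function(betas, labels, delta_min = 0.15, p_max = 0.05,
                            auc_min = 0.75, positive = NULL) {
  betas <- as.matrix(betas)
  pos <- .as_case_logical(labels, positive)
  if (length(pos) != ncol(betas)) stop("labels must match sample columns")
  if (!any(pos) || all(pos)) stop("both groups must be nonempty")
  res <- lapply(seq_len(nrow(betas)), function(i) {
    .hdm_call(betas[i, pos], betas[i, !pos], delta_min, p_max, auc_min)
  })
  out <- data.frame(
    probe_id = rownames(betas),
    hdm_level = vapply(res, `[[`, numeric(1), "hdm_level"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    auc = vapply(res, `[[`, numeric(1), "auc"),
    pass = vapply(res, `[[`, logical(1), "pass"),
    stringsAsFactors = FALSE
  )
  dropped <- is.na(out$hdm_level)
  if (any(dropped)) {
    warning(sprintf("excluding %d probe(s) with an all-missing group", sum(dropped)))
    out <- out[!dropped, , drop = FALSE]
  }
  out
}

#' Aggregate passing probes to promoter-level HDM genes
#'
#' A gene is called HDM when at least `min_probes` of its promoter
#' probes pass the probe-level criteria. Probes outside the promoter
#' region never count, regardless of their own call.
#'
#' @param probe_results Output of [call_hdm_probes()] (or any data frame
#'   with `probe_id` and `pass`).
#' @param probes Probe manifest with `probe_id`, `closest_gene`,
#'   `in_promoter`.
#' @param min_probes Minimum passing promoter probes (default 3).
#' @return Sorted character vector of HDM gene ids.
#' @export
aggregate_promoter <- function(probe_results, probes, min_probes = 3L) {
  stopifnot(all(c("probe_id", "pass") %in% names(probe_results)))
  stopifnot(all(c("probe_id", "closest_gene", "in_promoter") %in% names(probes)))
  m <- merge(probe_results, probes[, c("probe_id", "closest_gene", "in_promoter")],
             by = "probe_id")
  m <- m[m$pass & m$in_promoter, , drop = FALSE]
  if (nrow(m) == 0L) return(character(0))
  counts <- table(m$closest_gene)
  sort(names(counts)[counts >= min_probes])
}

#' Call HDM genes from pooled-specimen beta profiles
#'
#' Pooled-scraping stage: with only a handful of DNA pools per group no
#' hypothesis test is run; a probe passes when the mean case-pool beta
#' exceeds the mean control-pool beta by more than `delta_min`, and a
#' gene is called when at least `min_probes` of its promoter probes pass.
#'
#' @param betas Probes x pools beta matrix.
#' @param pool_labels Case/control identity of each pool column.
#' @param probes Probe manifest (see [aggregate_promoter()]).
#' @param delta_min Per-probe mean difference threshold (default 0.015).
#' @param min_probes Minimum passing promoter probes (default 3).
#' @param positive Case level when `pool_labels` is not logical.
#' @return Sorted character vector of HDM gene ids.
#' @export
call_pooled_hdm <- function(betas, pool_labels, probes, delta_min = 0.015,
                            min_probes = 3L, positive = NULL) {
  betas <- as.matrix(betas)
  pos <- .as_case_logical(pool_labels, positive)
  if (!any(pos) || all(pos)) stop("need at least one pool per group")
  delta <- rowMeans(betas[, pos, drop = FALSE], na.rm = TRUE) -
    rowMeans(betas[, !pos, drop = FALSE], na.rm = TRUE)
  probe_results <- data.frame(
    probe_id = rownames(betas),
    hdm_level = delta,
    pass = !is.na(delta) & delta > delta_min,
    stringsAsFactors = FALSE
  )
  aggregate_promoter(probe_results, probes, min_probes = min_probes)
}
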