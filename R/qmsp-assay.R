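#' Compute delta-Cp from qMSP crossing points
#'
#' DNA methylation readout of a methylation-specific PCR assay,
#' normalized for template input by the unmethylated reference gene
#' COL2A1: delta-Cp = Cp(gene) - Cp(reference). Lower delta-Cp means
#' more methylated template. A reference Cp above `ref_max` marks the
#' absence of template DNA and invalidates the measurement. An
#' undetected target with a valid reference is censored at
#' `censor_ceiling` cycles (no amplification = at most that little
#' methylated template) and flagged.
#'
#' @param cp_gene,cp_ref Crossing points in cycles; `NA` = undetected.
#' @param ref_max Reference validity limit in cycles (default 36).
#' @param censor_ceiling Delta-Cp assigned to an undetected target with
#'   valid reference (default 12 cycles).
#' @return Data frame with `delta_cp`, `valid`, `censored` (vectorized
#'   over the inputs).
#' @export
compute_delta_cp <- function(cp_gene, cp_ref, ref_max = 36, censor_ceiling = 12) {
  n <- max(length(cp_gene), length(cp_ref))
  cp_gene <- rep_len(cp_gene, n)
  cp_ref <- rep_len(cp_ref, n)
  valid <- !is.na(cp_ref) & cp_ref <= ref_max
  censored <- valid & is.na(cp_gene)
  delta <- ifelse(valid, ifelse(censored, censor_ceiling, cp_gene - cp_ref), NA_real_)
  data.frame(delta_cp = delta, valid = valid, censored = censored)
}

#' Aggregate replicate qMSP measurements
#'
#' Each specimen is assayed in duplicate per gene; the reported delta-Cp
#' is the mean of the valid replicates, invalid only when no replicate
#' is valid.
#'
#' @param delta_cp Numeric vector of replicate delta-Cp values.
#' @param valid Logical vector of replicate validity flags.
#' @return List with `delta_cp` (mean of valid replicates or `NA`) and
#'   `valid`.
#' @export
aggregate_duplicates <- function(delta_cp, valid = !is.na(delta_cp)) {
  stopifnot(length(delta_cp) >= 1L, length(valid) == length(delta_cp))
  if (!any(valid)) return(list(delta_cp = NA_real_, valid = FALSE))
  list(delta_cp = mean(delta_cp[valid]), valid = TRUE)
}

#' Pooled-DNA verification rule for a candidate gene
#'
#' A candidate passes verification when its pooled delta-Cp is lower in
#' ovarian-cancer pools than in normal pools: in at least one OC tissue
#' pool, and in every OC cervical-scraping pool. "Lower than the normal
#' controls" is judged against the minimum of the normal pools by
#' default (strictest reading), or their mean with
#' `compare = "mean"`. All comparisons are strict.
#'
#' @param tissue_oc,tissue_normal Delta-Cp of the OC and normal tissue
#'   pools (each nonempty).
#' @param scraping_oc,scraping_normal Delta-Cp of the OC and normal
#'   cervical-scraping pools (each nonempty).
#' @param compare `"min"` (default) or `"mean"` summary of the normal
#'   pools.
#' @return List with `pass`, the per-specimen-type criteria
#'   (`tissue_pass`, `scraping_pass`), and a `detail` data frame of
#'   every OC pool against the normal reference value.
#' @export
verify_candidate_pools <- function(tissue_oc, tissue_normal,
                                   scraping_oc, scraping_normal,
                                   compare = c("min", "mean")) {
  compare <- match.arg(compare)
  for (v in list(tissue_oc, tissue_normal, scraping_oc, scraping_normal)) {
    if (length(v) == 0L || all(is.na(v))) stop("every pool group needs at least one value")
  }
  ref_fn <- if (compare == "min") min else mean
  t_ref <- ref_fn(tissue_normal, na.rm = TRUE)
  s_ref <- ref_fn(scraping_normal, na.rm = TRUE)
  tissue_pass <- any(tissue_oc < t_ref, na.rm = TRUE)
  scraping_pass <- all(!is.na(scraping_oc)) && all(scraping_oc < s_ref)
  detail <- rbind(
    data.frame(
      specimen = "tissue", pool = seq_along(tissue_oc),
      oc_delta_cp = tissue_oc, normal_ref = t_ref,
      lower = tissue_oc < t_ref, stringsAsFactors = FALSE
    ),
    data.frame(
      specimen = "scraping", pool = seq_along(scraping_oc),
      oc_delta_cp = scraping_oc, normal_ref = s_ref,
      lower = scraping_oc < s_ref, stringsAsFactors = FALSE
    )
  )
  list(
    pass = tissue_pass && scraping_pass,
    tissue_pass = tissue_pass,
    scraping_pass = scraping_pass,
    detail = detail
  )
}

#' Pick the final panel genes cluster by cluster
#'
#' Among verified candidates, ranks the genes of each cluster by the
#' normal-minus-OC pooled delta-Cp gap (largest methylation contrast
#' first) and keeps up to `max_per_cluster` per cluster. Ties are broken
#' by gene id.
#'
#' @param candidates Data frame with columns `gene`, `cluster`, and
#'   `gap` (normal pooled delta-Cp minus OC pooled delta-Cp).
#' @param max_per_cluster Maximum genes kept per cluster (default 2).
#' @return Character vector of panel gene ids, ordered by cluster then
#'   rank.
#' @export
pick_per_cluster <- function(candidates, max_per_cluster = 2L) {
  stopifnot(all(c("gene", "cluster", "gap") %in% names(candidates)))
  if (nrow(candidates) == 0L) return(character(0))
  unlist(lapply(sort(unique(candidates$cluster)), function(cl) {
    d <- candidates[candidates$cluster == cl, , drop = FALSE]
    d <- d[order(-d$gap, d$gene), , drop = FALSE]
    utils::head(d$gene, max_per_cluster)
  }), use.names = FALSE)
}
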