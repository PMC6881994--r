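#' Intersect HDM gene sets across datasets
#'
#' @param ... Two or more character vectors of gene ids (or a single
#'   list of them).
#' @return Sorted character vector of the genes present in every set.
#' @export
intersect_gene_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]])) sets <- sets[[1L]]
  if (length(sets) < 2L) stop("need at least two gene sets")
  out <- Reduce(intersect, lapply(sets, as.character))
  sort(unique(out))
}

#' Cluster gene methylation profiles
#'
#' Unsupervised agglomerative clustering of per-gene methylation
#' profiles (rows = genes, columns = samples) with complete linkage on
#' Euclidean distance, cut to exactly `k` clusters. Missing values are
#' imputed by the gene's median before computing distances. Cluster
#' labels are canonical: clusters are renumbered 1..k by their
#' lexicographically smallest member gene id, so a permutation of the
#' input rows changes nothing.
#'
#' @param profiles Numeric matrix, genes x samples, rows named by gene.
#' @param k Number of clusters (default 4); must not exceed the number
#'   of genes.
#' @param standardize Row-standardize profiles (mean 0, sd 1) before
#'   clustering (default FALSE: raw beta/level profiles).
#' @return Named integer vector of cluster ids (1..k) per gene, ordered
#'   by gene id.
#' @export
cluster_genes <- function(profiles, k = 4L, standardize = FALSE) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) stop("profiles must have gene row names")
  if (k > nrow(profiles)) stop("k must not exceed the number of genes")
  # deterministic input order regardless of caller's ordering
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  if (anyNA(profiles)) {
    profiles <- t(apply(profiles, 1L, function(v) {
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      v
    }))
  }
  if (standardize) {
    profiles <- t(apply(profiles, 1L, function(v) {
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else v - mean(v)
    }))
  }
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = "complete")
  raw <- stats::cutree(hc, k = k)
  # canonical numbering by smallest member id (rows are sorted by id)
  first_seen <- raw[!duplicated(raw)]
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  out <- as.integer(relabel[as.character(raw)])
  names(out) <- names(raw)
  out
}

#' Select top candidate genes within each cluster
#'
#' Within every cluster larger than `min_cluster_to_apply` genes, the
#' top `ceiling(fraction * size)` genes by differential methylation
#' level (descending) are marked selected; smaller clusters keep all
#' their genes. Ties are broken by gene id.
#'
#' @param assignment Named integer vector of cluster ids (from
#'   [cluster_genes()]).
#' @param hdm_level Named numeric vector of per-gene differential
#'   methylation levels covering every clustered gene.
#' @param fraction Selection fraction (default 0.10).
#' @param min_cluster_to_apply The fraction rule applies only to
#'   clusters with more genes than this (default 5).
#' @return Data frame (one row per gene) with `gene`, `cluster`,
#'   `hdm_level`, `rank` (within cluster, by descending level), and
#'   `selected`.
#' @export
select_top_candidates <- function(assignment, hdm_level, fraction = 0.10,
                                  min_cluster_to_apply = 5L) {
  genes <- names(assignment)
  if (is.null(genes)) stop("assignment must be named by gene")
  missing_lvl <- setdiff(genes, names(hdm_level))
  if (length(missing_lvl) > 0L) {
    stop("missing hdm_level for: ", paste(missing_lvl, collapse = ", "))
  }
  out <- do.call(rbind, lapply(sort(unique(assignment)), function(cl) {
    g <- genes[assignment == cl]
    lv <- hdm_level[g]
    ord <- order(-lv, g)
    g <- g[ord]
    lv <- lv[ord]
    quota <- if (length(g) > min_cluster_to_apply) {
      ceiling(fraction * length(g))
    } else {
      length(g)
    }
    data.frame(
      gene = g, cluster = cl, hdm_level = unname(lv),
      rank = seq_along(g), selected = seq_along(g) <= quota,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
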