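#' Build promoter windows around transcription start sites
#'
#' Constructs, for each coding gene, the window spanning `upstream` bp
#' before and `downstream` bp after the TSS (default 1000/1000, i.e. a
#' 2000-bp promoter window). Coordinates are 0-based half-open
#' throughout. On the minus strand "upstream" runs toward larger
#' coordinates, so a symmetric 1000/1000 window has the same genomic
#' span on either strand. Genes on chrX/chrY are dropped when
#' `exclude_sex`, and non-NM (non-coding) RefSeq accessions are dropped
#' when the annotation carries an `accession` column.
#'
#' @param annotation Data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based), `strand` ("+"/"-"), and optionally `accession`.
#' @param upstream,downstream Window half-spans in bp (>= 0).
#' @param exclude_sex Drop genes on sex chromosomes (default TRUE).
#' @param nm_only Keep only NM-type accessions when available (default TRUE).
#' @return A [GenomicRanges::GRanges] with one window per retained gene
#'   (`gene_id` metadata column); starts falling below 0 are clamped with
#'   a warning.
#' @export
make_tss_windows <- function(annotation, upstream = 1000L, downstream = 1000L,
                             exclude_sex = TRUE, nm_only = TRUE) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(annotation)))
  if (upstream < 0 || downstream < 0) stop("upstream/downstream must be >= 0")
  ann <- annotation
  if (nm_only && "accession" %in% names(ann)) {
    ann <- ann[startsWith(as.character(ann$accession), "NM_"), , drop = FALSE]
  }
  if (exclude_sex) {
    sex <- ann$chrom %in% c("chrX", "chrY", "X", "Y")
    ann <- ann[!sex, , drop = FALSE]
  }
  if (nrow(ann) == 0L) {
    warning("no genes left after annotation filtering")
    return(GenomicRanges::GRanges())
  }
  plus <- ann$strand == "+"
  start0 <- ifelse(plus, ann$tss - upstream, ann$tss - downstream)
  end0 <- ifelse(plus, ann$tss + downstream, ann$tss + upstream)
  if (any(start0 < 0)) {
    warning("window(s) extending below position 0 clamped")
    start0 <- pmax(start0, 0)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0), # 1-based closed
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$gene_id <- as.character(ann$gene_id)
  gr
}

#' Quantify promoter-window methylation from read start coordinates
#'
#' Counts, per sample, the uniquely-mapped read starts falling inside
#' each TSS window (start position within the half-open window) and
#' normalizes by that sample's total mapped reads. The resulting raw
#' fractions represent MBD-captured methylation density.
#'
#' @param read_starts Named list, one element per sample: a data frame
#'   with columns `chrom` and `start` (0-based read start).
#' @param windows Windows from [make_tss_windows()].
#' @param totals Named numeric vector of total mapped reads per sample.
#' @return An object of class `window_methylation`: list with `levels`
#'   (gene x sample matrix), `totals`, and `mode = "raw"`. Samples with
#'   zero total reads are excluded with a warning.
#' @export
quantify_windows <- function(read_starts, windows, totals) {
  stopifnot(is.list(read_starts), length(read_starts) > 0L)
  samples <- names(read_starts)
  if (is.null(samples)) stop("read_starts must be a named list")
  totals <- totals[samples]
  bad <- is.na(totals) | totals <= 0
  if (any(bad)) {
    warning(sprintf(
      "excluding %d sample(s) with zero/missing total reads: %s",
      sum(bad), paste(samples[bad], collapse = ", ")
    ))
    samples <- samples[!bad]
    totals <- totals[!bad]
  }
  genes <- S4Vectors::mcols(windows)$gene_id
  counts <- matrix(0L, nrow = length(windows), ncol = length(samples),
                   dimnames = list(genes, samples))
  for (s in samples) {
    rs <- read_starts[[s]]
    if (nrow(rs) > 0L) {
      gr <- GenomicRanges::GRanges(
        seqnames = rs$chrom,
        ranges = IRanges::IRanges(start = rs$start + 1L, width = 1L)
      )
      counts[, s] <- GenomicRanges::countOverlaps(windows, gr, ignore.strand = TRUE)
    }
  }
  levels <- sweep(counts, 2L, totals, "/")
  structure(
    list(levels = levels, totals = totals, mode = "raw"),
    class = "window_methylation"
  )
}

#' Rescale window methylation levels
#'
#' Raw per-sample read fractions are of order 1e-6 and therefore not
#' comparable to threshold rules stated on a \[0, 1\] methylation scale;
#' this step maps each gene's values across samples onto such a scale.
#' `per_gene_minmax` (the default used by the discovery pipeline) maps
#' each gene's range to \[0, 1\] (a constant gene becomes all 0);
#' `rank` maps to (rank - 0.5) / n with midranks for ties; `none` passes
#' raw values through.
#'
#' @param wm A `window_methylation` object in raw mode.
#' @param method One of `"per_gene_minmax"`, `"rank"`, `"none"`.
#' @return A `window_methylation` object with `mode` set to the method.
#' @export
scale_levels <- function(wm, method = c("per_gene_minmax", "rank", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(wm, "window_methylation"))
  if (wm$mode != "raw") stop("scale_levels expects raw-mode input")
  x <- wm$levels
  scaled <- switch(method,
    none = x,
    per_gene_minmax = t(apply(x, 1L, function(v) {
      r <- range(v)
      if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, length(v))
    })),
    rank = t(apply(x, 1L, function(v) (rank(v) - 0.5) / length(v)))
  )
  dimnames(scaled) <- dimnames(x)
  structure(
    list(levels = scaled, totals = wm$totals, mode = method),
    class = "window_methylation"
  )
}

# Shared two-group HDM evaluation used by the tissue and array callers.
# Returns the group-median difference (case - control), two-sided
# Mann-Whitney p, case-oriented AUC, and the pass flag (hypermethylation
# direction required).
.hdm_call <- function(case, control, delta_min, p_max, auc_min) {
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (length(case) == 0L || length(control) == 0L) {
    return(list(hdm_level = NA_real_, p_value = NA_real_, auc = NA_real_, pass = FALSE))
  }
  delta <- stats::median(case) - stats::median(control)
  mw <- mann_whitney_two_tailed(case, control)
  auc <- roc_auc(
    c(case, control),
    c(rep(TRUE, length(case)), rep(FALSE, length(control))),
    direction = "higher_is_positive"
  )
  pass <- delta > delta_min && mw$p_value < p_max && auc > auc_min
  list(hdm_level = delta, p_value = mw$p_value, auc = auc, pass = pass)
}

#' Call highly differentially methylated genes in a tissue cohort
#'
#' Applies the tissue-stage HDM criteria gene by gene: two-sided
#' Mann-Whitney p below `p_max`, case-minus-control median difference of
#' the scaled level above `hdm_min`, and case-oriented AUC above
#' `auc_min`. Only hypermethylation in cases (positive difference) can
#' pass.
#'
#' @param wm A `window_methylation` object (typically scaled).
#' @param labels Case/control labels, one per sample column.
#' @param hdm_min,p_max,auc_min Thresholds (defaults 0.2, 0.01, 0.85).
#' @param positive Case level when `labels` is not logical.
#' @return Data frame with columns `gene`, `hdm_level`, `p_value`,
#'   `auc`, `pass`.
#' @export
call_hdm_genes <- function(wm, labels, hdm_min = 0.2, p_max = 0.01,
                           auc_min = 0.85, positive = NULL) {
  stopifnot(inherits(wm, "window_methylation"))
  x <- wm$levels
  pos <- .as_case_logical(labels, positive)
  if (length(pos) != ncol(x)) stop("labels must match sample columns")
  if (!any(pos) || all(pos)) stop("both groups must be nonempty")
  res <- lapply(seq_len(nrow(x)), function(i) {
    .hdm_call(x[i, pos], x[i, !pos], hdm_min, p_max, auc_min)
  })
  data.frame(
    gene = rownames(x),
    hdm_level = vapply(res, `[[`, numeric(1), "hdm_level"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    auc = vapply(res, `[[`, numeric(1), "auc"),
    pass = vapply(res, `[[`, logical(1), "pass"),
    stringsAsFactors = FALSE
  )
}
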