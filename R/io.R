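#' Write per-sample read starts as BED files
#'
#' One 4-column BED (0-based, half-open) per sample, each read as a
#' 1-bp interval at its start coordinate.
#'
#' @param reads Named list of data frames with `chrom`, `start`.
#' @param dir Output directory (created if needed).
#' @param read_length Interval width written to BED (default 1).
#' @return Invisibly, the written file paths.
#' @export
write_bed_reads <- function(reads, dir, read_length = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(reads), function(s) {
    df <- reads[[s]]
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, width = read_length)
    )
    S4Vectors::mcols(gr)$name <- sprintf("%s_r%06d", s, seq_along(gr))
    path <- file.path(dir, paste0(s, ".bed"))
    rtracklayer::export(gr, path, format = "BED")
    path
  }, character(1))
  invisible(paths)
}

#' Read read-start coordinates from a BED file
#'
#' @param path BED file path.
#' @return Data frame with `chrom` and 0-based `start`.
#' @export
read_bed_reads <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Write a TSS annotation as BED6
#'
#' Each TSS becomes a 1-bp BED interval; `name` holds
#' `gene_id|accession` when accessions are present.
#'
#' @param annotation Data frame with `gene_id`, `chrom`, `tss`,
#'   `strand`, optionally `accession`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tss_bed <- function(annotation, path) {
  name <- if ("accession" %in% names(annotation)) {
    paste(annotation$gene_id, annotation$accession, sep = "|")
  } else {
    annotation$gene_id
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$tss + 1L, width = 1L),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a TSS annotation from BED6
#'
#' @param path BED6 file as written by [write_tss_bed()].
#' @return Data frame with `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`, and `accession` when encoded in the name field.
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  name <- S4Vectors::mcols(gr)$name
  parts <- strsplit(name, "|", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 1L),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (all(lengths(parts) >= 2L)) {
    out$accession <- vapply(parts, `[`, character(1), 2L)
  }
  out
}

#' Write / read a feature-by-sample matrix as TSV
#'
#' @param x Numeric matrix with row and column names.
#' @param path File path.
#' @return `write_matrix_tsv` invisibly returns `path`;
#'   `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(feature = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a qMSP measurement table as CSV
#'
#' Long format: `sample_id`, `group`, `gene`, `replicate`, `cp_gene`,
#' `cp_ref` (plus any extra columns such as `pool_id`).
#'
#' @param measurements Data frame of measurements.
#' @param path File path.
#' @return `write_qmsp_csv` invisibly returns `path`; `read_qmsp_csv`
#'   returns the data frame.
#' @export
write_qmsp_csv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qmsp_csv
#' @export
read_qmsp_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a gene set as plain text (one gene per line)
#'
#' @param genes Character vector.
#' @param path File path.
#' @return `write_gene_set` invisibly returns `path`; `read_gene_set`
#'   returns the character vector.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  out <- readLines(path)
  out[nzchar(out)]
}

#' Serialize / restore a risk model as JSON
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @return `write_risk_model` invisibly returns `path`;
#'   `read_risk_model` returns the `risk_model`.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  prov <- model$provenance
  prov <- prov[!vapply(prov, is.function, logical(1))]
  jsonlite::write_json(
    list(
      genes = model$genes,
      beta = as.list(model$beta),
      epsilon = model$epsilon,
      cutoff = model$cutoff,
      provenance = prov
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_model(
    genes = x$genes,
    beta = unlist(x$beta)[x$genes],
    epsilon = x$epsilon,
    cutoff = x$cutoff,
    provenance = as.list(x$provenance)
  )
}
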