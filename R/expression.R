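#' Validate a genes x samples expression matrix
#'
#' Checks the structural invariants assumed throughout the package: a
#' numeric matrix with unique, non-empty gene identifiers as rownames and
#' unique sample identifiers as colnames, all values finite, at least two
#' genes and one sample. Values are expected on a log scale (e.g. log2
#' intensities or log2(FPKM + offset)); only the pairwise orderings within
#' each sample are consumed by the signature machinery, so any strictly
#' monotone per-sample scale is acceptable.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (nrow(x) < 2L)
    stop("expression matrix must contain at least 2 genes")
  if (ncol(x) < 1L)
    stop("expression matrix must contain at least 1 sample")
  dg <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dg))
    stop("duplicate gene id(s): ", paste(dg, collapse = ", "))
  ds <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(ds))
    stop("duplicate sample id(s): ", paste(ds, collapse = ", "))
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  invisible(x)
}

#' Read a genes x samples expression matrix from TSV
#'
#' Expects tab-separated text with a header row of sample identifiers and
#' gene identifiers in the first column (the first header cell is
#' ignored). For linear-scale input such as FPKM, pass `log_offset` to
#' apply `log2(x + log_offset)`; the default offset of 1 avoids minus
#' infinity at zero.
#'
#' @param path path to a TSV file.
#' @param log_offset non-negative offset for log2 transformation of
#'   linear-scale values, or `NULL` (default) when values are already on
#'   a log scale.
#' @return validated numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path, log_offset = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression TSV must have a gene column and at least one sample column")
  genes <- raw[[1L]]
  dg <- unique(genes[duplicated(genes)])
  if (length(dg))
    stop("duplicate gene id(s) in ", path, ": ", paste(dg, collapse = ", "))
  samples <- colnames(raw)[-1L]
  ds <- unique(samples[duplicated(samples)])
  if (length(ds))
    stop("duplicate sample id(s) in ", path, ": ", paste(ds, collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row %d (gene '%s'), column %d (sample '%s')",
                 bad[1L, 1L], genes[bad[1L, 1L]], bad[1L, 2L], samples[bad[1L, 2L]]))
  }
  dimnames(vals) <- list(genes, samples)
  if (!is.null(log_offset)) {
    if (!is.numeric(log_offset) || length(log_offset) != 1L || log_offset < 0)
      stop("log_offset must be a single non-negative number")
    vals <- log2(vals + log_offset)
  }
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()] (without the log transform);
#' values are written with full precision so a read/write round trip is
#' exact.
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map from two-column TSV
#'
#' Probes that map to no gene or to more than one distinct gene are
#' dropped (with a warning), so each retained probe maps to exactly one
#' gene.
#'
#' @param path two-column TSV (probe_id, gene_id), no header by default.
#' @param header logical; whether the file has a header row.
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path, header = FALSE) {
  raw <- utils::read.delim(path, header = header, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("probe map must have two columns: probe_id, gene_id")
  probe_map(raw[[1L]], raw[[2L]])
}

#' Construct a probe-to-gene map
#'
#' @param probe_id character vector of probe identifiers.
#' @param gene_id character vector of gene identifiers, aligned.
#' @return data.frame with columns `probe_id`, `gene_id`, one row per
#'   retained (unambiguous) probe.
#' @export
probe_map <- function(probe_id, gene_id) {
  stopifnot(length(probe_id) == length(gene_id))
  keep <- !is.na(gene_id) & nzchar(gene_id)
  pm <- unique(data.frame(probe_id = probe_id[keep], gene_id = gene_id[keep],
                          stringsAsFactors = FALSE))
  multi <- unique(pm$probe_id[duplicated(pm$probe_id)])
  if (length(multi)) {
    warning(length(multi), " probe(s) mapping to multiple genes dropped")
    pm <- pm[!pm$probe_id %in% multi, , drop = FALSE]
  }
  rownames(pm) <- NULL
  pm
}

#' Collapse a probe-level matrix to gene level by averaging
#'
#' Each gene's value in a sample is the arithmetic mean of that gene's
#' valid probes in that sample; probes absent from the matrix are ignored
#' with a warning, and ambiguous probes never reach this point (see
#' [probe_map()]).
#'
#' @param probe_matrix numeric matrix keyed by probe_id in rows.
#' @param map probe map as returned by [probe_map()].
#' @return gene-level expression matrix.
#' @export
collapse_probes <- function(probe_matrix, map) {
  if (!is.matrix(probe_matrix) || is.null(rownames(probe_matrix)))
    stop("probe_matrix must be a matrix with probe rownames")
  present <- map$probe_id %in% rownames(probe_matrix)
  if (any(!present))
    warning(sum(!present), " mapped probe(s) absent from matrix; ignored")
  map <- map[present, , drop = FALSE]
  if (nrow(map) == 0L) stop("no valid probe remains after mapping")
  sub <- probe_matrix[map$probe_id, , drop = FALSE]
  grp <- factor(map$gene_id, levels = sort(unique(map$gene_id)))
  out <- rowsum(sub, grp) / as.vector(table(grp))
  out <- as.matrix(out)
  colnames(out) <- colnames(probe_matrix)
  validate_expression_matrix(out)
  out
}

#' Intersect the gene universes of two or more expression matrices
#'
#' @param ... two or more expression matrices (or a single list of them).
#' @return sorted character vector of genes measured in every matrix.
#' @export
intersect_gene_universe <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]]))
    mats <- mats[[1L]]
  if (length(mats) < 2L) stop("need at least two expression matrices")
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0L) stop("gene universes are disjoint: empty intersection")
  sort(common)
}
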