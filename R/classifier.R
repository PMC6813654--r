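#' Classify samples by strict-majority REO voting
#'
#' For each sample, counts the signature pairs whose favorable ordering
#' (Ea > Eb) holds within that sample; the sample is called a responder
#' iff the count strictly exceeds half the signature size (for the
#' four-pair signature: more than two of the four). Each sample's call
#' depends only on that sample's own values, so single samples can be
#' classified without a reference cohort and the call is invariant to
#' any strictly increasing per-sample transformation.
#'
#' @param expr expression matrix containing every signature gene.
#' @param signature a `gps_signature`.
#' @return data.frame of class `gps_prediction` with columns
#'   `sample_id`, `vote_count`, `label` ("responder"/"non_responder").
#' @export
vote_classify <- function(expr, signature) {
  stopifnot(inherits(signature, "gps_signature"))
  validate_expression_matrix(expr)
  genes <- unique(c(signature$pairs$gene_a, signature$pairs$gene_b))
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g))
    stop("signature gene(s) missing from matrix: ", paste(missing_g, collapse = ", "))
  k <- nrow(signature$pairs)
  fav <- expr[signature$pairs$gene_a, , drop = FALSE] >
         expr[signature$pairs$gene_b, , drop = FALSE]
  votes <- colSums(fav)
  out <- data.frame(sample_id = colnames(expr),
                    vote_count = as.integer(votes),
                    label = ifelse(votes > k / 2, "responder", "non_responder"),
                    stringsAsFactors = FALSE)
  class(out) <- c("gps_prediction", "data.frame")
  out
}

#' The published four-pair ovarian-cancer signature (4-GPS)
#'
#' The shipped constant signature for predicting response to
#' platinum-taxane adjuvant chemotherapy in high-grade serous ovarian
#' cancer: oriented pairs FUS > THBS2, GUCY2C > RCVRN, PCSK6 > ZNF365
#' and PASK > DNAJB14 with the strict-majority rule (responder iff more
#' than two of the four favorable orderings hold).
#'
#' @return a `gps_signature` of four oriented pairs.
#' @export
four_gps <- function() {
  gps_signature(gene_pairs(
    gene_a = c("FUS", "GUCY2C", "PCSK6", "PASK"),
    gene_b = c("THBS2", "RCVRN", "ZNF365", "DNAJB14")
  ))
}

#' Specification of a median-anchored point-score comparator
#'
#' Quantitative comparator of the k-TSP-style vote: one point per gene
#' whose expression falls on the favorable side of the cohort median,
#' high risk when the total is strictly below `threshold`. Direction
#' `high_good` means high expression was associated with longer survival
#' in the comparator's own training data.
#'
#' @param gene character vector of gene ids.
#' @param direction per gene, `"high_good"` or `"high_bad"`.
#' @param threshold integer risk cut-off in `[0, length(gene)]`; samples
#'   scoring strictly below it are called high-risk (non-responder).
#' @return object of class `quant_signature_spec`.
#' @export
quant_signature_spec <- function(gene, direction, threshold) {
  if (length(gene) < 1L) stop("comparator needs at least one gene")
  if (length(direction) != length(gene) ||
      !all(direction %in% c("high_good", "high_bad")))
    stop("direction must be 'high_good' or 'high_bad' per gene")
  if (anyDuplicated(gene)) stop("duplicate gene in comparator spec")
  if (threshold < 0 || threshold > length(gene))
    stop("threshold must lie in [0, number of genes]")
  structure(list(genes = data.frame(gene = as.character(gene),
                                    direction = direction,
                                    stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "quant_signature_spec")
}

#' Read a comparator spec from JSON
#' @param path JSON with fields `genes` (array of {gene, direction}) and
#'   `threshold`.
#' @return a `quant_signature_spec`.
#' @export
read_quant_signature_spec <- function(path) {
  obj <- jsonlite::fromJSON(path)
  quant_signature_spec(obj$genes$gene, obj$genes$direction, obj$threshold)
}

#' Classify samples by the median-anchored point score
#'
#' For each gene, a sample earns one point when its value is strictly
#' above the cohort median of that gene (direction `high_good`) or
#' strictly below it (`high_bad`); values exactly at the median earn no
#' point. A sample is high-risk (non-responder) iff its total score is
#' strictly below the spec's threshold. Because the anchor is the median
#' over the supplied cohort, a sample's label can change when the cohort
#' around it changes — unlike the REO vote, this rule cannot classify a
#' single sample in isolation.
#'
#' @param expr expression matrix with at least two samples.
#' @param spec a `quant_signature_spec`.
#' @return data.frame of class `gps_prediction` with columns
#'   `sample_id`, `score`, `label`.
#' @export
quant_score_classify <- function(expr, spec) {
  stopifnot(inherits(spec, "quant_signature_spec"))
  validate_expression_matrix(expr)
  if (ncol(expr) < 2L)
    stop("comparator requires a cohort: at least two samples")
  missing_g <- setdiff(spec$genes$gene, rownames(expr))
  if (length(missing_g))
    stop("comparator gene(s) missing from matrix: ", paste(missing_g, collapse = ", "))
  sub <- expr[spec$genes$gene, , drop = FALSE]
  med <- apply(sub, 1L, stats::median)
  up <- sub > med
  down <- sub < med
  good <- spec$genes$direction == "high_good"
  pts <- up * good + down * (!good)
  score <- colSums(pts)
  out <- data.frame(sample_id = colnames(expr),
                    score = as.integer(score),
                    label = ifelse(score < spec$threshold,
                                   "non_responder", "responder"),
                    stringsAsFactors = FALSE)
  class(out) <- c("gps_prediction", "data.frame")
  out
}

#' Write a prediction table to TSV
#' @param predictions a `gps_prediction` data.frame.
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
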