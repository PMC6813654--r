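#' Construct an oriented gene-pair table
#'
#' An oriented pair (a, b) encodes the convention that the favorable
#' within-sample ordering is Ea > Eb (associated with longer
#' recurrence-free survival). Pairs are held as a data.frame so that
#' pair-level statistics (hazard ratio of the favorable pattern, Wald p,
#' BH-adjusted q, single-pair concordance index) travel with them.
#'
#' @param gene_a,gene_b character vectors of gene identifiers (favorable
#'   pattern: `gene_a` above `gene_b`).
#' @param hr,p,q,cindex optional aligned pair-level statistics.
#' @return data.frame of class `gene_pairs`.
#' @export
gene_pairs <- function(gene_a, gene_b, hr = NA_real_, p = NA_real_,
                       q = NA_real_, cindex = NA_real_) {
  if (any(gene_a == gene_b)) stop("a pair must join two distinct genes")
  n <- length(gene_a)
  df <- data.frame(gene_a = as.character(gene_a), gene_b = as.character(gene_b),
                   hr = rep_len(hr, n), p = rep_len(p, n), q = rep_len(q, n),
                   cindex = rep_len(cindex, n), stringsAsFactors = FALSE)
  key <- pair_key(df)
  if (anyDuplicated(key)) stop("duplicate unordered pair: ", key[duplicated(key)][1L])
  class(df) <- c("gene_pairs", "data.frame")
  df
}

pair_key <- function(pairs) {
  paste(pmin(pairs$gene_a, pairs$gene_b), pmax(pairs$gene_a, pairs$gene_b), sep = "|")
}

pair_name <- function(pairs) paste(pairs$gene_a, pairs$gene_b, sep = ">")

#' Construct a majority-voting gene-pair signature
#'
#' A signature is an ordered set of oriented pairs plus the
#' strict-majority voting rule: a sample is called a responder iff the
#' number of pairs showing the favorable ordering (Ea > Eb) strictly
#' exceeds half the signature size.
#'
#' @param pairs a `gene_pairs` table (or data.frame with columns
#'   `gene_a`, `gene_b`).
#' @param training_cindex optional concordance index achieved on the
#'   training cohort.
#' @return object of class `gps_signature`.
#' @export
gps_signature <- function(pairs, training_cindex = NA_real_) {
  if (!is.data.frame(pairs) || nrow(pairs) < 1L)
    stop("signature needs at least one gene pair")
  if (!all(c("gene_a", "gene_b") %in% names(pairs)))
    stop("pairs must have columns gene_a, gene_b")
  if (!inherits(pairs, "gene_pairs"))
    pairs <- gene_pairs(pairs$gene_a, pairs$gene_b)
  if (anyDuplicated(pair_key(pairs))) stop("duplicate unordered pair in signature")
  structure(list(pairs = pairs, rule = "strict_majority",
                 training_cindex = training_cindex),
            class = "gps_signature")
}

#' @export
print.gps_signature <- function(x, ...) {
  k <- nrow(x$pairs)
  cat(sprintf("Gene-pair signature: %d pair(s), strict-majority vote (responder iff > %g favorable)\n",
              k, k / 2))
  cat(paste0("  ", pair_name(x$pairs), collapse = "\n"), "\n")
  if (!is.na(x$training_cindex))
    cat(sprintf("  training C-index: %.3f\n", x$training_cindex))
  invisible(x)
}

#' @export
length.gps_signature <- function(x) nrow(x$pairs)

#' Serialize a signature to JSON
#'
#' Fixed key order (`pairs`, `rule`, `training_cindex`) so serialized
#' signatures diff cleanly.
#'
#' @param signature a `gps_signature`.
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "gps_signature"))
  obj <- list(
    pairs = lapply(seq_len(nrow(signature$pairs)), function(i)
      list(gene_a = signature$pairs$gene_a[i], gene_b = signature$pairs$gene_b[i])),
    rule = signature$rule,
    training_cindex = if (is.na(signature$training_cindex)) NULL
                      else signature$training_cindex
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' Read a signature from JSON
#' @param path path written by [write_signature()].
#' @return a `gps_signature`.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tc <- if (is.null(obj$training_cindex)) NA_real_ else obj$training_cindex
  gps_signature(gene_pairs(obj$pairs$gene_a, obj$pairs$gene_b), training_cindex = tc)
}
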