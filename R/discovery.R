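#' Select differentially expressed genes between response groups
#'
#' Step 1a of signature discovery: pooled-variance two-sample t-test of
#' each gene between pathological complete-response (CR) and
#' non-complete-response (nonCR) samples; genes with two-sided p strictly
#' below `alpha` are retained. Samples with a missing response state are
#' excluded; genes with zero pooled variance are skipped with a warning.
#'
#' @param expr expression matrix (genes x samples).
#' @param response_states character vector aligned with the samples of
#'   `expr` ("CR", "nonCR" or NA).
#' @param alpha strict p-value threshold, default 0.05.
#' @return character vector of selected gene ids (expression-matrix row
#'   order).
#' @export
select_de_genes <- function(expr, response_states, alpha = 0.05) {
  validate_expression_matrix(expr)
  if (length(response_states) != ncol(expr))
    stop("response_states must align with the samples of expr")
  use <- !is.na(response_states)
  g1 <- expr[, use & response_states == "CR", drop = FALSE]
  g2 <- expr[, use & response_states == "nonCR", drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  if (n1 < 2L || n2 < 2L) stop("each response group needs at least 2 samples")
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  degenerate <- sp2 == 0
  if (any(degenerate))
    warning(sum(degenerate), " gene(s) with zero pooled variance skipped")
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  rownames(expr)[!degenerate & p < alpha]
}

#' Select prognostic genes by univariate Cox on expression
#'
#' Step 1b: each candidate gene's continuous expression enters a
#' univariate Cox model; genes with Wald p strictly below `alpha` are
#' retained. Degenerate (constant) genes and non-converged fits are
#' excluded with a warning.
#'
#' @param expr expression matrix.
#' @param times,events survival outcome aligned with the samples.
#' @param candidate_genes genes to test (must be rows of `expr`).
#' @param alpha strict p-value threshold, default 0.05.
#' @return character vector of selected gene ids (candidate order).
#' @export
select_prognostic_genes <- function(expr, times, events, candidate_genes,
                                    alpha = 0.05) {
  validate_expression_matrix(expr)
  if (length(candidate_genes) == 0L) return(character(0))
  missing_g <- setdiff(candidate_genes, rownames(expr))
  if (length(missing_g))
    stop("candidate gene(s) not in matrix: ", paste(missing_g, collapse = ", "))
  n_skipped <- 0L
  keep <- vapply(candidate_genes, function(g) {
    f <- tryCatch(cox_fit(expr[g, ], times, events), error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      n_skipped <<- n_skipped + 1L
      return(FALSE)
    }
    f$wald_p_values[1L] < alpha
  }, logical(1))
  if (n_skipped > 0L)
    warning(n_skipped, " gene-level Cox fit(s) degenerate or non-converged; excluded")
  candidate_genes[keep]
}

#' Enumerate all candidate gene pairs
#'
#' All C(m, 2) unordered pairs of the given genes, in lexicographic
#' order (so enumeration is deterministic).
#'
#' @param genes character vector of at least two distinct gene ids.
#' @return `gene_pairs` table with `gene_a < gene_b` lexicographically.
#' @export
enumerate_candidate_pairs <- function(genes) {
  if (anyDuplicated(genes)) stop("duplicate gene in input")
  if (length(genes) < 2L) stop("need at least two genes to form pairs")
  g <- sort(genes)
  idx <- utils::combn(length(g), 2L)
  gene_pairs(g[idx[1L, ]], g[idx[2L, ]])
}

#' Within-sample relative expression ordering (REO) indicator
#'
#' For a pair (a, b), the indicator is 1 in samples where Ea > Eb
#' strictly and 0 otherwise (ties count as not-favorable; they have
#' measure zero in continuous data). The indicator depends only on the
#' rank relation within each sample, so it is invariant to any strictly
#' increasing per-sample transformation.
#'
#' @param expr expression matrix.
#' @param gene_a,gene_b gene ids (single pair).
#' @return named integer vector (one per sample) of 0/1.
#' @export
reo_indicator <- function(expr, gene_a, gene_b) {
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(expr)) stop("gene not in matrix: ", g)
  stats::setNames(as.integer(expr[gene_a, ] > expr[gene_b, ]), colnames(expr))
}

#' Select prognostic gene pairs by REO under FDR control
#'
#' Step 2: for every candidate pair, the binary REO indicator enters a
#' univariate Cox model; pairs are oriented so that the favorable pattern
#' (indicator = 1) has hazard ratio < 1, Wald p-values are BH-adjusted
#' over all tested pairs, and pairs with adjusted value strictly below
#' `fdr` are retained. Each selected pair carries the concordance index
#' of its own single-pair vote (risk 1 for the unfavorable ordering).
#'
#' @param expr expression matrix.
#' @param candidate_pairs `gene_pairs` table (orientation ignored).
#' @param times,events survival outcome aligned with samples.
#' @param fdr strict threshold on BH-adjusted values, default 0.05.
#' @return `gene_pairs` table of selected oriented pairs with `hr`, `p`,
#'   `q`, `cindex`, ordered by `q` then pair name.
#' @export
select_prognostic_pairs <- function(expr, candidate_pairs, times, events,
                                    fdr = 0.05) {
  validate_expression_matrix(expr)
  np <- nrow(candidate_pairs)
  if (np < 1L) stop("no candidate pairs")
  a <- candidate_pairs$gene_a; b <- candidate_pairs$gene_b
  res <- vector("list", np)
  n_dropped <- 0L
  for (i in seq_len(np)) {
    ind <- reo_indicator(expr, a[i], b[i])
    f <- tryCatch(cox_fit(ind, times, events), error = function(e) NULL)
    if (is.null(f) || !f$converged) { n_dropped <- n_dropped + 1L; next }
    beta <- f$coefficients[1L]
    if (exp(beta) <= 1) {
      res[[i]] <- list(gene_a = a[i], gene_b = b[i], hr = exp(beta),
                       p = f$wald_p_values[1L])
    } else {  # flip orientation so the favorable pattern has HR < 1
      res[[i]] <- list(gene_a = b[i], gene_b = a[i], hr = exp(-beta),
                       p = f$wald_p_values[1L])
    }
  }
  if (n_dropped > 0L)
    warning(n_dropped, " pair-level Cox fit(s) failed or degenerate; dropped")
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    return(gene_pairs(character(0), character(0)))
  tab <- do.call(rbind, lapply(res, as.data.frame, stringsAsFactors = FALSE))
  tab$q <- bh_fdr(tab$p)
  tab <- tab[tab$q < fdr, , drop = FALSE]
  if (nrow(tab) == 0L) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      hr = numeric(0), p = numeric(0), q = numeric(0),
                      cindex = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("gene_pairs", "data.frame")
    return(out)
  }
  tab$cindex <- vapply(seq_len(nrow(tab)), function(i) {
    risk <- 1 - reo_indicator(expr, tab$gene_a[i], tab$gene_b[i])
    concordance_index(risk, times, events)
  }, numeric(1))
  ord <- order(tab$q, paste(tab$gene_a, tab$gene_b, sep = ">"))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  gene_pairs(tab$gene_a, tab$gene_b, hr = tab$hr, p = tab$p, q = tab$q,
             cindex = tab$cindex)
}

#' Concordance index of a pair set's majority vote
#'
#' Classifies samples by the strict-majority vote of the given pairs
#' (risk score 1 for predicted non-responders, 0 for responders) and
#' returns the concordance of that score with survival.
#'
#' @param expr expression matrix.
#' @param pairs `gene_pairs` table (>= 1 pair).
#' @param times,events survival outcome.
#' @return concordance index.
#' @export
signature_cindex <- function(expr, pairs, times, events) {
  pred <- vote_classify(expr, gps_signature(pairs))
  concordance_index(as.numeric(pred$label == "non_responder"), times, events)
}

#' Greedy forward selection of a majority-voting signature
#'
#' Step 3: every prognostic pair serves once as a seed; from each seed
#' the remaining pair that most improves the majority-vote concordance
#' index is added, one at a time, until no addition strictly increases
#' it. Among all seed-grown sets the one with the largest final C-index
#' wins. Ties are broken deterministically: during growth, equal C-index
#' candidates (within 1e-12) are resolved by smallest pair-level q then
#' lexicographic pair name; among final sets, by largest C-index, then
#' fewest pairs, then lexicographic names.
#'
#' @param expr expression matrix.
#' @param prognostic_pairs `gene_pairs` from [select_prognostic_pairs()].
#' @param times,events survival outcome.
#' @return list with `signature` (a `gps_signature` whose
#'   `training_cindex` is the winning C-index) and `trace` (per-seed
#'   growth paths: data.frame with seed, step, added pair, C-index).
#' @export
forward_select_signature <- function(expr, prognostic_pairs, times, events) {
  np <- nrow(prognostic_pairs)
  if (is.null(np) || np < 1L) stop("prognostic_pairs is empty")
  validate_expression_matrix(expr)
  check_survival(times, events)
  eps <- 1e-12

  # oriented indicator matrix, pairs x samples, computed once
  ind <- matrix(0L, nrow = np, ncol = ncol(expr))
  for (i in seq_len(np))
    ind[i, ] <- reo_indicator(expr, prognostic_pairs$gene_a[i],
                              prognostic_pairs$gene_b[i])
  comp <- outer(times, times, "<") & (events == 1)
  n_comp <- sum(comp)
  if (n_comp == 0L) stop("no comparable pair")
  set_cindex <- function(members) {
    votes <- colSums(ind[members, , drop = FALSE])
    risk <- as.numeric(votes <= length(members) / 2)  # non-responder = 1
    (sum(comp & outer(risk, risk, ">")) +
       0.5 * sum(comp & outer(risk, risk, "=="))) / n_comp
  }

  nm <- pair_name(prognostic_pairs)
  qv <- if (all(is.na(prognostic_pairs$q))) rep(Inf, np) else prognostic_pairs$q
  trace <- list()
  best <- NULL
  for (seed in seq_len(np)) {
    members <- seed
    current <- set_cindex(members)
    path <- data.frame(seed = nm[seed], step = 1L, added = nm[seed],
                       cindex = current, stringsAsFactors = FALSE)
    repeat {
      remaining <- setdiff(seq_len(np), members)
      if (length(remaining) == 0L) break
      cand_c <- vapply(remaining, function(j) set_cindex(c(members, j)), numeric(1))
      top <- remaining[cand_c >= max(cand_c) - eps]
      pick <- top[order(qv[top], nm[top])][1L]
      pick_c <- cand_c[match(pick, remaining)]
      if (pick_c <= current + eps) break
      members <- c(members, pick)
      current <- pick_c
      path <- rbind(path, data.frame(seed = nm[seed], step = length(members),
                                     added = nm[pick], cindex = current,
                                     stringsAsFactors = FALSE))
    }
    trace[[seed]] <- path
    cand <- list(members = members, cindex = current,
                 key = paste(sort(nm[members]), collapse = ","))
    if (is.null(best) ||
        cand$cindex > best$cindex + eps ||
        (abs(cand$cindex - best$cindex) <= eps &&
         (length(cand$members) < length(best$members) ||
          (length(cand$members) == length(best$members) && cand$key < best$key))))
      best <- cand
  }
  sig_pairs <- prognostic_pairs[best$members, , drop = FALSE]
  rownames(sig_pairs) <- NULL
  list(signature = gps_signature(sig_pairs, training_cindex = best$cindex),
       trace = do.call(rbind, trace))
}
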