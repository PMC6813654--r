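stage_error <- function(stage, msg) {
  stop(errorCondition(sprintf("discovery stage '%s' left no survivors: %s", stage, msg),
                      stage = stage,
                      class = c("reosig_stage_error", "error", "condition")))
}

align_clinical <- function(expr, clinical) {
  validate_expression_matrix(expr)
  validate_clinical_table(clinical)
  miss <- setdiff(colnames(expr), clinical$sample_id)
  if (length(miss))
    stop("sample(s) missing from clinical table: ", paste(miss, collapse = ", "))
  clinical[match(colnames(expr), clinical$sample_id), , drop = FALSE]
}

#' Run the full signature-discovery pipeline
#'
#' Orchestrates discovery end to end: follow-up truncation at 60 months,
#' differential-expression screening between CR and nonCR samples,
#' prognostic-gene screening by univariate Cox on expression, oriented
#' gene-pair REO screening under BH false-discovery-rate control, and
#' greedy forward selection of the majority-voting signature by
#' concordance index. Any stage that leaves no survivors raises a
#' structured error of class `reosig_stage_error` naming the stage.
#'
#' @param expr expression matrix (genes x samples).
#' @param clinical clinical table covering every sample (needs
#'   `response_state` for the DE stage).
#' @param de_alpha strict p threshold for the DE t-test stage (default
#'   0.05).
#' @param cox_alpha strict p threshold for the gene-level Cox stage
#'   (default 0.05).
#' @param pair_fdr strict BH-adjusted threshold for the pair stage
#'   (default 0.05).
#' @param horizon_months follow-up truncation horizon (default 60;
#'   `NULL` to skip truncation).
#' @return object of class `discovery_result`: list with `signature`,
#'   `stage_counts` (named integer vector: genes, de_genes,
#'   prognostic_genes, candidate_pairs, prognostic_pairs,
#'   signature_pairs) and the forward-selection `trace`.
#' @export
run_discovery <- function(expr, clinical, de_alpha = 0.05, cox_alpha = 0.05,
                          pair_fdr = 0.05, horizon_months = 60) {
  clinical <- align_clinical(expr, clinical)
  if (!"response_state" %in% names(clinical))
    stop("clinical table needs response_state for the DE stage")
  if (!is.null(horizon_months))
    clinical <- truncate_followup(clinical, horizon_months)
  times <- clinical$rfs_months; events <- clinical$event

  de <- select_de_genes(expr, clinical$response_state, alpha = de_alpha)
  if (length(de) == 0L) stage_error("de_genes", "no differentially expressed gene")

  prog <- select_prognostic_genes(expr, times, events, de, alpha = cox_alpha)
  if (length(prog) == 0L) stage_error("prognostic_genes", "no prognostic gene")
  if (length(prog) < 2L)
    stage_error("candidate_pairs", "fewer than two prognostic genes")

  cand <- enumerate_candidate_pairs(prog)
  pairs <- select_prognostic_pairs(expr, cand, times, events, fdr = pair_fdr)
  if (nrow(pairs) == 0L) stage_error("prognostic_pairs", "no pair passed FDR control")

  fs <- forward_select_signature(expr, pairs, times, events)
  structure(list(
    signature = fs$signature,
    stage_counts = c(genes = nrow(expr), de_genes = length(de),
                     prognostic_genes = length(prog),
                     candidate_pairs = nrow(cand),
                     prognostic_pairs = nrow(pairs),
                     signature_pairs = nrow(fs$signature$pairs)),
    trace = fs$trace
  ), class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("Signature discovery run\n  stage counts:\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("    %-18s %d\n", nm, x$stage_counts[[nm]]))
  print(x$signature)
  invisible(x)
}

validate_labels <- function(labels, clinical) {
  stopifnot(length(labels) == nrow(clinical),
            all(labels %in% c("responder", "non_responder")))
  times <- clinical$rfs_months; events <- clinical$event
  risk <- as.numeric(labels == "non_responder")
  sizes <- c(responder = sum(risk == 0), non_responder = sum(risk == 1))
  rep_out <- list(n = length(labels), group_sizes = sizes,
                  km = NULL, logrank = NULL, cox_signature = NULL,
                  cindex = NULL, screened_covariates = character(0),
                  cox_multivariate = NULL, n_used_multivariate = NA_integer_,
                  not_computable = character(0))

  rep_out$km <- lapply(split(seq_along(labels), labels), function(ii)
    km_estimate(times[ii], events[ii]))

  if (any(sizes == 0) || sum(events) == 0) {
    rep_out$not_computable <- paste(
      "group comparison not computable:",
      if (any(sizes == 0)) "a predicted group is empty" else "no observed event")
    class(rep_out) <- "validation_report"
    return(rep_out)
  }
  rep_out$logrank <- logrank_test(labels, times, events)
  rep_out$cox_signature <- cox_fit(cbind(non_responder = risk), times, events)
  rep_out$cindex <- concordance_index(risk, times, events)

  covs <- code_clinical_covariates(clinical)
  usable <- names(covs)[vapply(covs, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && max(v) > min(v)
  }, logical(1))]
  covs <- covs[usable]
  rep_out$screened_covariates <-
    if (length(covs)) cox_screen_univariate(covs, times, events, alpha = 0.2)
    else character(0)
  x_multi <- cbind(non_responder = risk,
                   as.matrix(covs[rep_out$screened_covariates]))
  fit_multi <- tryCatch(cox_fit(x_multi, times, events), error = function(e) NULL)
  if (!is.null(fit_multi)) {
    rep_out$cox_multivariate <- fit_multi
    rep_out$n_used_multivariate <- fit_multi$n_used
  }
  class(rep_out) <- "validation_report"
  rep_out
}

#' Validate a signature on a cohort with survival follow-up
#'
#' Classifies the cohort with the strict-majority vote and reports the
#' survival contrast between predicted groups: Kaplan-Meier curves per
#' group, the log-rank test, univariate Cox of the predicted label
#' (non-responder vs responder), Harrell's C-index, and a multivariate
#' Cox of the label adjusted for clinical covariates passing the
#' univariate p < 0.2 screen (complete-case; `n_used_multivariate`
#' reported). If a predicted group is empty the group-contrast
#' statistics are marked not computable instead of erroring.
#'
#' @param expr expression matrix.
#' @param clinical clinical table covering every sample.
#' @param signature a `gps_signature`.
#' @param horizon_months follow-up truncation horizon (default 60;
#'   `NULL` to skip).
#' @return object of class `validation_report`.
#' @export
validate_signature <- function(expr, clinical, signature, horizon_months = 60) {
  clinical <- align_clinical(expr, clinical)
  if (!is.null(horizon_months))
    clinical <- truncate_followup(clinical, horizon_months)
  pred <- vote_classify(expr, signature)
  out <- validate_labels(pred$label, clinical)
  out$predictions <- pred
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: n = %d (responders %d, non-responders %d)\n",
              x$n, x$group_sizes[["responder"]], x$group_sizes[["non_responder"]]))
  if (length(x$not_computable)) {
    cat(" ", x$not_computable, "\n")
    return(invisible(x))
  }
  cat(sprintf("  log-rank: chi-square = %.3f, p = %.3g\n",
              x$logrank$chi_square, x$logrank$p_value))
  cat(sprintf("  univariate Cox (non-responder vs responder): HR = %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$cox_signature$hazard_ratios[1L], x$cox_signature$ci95_lower[1L],
              x$cox_signature$ci95_upper[1L], x$cox_signature$wald_p_values[1L]))
  cat(sprintf("  C-index = %.3f\n", x$cindex))
  if (!is.null(x$cox_multivariate))
    cat(sprintf("  multivariate Cox (n_used = %d), adjusted for: %s; signature HR = %.2f, p = %.3g\n",
                x$n_used_multivariate,
                if (length(x$screened_covariates))
                  paste(x$screened_covariates, collapse = ", ") else "(none)",
                x$cox_multivariate$hazard_ratios[["non_responder"]],
                x$cox_multivariate$wald_p_values[["non_responder"]]))
  invisible(x)
}

#' Cross-tabulate predicted response with pathological response
#'
#' Builds the 2x2 confusion matrix of recorded pathological response
#' state (CR / nonCR) against the predicted label and applies Fisher's
#' exact test. Samples without both a prediction and a recorded state
#' are dropped.
#'
#' @param predictions a `gps_prediction` table.
#' @param clinical clinical table with `response_state`.
#' @return a `contingency_result` (Fisher's exact); the observed table
#'   has rows CR/nonCR and columns responder/non_responder.
#' @export
response_crosstab <- function(predictions, clinical) {
  validate_clinical_table(clinical)
  if (!"response_state" %in% names(clinical))
    stop("clinical table has no response_state column")
  m <- merge(predictions, clinical[c("sample_id", "response_state")],
             by = "sample_id")
  m <- m[!is.na(m$response_state), , drop = FALSE]
  if (nrow(m) == 0L) stop("no sample with both a prediction and a response state")
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("CR", "nonCR"), c("responder", "non_responder")))
  cnt <- table(factor(m$response_state, levels = rownames(tab)),
               factor(m$label, levels = colnames(tab)))
  tab[] <- as.integer(cnt)
  fisher_exact_2x2(tab)
}

#' Survival validation within a clinical subgroup
#'
#' Restricts a prediction/clinical pairing to a subgroup (for example
#' pathological CR patients) and reports the survival contrast of the
#' predicted groups inside it.
#'
#' @param predictions a `gps_prediction` table.
#' @param clinical clinical table covering the predicted samples.
#' @param subgroup_filter predicate taking the clinical data.frame and
#'   returning a logical vector, or a logical vector aligned with
#'   `clinical` rows.
#' @param horizon_months follow-up truncation horizon (default 60).
#' @return a `validation_report` for the subgroup.
#' @export
subgroup_survival <- function(predictions, clinical, subgroup_filter,
                              horizon_months = 60) {
  validate_clinical_table(clinical)
  keep <- if (is.function(subgroup_filter)) subgroup_filter(clinical)
          else as.logical(subgroup_filter)
  keep[is.na(keep)] <- FALSE
  sub <- clinical[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty subgroup after filtering")
  if (!is.null(horizon_months)) sub <- truncate_followup(sub, horizon_months)
  idx <- match(sub$sample_id, predictions$sample_id)
  if (anyNA(idx)) stop("subgroup sample(s) without predictions")
  validate_labels(predictions$label[idx], sub)
}

#' Compare recurrence-free survival across cohorts
#'
#' Pools one predicted group from cohort A with one predicted group from
#' cohort B and runs a two-group log-rank test between them (e.g.
#' responders of one cohort against non-responders of another).
#'
#' @param labels_a,labels_b predicted labels per cohort.
#' @param times_a,events_a,times_b,events_b survival outcomes aligned
#'   with the labels.
#' @param group_a,group_b which label to select from each cohort
#'   ("responder" or "non_responder").
#' @return a `logrank_result`.
#' @export
cross_cohort_comparison <- function(labels_a, times_a, events_a,
                                    labels_b, times_b, events_b,
                                    group_a = "responder",
                                    group_b = "non_responder") {
  sel_a <- labels_a == group_a
  sel_b <- labels_b == group_b
  if (!any(sel_a) || !any(sel_b)) stop("empty group selection")
  logrank_test(rep(c("A", "B"), c(sum(sel_a), sum(sel_b))),
               c(times_a[sel_a], times_b[sel_b]),
               c(events_a[sel_a], events_b[sel_b]))
}

#' Robustness of classifiers to batch distortion and degradation
#'
#' For each grid setting, perturbs the expression matrix (strictly
#' monotone per-sample distortion and/or additive noise + dropout),
#' re-classifies with the REO majority vote and with the
#' median-anchored comparator, and records each classifier's
#' label-concordance with its own clean labels, averaged over
#' replicates. Pure monotone distortion leaves the REO labels exactly
#' unchanged; the comparator has no such guarantee.
#'
#' @param expr clean expression matrix.
#' @param signature a `gps_signature`.
#' @param comparator_spec a `quant_signature_spec`.
#' @param grid data.frame with columns `family` (NA for no monotone
#'   distortion, else "affine"/"power"/"softplus"), `noise_sd`,
#'   `dropout` (0 for none).
#' @param reps replicates per grid point (>= 1).
#' @param seed integer seed.
#' @return data.frame of class `robustness_report`: grid columns plus
#'   `reo_concordance`, `quant_concordance`, `reps`.
#' @export
robustness_experiment <- function(expr, signature, comparator_spec, grid,
                                  reps = 5, seed = 1) {
  if (!is.data.frame(grid) ||
      !all(c("family", "noise_sd", "dropout") %in% names(grid)))
    stop("grid must be a data.frame with columns family, noise_sd, dropout")
  if (reps < 1) stop("reps must be >= 1")
  clean_reo <- vote_classify(expr, signature)$label
  clean_quant <- quant_score_classify(expr, comparator_spec)$label
  out <- grid
  out$reo_concordance <- NA_real_
  out$quant_concordance <- NA_real_
  out$reps <- as.integer(reps)
  for (g in seq_len(nrow(grid))) {
    acc_reo <- acc_quant <- numeric(reps)
    for (r in seq_len(reps)) {
      s <- (seed + 7919L * g + r) %% .Machine$integer.max
      pert <- expr
      if (!is.na(grid$family[g]))
        pert <- apply_monotone_distortion(pert, grid$family[g], seed = s)
      if (grid$noise_sd[g] > 0 || grid$dropout[g] > 0)
        pert <- degrade_samples(pert, grid$noise_sd[g], grid$dropout[g], seed = s)
      acc_reo[r] <- mean(vote_classify(pert, signature)$label == clean_reo)
      acc_quant[r] <- mean(quant_score_classify(pert, comparator_spec)$label == clean_quant)
    }
    out$reo_concordance[g] <- mean(acc_reo)
    out$quant_concordance[g] <- mean(acc_quant)
  }
  class(out) <- c("robustness_report", "data.frame")
  out
}
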