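planted_cohort <- function(seed = 7, ...) {
  generate_cohort(generator_config(seed = seed, ...))
}

test_that("discovery runs are reproducible and report per-stage counts", {
  co <- planted_cohort(n_samples = 200, n_genes = 60, planted_pairs = 3)
  a <- suppressWarnings(run_discovery(co$expression, co$clinical))
  b <- suppressWarnings(run_discovery(co$expression, co$clinical))
  expect_identical(a$signature$pairs, b$signature$pairs)
  expect_identical(a$stage_counts, b$stage_counts)
  expect_identical(a$trace, b$trace)
  expect_named(a$stage_counts, c("genes", "de_genes", "prognostic_genes",
                                 "candidate_pairs", "prognostic_pairs",
                                 "signature_pairs"))
  expect_true(all(a$stage_counts > 0))
  expect_gte(a$stage_counts[["de_genes"]], a$stage_counts[["prognostic_genes"]])
})

test_that("thresholds of 1 disable all filtering stages", {
  set.seed(71)
  n <- 60; ng <- 8
  expr <- rand_expr(ng, n)
  cl <- toy_clinical(rexp(n, 0.05), rbinom(n, 1, 0.8),
                     response_state = sample(c("CR", "nonCR"), n, replace = TRUE),
                     sample_ids = colnames(expr))
  res <- suppressWarnings(run_discovery(expr, cl, de_alpha = 1, cox_alpha = 1,
                                        pair_fdr = 1))
  expect_equal(res$stage_counts[["de_genes"]], ng)
  expect_equal(res$stage_counts[["prognostic_genes"]], ng)
  expect_equal(res$stage_counts[["prognostic_pairs"]], choose(ng, 2))
})

test_that("a cohort without survival signal fails discovery at a named stage", {
  n_err <- 0L
  for (s in 1:10) {
    co <- planted_cohort(seed = 300 + s, n_samples = 150, n_genes = 60,
                         planted_pairs = 2, nonresponder_hr = 1)
    res <- tryCatch(suppressWarnings(run_discovery(co$expression, co$clinical)),
                    reosig_stage_error = function(e) {
                      expect_true(e$stage %in% c("de_genes", "prognostic_genes",
                                                 "candidate_pairs",
                                                 "prognostic_pairs"))
                      "stage_error"
                    })
    if (identical(res, "stage_error")) n_err <- n_err + 1L
  }
  expect_gt(n_err, 5)  # null cohorts should mostly die at a screening stage
})

test_that("validation report agrees with its statistical components", {
  co <- planted_cohort(n_samples = 300, n_genes = 40, planted_pairs = 3)
  sig <- gps_signature(co$planted)
  rep_out <- validate_signature(co$expression, co$clinical, sig)
  expect_equal(sum(rep_out$group_sizes), 300)

  cl <- truncate_followup(co$clinical)
  pred <- vote_classify(co$expression, sig)
  risk <- as.numeric(pred$label == "non_responder")
  ref <- cox_fit(risk, cl$rfs_months, cl$event)
  expect_identical(rep_out$cox_signature$hazard_ratios[[1]],
                   ref$hazard_ratios[[1]])
  expect_identical(rep_out$cindex, concordance_index(risk, cl$rfs_months, cl$event))
  expect_gt(rep_out$cox_signature$hazard_ratios[[1]], 1.5)
  expect_lt(rep_out$logrank$p_value, 0.01)
  expect_false(is.null(rep_out$cox_multivariate))
  expect_identical(rep_out$n_used_multivariate, rep_out$cox_multivariate$n_used)
})

test_that("a degenerate prediction (one group empty) yields a marked, not crashed, report", {
  n <- 30
  expr <- toy_expr(0, c("hi", "lo"), sprintf("S%02d", 1:n))
  expr["hi", ] <- 2 + runif(n); expr["lo", ] <- runif(n)
  cl <- toy_clinical(rexp(n, 0.05), rbinom(n, 1, 0.8), sample_ids = colnames(expr))
  rep_out <- validate_signature(expr, cl, gps_signature(gene_pairs("hi", "lo")))
  expect_equal(rep_out$group_sizes[["non_responder"]], 0)
  expect_match(rep_out$not_computable, "empty")
  expect_null(rep_out$logrank)
})

test_that("the response cross-tab reproduces the printed confusion-matrix test", {
  # CR: 10 responders / 12 non-responders; nonCR: 2 / 14
  labels <- rep(c("responder", "non_responder", "responder", "non_responder"),
                c(10, 12, 2, 14))
  states <- rep(c("CR", "nonCR"), c(22, 16))
  ids <- sprintf("P%02d", 1:38)
  pred <- data.frame(sample_id = ids, vote_count = NA_integer_, label = labels,
                     stringsAsFactors = FALSE)
  cl <- toy_clinical(rep(10, 38), rep(0, 38), response_state = states,
                     sample_ids = ids)
  res <- response_crosstab(pred, cl)
  expect_equal(round(res$p_value, 4), 0.0403)
  expect_equal(res$observed["CR", "responder"], 10)
  expect_equal(res$observed["nonCR", "non_responder"], 14)

  # identical row proportions: no association
  pred2 <- pred; pred2$label <- rep(c("responder", "non_responder"), 19)
  cl2 <- cl; cl2$response_state <- rep(c("CR", "CR", "nonCR", "nonCR"), length.out = 38)
  expect_equal(response_crosstab(pred2, cl2)$p_value, 1)
})

test_that("subgroup validation restricts correctly and matches the full report when unfiltered", {
  co <- planted_cohort(n_samples = 250, n_genes = 40, planted_pairs = 3)
  sig <- gps_signature(co$planted)
  full <- validate_signature(co$expression, co$clinical, sig)
  sub_all <- subgroup_survival(full$predictions, co$clinical, rep(TRUE, 250))
  expect_identical(sub_all$cindex, full$cindex)
  expect_identical(sub_all$logrank$chi_square, full$logrank$chi_square)

  cr_only <- subgroup_survival(full$predictions, co$clinical,
                               function(cl) cl$response_state == "CR")
  expect_equal(cr_only$n, sum(co$clinical$response_state == "CR"))
  expect_error(subgroup_survival(full$predictions, co$clinical,
                                 function(cl) cl$rfs_months < 0),
               "empty subgroup")
})

test_that("cross-cohort contrasts reduce to the within-cohort test and detect planted signal", {
  co <- planted_cohort(n_samples = 200, n_genes = 40, planted_pairs = 3)
  sig <- gps_signature(co$planted)
  cl <- truncate_followup(co$clinical)
  pred <- vote_classify(co$expression, sig)
  within <- logrank_test(pred$label, cl$rfs_months, cl$event)
  crossed <- cross_cohort_comparison(pred$label, cl$rfs_months, cl$event,
                                     pred$label, cl$rfs_months, cl$event,
                                     group_a = "responder",
                                     group_b = "non_responder")
  expect_equal(crossed$chi_square, within$chi_square, tolerance = 1e-12)

  co2 <- planted_cohort(seed = 8, n_samples = 200, n_genes = 40, planted_pairs = 3)
  cl2 <- truncate_followup(co2$clinical)
  pred2 <- vote_classify(co2$expression, gps_signature(co2$planted))
  between <- cross_cohort_comparison(pred$label, cl$rfs_months, cl$event,
                                     pred2$label, cl2$rfs_months, cl2$event)
  expect_lt(between$p_value, 0.05)
  expect_error(cross_cohort_comparison(rep("responder", 3), 1:3, rep(1, 3),
                                       rep("responder", 3), 1:3, rep(1, 3)),
               "empty")
})

test_that("robustness experiment: REO votes survive monotone distortion exactly", {
  co <- planted_cohort(n_samples = 60, n_genes = 30, planted_pairs = 3)
  sig <- gps_signature(co$planted)
  spec <- quant_signature_spec(rownames(co$expression)[1:10],
                               rep(c("high_good", "high_bad"), 5), 5)
  grid <- data.frame(family = c(NA, "affine", "power", "softplus"),
                     noise_sd = 0, dropout = 0, stringsAsFactors = FALSE)
  rr <- robustness_experiment(co$expression, sig, spec, grid, reps = 3, seed = 2)
  expect_equal(rr$reo_concordance, rep(1, 4))       # monotone invariance
  expect_equal(rr$quant_concordance[1], 1)          # identity perturbation
  expect_true(all(rr$quant_concordance >= 0 & rr$quant_concordance <= 1))

  noisy <- robustness_experiment(co$expression, sig, spec,
                                 data.frame(family = NA, noise_sd = 0.5,
                                            dropout = 0.05),
                                 reps = 3, seed = 2)
  expect_true(noisy$reo_concordance <= 1 && noisy$reo_concordance >= 0)
})
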