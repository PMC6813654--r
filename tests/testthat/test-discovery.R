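test_that("DE-gene selection agrees with an independent t-test and handles degenerate genes", {
  set.seed(31)
  n <- 100
  states <- rep(c("CR", "nonCR"), each = n / 2)
  expr <- rand_expr(20, n)
  expr["G001", states == "CR"] <- expr["G001", states == "CR"] + 2  # 2-sigma shift
  expr["G020", ] <- 5  # constant gene

  sel <- suppressWarnings(select_de_genes(expr, states, alpha = 0.05))
  expect_true("G001" %in% sel)
  expect_warning(select_de_genes(expr, states), "zero pooled variance")
  expect_false("G020" %in% sel)
  expect_identical(suppressWarnings(select_de_genes(expr, states, alpha = 0)),
                   character(0))

  # decision agrees gene-by-gene with stats::t.test (independent route)
  for (g in sprintf("G%03d", 1:19)) {
    p_ref <- t.test(expr[g, states == "CR"], expr[g, states == "nonCR"],
                    var.equal = TRUE)$p.value
    expect_identical(g %in% sel, p_ref < 0.05)
  }
})

test_that("prognostic-gene selection keeps strong proportional-hazards genes", {
  set.seed(32)
  n <- 200
  expr <- rand_expr(5, n, mean = 0)
  tm <- rexp(n, 0.05 * exp(1 * expr["G001", ]))
  ev <- rep(1, n)
  sel <- select_prognostic_genes(expr, tm, ev, rownames(expr))
  expect_true("G001" %in% sel)
  expect_identical(select_prognostic_genes(expr, tm, ev, character(0)),
                   character(0))
  expect_error(select_prognostic_genes(expr, tm, ev, "NOPE"), "NOPE")
})

test_that("candidate-pair enumeration is complete, deterministic and validated", {
  g70 <- sprintf("g%02d", 1:70)
  expect_equal(nrow(enumerate_candidate_pairs(g70)), choose(70, 2))
  two <- enumerate_candidate_pairs(c("B", "A"))
  expect_equal(nrow(two), 1)
  expect_identical(two$gene_a, "A")  # lexicographic
  expect_error(enumerate_candidate_pairs(c("A", "A")), "duplicate")
  expect_error(enumerate_candidate_pairs("A"), "at least two")
})

test_that("REO indicator follows the strict-ordering convention and is rank-invariant", {
  expr <- toy_expr(c(5, 3, 3, 3), c("a", "b"), c("s1", "s2"))
  expect_identical(unname(reo_indicator(expr, "a", "b")), c(1L, 0L))  # tie -> 0
  expect_error(reo_indicator(expr, "a", "zz"), "zz")

  set.seed(33)
  expr2 <- rand_expr(10, 30)
  ind <- reo_indicator(expr2, "G003", "G007")
  for (i in 1:10)
    expect_identical(reo_indicator(random_monotone(expr2), "G003", "G007"), ind)
})

test_that("prognostic-pair selection orients pairs favorably under FDR control", {
  set.seed(34)
  n <- 150
  state <- rbinom(n, 1, 0.5) == 1      # responder latent state
  expr <- rand_expr(6, n)
  # planted: G001 > G002 iff responder (longer survival)
  gap <- ifelse(state, 1, -1) * abs(rnorm(n, 1, 0.3))
  expr["G001", ] <- 8 + gap / 2
  expr["G002", ] <- 8 - gap / 2
  tm <- rexp(n, 0.02 * ifelse(state, 1, 3))
  ev <- rep(1L, n)

  cand <- enumerate_candidate_pairs(rownames(expr))
  sel <- suppressWarnings(select_prognostic_pairs(expr, cand, tm, ev, fdr = 0.05))
  key <- paste(sel$gene_a, sel$gene_b)
  expect_true("G001 G002" %in% key)
  expect_true(all(sel$hr < 1))

  # reversed candidate orientation comes back flipped, HR < 1
  rev_cand <- gene_pairs("G002", "G001")
  sel2 <- suppressWarnings(select_prognostic_pairs(expr, rev_cand, tm, ev, fdr = 0.05))
  expect_identical(sel2$gene_a, "G001")
  expect_true(sel2$hr < 1)

  expect_equal(nrow(suppressWarnings(
    select_prognostic_pairs(expr, cand, tm, ev, fdr = 0))), 0)
})

test_that("signature C-index equals the concordance of the vote labels", {
  set.seed(35)
  expr <- rand_expr(6, 40)
  tm <- rexp(40, 0.05); ev <- rbinom(40, 1, 0.8)
  pairs <- gene_pairs(c("G001", "G003"), c("G002", "G004"))
  pred <- vote_classify(expr, gps_signature(pairs))
  expect_identical(signature_cindex(expr, pairs, tm, ev),
                   concordance_index(as.numeric(pred$label == "non_responder"),
                                     tm, ev))

  # single pair separating an uncensored cohort perfectly
  n <- 20
  sep <- toy_expr(0, c("a", "b", "c"), sprintf("S%02d", 1:n))
  sep["a", ] <- c(rep(2, 10), rep(0, 10)); sep["b", ] <- 1; sep["c", ] <- 5
  # within-group times tied so the only comparable pairs are between groups
  tm2 <- c(rep(100, 10), rep(1, 10)); ev2 <- rep(1, n)
  expect_equal(signature_cindex(sep, gene_pairs("a", "b"), tm2, ev2), 1)
})

test_that("forward selection is exhaustive-verified on small cases and well-formed", {
  # pair A perfect, pair B pure noise: {A} must win over {A,B}, {B}, {B,A}
  set.seed(36)
  n <- 30
  expr <- toy_expr(0, c("a1", "a2", "b1", "b2"), sprintf("S%02d", 1:n))
  good <- rep(c(TRUE, FALSE), each = n / 2)
  expr["a1", ] <- ifelse(good, 1, -1); expr["a2", ] <- 0
  expr["b1", ] <- rnorm(n); expr["b2", ] <- rnorm(n)
  tm <- ifelse(good, 100, 1) + runif(n); ev <- rep(1, n)
  pairs <- gene_pairs(c("a1", "b1"), c("a2", "b2"), q = c(0.01, 0.04))
  fs <- forward_select_signature(expr, pairs, tm, ev)
  # exhaustive evaluation of all candidate subsets
  cA <- signature_cindex(expr, pairs[1, ], tm, ev)
  cB <- signature_cindex(expr, pairs[2, ], tm, ev)
  cAB <- signature_cindex(expr, pairs, tm, ev)
  expect_true(cA >= max(cB, cAB))
  expect_identical(pair_names <- paste(fs$signature$pairs$gene_a,
                                       fs$signature$pairs$gene_b), "a1 a2")
  expect_equal(fs$signature$training_cindex, cA)

  # single prognostic pair: signature is that pair with its own C-index
  one <- forward_select_signature(expr, pairs[1, ], tm, ev)
  expect_equal(nrow(one$signature$pairs), 1)
  expect_equal(one$signature$training_cindex, cA)

  expect_error(forward_select_signature(expr, pairs[0, ], tm, ev), "empty")
})

test_that("forward selection satisfies its growth invariants on planted cohorts", {
  co <- generate_cohort(generator_config(n_samples = 200, n_genes = 60,
                                         planted_pairs = 3, seed = 101))
  cl <- truncate_followup(co$clinical)
  cand <- enumerate_candidate_pairs(unique(c(co$planted$gene_a, co$planted$gene_b)))
  pp <- suppressWarnings(select_prognostic_pairs(co$expression, cand,
                                                 cl$rfs_months, cl$event))
  expect_gt(nrow(pp), 0)
  fs <- forward_select_signature(co$expression, pp, cl$rfs_months, cl$event)
  # every selected pair comes from the candidate list
  expect_true(all(paste(fs$signature$pairs$gene_a, fs$signature$pairs$gene_b) %in%
                  paste(pp$gene_a, pp$gene_b)))
  # final C-index is at least the best single-pair C-index
  expect_gte(fs$signature$training_cindex, max(pp$cindex))
  # each seed's growth path strictly increases
  for (sd_path in split(fs$trace, fs$trace$seed))
    expect_true(all(diff(sd_path$cindex) > 0))
})

test_that("pair selection and forward selection are invariant to monotone distortion", {
  co <- generate_cohort(generator_config(n_samples = 150, n_genes = 40,
                                         planted_pairs = 2, seed = 102))
  cl <- truncate_followup(co$clinical)
  genes <- rownames(co$expression)[1:12]
  cand <- enumerate_candidate_pairs(genes)
  base_pp <- suppressWarnings(select_prognostic_pairs(
    co$expression, cand, cl$rfs_months, cl$event, fdr = 0.5))
  dist <- apply_monotone_distortion(co$expression, "affine", seed = 9)
  dist_pp <- suppressWarnings(select_prognostic_pairs(
    dist, cand, cl$rfs_months, cl$event, fdr = 0.5))
  expect_identical(base_pp, dist_pp)
  if (nrow(base_pp) > 0) {
    fs_a <- forward_select_signature(co$expression, base_pp, cl$rfs_months, cl$event)
    fs_b <- forward_select_signature(dist, base_pp, cl$rfs_months, cl$event)
    expect_identical(fs_a$signature$pairs, fs_b$signature$pairs)
    expect_identical(fs_a$signature$training_cindex, fs_b$signature$training_cindex)
  }
})
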