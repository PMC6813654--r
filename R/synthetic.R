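#' Configuration for the synthetic-cohort generator
#'
#' Defines the statistical structure the discovery pipeline assumes: a
#' latent responder/non-responder state, planted oriented gene pairs
#' whose within-sample orderings track the latent state with a
#' controllable error, exponential proportional-hazards survival whose
#' hazard depends on the latent state, uniform administrative censoring,
#' and CR/nonCR labels that misreport the latent state at a controllable
#' rate. Defaults describe a cohort of 300 patients with 150 measured
#' genes, 4 planted pairs flipping with probability 0.05, responder
#' prevalence 0.5, baseline hazard 0.02/month with hazard ratio 3 for
#' non-responders, censoring uniform on (0, 80) months and a 10%
#' response-label misclassification rate.
#'
#' @param n_samples cohort size.
#' @param n_genes number of measured genes (>= 2 * planted_pairs).
#' @param planted_pairs number k of planted oriented pairs.
#' @param reo_error probability in \[0, 0.5) that a planted pair's
#'   ordering contradicts the latent state in a sample.
#' @param responder_prevalence latent responder probability in (0, 1).
#' @param baseline_hazard responder hazard per month (> 0).
#' @param nonresponder_hr hazard multiplier (>= 1) for latent
#'   non-responders.
#' @param censoring_max upper bound (months) of uniform censoring (> 0).
#' @param response_misclass probability in \[0, 0.5) that the recorded
#'   CR/nonCR label contradicts the latent state.
#' @param noise_sd spread of the planted within-pair expression gap:
#'   the gap magnitude is folded normal with location 1 and this sd.
#' @param seed integer seed; the cohort is a deterministic function of
#'   the full configuration.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 300, n_genes = 150,
                             planted_pairs = 4, reo_error = 0.05,
                             responder_prevalence = 0.5,
                             baseline_hazard = 0.02, nonresponder_hr = 3,
                             censoring_max = 80, response_misclass = 0.1,
                             noise_sd = 0.5, seed = 1) {
  fail <- function(field) stop("invalid generator config field: ", field)
  if (!is.numeric(n_samples) || n_samples < 2) fail("n_samples")
  if (!is.numeric(n_genes) || n_genes < 2) fail("n_genes")
  if (!is.numeric(planted_pairs) || planted_pairs < 0 ||
      2 * planted_pairs > n_genes) fail("planted_pairs")
  if (!is.numeric(reo_error) || reo_error < 0 || reo_error >= 0.5) fail("reo_error")
  if (!is.numeric(responder_prevalence) || responder_prevalence <= 0 ||
      responder_prevalence >= 1) fail("responder_prevalence")
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0) fail("baseline_hazard")
  if (!is.numeric(nonresponder_hr) || nonresponder_hr < 1) fail("nonresponder_hr")
  if (!is.numeric(censoring_max) || censoring_max <= 0) fail("censoring_max")
  if (!is.numeric(response_misclass) || response_misclass < 0 ||
      response_misclass >= 0.5) fail("response_misclass")
  if (!is.numeric(noise_sd) || noise_sd < 0) fail("noise_sd")
  if (!is.numeric(seed) || seed != round(seed)) fail("seed")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 planted_pairs = as.integer(planted_pairs),
                 reo_error = reo_error,
                 responder_prevalence = responder_prevalence,
                 baseline_hazard = baseline_hazard,
                 nonresponder_hr = nonresponder_hr,
                 censoring_max = censoring_max,
                 response_misclass = response_misclass,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# background gene means are drawn on a log2-like scale in this range
.gene_mean_range <- c(4, 12)

# planted-pair midpoint model: the shared midpoint of a pair shifts with the
# latent state (so each planted gene is individually differentially expressed
# and prognostic, as the discovery screens require) and carries per-sample
# spread like any other gene; the shared shift cancels in cross-gene
# differences, so only the oriented within-pair gap tracks the state cleanly
.planted_state_shift <- 2
.planted_mid_sd <- 1

#' Generate a synthetic cohort with planted gene-pair signal
#'
#' Latent responder states are Bernoulli(prevalence). Background genes
#' are independent normals (per-gene mean uniform on \[4, 12\], sd 1 on
#' the log2-like scale). Each planted pair (a, b) is built around a
#' per-sample midpoint m ~ N(mid-gene mean, 1): a = m + d/2 and
#' b = m - d/2, where the gap d is positive for latent responders and
#' negative for non-responders, the sign is flipped independently with
#' probability `reo_error`, and |d| is folded normal(1, noise_sd).
#' Survival is exponential with hazard `baseline_hazard` for responders
#' times `nonresponder_hr` for non-responders; censoring is uniform on
#' (0, censoring_max); the recorded CR/nonCR state contradicts the
#' latent state with probability `response_misclass`. Clinical
#' covariates (age, stage, grade, residual tumor) are drawn from fixed
#' marginal distributions independent of the latent state.
#'
#' @param config a `generator_config`.
#' @return object of class `synthetic_cohort`: list with `expression`
#'   (genes x samples matrix), `clinical` (data.frame), `truth`
#'   (data.frame with `sample_id`, `responder`), `planted` (oriented
#'   `gene_pairs`; favorable ordering tracks the responder state) and
#'   the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_samples; ng <- config$n_genes; k <- config$planted_pairs
  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(ng))

  responder <- stats::rbinom(n, 1, config$responder_prevalence) == 1
  mu <- stats::runif(ng, .gene_mean_range[1L], .gene_mean_range[2L])
  expr <- matrix(stats::rnorm(ng * n, mean = mu, sd = 1), nrow = ng,
                 dimnames = list(gene_ids, sample_ids))

  if (k > 0) {
    planted_idx <- sample(ng, 2L * k)
    a_idx <- planted_idx[seq_len(k) * 2L - 1L]
    b_idx <- planted_idx[seq_len(k) * 2L]
    for (i in seq_len(k)) {
      mid <- stats::rnorm(n, mean = (mu[a_idx[i]] + mu[b_idx[i]]) / 2 +
                            .planted_state_shift * (responder - 0.5),
                          sd = .planted_mid_sd)
      flip <- stats::rbinom(n, 1, config$reo_error) == 1
      sgn <- ifelse(xor(responder, flip), 1, -1)
      gap <- sgn * abs(stats::rnorm(n, 1, config$noise_sd))
      expr[a_idx[i], ] <- mid + gap / 2
      expr[b_idx[i], ] <- mid - gap / 2
    }
    planted <- gene_pairs(gene_ids[a_idx], gene_ids[b_idx])
  } else {
    planted <- NULL
  }

  rate <- config$baseline_hazard *
    ifelse(responder, 1, config$nonresponder_hr)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, config$censoring_max)
  misreport <- stats::rbinom(n, 1, config$response_misclass) == 1

  clinical <- data.frame(
    sample_id = sample_ids,
    rfs_months = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    response_state = ifelse(xor(responder, misreport), "CR", "nonCR"),
    age = round(stats::rnorm(n, 61, 10)),
    stage = sample(c("II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.1, 0.7, 0.2)),
    grade = sample(c(2, 3), n, replace = TRUE, prob = c(0.2, 0.8)),
    residual = sample(c("0-10mm", ">=11mm"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  validate_clinical_table(clinical)
  structure(list(expression = expr, clinical = clinical,
                 truth = data.frame(sample_id = sample_ids,
                                    responder = responder,
                                    stringsAsFactors = FALSE),
                 planted = planted, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples, %d planted pair(s), %.0f%% events\n",
              nrow(x$expression), ncol(x$expression),
              if (is.null(x$planted)) 0L else nrow(x$planted),
              100 * mean(x$clinical$event)))
  invisible(x)
}

#' Apply a strictly monotone per-sample distortion
#'
#' Emulates batch effects: each sample's values pass through an
#' independently drawn strictly increasing function, so within-sample
#' orderings are preserved while absolute values (and cohort-level
#' medians) shift. Families: `affine` (scale in (0.5, 2), shift in
#' (-2, 2)), `power` (values shifted positive, exponent in (0.5, 2)),
#' `softplus` (scaled shifted softplus composite).
#'
#' @param expr expression matrix.
#' @param family one of "affine", "power", "softplus".
#' @param seed integer seed for the per-sample parameter draws.
#' @param params optional fixed parameters overriding the draws: for
#'   affine, list(scale=, shift=); for power, list(gamma=); for
#'   softplus, list(a=, b=). Non-monotone values (scale, gamma, a or b
#'   <= 0) are an error.
#' @return distorted expression matrix, same dimensions.
#' @export
apply_monotone_distortion <- function(expr, family = c("affine", "power", "softplus"),
                                      seed, params = NULL) {
  family <- match.arg(family)
  validate_expression_matrix(expr)
  set.seed(seed)
  n <- ncol(expr)
  draw <- function(fixed, lo, hi) {
    if (is.null(fixed)) stats::runif(n, lo, hi) else rep_len(fixed, n)
  }
  out <- expr
  if (family == "affine") {
    scale <- draw(params$scale, 0.5, 2)
    shift <- draw(params$shift, -2, 2)
    if (any(scale <= 0)) stop("non-monotone parameterization: scale must be > 0")
    out <- sweep(sweep(expr, 2L, scale, "*"), 2L, shift, "+")
  } else if (family == "power") {
    gamma <- draw(params$gamma, 0.5, 2)
    if (any(gamma <= 0)) stop("non-monotone parameterization: gamma must be > 0")
    for (j in seq_len(n))
      out[, j] <- (expr[, j] - min(expr[, j]) + 1)^gamma[j]
  } else {
    a <- draw(params$a, 0.5, 2)
    b <- draw(params$b, 0.5, 2)
    if (any(a <= 0) || any(b <= 0))
      stop("non-monotone parameterization: a and b must be > 0")
    ctr <- colMeans(expr)
    shift <- stats::runif(n, -1, 1)
    for (j in seq_len(n))
      out[, j] <- a[j] * log1p(exp(b[j] * (expr[, j] - ctr[j]))) + shift[j]
  }
  out
}

#' Degrade samples with additive noise and dropout
#'
#' Emulates sample-quality loss (partial RNA degradation, amplification
#' bias): adds i.i.d. normal noise, then floors a random fraction of
#' each sample's values to that sample's minimum, keeping the matrix
#' dense so orderings stay defined.
#'
#' @param expr expression matrix.
#' @param noise_sd non-negative sd of additive normal noise.
#' @param dropout_fraction fraction in \[0, 1) of values per sample
#'   floored to the sample minimum.
#' @param seed integer seed.
#' @return degraded expression matrix.
#' @export
degrade_samples <- function(expr, noise_sd, dropout_fraction, seed) {
  validate_expression_matrix(expr)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.numeric(dropout_fraction) || dropout_fraction < 0 || dropout_fraction >= 1)
    stop("dropout_fraction must lie in [0, 1)")
  set.seed(seed)
  out <- expr
  if (noise_sd > 0)
    out <- out + matrix(stats::rnorm(length(out), 0, noise_sd), nrow = nrow(out))
  ndrop <- floor(dropout_fraction * nrow(out))
  if (ndrop > 0) {
    for (j in seq_len(ncol(out))) {
      idx <- sample(nrow(out), ndrop)
      out[idx, j] <- min(out[, j])
    }
  }
  out
}

#' Split a synthetic cohort into disjoint parts
#'
#' Seeded random partition (e.g. train/validation) preserving the
#' alignment of expression, clinical table and ground truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param fractions positive fractions summing to 1 (within 1e-9).
#' @param seed integer seed.
#' @return list of `synthetic_cohort`, one per fraction.
#' @export
split_cohort <- function(cohort, fractions, seed) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be positive and sum to 1")
  n <- ncol(cohort$expression)
  set.seed(seed)
  perm <- sample(n)
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  bounds <- cumsum(c(0L, counts))
  lapply(seq_along(fractions), function(i) {
    idx <- sort(perm[(bounds[i] + 1L):bounds[i + 1L]])
    structure(list(expression = cohort$expression[, idx, drop = FALSE],
                   clinical = cohort$clinical[idx, , drop = FALSE],
                   truth = cohort$truth[idx, , drop = FALSE],
                   planted = cohort$planted, config = cohort$config),
              class = "synthetic_cohort")
  })
}
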