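#' @importFrom survival coxph Surv survfit survdiff
NULL

check_survival <- function(times, events, need_event = TRUE) {
  if (length(times) != length(events))
    stop("times and events must have equal length")
  if (any(is.na(times)) || any(times < 0))
    stop("times must be non-negative and non-missing")
  if (!all(events %in% c(0, 1)))
    stop("events must be 0/1")
  if (need_event && sum(events) < 1)
    stop("at least one observed event is required")
  invisible(NULL)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with Efron tie handling
#' (Newton-Raphson via [survival::coxph()]), and reports Wald standard
#' errors, p-values and 95% confidence intervals `exp(coef +/- 1.96 se)`.
#' Rows with missing covariate values are dropped (complete-case) and
#' `n_used` records how many remained. A monotone-likelihood fit (perfect
#' separation driving a coefficient to infinity) is returned with
#' `converged = FALSE` rather than as an error.
#'
#' @param covariates numeric vector, matrix or data.frame (n x p).
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators aligned with `times`.
#' @return object of class `cox_fit`: list with `coefficients`,
#'   `hazard_ratios`, `standard_errors`, `wald_p_values`, `ci95_lower`,
#'   `ci95_upper`, `converged`, `n_used`.
#' @export
cox_fit <- function(covariates, times, events) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- if (ncol(x) == 1L) "x" else paste0("x", seq_len(ncol(x)))
  check_survival(times, events)
  if (nrow(x) != length(times)) stop("covariates and survival data misaligned")
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  times <- times[cc]; events <- events[cc]
  if (sum(events) < 1) stop("at least one observed event is required")
  const <- apply(x, 2L, function(v) max(v) - min(v) == 0)
  if (any(const))
    stop("degenerate covariate (constant): ", paste(colnames(x)[const], collapse = ", "))
  if (nrow(x) < ncol(x) + 2L) stop("too few records for the number of covariates")

  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "efron",
                    control = survival::coxph.control(eps = 1e-10, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|Loglik", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- unname(sqrt(diag(fit$var)))
  z <- beta / se
  nm <- colnames(x)
  structure(list(
    coefficients    = stats::setNames(beta, nm),
    hazard_ratios   = stats::setNames(exp(beta), nm),
    standard_errors = stats::setNames(se, nm),
    wald_p_values   = stats::setNames(2 * stats::pnorm(-abs(z)), nm),
    ci95_lower      = stats::setNames(exp(beta - 1.96 * se), nm),
    ci95_upper      = stats::setNames(exp(beta + 1.96 * se), nm),
    converged       = converged,
    n_used          = length(times)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties), n =", x$n_used,
      if (!x$converged) "[NOT CONVERGED]", "\n")
  print(data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                   se = x$standard_errors, p = x$wald_p_values,
                   ci95_lo = x$ci95_lower, ci95_hi = x$ci95_upper))
  invisible(x)
}

#' Screen covariates by univariate Cox p-value
#'
#' Fits each covariate alone and returns the names of those with Wald
#' p strictly below `alpha`, in the input order. The default alpha of 0.2
#' is the conventional screen for admitting clinical covariates into a
#' multivariate model. Covariates whose fit fails or does not converge
#' are excluded with a warning.
#'
#' @param covariate_set named data.frame or list of numeric covariates.
#' @param times,events survival outcome.
#' @param alpha strict p-value threshold, default 0.2.
#' @return character vector of retained covariate names.
#' @export
cox_screen_univariate <- function(covariate_set, times, events, alpha = 0.2) {
  nms <- names(covariate_set)
  if (length(covariate_set) && is.null(nms)) stop("covariates must be named")
  keep <- character(0)
  for (nm in nms) {
    f <- tryCatch(cox_fit(covariate_set[[nm]], times, events),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      if (!is.null(nm)) warning("covariate '", nm, "' not fittable; excluded")
      next
    }
    if (f$wald_p_values[1L] < alpha) keep <- c(keep, nm)
  }
  keep
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator returned as a right-continuous step function:
#' S(0) = 1 and S drops at each event time.
#'
#' @param times,events survival outcome (censoring allowed; events not
#'   required).
#' @return object of class `km_curve`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival data")
  check_survival(times, events, need_event = FALSE)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, surv = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km `km_curve` object from [km_estimate()].
#' @param t times at which to evaluate the step function.
#' @return survival probabilities S(t).
#' @export
km_survival_at <- function(km, t) {
  ev <- km[km$n_event > 0, , drop = FALSE]
  vapply(t, function(tt) {
    s <- ev$surv[ev$time <= tt]
    if (length(s)) s[length(s)] else 1
  }, numeric(1))
}

#' Log-rank test for equality of survival across groups
#'
#' @param group_labels categorical group per sample (>= 2 non-empty
#'   groups).
#' @param times,events survival outcome.
#' @return object of class `logrank_result`: list with `chi_square`,
#'   `df` (k - 1) and `p_value`.
#' @export
logrank_test <- function(group_labels, times, events) {
  g <- factor(group_labels)
  if (nlevels(g) < 2L) stop("log-rank test requires at least two groups")
  check_survival(times, events)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  structure(list(chi_square = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g, df = %d, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Harrell's concordance index
#'
#' A pair (i, j) is comparable iff their times differ and the subject
#' with the smaller time had an event; the pair is concordant when that
#' subject carries the strictly higher risk score, and tied risk scores
#' contribute 0.5. C = (concordant + 0.5 * ties) / comparable. 0.5 is
#' chance level, 1 perfect risk ordering.
#'
#' @param risk_scores numeric risk per sample (higher = worse predicted
#'   outcome).
#' @param times,events survival outcome.
#' @return concordance index in \[0, 1\].
#' @export
concordance_index <- function(risk_scores, times, events) {
  check_survival(times, events)
  if (length(risk_scores) != length(times))
    stop("risk_scores and survival data misaligned")
  lt <- outer(times, times, "<")           # [i,j]: t_i < t_j
  comp <- lt & (events == 1)               # row i had the event earlier
  n_comp <- sum(comp)
  if (n_comp == 0L) stop("no comparable pair")
  rgt <- outer(risk_scores, risk_scores, ">")
  req <- outer(risk_scores, risk_scores, "==")
  (sum(comp & rgt) + 0.5 * sum(comp & req)) / n_comp
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; selecting
#' features with adjusted value strictly below `q` controls the false
#' discovery rate at level `q`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted values aligned with the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sample t-test
#'
#' Pooled-variance (Student) two-sample t-test with `n_x + n_y - 2`
#' degrees of freedom and two-sided p-value by default; set
#' `var_equal = FALSE` for the Welch variant.
#'
#' @param x,y numeric vectors, each with at least two values.
#' @param var_equal assume equal variances (pooled); default TRUE.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
two_sample_t_test <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs at least 2 values")
  if (var_equal && stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate gene: zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts with all
#'   margins positive.
#' @return object of class `contingency_result` with `observed`, `test`,
#'   `statistic` (NA for the exact test) and `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  ft <- stats::fisher.test(tab)
  structure(list(observed = tab, test = "fisher_exact",
                 statistic = NA_real_, p_value = ft$p.value),
            class = "contingency_result")
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; degrees of freedom (r - 1)(c - 1); all
#' expected counts must be positive.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @return object of class `contingency_result` with the chi-square
#'   `statistic`, `df` and upper-tail `p_value`.
#' @export
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2x2 (df would be 0)")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stop("zero expected count")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(observed = tab, test = "chi_square",
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(x$test, "test\n")
  print(x$observed)
  if (!is.na(x$statistic))
    cat(sprintf("statistic = %.4g, df = %d, ", x$statistic, x$df))
  cat(sprintf("p = %.4g\n", x$p_value))
  invisible(x)
}
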