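#' Validate a per-sample clinical table
#'
#' The clinical table carries recurrence-free survival (RFS) and the
#' covariates used by the validation reports. Mandatory columns:
#' `sample_id` (unique), `rfs_months` (non-negative), `event` (1 =
#' recurrence observed, 0 = censored). Optional columns with controlled
#' vocabularies: `response_state` in {CR, nonCR} (NA = missing),
#' `age` (years), `stage` in {II, III, IV}, `grade` in {2, 3},
#' `residual` in {0-10mm, >=11mm}.
#'
#' @param clinical data.frame.
#' @return `clinical`, invisibly, if valid.
#' @export
validate_clinical_table <- function(clinical) {
  if (!is.data.frame(clinical)) stop("clinical table must be a data.frame")
  need <- c("sample_id", "rfs_months", "event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  dup <- unique(clinical$sample_id[duplicated(clinical$sample_id)])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (any(is.na(clinical$rfs_months)) || any(clinical$rfs_months < 0))
    stop("rfs_months must be non-negative and non-missing")
  if (!all(clinical$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (recurrence)")
  chk <- function(col, allowed) {
    if (col %in% names(clinical)) {
      v <- clinical[[col]]
      bad <- !is.na(v) & !v %in% allowed
      if (any(bad))
        stop(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                     paste(unique(v[bad]), collapse = ", "),
                     paste(allowed, collapse = ", ")))
    }
  }
  chk("response_state", c("CR", "nonCR"))
  chk("stage", c("II", "III", "IV"))
  chk("grade", c(2, 3, "2", "3"))
  chk("residual", c("0-10mm", ">=11mm"))
  invisible(clinical)
}

#' Read a clinical table from CSV
#'
#' @param path CSV with mandatory columns sample_id, rfs_months, event and
#'   optional response_state, age, stage, grade, residual.
#' @return validated clinical data.frame.
#' @export
read_clinical_table <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cl$sample_id <- as.character(cl$sample_id)
  validate_clinical_table(cl)
  cl
}

#' Write a clinical table to CSV
#' @param clinical validated clinical data.frame.
#' @param path output path.
#' @export
write_clinical_table <- function(clinical, path) {
  validate_clinical_table(clinical)
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Truncate follow-up at a horizon
#'
#' Records followed beyond the horizon are administratively censored at
#' the horizon: any record with `rfs_months > horizon_months` (strictly)
#' gets `rfs_months = horizon_months` and `event = 0`; records at or
#' below the horizon are unchanged. The default horizon of 60 months
#' (5 years) is the convention used throughout the validation reports.
#' The operation is idempotent.
#'
#' @param clinical validated clinical data.frame.
#' @param horizon_months positive horizon, default 60.
#' @return clinical table with truncated follow-up.
#' @export
truncate_followup <- function(clinical, horizon_months = 60) {
  validate_clinical_table(clinical)
  if (!is.numeric(horizon_months) || length(horizon_months) != 1L || horizon_months <= 0)
    stop("horizon_months must be a single positive number")
  over <- clinical$rfs_months > horizon_months
  clinical$event[over] <- 0
  clinical$rfs_months[over] <- horizon_months
  clinical
}

#' Code clinical covariates for Cox modelling
#'
#' Produces the numeric covariate codings used in univariate and
#' multivariate Cox models: `age_ge60` (1 if age >= 60), `stage_ord`
#' (ordinal 2/3/4 for II/III/IV), `grade_3` (1 if grade 3 vs 2) and
#' `residual_ge11` (1 if residual tumor >= 11 mm vs 0-10 mm). Missing
#' source fields propagate as NA; model fits handle exclusion.
#'
#' @param clinical validated clinical data.frame.
#' @return data.frame of numeric covariates aligned with `clinical`
#'   (columns only for source fields that are present).
#' @export
code_clinical_covariates <- function(clinical) {
  validate_clinical_table(clinical)
  out <- data.frame(row.names = seq_len(nrow(clinical)))
  if ("age" %in% names(clinical))
    out$age_ge60 <- as.numeric(clinical$age >= 60)
  if ("stage" %in% names(clinical))
    out$stage_ord <- c(II = 2, III = 3, IV = 4)[as.character(clinical$stage)]
  if ("grade" %in% names(clinical))
    out$grade_3 <- as.numeric(as.character(clinical$grade) == "3")
  if ("residual" %in% names(clinical))
    out$residual_ge11 <- as.numeric(clinical$residual == ">=11mm")
  rownames(out) <- NULL
  out
}
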