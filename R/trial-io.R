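#' Read a trial dataset from CSV
#'
#' Reads the flat one-row-per-patient CSV layout (columns `patient_id, age,
#' sex, item_01..item_30, total_baseline, vas_drowsiness, vas_sleep_quality,
#' psp, sqls, arm, week_0..week_6` and optionally `latent_label`). Empty
#' fields become missing values. The dataset is validated on read: ordinal
#' items must lie in 1--7, the arm column must contain only `treatment` /
#' `placebo`, and week 0 must be observed; violations are reported with the
#' offending patient id. Unknown extra columns are dropped with a warning.
#'
#' @param path Path to a CSV file.
#' @return A `trial_dataset`.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) {
    stop_validation("trial CSV not found: ", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  n_items <- sum(grepl("^item_\\d+$", names(raw)))
  known <- c("patient_id", "age", "sex", item_cols(n_items), "total_baseline",
             "vas_drowsiness", "vas_sleep_quality", "psp", "sqls", "arm",
             week_cols(), "latent_label")
  extras <- setdiff(names(raw), known)
  if (length(extras)) {
    warning("ignoring unknown column(s): ", paste(extras, collapse = ", "),
            call. = FALSE)
    raw <- raw[, setdiff(names(raw), extras), drop = FALSE]
  }
  as_trial_dataset(raw)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_trial_csv()]; missing values are written as empty fields
#' so the file round-trips losslessly.
#'
#' @param dataset A `trial_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  utils::write.csv(dataset, path, row.names = FALSE, na = "")
  invisible(path)
}
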