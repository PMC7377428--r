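TRIALS_COLUMNS <- c("subject_id", "block", "block_type", "trial", "pair",
                    "left_stim", "choice", "rt_s", "outcome", "counterfactual",
                    "satisfaction")

#' Write a trials table
#'
#' Comma-separated, one header row, UTF-8, `.` decimal; `counterfactual` is
#' empty outside counterfactual blocks.
#'
#' @param trials trial table with the canonical columns.
#' @param path output file.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIALS_COLUMNS, names(trials))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  write.csv(trials[, TRIALS_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trials table
#'
#' Schema violations are reported with 1-based data row numbers. RTs may be
#' recorded in milliseconds; pass `units = "ms"` to convert to seconds on
#' read.
#'
#' @param path CSV file written by [write_trials()] or matching its schema.
#' @param units unit of the `rt_s` column in the file: `"s"` (default) or
#'   `"ms"`.
#' @return validated trials data.frame (RTs in seconds).
#' @export
read_trials <- function(path, units = c("s", "ms")) {
  units <- match.arg(units)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIALS_COLUMNS, names(raw))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (!is.numeric(raw$rt_s)) stop("rt_s must be numeric")
  bad_rt <- which(!is.finite(raw$rt_s) | raw$rt_s <= 0)
  if (length(bad_rt)) stop("non-positive or missing rt on row(s): ",
                           paste(utils::head(bad_rt, 10), collapse = ", "))
  if (units == "ms") raw$rt_s <- raw$rt_s / 1000
  ps <- split_pair(raw$pair)
  bad_pair <- which(is.na(ps$stim1) | is.na(ps$stim2) |
                      !(ps$stim1 %in% STIMULI) | !(ps$stim2 %in% STIMULI) |
                      ps$stim1 == ps$stim2)
  if (length(bad_pair)) stop("malformed pair on row(s): ",
                             paste(utils::head(bad_pair, 10), collapse = ", "))
  bad_choice <- which(raw$choice != ps$stim1 & raw$choice != ps$stim2)
  if (length(bad_choice)) stop("choice not in pair on row(s): ",
                               paste(utils::head(bad_choice, 10), collapse = ", "))
  bad_out <- which(!(raw$outcome %in% c(0, 20, 40)))
  if (length(bad_out)) stop("outcome outside {0,20,40} on row(s): ",
                            paste(utils::head(bad_out, 10), collapse = ", "))
  cf_mismatch <- which(xor(raw$block_type == "counterfactual",
                           !is.na(raw$counterfactual)))
  if (length(cf_mismatch)) stop("counterfactual presence does not match block type on row(s): ",
                                paste(utils::head(cf_mismatch, 10), collapse = ", "))
  raw
}

#' Write/read a subjects table
#'
#' @param subjects table from [sample_population()] (or at minimum
#'   `subject_id`, `stai_t`).
#' @param path CSV file.
#' @export
write_subjects <- function(subjects, path) {
  stopifnot(all(c("subject_id", "stai_t") %in% names(subjects)))
  write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "stai_t") %in% names(s)))
  s
}
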