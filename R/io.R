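# Trial-table I/O. One schema is shared by real and simulated data so that
# empirical studies can use the tool unchanged:
#   assemblage_id, replicate_id, N0, Ne, t_days  (extra columns preserved)

trial_cols <- c("assemblage_id", "replicate_id", "N0", "Ne", "t_days")

# round-half-away-from-zero; R's round() is round-half-even
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Validate a trial table
#'
#' Checks the shared trial schema: columns `assemblage_id`, `replicate_id`,
#' `N0`, `Ne`, `t_days`; `N0 >= 1` integer, `0 <= Ne <= N0`, `t_days > 0`.
#' Violations are reported with their row numbers.
#'
#' @param trials a data frame.
#' @return the validated data frame (invisibly coerced numeric columns).
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("trials must be a data frame")
  missing_cols <- setdiff(trial_cols, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("replicate_id", "N0", "Ne", "t_days")) {
    trials[[col]] <- as.numeric(trials[[col]])
  }
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop(what, " at row(s) ", paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) " ..." else "")
    }
  }
  bad(!is.finite(trials$N0) | trials$N0 < 1 | trials$N0 != round(trials$N0),
      "N0 must be an integer >= 1")
  bad(!is.finite(trials$Ne) | trials$Ne < 0 | trials$Ne > trials$N0,
      "Ne must satisfy 0 <= Ne <= N0")
  bad(!is.finite(trials$t_days) | trials$t_days <= 0, "t_days must be > 0")
  bad(!is.finite(trials$replicate_id) | trials$replicate_id < 1,
      "replicate_id must be >= 1")
  trials
}

#' Read a trial table from delimited text
#'
#' Comma-separated UTF-8 text with a header row. Required columns:
#' `assemblage_id`, `replicate_id`, `N0`, `Ne`, `t_days`; extra columns are
#' preserved. Malformed rows are rejected with row numbers.
#'
#' @param path file path.
#' @return validated data frame of trials.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(out)
}

#' Write a trial table as delimited text
#'
#' @param trials data frame conforming to the trial schema.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a run configuration as key-value text
#'
#' Flat named lists round-trip losslessly through Debian-control-style text;
#' numeric vectors are serialised comma-separated at full precision.
#'
#' @param config named list of scalars / numeric vectors.
#' @param path file path.
#' @return `read_config`: the named list; `write_config`: `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  flat <- vapply(config, function(v) {
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = ",")
  }, character(1))
  write.dcf(as.data.frame(as.list(flat), check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  m <- read.dcf(path)
  out <- lapply(seq_len(ncol(m)), function(i) {
    parts <- strsplit(m[1, i], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  names(out) <- colnames(m)
  out
}
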