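#' Trial summary data model
#'
#' A `trial_set` is a data frame of per-trial summary statistics, one row per
#' randomized trial, ordered by publication. Each row carries the observed
#' result (mean difference in the outcome between active and sham arm with
#' its standard error) together with the trial's own planning assumptions
#' where these were reported: the calculated per-arm sample sizes, the
#' planned power, and the anticipated mean difference and common per-arm
#' standard deviation. The sign convention follows the blood-pressure
#' literature: a negative mean difference favors the active intervention.
#'
#' Required columns:
#' `trial_id`, `label`, `order`, `year`, `n_active`, `n_sham`, `md`,
#' `se_md`, `planned_n_active`, `planned_n_sham`, `planned_power`,
#' `anticipated_delta`, `anticipated_sd`, `allocation_ratio`,
#' `prospectively_powered`.
#'
#' Planning fields may be missing (`NA`): proof-of-concept trials report no
#' power calculation, in which case `planned_power`, `anticipated_delta` and
#' `anticipated_sd` must all be absent together.
#'
#' @param x data frame with the columns listed above.
#' @return `x`, sorted by `order`, with class `trial_set` prepended.
#' @examples
#' ts <- trial_set(data.frame(
#'   trial_id = "t1", label = "Trial 1", order = 1, year = 2020,
#'   n_active = 40, n_sham = 40, md = -3, se_md = 2.1,
#'   planned_n_active = NA, planned_n_sham = NA, planned_power = NA,
#'   anticipated_delta = NA, anticipated_sd = NA,
#'   allocation_ratio = 1, prospectively_powered = FALSE))
#' @export
trial_set <- function(x) {
  required <- c("trial_id", "label", "order", "year", "n_active", "n_sham",
                "md", "se_md", "planned_n_active", "planned_n_sham",
                "planned_power", "anticipated_delta", "anticipated_sd",
                "allocation_ratio", "prospectively_powered")
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0L) stop("trial set must contain at least one trial",
                          call. = FALSE)
  x <- as.data.frame(x)[required]
  x$trial_id <- as.character(x$trial_id)
  x$label <- as.character(x$label)
  for (nm in c("order", "year", "n_active", "n_sham", "planned_n_active",
               "planned_n_sham")) {
    x[[nm]] <- as.integer(x[[nm]])
  }
  x$prospectively_powered <- as.logical(x$prospectively_powered)

  fail_row <- function(i, what) {
    stop(sprintf("trial row %d (%s): %s", i, x$trial_id[i], what),
         call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    if (is.na(x$trial_id[i]) || !nzchar(x$trial_id[i]))
      fail_row(i, "empty trial_id")
    if (is.na(x$order[i]) || x$order[i] < 1L) fail_row(i, "invalid order")
    if (is.na(x$n_active[i]) || x$n_active[i] < 1L)
      fail_row(i, "n_active must be >= 1")
    if (is.na(x$n_sham[i]) || x$n_sham[i] < 1L)
      fail_row(i, "n_sham must be >= 1")
    if (is.na(x$md[i])) fail_row(i, "missing mean difference")
    if (is.na(x$se_md[i]) || x$se_md[i] <= 0)
      fail_row(i, "se_md must be > 0")
    if (is.na(x$allocation_ratio[i]) || x$allocation_ratio[i] <= 0)
      fail_row(i, "allocation_ratio must be > 0")
    plan <- c(x$planned_power[i], x$anticipated_delta[i], x$anticipated_sd[i])
    if (any(is.na(plan)) && !all(is.na(plan)))
      fail_row(i, "planning fields must be jointly present or jointly absent")
    if (!is.na(x$planned_power[i]) &&
        (x$planned_power[i] <= 0 || x$planned_power[i] >= 1))
      fail_row(i, "planned_power must lie in (0, 1)")
    if (!is.na(x$anticipated_sd[i]) && x$anticipated_sd[i] <= 0)
      fail_row(i, "anticipated_sd must be > 0")
  }
  if (anyDuplicated(x$trial_id))
    stop("duplicate trial_id values", call. = FALSE)
  if (anyDuplicated(x$order))
    stop("duplicate order values", call. = FALSE)
  x <- x[order(x$order), , drop = FALSE]
  rownames(x) <- NULL
  if (!identical(x$order, seq_len(nrow(x))))
    stop("order values must be consecutive integers starting at 1",
         call. = FALSE)
  class(x) <- c("trial_set", "data.frame")
  x
}

#' Read a trial set from CSV
#'
#' The CSV dialect is comma-separated UTF-8 with "." as decimal mark; an
#' empty cell encodes a missing planning field (never zero). The header must
#' match the documented `trial_set` schema.
#'
#' @param path path to a CSV file.
#' @return a validated [trial_set].
#' @seealso [write_trials()], [rdn_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       fileEncoding = "UTF-8")
  trial_set(x)
}

#' Write a trial set to CSV
#'
#' Missing planning fields are written as empty cells, so a write/read
#' round trip reproduces every field exactly.
#'
#' @param trials a [trial_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- trial_set(trials)
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a trial set as JSON
#'
#' Row-wise JSON export of the same schema as the CSV interface, used by the
#' pipeline report.
#'
#' @param trials a [trial_set].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_trials_json <- function(trials, path) {
  trials <- trial_set(trials)
  jsonlite::write_json(as.data.frame(trials), path, dataframe = "rows",
                       na = "null", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The six renal-denervation sham-RCTs
#'
#' Returns the packaged summary data of the six randomized trials comparing
#' renal sympathetic denervation to a sham procedure in patients with
#' arterial hypertension (981 participants in total; outcome: mean change in
#' 24-hour ambulatory systolic blood pressure, mmHg). The first trial
#' randomized 2:1 in favor of the active arm; the two proof-of-concept
#' trials carry no planning assumptions. The planning row of the first trial
#' is retained as reported even though its published calculation cannot be
#' reproduced from the stated inputs (see [replicate_reported()]).
#'
#' @return a [trial_set] of six trials.
#' @examples
#' rdn <- rdn_trials()
#' summarize_trials(rdn)
#' @export
rdn_trials <- function() {
  path <- system.file("extdata", "rdn_trials.csv", package = "condplan",
                      mustWork = TRUE)
  read_trials(path)
}

#' Summarize achieved sample sizes of a trial set
#'
#' @param trials a [trial_set] (or any subset of its rows).
#' @return a list with total, per-arm totals, number of trials, and the
#'   median/min/max of per-trial total sizes.
#' @export
summarize_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("need a non-empty set of trials", call. = FALSE)
  if (!all(c("n_active", "n_sham") %in% names(trials)))
    stop("need columns n_active and n_sham", call. = FALSE)
  if (any(is.na(trials$n_active)) || any(is.na(trials$n_sham)) ||
      any(trials$n_active < 1) || any(trials$n_sham < 1))
    stop("per-arm sizes must be >= 1", call. = FALSE)
  totals <- trials$n_active + trials$n_sham
  list(
    k_trials = nrow(trials),
    n_total = sum(totals),
    n_active = sum(trials$n_active),
    n_sham = sum(trials$n_sham),
    median_total = stats::median(totals),
    min_total = min(totals),
    max_total = max(totals)
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d trials, %d participants (%d active, %d sham)\n",
              nrow(x), sum(x$n_active + x$n_sham), sum(x$n_active),
              sum(x$n_sham)))
  print.data.frame(x, ...)
  invisible(x)
}
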