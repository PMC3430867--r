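# Trial-level data structures and defective-quantile summaries.
#
# On-disk schema: one row per trial with columns
#   subject, session (drug/placebo), block, cue (speed/accuracy/dummy),
#   direction (left/right), response (left/right/none), correct (logical),
#   rt_ms (milliseconds), responded (logical).
# RTs are stored in milliseconds on disk and carried in seconds (column `rt`)
# internally.

.trial_columns <- c("subject", "session", "block", "cue", "direction",
                    "response", "correct", "rt_ms", "responded")
.sessions <- c("drug", "placebo")
.cues <- c("speed", "accuracy")

#' Construct a validated trial table
#'
#' A trial table is a data frame of two-choice trials carrying its provenance
#' (generator configuration, seed, preprocessing log) in a `metadata`
#' attribute. Rows violating the trial invariants are reported by row number.
#'
#' @param df data frame with columns `subject`, `session`, `block`, `cue`,
#'   `direction`, `response`, `correct`, `rt_ms`, `responded`.
#' @param metadata named list of provenance information.
#' @return An object of class `trial_table` (a data frame with a `metadata`
#'   attribute and an internal `rt` column in seconds).
#' @export
trial_table <- function(df, metadata = list()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trial_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$responded <- as.logical(df$responded)
  df$correct <- as.logical(df$correct)
  df$rt_ms <- suppressWarnings(as.numeric(df$rt_ms))
  df$block <- suppressWarnings(as.integer(df$block))
  bad <- .validate_trial_rows(df)
  if (length(bad$rows) > 0) {
    stop("invalid trial rows [", paste(head(bad$rows, 10L), collapse = ", "),
         if (length(bad$rows) > 10L) ", ..." else "",
         "]: ", paste(unique(bad$why), collapse = "; "))
  }
  df$rt <- df$rt_ms / 1000
  df$rt[!df$responded] <- NA_real_
  structure(df, metadata = metadata,
            class = c("trial_table", "data.frame"))
}

# Returns the offending row indices and reasons, without stopping.
.validate_trial_rows <- function(df) {
  rows <- integer(0); why <- character(0)
  flag <- function(idx, msg) {
    if (any(idx, na.rm = TRUE)) {
      rows <<- c(rows, which(idx))
      why <<- c(why, msg)
    }
  }
  flag(!(df$session %in% .sessions), "session not in {drug, placebo}")
  flag(!(df$cue %in% c(.cues, "dummy")), "cue not in {speed, accuracy, dummy}")
  flag(is.na(df$block) | df$block < 1L, "block must be an integer >= 1")
  flag(is.na(df$responded), "responded must be logical")
  resp <- !is.na(df$responded) & df$responded
  flag(resp & (is.na(df$rt_ms) | df$rt_ms <= 0), "rt must be > 0 when responded")
  flag(resp & !(df$response %in% c("left", "right")),
       "responded trials need response in {left, right}")
  flag(resp & !is.na(df$correct) & (df$response %in% c("left", "right")) &
         (df$direction %in% c("left", "right")) &
         (df$correct != (df$response == df$direction)),
       "correct must equal (response == direction)")
  flag(!is.na(df$responded) & !df$responded & df$response != "none",
       "non-responded trials must have response 'none'")
  list(rows = sort(unique(rows)), why = why)
}

#' Metadata of a trial table
#' @param x a `trial_table`.
#' @return The named metadata list.
#' @export
trial_metadata <- function(x) attr(x, "metadata")

`trial_metadata<-` <- function(x, value) { attr(x, "metadata") <- value; x }

#' Read a trial table from delimited text
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return A validated [trial_table()].
#' @export
read_trials <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  trial_table(df, metadata = list(source = path))
}

#' Write a trial table as delimited text
#'
#' Writes the on-disk schema (RTs in milliseconds); the internal seconds
#' column is dropped.
#'
#' @param x a `trial_table`.
#' @param path file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path, sep = ",") {
  df <- as.data.frame(x)[, intersect(.trial_columns, names(x)), drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preprocess a trial table for model fitting
#'
#' Removes labelled dummy trials and trials without a response, and drops
#' stimulus direction as a modelling factor (the correct/error coding is
#' retained; left and right motion trials are collapsed). Counts of removed
#' trials are appended to the metadata. Idempotent.
#'
#' @param x a `trial_table`.
#' @return A preprocessed `trial_table`.
#' @export
preprocess <- function(x) {
  md <- trial_metadata(x)
  df <- as.data.frame(x)
  is_dummy <- df$cue == "dummy"
  cells_before <- unique(paste(df$subject, df$session, df$cue)[!is_dummy])
  df <- df[!is_dummy, , drop = FALSE]
  no_resp <- !df$responded
  df <- df[no_resp == FALSE, , drop = FALSE]
  df <- df[, setdiff(names(df), c("direction", "response")), drop = FALSE]
  cells_after <- unique(paste(df$subject, df$session, df$cue))
  emptied <- setdiff(cells_before, cells_after)
  if (length(emptied) > 0) {
    stop("no trials left in cell (", gsub(" ", ", ", emptied[1]),
         ") after preprocessing")
  }
  md$n_dummy_removed <- sum(is_dummy) + (md$n_dummy_removed %||% 0L)
  md$n_noresponse_removed <- sum(no_resp) + (md$n_noresponse_removed %||% 0L)
  md$preprocessed <- TRUE
  rownames(df) <- NULL
  structure(df, metadata = md, class = c("trial_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exclude subjects with poor accuracy-condition performance
#'
#' Subjects whose proportion correct on accuracy-cue trials falls strictly
#' below `min_accuracy` are removed. By default accuracy is pooled over both
#' sessions and computed over responded trials only; both choices are
#' configurable.
#'
#' @param x a preprocessed `trial_table`.
#' @param min_accuracy exclusion threshold (default 0.60; comparison is
#'   strict `<`, so a subject at exactly the threshold is retained).
#' @param per `"pooled"` (default) to assess accuracy across both sessions
#'   jointly, or `"session"` to exclude a subject if either session falls
#'   below threshold.
#' @return A `trial_table` without the excluded subjects; the exclusion list
#'   is recorded in `metadata$excluded_subjects`.
#' @export
apply_subject_exclusions <- function(x, min_accuracy = 0.60,
                                     per = c("pooled", "session")) {
  per <- match.arg(per)
  df <- as.data.frame(x)
  acc_trials <- df[df$cue == "accuracy" & df$responded, , drop = FALSE]
  excluded <- character(0)
  for (subj in unique(df$subject)) {
    st <- acc_trials[acc_trials$subject == subj, , drop = FALSE]
    if (nrow(st) == 0) next
    if (per == "pooled") {
      if (mean(st$correct) < min_accuracy) excluded <- c(excluded, subj)
    } else {
      accs <- tapply(st$correct, st$session, mean)
      if (any(accs < min_accuracy)) excluded <- c(excluded, subj)
    }
  }
  if (length(excluded) == length(unique(df$subject))) {
    stop("all subjects excluded at min_accuracy = ", min_accuracy)
  }
  md <- trial_metadata(x)
  md$excluded_subjects <- excluded
  md$min_accuracy <- min_accuracy
  out <- df[!(df$subject %in% excluded), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, metadata = md, class = c("trial_table", "data.frame"))
}

#' RT quantiles by linear interpolation of order statistics
#'
#' Uses the standard "type 7" definition (linear interpolation between order
#' statistics), the same convention as [stats::quantile()]'s default.
#'
#' @param rts numeric vector of response times (seconds), at least one.
#' @param probs strictly increasing probabilities in (0, 1); default the five
#'   canonical probabilities 0.1, 0.3, 0.5, 0.7, 0.9.
#' @return Named nondecreasing numeric vector of quantiles.
#' @export
rt_quantiles <- function(rts, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (length(rts) < 1 || anyNA(rts)) stop("rts must be non-empty and free of NA")
  if (any(probs <= 0) || any(probs >= 1) || is.unsorted(probs, strictly = TRUE)) {
    stop("probs must be strictly increasing within (0, 1)")
  }
  quantile(rts, probs = probs, type = 7, names = TRUE)
}

#' Summarise one (session, cue) cell as defective RT quantiles
#'
#' Computes the proportion correct among responded trials and RT quantiles
#' separately for correct and error responses. Cells with fewer error
#' responses than `sparse_n` are flagged sparse: their error RTs are not
#' quantized and model fitting collapses them into a single bin.
#'
#' @param x a preprocessed `trial_table` restricted to one subject (or any
#'   set of trials to be treated as one cell).
#' @param session,cue the cell to summarise.
#' @param probs quantile probabilities.
#' @param sparse_n minimum number of error responses required to quantize
#'   error RTs (default 5).
#' @return An object of class `quantile_summary`.
#' @export
summarize_cell <- function(x, session, cue,
                           probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           sparse_n = 5L) {
  df <- as.data.frame(x)
  cell <- df[df$session == session & df$cue == cue & df$responded, , drop = FALSE]
  if (nrow(cell) == 0) stop("no responded trials in cell (", session, ", ", cue, ")")
  n_correct <- sum(cell$correct)
  n_error <- sum(!cell$correct)
  sparse <- n_error < sparse_n
  structure(list(
    session = session, cue = cue,
    n_trials = nrow(cell), n_correct = n_correct, n_error = n_error,
    p_correct = n_correct / nrow(cell),
    probs = probs,
    correct_quantiles = if (n_correct >= 1) unname(rt_quantiles(cell$rt[cell$correct], probs)) else NULL,
    error_quantiles = if (!sparse) unname(rt_quantiles(cell$rt[!cell$correct], probs)) else NULL,
    sparse_error = sparse
  ), class = "quantile_summary")
}

#' @export
print.quantile_summary <- function(x, ...) {
  cat(sprintf("<quantile_summary> %s/%s: n = %d, p(correct) = %.3f%s\n",
              x$session, x$cue, x$n_trials, x$p_correct,
              if (x$sparse_error) sprintf(" [sparse errors: %d]", x$n_error) else ""))
  if (!is.null(x$correct_quantiles)) {
    cat("  correct RT quantiles (s):",
        paste(sprintf("%.3f", x$correct_quantiles), collapse = " "), "\n")
  }
  if (!is.null(x$error_quantiles)) {
    cat("  error RT quantiles (s):  ",
        paste(sprintf("%.3f", x$error_quantiles), collapse = " "), "\n")
  }
  invisible(x)
}

#' Summarise both cue cells of one session
#'
#' Convenience wrapper returning the speed and accuracy [summarize_cell()]
#' summaries of one session, the unit consumed by [fit_ddm()].
#'
#' @inheritParams summarize_cell
#' @param session session label.
#' @return Named list with elements `speed` and `accuracy`.
#' @export
summarize_session <- function(x, session,
                              probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              sparse_n = 5L) {
  list(speed = summarize_cell(x, session, "speed", probs, sparse_n),
       accuracy = summarize_cell(x, session, "accuracy", probs, sparse_n))
}

#' Vincentize per-subject quantile summaries into a group summary
#'
#' Averages corresponding RT quantiles (and response proportions) across
#' subjects with equal weight, the standard way of building a
#' group-representative defective RT distribution. Error quantiles are
#' averaged over the subjects whose error counts were not sparse.
#'
#' @param summaries list of `quantile_summary` objects for the same
#'   (session, cue) cell on the same probability grid.
#' @return A group `quantile_summary`.
#' @export
vincentize <- function(summaries) {
  if (length(summaries) == 0) stop("no summaries to vincentize")
  probs <- summaries[[1]]$probs
  cell <- c(summaries[[1]]$session, summaries[[1]]$cue)
  for (s in summaries) {
    if (!isTRUE(all.equal(s$probs, probs))) stop("mismatched probability grids")
    if (!identical(c(s$session, s$cue), cell)) stop("mismatched cells")
  }
  cq <- do.call(rbind, lapply(summaries, function(s) s$correct_quantiles))
  eq_list <- lapply(summaries, function(s) s$error_quantiles)
  eq <- do.call(rbind, eq_list[!vapply(eq_list, is.null, logical(1))])
  structure(list(
    session = cell[1], cue = cell[2],
    n_trials = sum(vapply(summaries, function(s) s$n_trials, numeric(1))),
    n_correct = sum(vapply(summaries, function(s) s$n_correct, numeric(1))),
    n_error = sum(vapply(summaries, function(s) s$n_error, numeric(1))),
    p_correct = mean(vapply(summaries, function(s) s$p_correct, numeric(1))),
    probs = probs,
    correct_quantiles = if (!is.null(cq)) colMeans(cq) else NULL,
    error_quantiles = if (!is.null(eq)) colMeans(eq) else NULL,
    sparse_error = is.null(eq),
    n_subjects = length(summaries)
  ), class = "quantile_summary")
}
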