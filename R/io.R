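#' Read a behavioral trial table
#'
#' Reads a comma-separated trial table (one row per completed trial) and
#' validates it against the trial-record contract. Required columns:
#' \code{session_id, trial_index, value1, value2, chosen, latency_ms, stim,
#' task}. An optional \code{latency2_ms} column (release latency for the
#' second object, present only on unchosen decision trials) is passed
#' through. Absent values are empty fields. Rows are returned grouped by
#' session and ordered by \code{trial_index}.
#'
#' Contract: \code{value1} in 1..6; \code{chosen} in \{0, 1\};
#' \code{latency_ms} present iff \code{chosen == 1} on decision trials;
#' \code{trial_index} strictly increasing within a session.
#'
#' @param path Path to a CSV file.
#' @return A \code{data.frame} of validated trials.
#' @export
read_trials <- function(path) {
  df <- read_csv_checked(path, c("session_id", "trial_index", "value1",
                                 "value2", "chosen", "latency_ms", "stim",
                                 "task"))
  validate_trials(df)
}

#' Validate an in-memory trial table
#'
#' Applies the same invariant checks as [read_trials()] to a data.frame built
#' in code; returns the table grouped by session and ordered by trial index.
#'
#' @param df Trial data.frame.
#' @return The validated, reordered data.frame.
#' @export
validate_trials <- function(df) {
  req <- c("session_id", "trial_index", "value1", "value2", "chosen",
           "latency_ms", "stim", "task")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trial table lacks required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty trial table")
  df$trial_index <- as_integer_checked(df$trial_index, "trial_index")
  df$value1 <- as_integer_checked(df$value1, "value1")
  df$value2 <- suppressWarnings(as.integer(df$value2))
  df$chosen <- as_integer_checked(df$chosen, "chosen")
  df$stim <- as_integer_checked(df$stim, "stim")
  df$latency_ms <- as.numeric(df$latency_ms)
  if (!"latency2_ms" %in% names(df)) df$latency2_ms <- NA_real_
  df$latency2_ms <- as.numeric(df$latency2_ms)
  df$task <- as.character(df$task)

  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("trial row %d: %s", i[1], msg))
  }
  bad_row(!df$value1 %in% 1:6, "value1 must be an integer in 1..6")
  bad_row(!is.na(df$value2) & !df$value2 %in% 1:6,
          "value2 must be an integer in 1..6 or absent")
  bad_row(!df$chosen %in% 0:1, "chosen must be 0 or 1")
  bad_row(!df$stim %in% 0:1, "stim must be 0 or 1")
  bad_row(!df$task %in% c("decision", "button_release"),
          "task must be 'decision' or 'button_release'")
  dec <- df$task == "decision"
  bad_row(dec & df$chosen == 1 & is.na(df$latency_ms),
          "latency_ms must be present when chosen = 1")
  bad_row(dec & df$chosen == 0 & !is.na(df$latency_ms),
          "latency_ms must be absent when chosen = 0")
  bad_row(!is.na(df$latency_ms) & df$latency_ms <= 0,
          "latency_ms must be > 0")
  bad_row(!is.na(df$latency2_ms) & df$latency2_ms <= 0,
          "latency2_ms must be > 0")
  bad_row(dec & df$chosen == 1 & !is.na(df$latency2_ms),
          "latency2_ms only applies to unchosen trials")

  df <- df[order(df$session_id, df$trial_index), , drop = FALSE]
  for (s in unique(df$session_id)) {
    ti <- df$trial_index[df$session_id == s]
    if (any(diff(ti) <= 0))
      stop(sprintf("session %s: trial_index not strictly increasing", s))
  }
  rownames(df) <- NULL
  df
}

as_integer_checked <- function(x, name) {
  xi <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(xi) | xi != round(xi))
  if (length(bad))
    stop(sprintf("row %d: column '%s' is not an integer (value '%s')",
                 bad[1], name, as.character(x[bad[1]])))
  as.integer(xi)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty input file (header only): ", path)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read a spike-time table
#'
#' Reads long-format spike times (\code{neuron_id, session_id, trial_index,
#' spike_ms}; ms relative to first-object onset, negative allowed for the
#' baseline period) and returns them as a nested list of spike trains:
#' \code{trains[[neuron]][[trial]]}, one sorted numeric vector per trial.
#' Trials present in \code{trials} but without spikes for a neuron appear as
#' empty trains, so zero-rate trials are never silently dropped. Spikes
#' referencing a (session, trial) absent from the trial table are an error.
#'
#' @param path Path to a CSV file (may contain zero data rows).
#' @param trials Validated trial table defining the trial universe.
#' @return Named list (by neuron) of named lists (by \code{session_id:trial_index})
#'   of sorted numeric spike-time vectors.
#' @export
read_spikes <- function(path, trials) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("neuron_id", "session_id", "trial_index", "spike_ms"),
                  names(df))
  if (length(miss))
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  spike_trains(df, trials)
}

#' Assemble spike trains from a long-format table
#'
#' @param spikes data.frame with columns \code{neuron_id, session_id,
#'   trial_index, spike_ms}; may have zero rows.
#' @param trials Validated trial table.
#' @return Nested list as in [read_spikes()].
#' @export
spike_trains <- function(spikes, trials) {
  trial_key <- paste(trials$session_id, trials$trial_index, sep = ":")
  empty <- stats::setNames(
    replicate(length(trial_key), numeric(0), simplify = FALSE), trial_key)
  if (nrow(spikes) == 0) return(list())
  if (any(!is.finite(spikes$spike_ms)))
    stop("non-finite spike time in spike table")
  skey <- paste(spikes$session_id, spikes$trial_index, sep = ":")
  unknown <- !skey %in% trial_key
  if (any(unknown))
    stop(sprintf("spike row %d references unknown trial %s",
                 which(unknown)[1], skey[which(unknown)[1]]))
  out <- list()
  for (nid in unique(as.character(spikes$neuron_id))) {
    sel <- as.character(spikes$neuron_id) == nid
    tr <- empty
    got <- split(spikes$spike_ms[sel], skey[sel])
    tr[names(got)] <- lapply(got, sort)
    out[[nid]] <- tr
  }
  out
}

#' Write a result table to delimited text
#'
#' Writes any result data.frame as CSV with a header; numeric columns keep at
#' least 6 significant digits so that a read-back reproduces the values to
#' formatting precision. Absent values are written as empty fields.
#'
#' @param records data.frame of results.
#' @param path Output path (directory must exist).
#' @param allow_empty Permit a zero-row table (header-only file).
#' @return Invisibly, the path.
#' @export
write_results <- function(records, path, allow_empty = FALSE) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  if (nrow(records) == 0 && !allow_empty)
    stop("refusing to write empty result table (set allow_empty = TRUE)")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 8, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
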