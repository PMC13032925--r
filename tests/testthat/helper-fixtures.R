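# Small in-code fixtures shared across test files.

# Minimal well-formed trial table (decision task, one session).
toy_trials <- function(n = 6, session_id = "s1") {
  chosen <- rep(c(1L, 0L), length.out = n)
  data.frame(
    session_id = session_id,
    trial_index = seq_len(n),
    value1 = rep(1:6, length.out = n),
    value2 = rep(6:1, length.out = n),
    chosen = chosen,
    latency_ms = ifelse(chosen == 1, 400, NA_real_),
    stim = 0L,
    task = "decision",
    latency2_ms = ifelse(chosen == 0, 320, NA_real_),
    stringsAsFactors = FALSE)
}

write_tmp_csv <- function(df, name = "tmp.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# A stimulation session table built directly (deterministic counts).
toy_stim_session <- function(n_per_cell = 25, p_stim, p_nostim,
                             session_id = "site1") {
  rows <- list()
  idx <- 1L
  for (v in 1:6) for (stim in 0:1) {
    p <- if (stim == 1) p_stim[v] else p_nostim[v]
    n1 <- round(p * n_per_cell)
    chosen <- c(rep(1L, n1), rep(0L, n_per_cell - n1))
    rows[[length(rows) + 1]] <- data.frame(
      session_id = session_id, trial_index = idx:(idx + n_per_cell - 1),
      value1 = v, value2 = 3L, chosen = chosen,
      latency_ms = ifelse(chosen == 1, 400, NA_real_),
      stim = stim, task = "decision", latency2_ms = NA_real_,
      stringsAsFactors = FALSE)
    idx <- idx + n_per_cell
  }
  do.call(rbind, rows)
}
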