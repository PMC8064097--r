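# Delimited-text readers for the trace-table dialect.

#' Read a trace table into breath sessions
#'
#' The trace-table dialect is one row per second per session with columns
#' `session_id`, `t_s`, `co2_pct`, `trigger`, optionally `phase`, and one
#' column per ion channel named `mz<value>`. Participant and timepoint
#' are recovered from `session_id` (`participant_timepoint`).
#'
#' @param x Path to a delimited text file (tab-separated) or a data frame
#'   already in that layout.
#' @return Named list of [breath_session()] objects (insertion order =
#'   order of first appearance).
#' @export
read_trace_table <- function(x) {
  df <- if (is.character(x)) read.delim(x, check.names = FALSE) else x
  need <- c("session_id", "t_s", "co2_pct", "trigger")
  if (!all(need %in% names(df))) {
    stop("trace table must have columns: ", paste(need, collapse = ", "))
  }
  ion_cols <- grep("^mz[0-9]", names(df), value = TRUE)
  if (length(ion_cols) == 0) stop("trace table has no mz<value> ion columns")
  ids <- unique(df$session_id)
  sessions <- lapply(ids, function(sid) {
    d <- df[df$session_id == sid, , drop = FALSE]
    d <- d[order(d$t_s), , drop = FALSE]
    parts <- strsplit(sid, "_", fixed = TRUE)[[1]]
    cps <- as.matrix(d[, ion_cols, drop = FALSE])
    dimnames(cps) <- list(NULL, ion_cols)
    breath_session(
      session_id = sid, time = d$t_s, co2 = d$co2_pct,
      cps = cps,
      trigger = d$trigger,
      phase = if ("phase" %in% names(d)) d$phase else NULL,
      participant = parts[1],
      timepoint = if (length(parts) > 1)
        paste(parts[-1], collapse = "_") else NA_character_
    )
  })
  names(sessions) <- ids
  sessions
}

#' Read a study design table
#'
#' @param path Delimited text file with columns `participant` (or
#'   `participant_id`) and `group`.
#' @return Data frame with columns `participant`, `group`.
#' @export
read_design_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if ("participant_id" %in% names(df) && !"participant" %in% names(df)) {
    names(df)[names(df) == "participant_id"] <- "participant"
  }
  if (!all(c("participant", "group") %in% names(df))) {
    stop("design table must have columns participant(_id) and group")
  }
  df
}
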