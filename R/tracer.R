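# CO2-trigger detection, end-tidal extraction, duplicate pairing and
# carryover QC on 1 Hz instrument traces.

#' Construct a raw trace session
#'
#' One continuously recorded sampling session (one participant at one
#' timepoint): a uniform 1 Hz time grid with the CO2 percentage, the
#' hardware trigger channel, a ticks-by-ions cps matrix and a phase
#' label per tick (`background`, `breath`, `flush` or `unknown`).
#'
#' @param session_id Identifier (conventionally `participant_timepoint`).
#' @param time Seconds; strictly increasing, uniform 1 s spacing.
#' @param co2 CO2 percentage per tick (>= 0).
#' @param cps Ticks-by-ions matrix of counts per second (>= 0), columns
#'   named by channel (`mz<value>`).
#' @param trigger Optional 0/1 hardware trigger channel; derived from
#'   `co2 >= 4` when missing.
#' @param phase Optional phase label per tick (default `unknown`).
#' @param participant,timepoint Optional design fields.
#' @return Object of class `breath_session`.
#' @export
breath_session <- function(session_id, time, co2, cps, trigger = NULL,
                           phase = NULL, participant = NA_character_,
                           timepoint = NA_character_) {
  n <- length(time)
  stopifnot(n >= 1, length(co2) == n, is.matrix(cps), nrow(cps) == n,
            !is.null(colnames(cps)))
  if (n > 1) {
    dt <- diff(time)
    if (any(dt <= 0) || any(abs(dt - 1) > 1e-9)) {
      stop("time must be strictly increasing with uniform 1 s spacing")
    }
  }
  if (any(co2 < 0) || any(cps < 0)) stop("co2 and cps must be non-negative")
  if (is.null(trigger)) trigger <- as.integer(co2 >= 4)
  if (is.null(phase)) phase <- rep("unknown", n)
  structure(list(
    session_id = session_id, participant = participant, timepoint = timepoint,
    time = as.numeric(time), co2 = as.numeric(co2),
    trigger = as.integer(trigger), cps = cps, phase = phase
  ), class = "breath_session")
}

#' @export
print.breath_session <- function(x, ...) {
  cat(sprintf("breath_session %s: %d ticks, %d ion channels, %d exhalation(s)\n",
              x$session_id, length(x$time), ncol(x$cps),
              length(detect_triggers(x))))
  invisible(x)
}

#' Detect CO2 exhalation triggers
#'
#' A trigger fires at the first tick where the CO2 concentration crosses
#' the threshold from below (an exhalation reaching the end-tidal
#' plateau). The detector then re-arms only after CO2 falls back below
#' the threshold, so a noisy plateau cannot fire twice within one
#' exhalation. A trace already at/above threshold at its first tick
#' triggers there.
#'
#' @param session A [breath_session()].
#' @param threshold CO2 percentage (default 4).
#' @return Sorted numeric vector of trigger times (possibly empty).
#' @export
detect_triggers <- function(session, threshold = 4) {
  co2 <- session$co2
  high <- co2 >= threshold
  rising <- high & !c(FALSE, high[-length(high)])
  session$time[rising]
}

#' Extract the end-tidal fraction of each exhalation
#'
#' For each trigger, averages the ion signal over the window starting
#' `delay_s` seconds after trigger activation and lasting `window_s`
#' seconds (default 5 + 5 s: at 1 Hz, five spectra per breath sample).
#' A sample whose window runs past the end of the exhalation (CO2 drops
#' below threshold inside the window) or past the end of the recording
#' is flagged `short_exhalation` rather than silently truncated, so that
#' every retained sample averages the same number of spectra.
#'
#' @param session A [breath_session()].
#' @param triggers Trigger times, normally from [detect_triggers()].
#' @param delay_s,window_s Window delay and length in seconds (> 0).
#' @param co2_threshold End-tidal CO2 threshold used for the overrun
#'   check.
#' @return Data frame of class `breath_samples`: one row per trigger
#'   with session/meta columns, `n_spectra`, QC flag columns, and one
#'   mean-cps column per ion channel (attribute `ion_cols`).
#' @export
extract_end_tidal <- function(session, triggers = detect_triggers(session),
                              delay_s = 5, window_s = 5, co2_threshold = 4) {
  stopifnot(delay_s > 0, window_s > 0)
  ions <- colnames(session$cps)
  rows <- lapply(seq_along(triggers), function(i) {
    t0 <- triggers[i]
    sel <- session$time >= t0 + delay_s & session$time < t0 + delay_s + window_s
    n_spec <- sum(sel)
    overrun <- n_spec < window_s # 1 Hz grid: expected one spectrum per second
    short <- overrun || any(session$co2[sel] < co2_threshold)
    if (short) {
      message(sprintf("session %s: sample %d flagged short_exhalation (trigger t=%g)",
                      session$session_id, i, t0))
    }
    m <- if (n_spec > 0) colMeans(session$cps[sel, , drop = FALSE]) else
      setNames(rep(NA_real_, length(ions)), ions)
    cbind(
      data.frame(session_id = session$session_id,
                 participant = session$participant,
                 timepoint = session$timepoint,
                 sample_index = i, trigger_time = t0,
                 win_start = t0 + delay_s, win_end = t0 + delay_s + window_s,
                 n_spectra = n_spec,
                 short_exhalation = short, carryover_suspect = FALSE,
                 missing_replicate = FALSE, replicate = NA_integer_,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(m))
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(session_id = character(), participant = character(),
                     timepoint = character(), sample_index = integer(),
                     trigger_time = numeric(), win_start = numeric(),
                     win_end = numeric(), n_spectra = integer(),
                     short_exhalation = logical(), carryover_suspect = logical(),
                     missing_replicate = logical(), replicate = integer()),
          as.data.frame(matrix(numeric(0), 0, length(ions),
                               dimnames = list(NULL, ions))))
  names(out)[seq(ncol(out) - length(ions) + 1, ncol(out))] <- ions
  attr(out, "ion_cols") <- ions
  class(out) <- c("breath_samples", class(out))
  out
}

#' Pair duplicate breath samples within a session
#'
#' Each participant provided two single-breath samples per timepoint.
#' The first two unflagged samples of a session become replicates 1 and
#' 2; sessions with fewer than two usable samples keep what they have
#' and are flagged `missing_replicate`; sessions with none are dropped
#' with a message.
#'
#' @param samples A `breath_samples` data frame (possibly several
#'   sessions).
#' @return The same data frame with `replicate` filled in (NA for unused
#'   samples) and `missing_replicate` updated.
#' @export
pair_duplicates <- function(samples) {
  ions <- attr(samples, "ion_cols")
  parts <- split(seq_len(nrow(samples)), samples$session_id)
  for (idx in parts) {
    usable <- idx[!samples$short_exhalation[idx] &
                  !samples$carryover_suspect[idx]]
    if (length(usable) == 0) {
      message("session ", samples$session_id[idx[1]],
              ": no usable breath sample, session excluded")
      samples$missing_replicate[idx] <- TRUE
      next
    }
    take <- head(usable, 2)
    samples$replicate[take] <- seq_along(take)
    if (length(take) < 2) {
      message("session ", samples$session_id[idx[1]],
              ": only one usable sample, flagged missing_replicate")
      samples$missing_replicate[idx] <- TRUE
    }
  }
  attr(samples, "ion_cols") <- ions
  samples
}

#' Flag carryover-suspect samples
#'
#' Compounds such as ethanol and monoterpenes can linger in the sampling
#' line after a contaminated breath. A sample is flagged when the
#' room-air signal just before its exhalation exceeds `factor` times the
#' session's catalyzed-air background median for a watched ion. Requires
#' a labelled background phase; otherwise flags are indeterminate and a
#' message is logged.
#'
#' @param session The [breath_session()] the samples came from.
#' @param samples `breath_samples` rows of that session.
#' @param ions Watched channels (default ethanol and the monoterpene
#'   fragment).
#' @param factor Flagging multiple of the background median (default 3).
#' @param pre_window_s Room-air lookback: ticks in
#'   `[trigger - pre_window_s, trigger - 2)` with CO2 < 1\% are used.
#' @param min_excess_cps Absolute excess over the background median a
#'   watched ion must additionally show; guards against flags driven by
#'   counting statistics on near-zero backgrounds.
#' @return `samples` with `carryover_suspect` updated.
#' @export
flag_carryover <- function(session, samples, ions = c("mz47.05", "mz81.08"),
                           factor = 3, pre_window_s = 10,
                           min_excess_cps = 5) {
  ion_cols <- attr(samples, "ion_cols")
  ions <- intersect(ions, colnames(session$cps))
  if (length(ions) == 0) return(samples)
  bg <- session$phase == "background"
  if (!any(bg)) {
    message("session ", session$session_id,
            ": no background phase, carryover flags indeterminate")
    return(samples)
  }
  bg_med <- apply(session$cps[bg, ions, drop = FALSE], 2, median)
  here <- which(samples$session_id == session$session_id)
  for (i in here) {
    t0 <- samples$trigger_time[i]
    sel <- session$time >= t0 - pre_window_s & session$time < t0 - 2 &
      session$co2 < 1
    if (!any(sel)) next
    pre <- colMeans(session$cps[sel, ions, drop = FALSE])
    hot <- pre > factor * bg_med & pre - bg_med > min_excess_cps
    if (any(hot)) {
      samples$carryover_suspect[i] <- TRUE
      message(sprintf("session %s: sample %d carryover_suspect (%s)",
                      session$session_id, samples$sample_index[i],
                      paste(ions[hot], collapse = ", ")))
    }
  }
  attr(samples, "ion_cols") <- ion_cols
  samples
}
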