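# Session set -> quantified, LoD-filtered study matrix.

#' Quantify a set of breath sessions
#'
#' Runs the full per-session chain — trigger detection, end-tidal
#' extraction, carryover QC, duplicate pairing — then normalizes each
#' sample's mean cps to the primary-ion signal averaged over the same
#' window, converts to ppbv with the kinetic configuration, pools the
#' catalyzed-air background across sessions into per-ion LoDs, replaces
#' sub-LoD values, and applies the per-group retention filter.
#'
#' @param sessions Named list of [breath_session()] (e.g. from
#'   [simulate_study()] or [read_trace_table()]).
#' @param design Data frame with `participant` and `group`; group labels
#'   drive the retention filter. With NULL, all samples form one group.
#' @param config A [kinetic_config()].
#' @param ion_table Ion panel; primary channels are consumed by the
#'   normalization and do not appear as analyte columns.
#' @param delay_s,window_s,co2_threshold End-tidal extraction settings.
#' @param carryover_ions,carryover_factor Carryover QC settings (see
#'   [flag_carryover()]).
#' @return Object of class `study_matrix`: list with `conc` (paired,
#'   unflagged samples by analyte ions, ppbv, after LoD replacement),
#'   `meta` (participant, group, timepoint, replicate per row), masks
#'   `below_lod`/`above_lod`, `lods`, `retained` (channels passing the
#'   filter), `samples` (the full per-sample QC table) and `ion_table`.
#' @export
quantify_sessions <- function(sessions, design = NULL,
                              config = kinetic_config(),
                              ion_table = default_ion_table(),
                              delay_s = 5, window_s = 5, co2_threshold = 4,
                              carryover_ions = c("mz47.05", "mz81.08"),
                              carryover_factor = 3) {
  stopifnot(length(sessions) >= 1)
  all_samples <- list()
  bg_conc <- list()
  first <- sessions[[1]]
  prim <- intersect(c("mz21.02", "mz39.03"), colnames(first$cps))
  if (length(prim) != 2) {
    stop("sessions must carry both primary channels mz21.02 and mz39.03")
  }
  analytes <- setdiff(colnames(first$cps), prim)

  for (sess in sessions) {
    smp <- extract_end_tidal(sess, detect_triggers(sess, co2_threshold),
                             delay_s = delay_s, window_s = window_s,
                             co2_threshold = co2_threshold)
    smp <- flag_carryover(sess, smp, ions = carryover_ions,
                          factor = carryover_factor)
    smp <- pair_duplicates(smp)
    all_samples[[sess$session_id]] <- smp
    bg <- sess$phase == "background"
    if (any(bg)) {
      ncps_bg <- normalize_primary_ions(
        sess$cps[bg, analytes, drop = FALSE],
        sess$cps[bg, "mz21.02"], sess$cps[bg, "mz39.03"],
        target = config$normalization_target)
      bg_conc[[sess$session_id]] <- vapply(analytes, function(ch) {
        cps_to_concentration(ncps_bg[, ch], config, ch)
      }, numeric(sum(bg)))
    }
  }
  samples <- do.call(rbind, c(all_samples, make.row.names = FALSE))
  attr(samples, "ion_cols") <- attr(all_samples[[1]], "ion_cols")

  keep <- !is.na(samples$replicate)
  used <- samples[keep, , drop = FALSE]
  ncps <- normalize_primary_ions(
    as.matrix(used[, analytes, drop = FALSE]),
    used[["mz21.02"]], used[["mz39.03"]],
    target = config$normalization_target)
  conc <- vapply(analytes, function(ch) {
    cps_to_concentration(ncps[, ch], config, ch)
  }, numeric(nrow(used)))
  conc <- matrix(conc, nrow = nrow(used),
                 dimnames = list(NULL, analytes))

  if (length(bg_conc) == 0) {
    stop("no background phase in any session; LoD unavailable")
  }
  bg_all <- do.call(rbind, bg_conc)
  lods <- compute_lod(bg_all)

  lodded <- apply_lod(conc, lods)
  above <- sweep(conc, 2, lods[analytes], ">")

  meta <- data.frame(
    session_id = used$session_id, participant = used$participant,
    timepoint = used$timepoint, replicate = used$replicate,
    stringsAsFactors = FALSE)
  if (!is.null(design)) {
    meta$group <- design$group[match(meta$participant, design$participant)]
    if (anyNA(meta$group)) {
      stop("design table misses group labels for: ",
           paste(unique(meta$participant[is.na(meta$group)]), collapse = ", "))
    }
  } else {
    meta$group <- "all"
  }
  retained <- filter_ions(above, meta$group)

  structure(list(conc = lodded$conc, meta = meta,
                 below_lod = lodded$below_lod, above_lod = above,
                 lods = lods, retained = retained, samples = samples,
                 ion_table = ion_table), class = "study_matrix")
}

#' Retained concentration matrix of a study
#'
#' @param sm A `study_matrix`.
#' @param retained_only Keep only ions passing the retention filter.
#' @return Numeric samples-by-ions matrix (ppbv).
#' @export
study_conc <- function(sm, retained_only = TRUE) {
  stopifnot(inherits(sm, "study_matrix"))
  if (retained_only) sm$conc[, sm$retained, drop = FALSE] else sm$conc
}

#' @export
print.study_matrix <- function(x, ...) {
  cat(sprintf(
    "study_matrix: %d samples x %d ions (%d retained), %d below-LoD entries\n",
    nrow(x$conc), ncol(x$conc), length(x$retained), sum(x$below_lod)))
  invisible(x)
}

#' Collapse duplicates to one row per participant-timepoint
#'
#' Downstream statistics use the mean of the two duplicate
#' concentrations per participant-timepoint as the analysis unit
#' (avoiding pseudo-replication).
#'
#' @param sm A `study_matrix`.
#' @return A `study_matrix` with one row per participant-timepoint (no
#'   `replicate` column; masks are dropped).
#' @export
collapse_replicates <- function(sm) {
  stopifnot(inherits(sm, "study_matrix"))
  key <- paste(sm$meta$participant, sm$meta$timepoint, sep = "\r")
  idx <- split(seq_len(nrow(sm$conc)), key)
  conc <- t(vapply(idx, function(i) colMeans(sm$conc[i, , drop = FALSE]),
                   numeric(ncol(sm$conc))))
  first <- vapply(idx, `[`, integer(1), 1L)
  meta <- sm$meta[first, c("participant", "timepoint", "group"), drop = FALSE]
  rownames(meta) <- NULL
  ord <- order(match(meta$participant, unique(sm$meta$participant)),
               match(meta$timepoint, unique(sm$meta$timepoint)))
  structure(list(conc = conc[ord, , drop = FALSE], meta = meta[ord, ],
                 lods = sm$lods, retained = sm$retained,
                 ion_table = sm$ion_table), class = "study_matrix")
}
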