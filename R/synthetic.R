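# Synthetic study generator: raw 1 Hz trace sessions with CO2-triggered
# exhalations, a known effect structure and full ground truth, emulating
# a three-group five-timepoint repeated-measures breath campaign.

#' Study design specification
#'
#' The sampling design of the synthetic campaign. Defaults reproduce the
#' field study's structure: 62 participants in three groups (non-statin
#' users St0 n=24, statin users St1 n=17, statin users with muscle
#' complaints St2 n=21), five timepoints (pre-walking baseline Day0,
#' post-walking Day1/Day2/Day3, and the pre-walking Day2am), and
#' duplicate breath samples per participant-timepoint.
#'
#' @param n_per_group Named counts per group (each >= 2).
#' @param timepoints Ordered timepoint labels (non-empty, unique).
#' @param replicates_per_timepoint Breath samples per session (default 2).
#' @param ion_table Ion panel (see [default_ion_table()]); must contain
#'   exactly one primary channel at m/z 21.02 and one at 39.03, and every
#'   fragment must reference an existing parent channel.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return List of class `study_design_spec`.
#' @export
study_design_spec <- function(n_per_group = c(St0 = 24, St1 = 17, St2 = 21),
                              timepoints = c("Day0", "Day1", "Day2am",
                                             "Day2", "Day3"),
                              replicates_per_timepoint = 2,
                              ion_table = default_ion_table(),
                              seed = 1) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("n_per_group must be named by group")
  }
  if (any(n_per_group < 2)) stop("every group needs at least 2 participants")
  if (length(timepoints) < 1 || anyDuplicated(timepoints)) {
    stop("timepoints must be non-empty, ordered and unique")
  }
  if (replicates_per_timepoint < 1) stop("need >= 1 replicate per timepoint")
  prim <- ion_table$channel[ion_table$role == "primary"]
  if (!setequal(prim, c("mz21.02", "mz39.03")) || length(prim) != 2) {
    stop("ion table must contain exactly one primary channel each at ",
         "m/z 21.02 and 39.03")
  }
  frag <- !is.na(ion_table$parent)
  if (any(frag)) {
    par_ok <- ion_table$parent[frag] %in%
      ion_table$channel[is.na(ion_table$parent) & ion_table$role != "primary"]
    if (!all(par_ok)) {
      stop("fragment parent(s) not found among parent channels: ",
           paste(ion_table$parent[frag][!par_ok], collapse = ", "))
    }
  }
  structure(list(n_per_group = n_per_group, timepoints = timepoints,
                 replicates_per_timepoint = replicates_per_timepoint,
                 ion_table = ion_table, seed = as.integer(seed)),
            class = "study_design_spec")
}

#' Effect specification for the synthetic study
#'
#' True effect structure on the natural-log concentration scale. The
#' defaults encode the campaign's qualitative findings as generative
#' truth: all endogenous compounds rise after the first day of walking
#' (+`exercise_day1`), relax most of the way back by the next pre-walking
#' morning (+`exercise_rest`), and rise again after the second and third
#' walking days (+`exercise_later`, equal on both days so their breath
#' profiles overlap); isoprene carries the same pattern with opposite
#' sign. The short-chain fatty acids additionally get a group-by-time
#' effect: non-statin users (St0) respond more strongly post-walking
#' (+`scfa_group_boost`), while statin users stay elevated at the
#' pre-walking morning (+`statin_rest_boost`). Ethanol and monoterpene
#' occasionally show large exogenous outliers (alcohol/food intake).
#'
#' @param design A [study_design_spec()] (supplies ion panel, groups,
#'   timepoints).
#' @param baseline_ppbv Named baseline concentrations (ppbv) per parent
#'   channel; defaults are typical breath levels. The designed trace
#'   channel at m/z 131.07 sits below the detection limit.
#' @param responsive_channels Channels carrying the exercise effect
#'   (default: the nine identified endogenous compounds; fragments
#'   inherit their parent's response).
#' @param subject_sd Between-subject random-effect SD (log scale).
#' @param noise_cv Within-replicate technical coefficient of variation
#'   (< 1); multiplicative lognormal noise on each replicate.
#' @param counting_noise Add Poisson counting noise on cps (default
#'   TRUE); set FALSE together with `noise_cv = 0` for fully
#'   deterministic signals.
#' @param exercise_day1,exercise_rest,exercise_later Exercise effect at
#'   Day1 / pre-walking rest (Day2am) / Day2 and Day3, log units.
#' @param isoprene_sign Sign flip of the isoprene effect (-1).
#' @param scfa_group_boost,statin_rest_boost Group-by-time SCFA effects,
#'   log units.
#' @param outlier_rate,outlier_magnitude Probability and log-scale size
#'   of exogenous outliers per participant-timepoint (post-walking).
#' @param background_mean,background_sd Catalyzed-air background cps per
#'   ion channel.
#' @param primary_cps Mean cps of the two primary-ion channels.
#' @param exercise_effect,group_effect Optional full overrides: a
#'   parents-by-timepoints matrix and a parents-by-groups-by-timepoints
#'   array.
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(design = study_design_spec(),
                        baseline_ppbv = c(mz33.03 = 150, mz45.03 = 25,
                                          mz47.05 = 100, mz59.05 = 500,
                                          mz69.07 = 100, mz87.09 = 5,
                                          mz61.03 = 30, mz75.05 = 10,
                                          mz89.06 = 5, mz137.13 = 2,
                                          mz149.10 = 1.5,
                                          mz42.03 = 5, mz49.01 = 2,
                                          mz60.08 = 1.5, mz63.03 = 8,
                                          mz73.06 = 10, mz79.05 = 3,
                                          mz83.09 = 2, mz85.10 = 1.5,
                                          mz93.07 = 2, mz95.09 = 1.2,
                                          mz99.08 = 1.5, mz101.10 = 3,
                                          mz107.09 = 1.5, mz109.10 = 1.2,
                                          mz111.12 = 1.2, mz121.10 = 1.5,
                                          mz135.12 = 1.2, mz143.14 = 1.5,
                                          mz131.07 = 0.15),
                        responsive_channels = c("mz33.03", "mz45.03",
                                                "mz47.05", "mz59.05",
                                                "mz69.07", "mz87.09",
                                                "mz61.03", "mz75.05",
                                                "mz89.06"),
                        subject_sd = 0.4, noise_cv = 0.10,
                        counting_noise = TRUE,
                        exercise_day1 = 0.5, exercise_rest = 0.1,
                        exercise_later = 0.4, isoprene_sign = -1,
                        scfa_group_boost = 0.5, statin_rest_boost = 0.2,
                        outlier_rate = 0.048, outlier_magnitude = 2.5,
                        background_mean = 2, background_sd = 0.5,
                        primary_cps = c(mz21.02 = 1000, mz39.03 = 2000),
                        exercise_effect = NULL, group_effect = NULL) {
  it <- design$ion_table
  tps <- design$timepoints
  grps <- names(design$n_per_group)
  parents <- it$channel[is.na(it$parent) & it$role != "primary"]
  if (!all(parents %in% names(baseline_ppbv))) {
    stop("baseline_ppbv missing for: ",
         paste(setdiff(parents, names(baseline_ppbv)), collapse = ", "))
  }
  if (subject_sd < 0 || background_sd < 0 || noise_cv < 0) {
    stop("all spreads must be >= 0")
  }
  if (noise_cv >= 1) stop("noise_cv must be < 1")
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate in [0, 1]")

  if (is.null(exercise_effect)) {
    exercise_effect <- matrix(0, length(parents), length(tps),
                              dimnames = list(parents, tps))
    endo <- intersect(parents, responsive_channels)
    if ("Day1" %in% tps) exercise_effect[endo, "Day1"] <- exercise_day1
    if ("Day2am" %in% tps) exercise_effect[endo, "Day2am"] <- exercise_rest
    for (tp in intersect(c("Day2", "Day3"), tps)) {
      exercise_effect[endo, tp] <- exercise_later
    }
    if ("mz69.07" %in% endo) {
      exercise_effect["mz69.07", ] <- isoprene_sign *
        exercise_effect["mz69.07", ]
    }
  } else {
    exercise_effect <- as.matrix(exercise_effect)
    stopifnot(all(dim(exercise_effect) == c(length(parents), length(tps))))
    dimnames(exercise_effect) <- list(parents, tps)
  }
  if (!is.null(group_effect)) {
    stopifnot(all(dim(group_effect) == c(length(parents), length(grps),
                                         length(tps))))
    group_effect <- array(group_effect,
                          dim = c(length(parents), length(grps), length(tps)),
                          dimnames = list(parents, grps, tps))
  } else {
    group_effect <- array(0, dim = c(length(parents), length(grps),
                                     length(tps)),
                          dimnames = list(parents, grps, tps))
    scfa <- intersect(c("mz61.03", "mz75.05", "mz89.06"), parents)
    if ("St0" %in% grps && length(scfa)) {
      for (tp in intersect(c("Day1", "Day2", "Day3"), tps)) {
        group_effect[scfa, "St0", tp] <- scfa_group_boost
      }
    }
    for (g in intersect(c("St1", "St2"), grps)) {
      if ("Day2am" %in% tps && length(scfa)) {
        group_effect[scfa, g, "Day2am"] <- statin_rest_boost
      }
    }
  }
  # isoprene must respond opposite to the bulk of the endogenous panel
  if ("mz69.07" %in% parents) {
    others <- setdiff(intersect(parents, responsive_channels), "mz69.07")
    s_iso <- sum(exercise_effect["mz69.07", ])
    s_oth <- sum(exercise_effect[others, , drop = FALSE])
    if (s_iso != 0 && s_oth != 0 && sign(s_iso) == sign(s_oth)) {
      stop("isoprene exercise effect must have the opposite sign to the ",
           "rest of the endogenous panel")
    }
  }
  structure(list(
    baseline_log_mean = log(baseline_ppbv[parents]),
    subject_sd = subject_sd, noise_cv = noise_cv,
    counting_noise = counting_noise,
    exercise_effect = exercise_effect, group_effect = group_effect,
    outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
    outlier_ions = intersect(c("mz47.05", "mz137.13"), parents),
    outlier_timepoints = intersect(c("Day1", "Day2", "Day3"), tps),
    background_mean = background_mean, background_sd = background_sd,
    primary_cps = primary_cps
  ), class = "effect_spec")
}

# trapezoidal CO2 profile of one exhalation: 2 s rise, plateau, 2 s fall
.RISE_FRAC <- c(0.30, 0.70)
.FALL_FRAC <- c(0.60, 0.25)
.ROOM_CO2 <- 0.04

#' Simulate a breath study
#'
#' Generates one raw 1 Hz trace session per participant-timepoint. Each
#' session starts with a catalyzed-air background segment and contains
#' one exhalation per replicate, separated by room-air flush gaps. CO2
#' follows a trapezoid (2 s rise, >= 15 s plateau between 4.6 and 5.4\%,
#' 2 s fall) so the full extraction window always fits inside the
#' plateau; the trigger channel goes high exactly when CO2 first reaches
#' 4\% within an exhalation and resets in between. During the breath
#' phase each ion's cps is proportional to the replicate's true
#' concentration (inverting the quantification chain exactly), with
#' multiplicative lognormal technical noise per replicate and optional
#' Poisson counting noise per tick; room-air and background phases sit
#' at the catalyzed-air background level. Everything is deterministic
#' given `design$seed`.
#'
#' @param design A [study_design_spec()].
#' @param effects An [effect_spec()].
#' @param config A [kinetic_config()]; defines the cps <-> ppbv mapping.
#' @param delay_s,window_s End-tidal extraction window the traces must
#'   support; rejected if `delay_s + window_s` exceeds the plateau.
#' @param plateau_s Plateau length in seconds (>= delay + window).
#' @param background_s,flush_s Background and inter-breath gap lengths.
#' @param traces Assemble raw trace sessions (default TRUE). With FALSE
#'   only the ground-truth concentrations are generated (faster; the
#'   random stream then differs from a traced run).
#' @return List of class `breath_study`: `sessions` (named list of
#'   [breath_session()]), `design` (participant/group table), `ion_table`
#'   and `truth` (subject- and replicate-level true concentrations,
#'   per-ion effect flags, subject offsets, trigger times).
#' @export
simulate_study <- function(design = study_design_spec(),
                           effects = effect_spec(design),
                           config = kinetic_config(),
                           delay_s = 5, window_s = 5, plateau_s = 16,
                           background_s = 30, flush_s = 8, traces = TRUE) {
  stopifnot(inherits(design, "study_design_spec"),
            inherits(effects, "effect_spec"))
  if (delay_s + window_s > plateau_s) {
    stop("extraction window (", delay_s + window_s,
         " s) longer than the exhalation plateau (", plateau_s,
         " s): rejected")
  }
  set.seed(design$seed)
  it <- design$ion_table
  tps <- design$timepoints
  grps <- names(design$n_per_group)
  nrep <- design$replicates_per_timepoint
  parents <- rownames(effects$exercise_effect)
  frag_rows <- which(!is.na(it$parent))
  channels <- it$channel
  nonprim <- it$channel[it$role != "primary"]

  n_subj <- sum(design$n_per_group)
  participants <- sprintf("P%02d", seq_len(n_subj))
  group_of <- rep(grps, design$n_per_group)
  design_tab <- data.frame(participant = participants, group = group_of,
                           stringsAsFactors = FALSE)

  sdlog <- sqrt(log(1 + effects$noise_cv^2))
  offsets <- matrix(rnorm(n_subj * length(parents), 0, effects$subject_sd),
                    n_subj, length(parents),
                    dimnames = list(participants, parents))

  # subject-level true concentrations (ppbv), parents then fragments
  meta_s <- expand.grid(timepoint = tps, participant = participants,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta_s <- meta_s[, c("participant", "timepoint")]
  meta_s$group <- group_of[match(meta_s$participant, participants)]
  conc_subject <- matrix(NA_real_, nrow(meta_s), length(channels),
                         dimnames = list(NULL, channels))
  for (i in seq_len(nrow(meta_s))) {
    s <- match(meta_s$participant[i], participants)
    tp <- meta_s$timepoint[i]
    g <- meta_s$group[i]
    logc <- effects$baseline_log_mean + offsets[s, ] +
      effects$exercise_effect[, tp] + effects$group_effect[, g, tp]
    if (tp %in% effects$outlier_timepoints &&
        length(effects$outlier_ions) && effects$outlier_rate > 0) {
      hit <- rbinom(length(effects$outlier_ions), 1,
                    effects$outlier_rate) == 1
      logc[effects$outlier_ions[hit]] <-
        logc[effects$outlier_ions[hit]] + effects$outlier_magnitude
    }
    conc_subject[i, parents] <- exp(logc)
  }
  for (j in frag_rows) {
    conc_subject[, it$channel[j]] <-
      it$frag_fraction[j] * conc_subject[, it$parent[j]]
  }
  conc_subject <- conc_subject[, nonprim, drop = FALSE]

  # replicate-level concentrations: technical noise on parents,
  # fragments carry the parent's noisy signal times a fixed fraction
  meta_r <- meta_s[rep(seq_len(nrow(meta_s)), each = nrep), ]
  meta_r$replicate <- rep(seq_len(nrep), nrow(meta_s))
  rownames(meta_r) <- NULL
  conc_replicate <- matrix(NA_real_, nrow(meta_r), length(channels),
                           dimnames = list(NULL, channels))
  for (i in seq_len(nrow(meta_s))) {
    for (r in seq_len(nrep)) {
      eps <- if (effects$noise_cv > 0)
        exp(rnorm(length(parents), 0, sdlog)) else rep(1, length(parents))
      conc_replicate[(i - 1) * nrep + r, parents] <-
        conc_subject[i, parents] * eps
    }
  }
  for (j in frag_rows) {
    conc_replicate[, it$channel[j]] <-
      it$frag_fraction[j] * conc_replicate[, it$parent[j]]
  }
  conc_replicate <- conc_replicate[, nonprim, drop = FALSE]

  qf <- vapply(nonprim, function(ch) ppbv_per_ncps(config, ch), numeric(1))
  denom <- 500 * effects$primary_cps[["mz21.02"]] +
    250 * effects$primary_cps[["mz39.03"]]
  cps_scale <- denom / config$normalization_target # ncps -> cps

  sessions <- list()
  trig_rows <- list()
  if (traces) {
    for (i in seq_len(nrow(meta_s))) {
      sid <- paste(meta_s$participant[i], meta_s$timepoint[i], sep = "_")
      # layout
      plateau_co2 <- runif(nrep, 4.6, 5.4)
      seg_phase <- c(rep("background", background_s))
      seg_co2 <- rep(.ROOM_CO2, background_s)
      seg_breath <- rep(0L, background_s) # replicate index per tick, 0 = none
      seg_rel <- rep(NA_real_, background_s) # co2 fraction of plateau
      for (r in seq_len(nrep)) {
        seg_phase <- c(seg_phase, rep("flush", flush_s),
                       rep("breath", 2 + plateau_s + 2))
        seg_co2 <- c(seg_co2, rep(.ROOM_CO2, flush_s),
                     .RISE_FRAC * plateau_co2[r],
                     rep(plateau_co2[r], plateau_s),
                     .FALL_FRAC * plateau_co2[r])
        seg_breath <- c(seg_breath, rep(0L, flush_s),
                        rep(r, 2 + plateau_s + 2))
        seg_rel <- c(seg_rel, rep(NA_real_, flush_s),
                     .RISE_FRAC, rep(1, plateau_s), .FALL_FRAC)
      }
      seg_phase <- c(seg_phase, rep("flush", 5))
      seg_co2 <- c(seg_co2, rep(.ROOM_CO2, 5))
      seg_breath <- c(seg_breath, rep(0L, 5))
      seg_rel <- c(seg_rel, rep(NA_real_, 5))
      n_tick <- length(seg_co2)
      tgrid <- seq_len(n_tick) - 1

      cps <- matrix(0, n_tick, length(channels),
                    dimnames = list(NULL, channels))
      bg_tick <- seg_breath == 0L
      for (ch in nonprim) {
        expected <- numeric(n_tick)
        if (effects$background_sd > 0) {
          expected[bg_tick] <- pmax(0, rnorm(sum(bg_tick),
                                             effects$background_mean,
                                             effects$background_sd))
        } else {
          expected[bg_tick] <- effects$background_mean
        }
        for (r in seq_len(nrep)) {
          sel <- seg_breath == r
          c_rep <- conc_replicate[(i - 1) * nrep + r, ch]
          expected[sel] <- c_rep / qf[[ch]] * cps_scale * seg_rel[sel]
        }
        cps[, ch] <- if (effects$counting_noise)
          rpois(n_tick, expected) else expected
      }
      for (ch in names(effects$primary_cps)) {
        expected <- rep(effects$primary_cps[[ch]], n_tick)
        cps[, ch] <- if (effects$counting_noise)
          rpois(n_tick, expected) else expected
      }
      sess <- breath_session(sid, tgrid, seg_co2, cps,
                             trigger = as.integer(seg_co2 >= 4),
                             phase = seg_phase,
                             participant = meta_s$participant[i],
                             timepoint = meta_s$timepoint[i])
      sessions[[sid]] <- sess
      trig_rows[[sid]] <- data.frame(
        session_id = sid, trigger_time = tgrid[c(FALSE, diff(seg_co2 >= 4) == 1)
                                               | c(seg_co2[1] >= 4,
                                                   rep(FALSE, n_tick - 1))],
        stringsAsFactors = FALSE)
    }
  }

  flags <- data.frame(
    channel = nonprim,
    exercise_responsive = vapply(nonprim, function(ch) {
      p <- if (ch %in% parents) ch else it$parent[match(ch, it$channel)]
      any(effects$exercise_effect[p, ] != 0)
    }, logical(1)),
    group_differential = vapply(nonprim, function(ch) {
      p <- if (ch %in% parents) ch else it$parent[match(ch, it$channel)]
      any(effects$group_effect[p, , ] != 0)
    }, logical(1)),
    stringsAsFactors = FALSE
  )

  structure(list(
    sessions = sessions, design = design_tab, ion_table = it,
    truth = list(meta_subject = meta_s, conc_subject = conc_subject,
                 meta_replicate = meta_r, conc_replicate = conc_replicate,
                 flags = flags, offsets = offsets,
                 triggers = if (length(trig_rows))
                   do.call(rbind, c(trig_rows, make.row.names = FALSE))
                 else NULL),
    design_spec = design, effects = effects, config = config
  ), class = "breath_study")
}

#' @export
print.breath_study <- function(x, ...) {
  cat(sprintf(
    "breath_study: %d participants (%s), %d timepoints, %d sessions\n",
    nrow(x$design),
    paste(sprintf("%s=%d", names(x$design_spec$n_per_group),
                  x$design_spec$n_per_group), collapse = "/"),
    length(x$design_spec$timepoints), length(x$sessions)))
  invisible(x)
}

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write '", path, "': ", conditionMessage(ok))
  }
  invisible(path)
}

#' Write a simulated study to plain-text fixtures
#'
#' Writes the study in the package's delimited-text dialect: `traces.tsv`
#' (session_id, t_s, co2_pct, trigger, phase, one `mz<value>` column per
#' channel), `design.tsv`, `ions.tsv` and the ground-truth tables. Files
#' round-trip through [read_fixtures()].
#'
#' @param study A [simulate_study()] result.
#' @param dir Writable directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(study, dir) {
  stopifnot(inherits(study, "breath_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- study$ion_table$channel
  if (length(study$sessions)) {
    traces <- do.call(rbind, lapply(study$sessions, function(s) {
      cbind(data.frame(session_id = s$session_id, t_s = s$time,
                       co2_pct = s$co2, trigger = s$trigger, phase = s$phase,
                       stringsAsFactors = FALSE),
            as.data.frame(s$cps))
    }))
    rownames(traces) <- NULL
  } else {
    traces <- cbind(
      data.frame(session_id = character(), t_s = numeric(),
                 co2_pct = numeric(), trigger = integer(), phase = character()),
      as.data.frame(matrix(numeric(0), 0, length(channels),
                           dimnames = list(NULL, channels))))
  }
  files <- c(
    traces = file.path(dir, "traces.tsv"),
    design = file.path(dir, "design.tsv"),
    ions = file.path(dir, "ions.tsv"),
    truth_subject = file.path(dir, "truth_subject.tsv"),
    truth_replicate = file.path(dir, "truth_replicate.tsv"),
    truth_flags = file.path(dir, "truth_flags.tsv")
  )
  .write_tsv(traces, files[["traces"]])
  .write_tsv(study$design, files[["design"]])
  .write_tsv(study$ion_table, files[["ions"]])
  .write_tsv(cbind(study$truth$meta_subject,
                   as.data.frame(study$truth$conc_subject)),
             files[["truth_subject"]])
  .write_tsv(cbind(study$truth$meta_replicate,
                   as.data.frame(study$truth$conc_replicate)),
             files[["truth_replicate"]])
  .write_tsv(study$truth$flags, files[["truth_flags"]])
  if (!is.null(study$truth$triggers)) {
    files <- c(files, triggers = file.path(dir, "triggers.tsv"))
    .write_tsv(study$truth$triggers, files[["triggers"]])
  }
  invisible(files)
}

#' Read study fixtures written by [write_fixtures()]
#'
#' @param dir Directory containing the fixture files.
#' @return List with `sessions`, `design`, `ion_table` and `truth`
#'   (tables as written).
#' @export
read_fixtures <- function(dir) {
  traces <- read.delim(file.path(dir, "traces.tsv"), check.names = FALSE)
  design <- read.delim(file.path(dir, "design.tsv"), check.names = FALSE)
  ion_table <- read.delim(file.path(dir, "ions.tsv"), check.names = FALSE)
  sessions <- read_trace_table(traces)
  truth <- list(
    subject = read.delim(file.path(dir, "truth_subject.tsv"),
                         check.names = FALSE),
    replicate = read.delim(file.path(dir, "truth_replicate.tsv"),
                           check.names = FALSE),
    flags = read.delim(file.path(dir, "truth_flags.tsv"), check.names = FALSE)
  )
  trg <- file.path(dir, "triggers.tsv")
  if (file.exists(trg)) truth$triggers <- read.delim(trg, check.names = FALSE)
  list(sessions = sessions, design = design, ion_table = ion_table,
       truth = truth)
}
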