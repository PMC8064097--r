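# Shared builders for the test suite. Everything is generated in code.

# hand-built session: trapezoid CO2 around given plateau, constant ion cps
make_session <- function(co2, cps_values = NULL, ions = c("mz21.02", "mz39.03",
                                                          "mz59.05"),
                         phase = NULL, id = "T01_Day0") {
  n <- length(co2)
  if (is.null(cps_values)) {
    cps <- matrix(rep(c(1000, 2000, 100), each = n), n, length(ions),
                  dimnames = list(NULL, ions))
  } else {
    cps <- matrix(cps_values, n, length(ions),
                  dimnames = list(NULL, ions))
  }
  breath_session(id, seq_len(n) - 1, co2, cps, phase = phase,
                 participant = "T01", timepoint = "Day0")
}

# small 7-participant design for fast pipeline runs
tiny_design <- function(seed = 7, ...) {
  study_design_spec(n_per_group = c(St0 = 3, St1 = 2, St2 = 2), seed = seed,
                    ...)
}

quiet_quantify <- function(study, ...) {
  suppressMessages(quantify_sessions(study$sessions, study$design, ...))
}

# the full-size default study is expensive; build it once per test run
.study_cache <- new.env(parent = emptyenv())
default_study_matrix <- function(seed = 20260927) {
  key <- as.character(seed)
  if (is.null(.study_cache[[key]])) {
    st <- simulate_study(study_design_spec(seed = seed))
    .study_cache[[key]] <- list(study = st, sm = quiet_quantify(st))
  }
  .study_cache[[key]]
}
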