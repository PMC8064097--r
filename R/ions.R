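# Accurate-mass arithmetic for protonated product ions and the default
# ion panel of the breath study.

# CODATA/AME monoisotopic atomic masses (u); [18O] is the oxygen-18 isotope
# used by the primary-ion isotopologue channels.
.ATOMIC_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  `[18O]` = 17.9991610
)
.ELECTRON_MASS <- 0.000548579909

#' Parse an ion formula
#'
#' Parses formulas such as `"C3H6OH+"` or `"H3[18O]+"` over the elements
#' C, H, O, N, S and the oxygen-18 isotope written `[18O]`. A single
#' trailing `+` (charge +1) is allowed and ignored for counting.
#'
#' @param formula Character scalar.
#' @return Named integer vector of element counts.
#' @keywords internal
parse_ion_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  body <- sub("\\+$", "", formula)
  pat <- "\\[18O\\][0-9]*|[A-Z][a-z]?[0-9]*"
  toks <- regmatches(body, gregexpr(pat, body))[[1]]
  if (paste(toks, collapse = "") != body) {
    left <- body
    for (tk in toks) left <- sub(tk, "", left, fixed = TRUE)
    stop("cannot parse formula '", formula, "': offending token near '",
         substr(left, 1, 4), "'")
  }
  counts <- integer(0)
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    n <- sub("^.*?([0-9]*)$", "\\1", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.ATOMIC_MASS)) {
      stop("cannot parse formula '", formula, "': unknown element '", el, "'")
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Theoretical m/z of a protonated (charge +1) ion
#'
#' Monoisotopic mass of the ion formula minus one electron mass. High
#' mass resolution instruments report these values to two decimals; the
#' full-precision value is returned here.
#'
#' @param formula Ion formula, e.g. `"C3H6OH+"` for protonated acetone
#'   (59.0491) or `"H3[18O]+"` for the calibration isotopologue (21.0221).
#' @return Numeric m/z (charge +1 assumed).
#' @examples
#' round(theoretical_mz("C3H6OH+"), 2)  # acetone, 59.05
#' round(theoretical_mz("H3[18O]+"), 2) # 21.02
#' @export
theoretical_mz <- function(formula) {
  counts <- parse_ion_formula(formula)
  sum(.ATOMIC_MASS[names(counts)] * counts) - .ELECTRON_MASS
}

#' Match a measured m/z against candidate formulas
#'
#' Ranks candidate formulas by absolute ppm error against a measured m/z.
#' The default tolerance of 200 ppm reflects a ToF resolving power of
#' 4000-5000 (peaks are separated to roughly that relative precision).
#'
#' @param mz Measured m/z (numeric scalar).
#' @param candidates Data frame with at least columns `formula` and
#'   (optionally) `compound`; defaults to [default_ion_table()].
#' @param tol_ppm Tolerance in ppm (> 0).
#' @return Data frame of matching candidates sorted by |ppm error|,
#'   with columns `formula`, `compound`, `theoretical_mz`, `ppm_error`.
#'   Zero rows when nothing matches.
#' @export
match_formula <- function(mz, candidates = default_ion_table(), tol_ppm = 200) {
  stopifnot(is.numeric(mz), length(mz) == 1L, tol_ppm > 0)
  cand <- candidates[!is.na(candidates$formula), , drop = FALSE]
  th <- vapply(cand$formula, theoretical_mz, numeric(1))
  ppm <- (mz - th) / th * 1e6
  keep <- abs(ppm) <= tol_ppm
  out <- data.frame(
    formula = cand$formula[keep],
    compound = if ("compound" %in% names(cand)) cand$compound[keep] else NA_character_,
    theoretical_mz = th[keep],
    ppm_error = ppm[keep],
    stringsAsFactors = FALSE
  )
  out[order(abs(out$ppm_error)), , drop = FALSE]
}

#' Default ion panel
#'
#' The study's ion channels: two primary-ion isotopologue channels
#' (m/z 21.02 x500 and 39.03 x250), nine exercise-responsive endogenous
#' compounds (methanol, acetaldehyde, ethanol, acetone, isoprene,
#' pentanone and the three short-chain fatty acids), their known
#' product-ion fragments, the exogenous monoterpene/estragole channels,
#' and a set of common non-responsive endogenous breath VOCs
#' (acetonitrile, sulfides, aldehydes, aromatics, ...) that real
#' untargeted PTR-ToF-MS retention produces in large numbers — the
#' retained panel is dominated by ions that do not respond to the
#' studied stimulus, which is what makes VIP selection meaningful. One
#' trace channel sits below the detection limit by design so the
#' retention filter has designed structure. Channel names follow the
#' instrument's printed two-decimal labels (`mz<value>`); theoretical
#' masses are in `theoretical_mz`. `parent`/`frag_fraction` describe
#' in-instrument fragmentation (a fragment channel carries that fixed
#' fraction of its parent's signal). `k` holds compound-specific
#' reaction-rate coefficients (cm^3/s) where experimentally known.
#'
#' @return Data frame with one row per channel.
#' @export
default_ion_table <- function() {
  tab <- data.frame(
    channel = c("mz21.02", "mz39.03",
                "mz33.03", "mz45.03", "mz47.05", "mz59.05", "mz69.07",
                "mz87.09", "mz61.03", "mz75.05", "mz89.06",
                "mz41.04", "mz43.02", "mz57.04", "mz71.05",
                "mz137.13", "mz81.08", "mz149.10",
                "mz42.03", "mz49.01", "mz60.08", "mz63.03", "mz73.06",
                "mz79.05", "mz83.09", "mz85.10", "mz93.07", "mz95.09",
                "mz99.08", "mz101.10", "mz107.09", "mz109.10", "mz111.12",
                "mz121.10", "mz135.12", "mz143.14", "mz131.07"),
    mz = c(21.02, 39.03,
           33.03, 45.03, 47.05, 59.05, 69.07,
           87.09, 61.03, 75.05, 89.06,
           41.04, 43.02, 57.04, 71.05,
           137.13, 81.08, 149.10,
           42.03, 49.01, 60.08, 63.03, 73.06,
           79.05, 83.09, 85.10, 93.07, 95.09,
           99.08, 101.10, 107.09, 109.10, 111.12,
           121.10, 135.12, 143.14, 131.07),
    formula = c("H3[18O]+", "H5O[18O]+",
                "CH4OH+", "C2H4OH+", "C2H6OH+", "C3H6OH+", "C5H8H+",
                "C5H10OH+", "C2H4O2H+", "C3H6O2H+", "C4H8O2H+",
                "C3H4H+", "C2H2OH+", "C3H4OH+", "C4H6OH+",
                "C10H16H+", "C6H8H+", "C10H12OH+",
                "C2H3NH+", "CH4SH+", "C3H9NH+", "C2H6SH+", "C4H8OH+",
                "C6H6H+", "C6H10H+", "C6H12H+", "C7H8H+", "C7H10H+",
                "C6H10OH+", "C6H12OH+", "C8H10H+", "C8H12H+", "C8H14H+",
                "C9H12H+", "C10H14H+", "C9H18OH+", "C6H10O3H+"),
    compound = c("hydronium (18O)", "water cluster (18O)",
                 "Methanol", "Acetaldehyde", "Ethanol", "Acetone", "Isoprene",
                 "Pentanone", "Acetic acid", "Propanoic acid", "Butanoic acid",
                 "Isoprene fragment", "Acetic acid fragment",
                 "Propanoic acid fragment", "Butanoic acid fragment",
                 "Monoterpene", "Monoterpene fragment", "Estragole",
                 "Acetonitrile", "Methanethiol", "Trimethylamine",
                 "Dimethyl sulfide", "Butanone", "Benzene", "Hexadiene",
                 "Hexene", "Toluene", "Methylcyclohexadiene", "Hexenal",
                 "Hexanal", "Xylene", "Octadiene", "Octene",
                 "Trimethylbenzene", "Cymene", "Nonanone",
                 "Trace channel (designed sub-LoD)"),
    role = c("primary", "primary",
             rep("endogenous", 9),
             rep("fragment", 4),
             "exogenous", "exogenous", "exogenous",
             rep("endogenous", 19)),
    parent = c(NA, NA,
               NA, NA, NA, NA, NA, NA, NA, NA, NA,
               "mz69.07", "mz61.03", "mz75.05", "mz89.06",
               NA, "mz137.13", NA,
               rep(NA, 19)),
    frag_fraction = c(NA, NA,
                      NA, NA, NA, NA, NA, NA, NA, NA, NA,
                      0.30, 0.35, 0.35, 0.35,
                      NA, 0.50, NA,
                      rep(NA, 19)),
    k = c(NA, NA,
          2.2e-9, NA, NA, 3.0e-9, 1.9e-9, NA, NA, NA, NA,
          NA, NA, NA, NA,
          NA, NA, NA,
          rep(NA, 19)),
    stringsAsFactors = FALSE
  )
  tab$theoretical_mz <- vapply(tab$formula, theoretical_mz, numeric(1))
  tab
}

#' Cluster related ions by cross-sample correlation
#'
#' Builds a graph with an edge between two ions whenever the squared
#' Pearson correlation of their (log) values across samples reaches
#' `r2_cut`, and returns the connected components as clusters. Fragments
#' and hydrate clusters of the same molecule co-vary almost perfectly
#' across samples and end up in one cluster; singletons are allowed.
#' Constant columns have undefined correlations and become singletons.
#'
#' @param x Samples-by-ions numeric matrix of concentrations (or a
#'   [quantify_sessions()] result, in which case its retained
#'   concentration matrix is used).
#' @param r2_cut Squared-correlation threshold (default 0.85).
#' @param use_log Correlate log-transformed values (default TRUE; values
#'   must be positive, which LoD replacement guarantees).
#' @return Data frame with columns `channel` and `cluster` (integer id).
#' @export
correlate_ions <- function(x, r2_cut = 0.85, use_log = TRUE) {
  if (inherits(x, "study_matrix")) x <- study_conc(x)
  stopifnot(is.matrix(x), nrow(x) >= 3)
  if (use_log) {
    if (any(x <= 0)) stop("log correlation requires positive values")
    x <- log(x)
  }
  p <- ncol(x)
  csd <- apply(x, 2, sd)
  const <- csd == 0
  if (any(const)) {
    message("constant ion column(s) become singleton clusters: ",
            paste(colnames(x)[const], collapse = ", "))
  }
  adj <- matrix(FALSE, p, p)
  ok <- which(!const)
  if (length(ok) >= 2) {
    r2 <- suppressWarnings(cor(x[, ok, drop = FALSE]))^2
    adj[ok, ok] <- r2 >= r2_cut
  }
  diag(adj) <- TRUE
  # connected components by BFS
  cluster <- rep(NA_integer_, p)
  cid <- 0L
  for (i in seq_len(p)) {
    if (!is.na(cluster[i])) next
    cid <- cid + 1L
    frontier <- i
    cluster[i] <- cid
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(cluster))
      cluster[nb] <- cid
      frontier <- nb
    }
  }
  data.frame(channel = colnames(x), cluster = cluster, stringsAsFactors = FALSE)
}

#' Annotate ion channels
#'
#' Combines accurate-mass formula matching with correlation clustering
#' into one annotation table. Exogenous channels keep an `exogenous`
#' source label so downstream models can exclude them from the exercise
#' analysis.
#'
#' @param ion_table Ion panel (see [default_ion_table()]).
#' @param clusters Optional output of [correlate_ions()]; joined on
#'   channel when given.
#' @param tol_ppm Tolerance for the mass match (ppm).
#' @return Data frame: channel, mz, formula, theoretical_mz, ppm_error,
#'   cluster, source.
#' @export
annotate_ions <- function(ion_table = default_ion_table(), clusters = NULL,
                          tol_ppm = 200) {
  th <- vapply(ion_table$formula, theoretical_mz, numeric(1))
  ppm <- (ion_table$mz - th) / th * 1e6
  src <- ifelse(ion_table$role == "exogenous", "exogenous",
                ifelse(abs(ppm) <= tol_ppm, "mass-match", "unassigned"))
  out <- data.frame(
    channel = ion_table$channel, mz = ion_table$mz,
    formula = ion_table$formula, theoretical_mz = th, ppm_error = ppm,
    cluster = NA_integer_, source = src, stringsAsFactors = FALSE
  )
  if (!is.null(clusters)) {
    out$cluster <- clusters$cluster[match(out$channel, clusters$channel)]
  }
  out
}
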