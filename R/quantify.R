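# Primary-ion normalization, first-order kinetic quantification and
# LoD handling.

.KB <- 1.380649e-23 # Boltzmann constant, J/K

#' Drift-tube and kinetic configuration
#'
#' Physical settings of the drift tube and the reaction-kinetics inputs
#' used to turn normalized counts into ppbv. Defaults match the campaign
#' instrument: 600 V, 2.6 mbar, 60 degC (E/N = 120 Td at the default
#' drift length). The generic proton-transfer rate coefficient is
#' k = 2e-9 cm^3/s; compound-specific values can be supplied per channel
#' via `k_overrides` (the default ion table carries experimentally known
#' values for methanol, acetone and isoprene).
#'
#' @param k_default Reaction-rate coefficient, cm^3 s^-1.
#' @param k_overrides Named numeric vector (names = ion channels).
#' @param reaction_time_s Ion residence time in the drift tube, s.
#' @param drift_voltage_V,drift_pressure_mbar,drift_temperature_C,drift_length_m
#'   Drift-tube settings.
#' @param normalization_target Primary-ion-equivalent count the signals
#'   are normalized to (conventional ncps: counts per 1e6 primary ions).
#' @return List of class `kinetic_config`.
#' @export
kinetic_config <- function(k_default = 2e-9,
                           k_overrides = c(mz33.03 = 2.2e-9,
                                           mz59.05 = 3.0e-9,
                                           mz69.07 = 1.9e-9),
                           reaction_time_s = 1e-4,
                           drift_voltage_V = 600,
                           drift_pressure_mbar = 2.6,
                           drift_temperature_C = 60,
                           drift_length_m = 0.0885,
                           normalization_target = 1e6) {
  num <- c(k_default = k_default, reaction_time_s = reaction_time_s,
           drift_voltage_V = drift_voltage_V,
           drift_pressure_mbar = drift_pressure_mbar,
           normalization_target = normalization_target)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all physical configuration quantities must be positive")
  }
  if (drift_temperature_C <= -273.15) stop("temperature below absolute zero")
  if (length(k_overrides) && (is.null(names(k_overrides)) ||
                              any(!nzchar(names(k_overrides))))) {
    stop("k_overrides must be a named vector of ion channels")
  }
  if (any(k_overrides <= 0)) stop("k_overrides must be positive")
  structure(list(
    k_default = k_default, k_overrides = k_overrides,
    reaction_time_s = reaction_time_s,
    drift_voltage_V = drift_voltage_V,
    drift_pressure_mbar = drift_pressure_mbar,
    drift_temperature_C = drift_temperature_C,
    drift_length_m = drift_length_m,
    normalization_target = normalization_target
  ), class = "kinetic_config")
}

# gas number density in the drift tube, cm^-3
drift_number_density <- function(config) {
  p_pa <- config$drift_pressure_mbar * 100
  t_k <- config$drift_temperature_C + 273.15
  p_pa / (.KB * t_k) * 1e-6
}

resolve_k <- function(config, ion = NULL) {
  if (!is.null(ion) && length(config$k_overrides) &&
      ion %in% names(config$k_overrides)) {
    unname(config$k_overrides[[ion]])
  } else {
    config$k_default
  }
}

#' Reduced electric field E/N of the drift tube
#'
#' E/N = (U / L) / N expressed in Townsend (1 Td = 1e-17 V cm^2), with N
#' the gas number density at the drift pressure and temperature. Used as
#' a configuration sanity check: a warning is issued when the value is
#' more than 5\% away from the instrument's nominal 120 Td.
#'
#' @param config A [kinetic_config()].
#' @param nominal_td Nominal operating value to check against.
#' @return E/N in Td (invisibly NA with a warning if no drift length).
#' @export
compute_reduced_field <- function(config, nominal_td = 120) {
  if (is.null(config$drift_length_m) || !is.finite(config$drift_length_m)) {
    warning("drift length not set; E/N unavailable")
    return(invisible(NA_real_))
  }
  if (config$drift_length_m <= 0) stop("drift length must be positive")
  e_vcm <- config$drift_voltage_V / (config$drift_length_m * 100)
  en_td <- e_vcm / drift_number_density(config) / 1e-17
  if (abs(en_td - nominal_td) > 0.05 * nominal_td) {
    warning(sprintf(
      "E/N = %.1f Td differs from the nominal %.0f Td; check drift settings",
      en_td, nominal_td))
  }
  en_td
}

#' Normalize ion counts to the primary-ion signal
#'
#' The H3O+ reagent-ion signal is monitored through its 18O isotopologue
#' at m/z 21.02 (x500) and the water-cluster isotopologue at m/z 39.03
#' (x250). Product-ion counts are expressed per `target` (default 1e6)
#' primary ions:
#' `ncps = cps_ion * target / (500 * cps_mz21 + 250 * cps_mz39)`.
#'
#' @param cps_ion Product-ion counts per second (vector ok).
#' @param cps_mz21,cps_mz39 Primary-ion isotopologue counts per second.
#' @param target Normalization target (counts of primary ions).
#' @return Normalized counts (ncps); NA with a warning where the
#'   primary-ion signal is not positive (invalid sample).
#' @export
normalize_primary_ions <- function(cps_ion, cps_mz21, cps_mz39, target = 1e6) {
  denom <- 500 * cps_mz21 + 250 * cps_mz39
  bad <- !is.finite(denom) | denom <= 0
  if (any(bad)) {
    warning("zero primary-ion signal: ", sum(bad), " sample(s) flagged NA")
    denom[bad] <- NA_real_
  }
  cps_ion * target / denom
}

# ppbv corresponding to one normalized count, for a given ion's k
ppbv_per_ncps <- function(config, ion = NULL) {
  k <- resolve_k(config, ion)
  n_cm3 <- drift_number_density(config)
  ratio_per_ncps <- 1 / config$normalization_target
  ratio_per_ncps / (k * config$reaction_time_s) / n_cm3 * 1e9
}

#' Convert normalized counts to concentration (ppbv)
#'
#' First-order kinetics of the proton-transfer reaction: the product-ion
#' to primary-ion signal ratio grows linearly with the VOC number
#' density, `[VOC] = I_product / (I_H3O+ * k * t)`. With signals
#' normalized to `target` primary ions the mixing ratio in ppbv is
#' `ncps / target / (k t) / N * 1e9`, N being the drift-tube gas number
#' density.
#'
#' @param ncps Normalized counts (see [normalize_primary_ions()]).
#' @param config A [kinetic_config()].
#' @param ion Optional channel name used to resolve a compound-specific
#'   rate coefficient; the generic `k_default` applies otherwise.
#' @return Concentration(s) in ppbv, linear in `ncps`.
#' @export
cps_to_concentration <- function(ncps, config = kinetic_config(), ion = NULL) {
  stopifnot(inherits(config, "kinetic_config"))
  ncps * ppbv_per_ncps(config, ion)
}

#' Limit of detection from catalyzed-air background
#'
#' IUPAC-style blank-based LoD: mean of the background signal plus three
#' times its standard deviation, computed on the concentration scale.
#' No calibration slope exists for direct kinetic quantification, so the
#' plain 3-sigma form is used; the multiplier is exposed.
#'
#' @param background Numeric vector (one ion) or ticks-by-ions matrix of
#'   background concentrations.
#' @param k_sigma Sigma multiplier (default 3).
#' @param min_ticks Minimum number of background ticks required per ion.
#' @return Named numeric vector of LoDs (NA, with a message, for ions
#'   without enough background).
#' @export
compute_lod <- function(background, k_sigma = 3, min_ticks = 10) {
  if (is.null(dim(background))) background <- cbind(ion = background)
  n_ok <- colSums(is.finite(background))
  lod <- colMeans(background, na.rm = TRUE) +
    k_sigma * apply(background, 2, sd, na.rm = TRUE)
  short <- n_ok < min_ticks
  if (any(short)) {
    message("LoD undefined (insufficient background) for: ",
            paste(colnames(background)[short], collapse = ", "))
    lod[short] <- NA_real_
  }
  lod
}

#' Replace sub-LoD concentrations by the LoD
#'
#' Values strictly below the ion's LoD are replaced by the LoD itself
#' (values exactly at the LoD are untouched). Returns the matrix plus
#' masks recording which entries were below LoD / replaced.
#'
#' @param conc Samples-by-ions concentration matrix (ppbv).
#' @param lods Named LoD vector covering the matrix columns.
#' @return List with `conc` (after replacement), `below_lod`, `replaced`
#'   (logical masks), `lods`.
#' @export
apply_lod <- function(conc, lods) {
  stopifnot(is.matrix(conc), all(colnames(conc) %in% names(lods)))
  lod <- unname(lods[colnames(conc)])
  below <- sweep(conc, 2, lod, "<")
  below[is.na(below)] <- FALSE
  out <- conc
  out[below] <- rep(lod, each = nrow(conc))[below]
  lod <- setNames(lod, colnames(conc))
  list(conc = out, below_lod = below, replaced = below, lods = lod)
}

#' Retention filter: above LoD in more than half of every group
#'
#' An ion is retained only if, within each study group separately,
#' strictly more than 50\% of that group's samples have a concentration
#' strictly above the ion's LoD. Evaluated on all individual samples
#' (both duplicates), not on replicate means.
#'
#' @param above_lod Samples-by-ions logical matrix (concentration > LoD,
#'   evaluated before replacement).
#' @param groups Group label per sample (length nrow).
#' @param min_fraction Retention threshold (strict; default 0.5).
#' @return Character vector of retained ion channels.
#' @export
filter_ions <- function(above_lod, groups, min_fraction = 0.5) {
  stopifnot(is.matrix(above_lod), nrow(above_lod) == length(groups))
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 1) {
    stop("retention filter undefined: empty group")
  }
  frac <- vapply(levels(groups), function(g) {
    colMeans(above_lod[groups == g, , drop = FALSE])
  }, numeric(ncol(above_lod)))
  frac <- matrix(frac, nrow = ncol(above_lod))
  keep <- apply(frac > min_fraction, 1, all)
  colnames(above_lod)[keep]
}
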