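test_that("primary-ion normalization follows the stated formula", {
  expect_equal(normalize_primary_ions(100, 1000, 2000), 100)
  expect_equal(normalize_primary_ions(0, 1000, 2000), 0)
  # scale invariance
  expect_equal(normalize_primary_ions(2 * 37, 2 * 800, 2 * 1500),
               normalize_primary_ions(37, 800, 1500))
  expect_warning(out <- normalize_primary_ions(10, 0, 0), "primary")
  expect_true(is.na(out))
})

test_that("kinetic quantification matches an independent hand evaluation", {
  cfg <- kinetic_config()
  # signal ratio 1e-4 at k = 2e-9 cm3/s, t = 100 us, N = p/(kB T)
  n_cm3 <- 2.6 * 100 / (1.380649e-23 * (60 + 273.15)) * 1e-6
  expected_ppbv <- 1e-4 / (2e-9 * 1e-4 * n_cm3) * 1e9
  ncps <- 1e-4 * cfg$normalization_target # ratio 1e-4 in ncps units
  expect_equal(cps_to_concentration(ncps, cfg), expected_ppbv)

  expect_equal(cps_to_concentration(0, cfg), 0)
  # halving k doubles the reported concentration
  cfg2 <- kinetic_config(k_default = 1e-9)
  expect_equal(cps_to_concentration(50, cfg2),
               2 * cps_to_concentration(50, cfg))
  # linearity
  expect_equal(cps_to_concentration(7 * 50, cfg),
               7 * cps_to_concentration(50, cfg))
  # per-ion override (acetone k = 3e-9 < generic 2e-9 -> lower ppbv)
  expect_equal(cps_to_concentration(50, cfg, "mz59.05"),
               cps_to_concentration(50, cfg) * 2 / 3)
  expect_error(kinetic_config(k_default = -1), "positive")
})

test_that("reduced field evaluates to the instrument's 120 Td", {
  expect_equal(compute_reduced_field(kinetic_config()), 120, tolerance = 0.01)
  cfg2 <- kinetic_config(drift_length_m = 2 * 0.0885)
  expect_equal(suppressWarnings(compute_reduced_field(cfg2)), 60,
               tolerance = 0.01)
  # N ~ 1/T: doubling the absolute temperature doubles E/N
  t2 <- 2 * (60 + 273.15) - 273.15
  cfg3 <- kinetic_config(drift_temperature_C = t2)
  expect_equal(suppressWarnings(compute_reduced_field(cfg3)), 240,
               tolerance = 0.01)
  cfg4 <- kinetic_config(drift_length_m = NA)
  expect_warning(en <- compute_reduced_field(cfg4), "unavailable")
  expect_true(is.na(en))
})

test_that("LoD is blank mean + 3 sd and degenerates sensibly", {
  expect_equal(unname(compute_lod(rep(4.2, 12))), 4.2)
  series <- c(8.1, 11.3, 9.9, 12.0, 10.4, 7.6, 9.2, 10.8, 11.5, 8.7)
  expect_equal(unname(compute_lod(series)), mean(series) + 3 * sd(series))
  two <- cbind(a = series, b = series)
  lods <- compute_lod(two)
  expect_equal(lods[["a"]], lods[["b"]])
  expect_message(short <- compute_lod(series[1:5]), "insufficient")
  expect_true(is.na(short))
})

test_that("LoD replacement is strict-below with mask bookkeeping", {
  m <- matrix(c(1.0, 0.1, 0.5, 2.0), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  lods <- c(a = 0.5, b = 0.5)
  out <- apply_lod(m, lods)
  expect_equal(unname(out$conc[2, "a"]), 0.5) # replaced
  expect_true(out$below_lod[2, "a"])
  expect_equal(unname(out$conc[1, "b"]), 0.5) # exactly at LoD: untouched
  expect_false(out$below_lod[1, "b"])
  expect_equal(unname(out$conc[1, "a"]), 1.0)
  all_above <- apply_lod(m + 10, lods)
  expect_equal(all_above$conc, m + 10)
  expect_false(any(all_above$below_lod))
})

test_that("retention needs >50% above LoD in every group separately", {
  set.seed(51)
  groups <- rep(c("St0", "St1", "St2"), each = 10)
  ok <- matrix(TRUE, 30, 1, dimnames = list(NULL, "full"))
  expect_equal(filter_ions(ok, groups), "full")

  # 80% / 80% / 40%: fails the third group
  mixed <- matrix(c(rep(TRUE, 8), rep(FALSE, 2),
                    rep(TRUE, 8), rep(FALSE, 2),
                    rep(TRUE, 4), rep(FALSE, 6)), 30, 1,
                  dimnames = list(NULL, "partial"))
  expect_equal(filter_ions(mixed, groups), character(0))

  # exactly 50% in one group fails the strict rule
  half <- matrix(rep(TRUE, 30), 30, 1, dimnames = list(NULL, "edge"))
  half[groups == "St1", 1] <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(filter_ions(half, groups), character(0))

  expect_error(filter_ions(ok[groups == "St0", , drop = FALSE],
                           factor(groups[1:10], levels = c("St0", "St1"))),
               "empty group")

  # monotonicity: raising any LoD never grows the retained set
  conc <- matrix(rlnorm(30 * 4), 30, 4,
                 dimnames = list(NULL, paste0("i", 1:4)))
  lods <- c(i1 = 0.5, i2 = 1, i3 = 2, i4 = 0.1)
  kept1 <- filter_ions(sweep(conc, 2, lods, ">"), groups)
  lods2 <- lods * c(1, 3, 1, 5)
  kept2 <- filter_ions(sweep(conc, 2, lods2, ">"), groups)
  expect_true(all(kept2 %in% kept1))
})

test_that("quantification round-trips the generator concentrations", {
  d <- tiny_design(seed = 61)
  # noiseless: the pipeline must invert the simulated signal exactly
  eff0 <- effect_spec(d, noise_cv = 0, counting_noise = FALSE,
                      outlier_rate = 0)
  st0 <- simulate_study(d, eff0)
  sm0 <- quiet_quantify(st0)
  tr <- st0$truth
  key_sm <- paste(sm0$meta$participant, sm0$meta$timepoint, sm0$meta$replicate)
  key_tr <- paste(tr$meta_replicate$participant, tr$meta_replicate$timepoint,
                  tr$meta_replicate$replicate)
  idx <- match(key_sm, key_tr)
  ions <- intersect(sm0$retained, colnames(tr$conc_replicate))
  above <- sm0$above_lod[, ions]
  rel <- abs(sm0$conc[, ions] / tr$conc_replicate[idx, ions] - 1)
  expect_lt(max(rel[above]), 1e-9)

  # with technical noise the replicate truth is still recovered exactly
  # up to the counting statistics left out here
  effn <- effect_spec(d, noise_cv = 0.05, counting_noise = FALSE,
                      outlier_rate = 0)
  d2 <- tiny_design(seed = 62)
  stn <- simulate_study(d2, effn)
  smn <- quiet_quantify(stn)
  key_sm <- paste(smn$meta$participant, smn$meta$timepoint, smn$meta$replicate)
  key_tr <- paste(stn$truth$meta_replicate$participant,
                  stn$truth$meta_replicate$timepoint,
                  stn$truth$meta_replicate$replicate)
  idx <- match(key_sm, key_tr)
  rel <- abs(smn$conc[, ions] / stn$truth$conc_replicate[idx, ions] - 1)
  expect_lt(max(rel[smn$above_lod[, ions]]), 1e-9)
})
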