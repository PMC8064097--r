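test_that("Lilliefors statistic matches the reference implementation", {
  library(nortest)
  set.seed(81)
  for (i in 1:10) {
    x <- if (i %% 2) rnorm(40) else rlnorm(40)
    expect_equal(breathflow:::.lilliefors_stat(x),
                 unname(lillie.test(x)$statistic))
  }
})

test_that("Lilliefors is affine-invariant and calibrated at the null", {
  set.seed(82)
  x <- rnorm(60)
  d1 <- breathflow:::.lilliefors_stat(x)
  d2 <- breathflow:::.lilliefors_stat(3.7 * x - 11)
  expect_equal(d1, d2)

  # type-I calibration: rejection rate near alpha under the null
  rej <- vapply(1:150, function(i) {
    lilliefors(rnorm(50), nsim = 300)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)

  # power against a strongly skewed alternative
  pow <- vapply(1:40, function(i) {
    lilliefors(rlnorm(200), nsim = 300)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(pow), 0.9)

  const <- lilliefors(rep(1, 10))
  expect_equal(const$p_value, 0)
  expect_match(const$note, "degenerate")
})

test_that("Kruskal-Wallis H matches the hand-ranked oracle", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(1:3, each = 3))
  expect_equal(r$statistic, 7.2)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  tie <- kruskal_wallis(rep(5, 6), rep(1:2, each = 3))
  expect_equal(tie$statistic, 0)
  expect_equal(tie$p_value, 1)
})

test_that("exact permutation p agrees with the chi-square approximation", {
  vals <- c(1, 2, 5, 3, 4, 8, 6, 7, 9)
  g <- rep(1:3, each = 3)
  approx <- kruskal_wallis(vals, g)
  exact <- kruskal_wallis(vals, g, exact = TRUE)
  expect_equal(exact$statistic, approx$statistic)
  expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  expect_error(kruskal_wallis(rnorm(12), rep(1:3, each = 4), exact = TRUE),
               "n <= 10")
})

test_that("mean-rank post hoc comparisons isolate the shifted group", {
  set.seed(83)
  x <- c(rnorm(15), rnorm(15), rnorm(15, mean = 6)) # 6-sd shift in group c
  g <- rep(c("a", "b", "c"), each = 15)
  ph <- posthoc_mean_ranks(x, g)
  expect_equal(nrow(ph), 3)
  sig <- ph$p_value < 0.05
  expect_false(sig[ph$comparison == "a vs b"])
  expect_true(all(sig[ph$comparison %in% c("a vs c", "b vs c")]))

  # literally identical groups: equal mean ranks, adjusted p = 1
  same <- posthoc_mean_ranks(rep(c(1, 2, 3, 4, 5), 2),
                             rep(c("a", "b"), each = 5))
  expect_equal(same$p_value, 1)

  # family-wise adjustment never lowers a pairwise p
  dn <- posthoc_mean_ranks(x, g, method = "dunn-holm")
  raw <- 2 * pnorm(-abs(dn$statistic))
  expect_true(all(dn$p_value >= raw - 1e-12))
})

test_that("the omnibus branch follows the Lilliefors decision", {
  set.seed(84)
  g <- rep(c("a", "b", "c"), each = 40)
  normal <- omnibus_test(rnorm(120), g, nsim = 400)
  expect_equal(normal$branch, "anova")
  expect_equal(normal$omnibus$test, "anova")

  skewed <- omnibus_test(rlnorm(120, sdlog = 1.5), g, nsim = 400)
  expect_equal(skewed$branch, "kruskal-wallis")
  expect_equal(skewed$omnibus$test, "kruskal-wallis")
})

test_that("SCFA series sums the three acids and summarizes by cell", {
  fx <- default_study_matrix()
  cs <- collapse_replicates(fx$sm)
  ser <- scfa_cluster_series(cs)
  expect_equal(ser$samples$scfa_total,
               unname(rowSums(cs$conc[, c("mz61.03", "mz75.05", "mz89.06")])))
  # brute-force one cell
  cell <- ser$samples$group == "St0" & ser$samples$timepoint == "Day1"
  row <- ser$summary[ser$summary$group == "St0" &
                       ser$summary$timepoint == "Day1", ]
  expect_equal(row$mean, mean(ser$samples$scfa_total[cell]))
  expect_equal(row$se, sd(ser$samples$scfa_total[cell]) / sqrt(sum(cell)))
  expect_error(scfa_cluster_series(cs, scfa_channels = c("mz61.03", "mzXX")),
               "mzXX")
})

test_that("relative-change rows are reference-anchored with unit range", {
  # constructed medians 2 / 4 / 6 with reference 2 -> 0, 0.5, 1
  conc <- matrix(c(rep(2, 4), rep(4, 4), rep(6, 4)), ncol = 1,
                 dimnames = list(NULL, "ion"))
  sm <- structure(list(
    conc = conc,
    meta = data.frame(participant = sprintf("P%02d", 1:12),
                      timepoint = rep(c("Day0", "Day1", "Day2"), each = 4),
                      group = "St0"),
    retained = "ion", lods = c(ion = 0.1),
    ion_table = data.frame(channel = "ion", role = "endogenous")
  ), class = "study_matrix")
  rc <- relative_change_matrix(sm, reference = c(group = "St0",
                                                 timepoint = "Day0"))
  expect_equal(as.vector(rc$matrix), c(0, 0.5, 1))
  # scale invariance
  sm2 <- sm; sm2$conc <- sm$conc * 17
  rc2 <- relative_change_matrix(sm2, reference = c(group = "St0",
                                                   timepoint = "Day0"))
  expect_equal(rc2$matrix, rc$matrix)
  # constant compound -> flagged all-zero row
  sm3 <- sm; sm3$conc[] <- 5
  expect_message(rc3 <- relative_change_matrix(sm3,
                                               reference = c(group = "St0",
                                                             timepoint = "Day0")),
                 "zero range")
  expect_true(all(rc3$matrix == 0))
  expect_true(rc3$flat_rows[["ion"]])
})

test_that("the exercise recovery pattern shows in the cell medians", {
  fx <- default_study_matrix()
  cs <- collapse_replicates(fx$sm)
  rc <- relative_change_matrix(cs)$matrix
  affected <- fx$study$truth$flags$channel[fx$study$truth$flags$exercise_responsive]
  iso <- c("mz69.07", "mz41.04")
  for (g in c("St0", "St1", "St2")) {
    cell <- function(tp) paste(g, tp, sep = ":")
    for (ion in setdiff(intersect(affected, rownames(rc)), iso)) {
      expect_gt(rc[ion, cell("Day1")], rc[ion, cell("Day0")])
      expect_lt(rc[ion, cell("Day2am")], rc[ion, cell("Day1")])
      expect_gt(rc[ion, cell("Day2")], rc[ion, cell("Day2am")])
    }
    for (ion in iso) { # isoprene mirrors the pattern
      expect_lt(rc[ion, cell("Day1")], rc[ion, cell("Day0")])
      expect_gt(rc[ion, cell("Day2am")], rc[ion, cell("Day1")])
      expect_lt(rc[ion, cell("Day2")], rc[ion, cell("Day2am")])
    }
  }
})
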