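# Univariate follow-up: Lilliefors normality, Kruskal-Wallis / ANOVA
# with post hoc mean-rank comparisons, SCFA cluster summaries and the
# relative-change matrix.

.test_result <- function(variable, test, statistic, p_value, alpha = 0.05,
                         comparison = NA_character_, note = NA_character_) {
  data.frame(variable = variable, test = test, statistic = statistic,
             p_value = p_value, alpha = alpha,
             decision = ifelse(is.na(p_value), NA, p_value < alpha),
             comparison = comparison, note = note, stringsAsFactors = FALSE)
}

# Kolmogorov-Smirnov distance of x to a normal with estimated moments
.lilliefors_stat <- function(x) {
  n <- length(x)
  z <- pnorm(sort(x), mean(x), sd(x))
  i <- seq_len(n)
  max(max(i / n - z), max(z - (i - 1) / n))
}

#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean
#' and standard deviation estimated from the sample; because the
#' parameters are estimated, the null distribution is obtained by Monte
#' Carlo simulation (default 10^4 standard-normal samples of the same
#' size). The statistic is invariant to affine transformations of the
#' data. A constant sample is degenerate and reported as non-normal
#' with a note.
#'
#' @param x Numeric sample (n >= 5).
#' @param nsim Monte Carlo draws for the null distribution.
#' @param alpha Decision level.
#' @param variable Label carried into the result.
#' @return One-row data frame (variable, test, statistic, p_value,
#'   alpha, decision, note).
#' @export
lilliefors <- function(x, nsim = 10000, alpha = 0.05, variable = "x") {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("Lilliefors test needs n >= 5")
  if (sd(x) == 0) {
    return(.test_result(variable, "lilliefors", NA_real_, 0, alpha,
                        note = "degenerate constant sample"))
  }
  d <- .lilliefors_stat(x)
  n <- length(x)
  null <- vapply(seq_len(nsim), function(i) .lilliefors_stat(rnorm(n)),
                 numeric(1))
  p <- (1 + sum(null >= d)) / (nsim + 1)
  .test_result(variable, "lilliefors", d, p, alpha)
}

# exact permutation distribution of the KW statistic (small total n)
.kw_exact_p <- function(values, groups, h_obs) {
  n <- length(values)
  sizes <- table(groups)
  perms <- function(pool, sizes) {
    if (length(sizes) == 1) return(list(list(pool)))
    out <- list()
    first <- utils::combn(seq_along(pool), sizes[1], simplify = FALSE)
    for (sel in first) {
      rest <- perms(pool[-sel], sizes[-1])
      for (r in rest) out[[length(out) + 1L]] <- c(list(pool[sel]), r)
    }
    out
  }
  all_parts <- perms(seq_len(n), as.vector(sizes))
  hs <- vapply(all_parts, function(part) {
    g <- integer(n)
    for (k in seq_along(part)) g[part[[k]]] <- k
    suppressWarnings(kruskal.test(values, factor(g))$statistic)
  }, numeric(1))
  hs[is.nan(hs)] <- 0
  mean(hs >= h_obs - 1e-12)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic with the chi-square approximation
#' (df = g - 1), delegated to [stats::kruskal.test()]. For small samples
#' (total n <= 10) an exact permutation p-value over all group
#' assignments is available. A fully tied sample yields H = 0, p = 1.
#'
#' @param values Numeric response.
#' @param groups Group label per value (>= 2 groups, total n >= 3).
#' @param exact Use the exact permutation null (only for total n <= 10).
#' @param alpha Decision level.
#' @param variable Label carried into the result.
#' @return One-row data frame (see [lilliefors()] for the layout).
#' @export
kruskal_wallis <- function(values, groups, exact = FALSE, alpha = 0.05,
                           variable = "x") {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, length(values) >= 3,
            length(values) == length(groups))
  if (length(unique(values)) == 1) {
    return(.test_result(variable, "kruskal-wallis", 0, 1, alpha,
                        note = "all values identical"))
  }
  kt <- kruskal.test(values, groups)
  h <- unname(kt$statistic)
  p <- kt$p.value
  note <- NA_character_
  if (exact) {
    if (length(values) > 10) stop("exact permutation p only for total n <= 10")
    p <- .kw_exact_p(values, groups, h)
    note <- "exact permutation p"
  }
  .test_result(variable, "kruskal-wallis", h, p, alpha, note = note)
}

#' Post hoc pairwise comparisons on group mean ranks
#'
#' The post hoc companion applied after a Kruskal-Wallis fit in common
#' statistical software: Tukey-Kramer comparisons of the group mean
#' ranks against the studentized-range distribution (tie-corrected rank
#' variance, infinite degrees of freedom), yielding family-wise adjusted
#' p-values. Dunn's z-tests with Holm adjustment are available as an
#' alternative.
#'
#' @param values Numeric response.
#' @param groups Group label per value.
#' @param method `"tukey"` (default) or `"dunn-holm"`.
#' @param alpha Decision level.
#' @param variable Label carried into the results.
#' @return Data frame with one row per group pair (statistic = q or z,
#'   `p_value` family-wise adjusted).
#' @export
posthoc_mean_ranks <- function(values, groups, method = c("tukey", "dunn-holm"),
                               alpha = 0.05, variable = "x") {
  method <- match.arg(method)
  groups <- factor(groups)
  g <- nlevels(groups)
  n <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  n_i <- table(groups)
  ties <- table(rk)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  v <- n * (n + 1) / 12 * tie_corr
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    ni <- n_i[[pr[1]]]; nj <- n_i[[pr[2]]]
    if (ni == 0 || nj == 0) return(NULL)
    diff <- abs(mean_rank[[pr[1]]] - mean_rank[[pr[2]]])
    if (method == "tukey") {
      q <- diff / sqrt(v / 2 * (1 / ni + 1 / nj))
      p <- ptukey(q, g, Inf, lower.tail = FALSE)
      stat <- q
    } else {
      z <- diff / sqrt(v * (1 / ni + 1 / nj))
      p <- 2 * pnorm(-z)
      stat <- z
    }
    .test_result(variable, paste0("posthoc-", method), stat, p, alpha,
                 comparison = paste(pr, collapse = " vs "))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (method == "dunn-holm") {
    out$p_value <- p.adjust(out$p_value, "holm")
    out$decision <- out$p_value < alpha
  }
  rownames(out) <- NULL
  out
}

#' Normality-gated omnibus test with post hoc comparisons
#'
#' The pipeline's univariate decision rule: Lilliefors decides the
#' branch — normal data go to one-way ANOVA with Tukey's HSD, non-normal
#' data to Kruskal-Wallis with Tukey-Kramer mean-rank comparisons.
#'
#' @param values Numeric response.
#' @param groups Group label per value.
#' @param alpha Level for both the normality gate and the tests.
#' @param nsim Monte Carlo draws for the Lilliefors p-value.
#' @param variable Label carried through.
#' @return List with `normality`, `branch` ("anova" or
#'   "kruskal-wallis"), `omnibus`, `posthoc`.
#' @export
omnibus_test <- function(values, groups, alpha = 0.05, nsim = 2000,
                         variable = "x") {
  groups <- factor(groups)
  norm <- lilliefors(values, nsim = nsim, alpha = alpha, variable = variable)
  if (!is.na(norm$decision) && !norm$decision) {
    fit <- aov(values ~ groups)
    an <- summary(fit)[[1]]
    omni <- .test_result(variable, "anova", an[["F value"]][1],
                         an[["Pr(>F)"]][1], alpha)
    tk <- TukeyHSD(fit)$groups
    post <- do.call(rbind, lapply(seq_len(nrow(tk)), function(i) {
      .test_result(variable, "posthoc-tukey-hsd", tk[i, "diff"],
                   tk[i, "p adj"], alpha,
                   comparison = sub("-", " vs ", rownames(tk)[i]))
    }))
    branch <- "anova"
  } else {
    omni <- kruskal_wallis(values, groups, alpha = alpha, variable = variable)
    post <- posthoc_mean_ranks(values, groups, alpha = alpha,
                               variable = variable)
    branch <- "kruskal-wallis"
  }
  list(normality = norm, branch = branch, omnibus = omni, posthoc = post)
}

#' Total short-chain fatty acid series
#'
#' Sums the three SCFA parent ions (acetic, propanoic and butanoic acid)
#' per sample and summarizes each group-by-timepoint cell as mean +/-
#' standard error. Omnibus/post hoc testing of the series is delegated
#' to [omnibus_test()] by the caller.
#'
#' @param sm A `study_matrix` (collapsed or not).
#' @param scfa_channels The three SCFA parent channels.
#' @return List with `samples` (meta + `scfa_total`) and `summary`
#'   (group, timepoint, n, mean, se).
#' @export
scfa_cluster_series <- function(sm, scfa_channels = c("mz61.03", "mz75.05",
                                                      "mz89.06")) {
  stopifnot(inherits(sm, "study_matrix"))
  missing <- setdiff(scfa_channels, colnames(sm$conc))
  if (length(missing)) {
    stop("SCFA ion(s) missing from the matrix: ",
         paste(missing, collapse = ", "))
  }
  total <- rowSums(sm$conc[, scfa_channels, drop = FALSE])
  samples <- cbind(sm$meta, scfa_total = total)
  agg <- aggregate(scfa_total ~ group + timepoint, data = samples,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       se = sd(v) / sqrt(length(v))))
  summary <- data.frame(group = agg$group, timepoint = agg$timepoint,
                        n = agg$scfa_total[, "n"],
                        mean = agg$scfa_total[, "mean"],
                        se = agg$scfa_total[, "se"],
                        stringsAsFactors = FALSE)
  list(samples = samples, summary = summary)
}

#' Relative-change matrix of cell medians
#'
#' For each compound: the median concentration per group-by-timepoint
#' cell, centered on the reference cell's median (non-statin users
#' before walking by default) and divided by the range of the centered
#' medians, so every row has unit range and the reference cell sits at
#' 0. The heat-map behind the exercise-trend summary. Rows with zero
#' range are reported as all-zero and flagged.
#'
#' @param sm A `study_matrix`, normally collapsed to replicate means.
#' @param reference Named character vector with `group` and `timepoint`
#'   of the reference cell.
#' @param ions Compounds (rows); defaults to the retained ions.
#' @return List with `matrix` (compounds x group:timepoint cells),
#'   `flat_rows` (compounds flagged for zero range), `reference`.
#' @export
relative_change_matrix <- function(sm,
                                   reference = c(group = "St0",
                                                 timepoint = "Day0"),
                                   ions = NULL) {
  stopifnot(inherits(sm, "study_matrix"))
  if (is.null(ions)) ions <- sm$retained
  meta <- sm$meta
  ref_sel <- meta$group == reference[["group"]] &
    meta$timepoint == reference[["timepoint"]]
  if (!any(ref_sel)) stop("reference cell is empty")
  cells <- expand.grid(group = unique(meta$group),
                       timepoint = unique(meta$timepoint),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_names <- paste(cells$group, cells$timepoint, sep = ":")
  out <- matrix(NA_real_, length(ions), nrow(cells),
                dimnames = list(ions, cell_names))
  flat <- logical(length(ions)); names(flat) <- ions
  for (ion in ions) {
    med <- vapply(seq_len(nrow(cells)), function(i) {
      sel <- meta$group == cells$group[i] & meta$timepoint == cells$timepoint[i]
      if (!any(sel)) return(NA_real_)
      median(sm$conc[sel, ion])
    }, numeric(1))
    ref_med <- median(sm$conc[ref_sel, ion])
    ctr <- med - ref_med
    rng <- diff(range(ctr, na.rm = TRUE))
    if (!is.finite(rng) || rng == 0) {
      out[ion, ] <- 0
      flat[ion] <- TRUE
      message("compound ", ion, ": zero range, row reported as all-zero")
    } else {
      out[ion, ] <- ctr / rng
    }
  }
  list(matrix = out, flat_rows = flat, reference = reference)
}
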