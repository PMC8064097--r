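test_that("log-centering matches hand arithmetic and is idempotent", {
  x <- matrix(c(1, exp(1), exp(2)), 3, 1, dimnames = list(NULL, "a"))
  lc <- log_center(x)
  expect_equal(as.vector(lc), c(-1, 0, 1))
  again <- sweep(lc, 2, colMeans(lc))
  expect_equal(unclass(again), unclass(lc), ignore_attr = TRUE)
  # centering quality relative to the column spread
  set.seed(71)
  y <- matrix(rlnorm(200), 50, 4, dimnames = list(NULL, paste0("i", 1:4)))
  ly <- log_center(y)
  expect_true(all(abs(colMeans(ly)) < 1e-10 * apply(ly, 2, sd)))
  y[3, 2] <- 0
  expect_error(log_center(y), "non-positive")
})

test_that("between/within split equals a brute-force per-subject oracle", {
  set.seed(72)
  X <- matrix(rnorm(18), 6, 3)
  subj <- c("a", "a", "b", "b", "b", "c")
  # subject c has one sample and must be excluded
  expect_warning(sp <- multilevel_split(X, subj), "single sample")
  expect_equal(nrow(sp$within), 5)
  brute_between <- X[1:5, ]
  for (s in c("a", "b")) {
    rows <- which(subj[1:5] == s)
    brute_between[rows, ] <- matrix(colMeans(X[rows, , drop = FALSE]),
                                    length(rows), 3, byrow = TRUE)
  }
  expect_equal(sp$between, brute_between, ignore_attr = TRUE)
  expect_equal(sp$between + sp$within, X[1:5, ], ignore_attr = TRUE)
  # within-block column means vanish per subject
  for (s in c("a", "b")) {
    rows <- sp$subject == s
    expect_true(all(abs(colMeans(sp$within[rows, , drop = FALSE])) < 1e-12))
  }

  # one subject only: within = X - column means
  X1 <- matrix(rnorm(12), 4, 3)
  sp1 <- multilevel_split(X1, rep("s", 4))
  expect_equal(sp1$within, sweep(X1, 2, colMeans(X1)), ignore_attr = TRUE)
})

test_that("multilevel PCA recovers structure and matches an eigen oracle", {
  # all within-variation on one line -> first component explains all
  subj <- rep(c("a", "b"), each = 4)
  dir <- c(1, -2, 0.5)
  t_dev <- rep(c(-1.5, -0.5, 0.5, 1.5), 2)
  X <- outer(t_dev, dir) + rep(c(0, 5), each = 4)
  pc <- mpca(X, subj, ncomp = 2)
  expect_equal(pc$explained[1], 1)

  set.seed(73)
  X2 <- matrix(rnorm(12), 4, 3)
  subj2 <- rep(c("a", "b"), each = 2)
  pc2 <- mpca(X2, subj2, ncomp = 2)
  W <- multilevel_split(X2, subj2)$within
  ev <- eigen(crossprod(W))
  for (k in 1:2) {
    expect_equal(abs(sum(pc2$loadings[, k] * ev$vectors[, k])), 1)
  }
  expect_true(all(diff(pc2$explained) <= 1e-12))
  # loadings orthonormal, reconstruction at full rank
  pcf <- mpca(X2, subj2, ncomp = 3)
  expect_equal(crossprod(pcf$loadings), diag(ncol(pcf$loadings)),
               ignore_attr = TRUE)
  expect_equal(pcf$scores %*% t(pcf$loadings), W, ignore_attr = TRUE)
})

test_that("PLS-DA separates constructed classes and finds the signal ion", {
  set.seed(74)
  n_subj <- 20
  subj <- rep(sprintf("S%02d", 1:n_subj), each = 2)
  lab <- rep(c("A", "B"), n_subj)
  X <- matrix(rnorm(2 * n_subj * 5, sd = 0.5), 2 * n_subj, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  X[lab == "B", 3] <- X[lab == "B", 3] + 6 * 0.5 # 6-sd class shift on v3
  Xc <- sweep(X, 2, colMeans(X))
  m <- mplsda(Xc, subj, lab, ncomp = 2)
  lv1 <- m$scores[, 1]
  expect_true(max(lv1[m$labels == "A"]) < min(lv1[m$labels == "B"]) ||
                min(lv1[m$labels == "A"]) > max(lv1[m$labels == "B"]))
  expect_equal(names(which.max(abs(m$weights[, 1]))), "v3")
  v <- vip_scores(m)
  expect_equal(names(which.max(v)), "v3")
  # single informative ion at one component: VIP -> sqrt(p)
  m1 <- mplsda(Xc, subj, lab, ncomp = 1)
  expect_equal(unname(vip_scores(m1)["v3"]), sqrt(5), tolerance = 0.15)
  expect_error(mplsda(Xc, subj, rep("A", length(lab))), "2 classes")
})

test_that("multilevel identities hold on random matrices", {
  set.seed(75)
  for (i in 1:20) {
    n_subj <- sample(4:8, 1)
    per <- sample(2:4, 1)
    p <- sample(3:10, 1)
    subj <- rep(sprintf("S%d", 1:n_subj), each = per)
    lab <- rep(rep(c("A", "B"), length.out = per), n_subj)
    X <- matrix(rnorm(n_subj * per * p), n_subj * per, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    Xc <- sweep(X, 2, colMeans(X))
    sp <- multilevel_split(Xc, subj)
    expect_equal(sp$between + sp$within, Xc, ignore_attr = TRUE)
    nc <- min(3, p)
    m <- mplsda(Xc, subj, lab, ncomp = nc)
    expect_equal(sum(vip_scores(m)^2), p, tolerance = 1e-8)
    G <- crossprod(m$scores)
    off <- abs(G[upper.tri(G)])
    lim <- 1e-8 * sqrt(outer(diag(G), diag(G)))[upper.tri(G)]
    expect_true(all(off <= lim))
  }
})

test_that("subject-level cross-validation is leakage-safe and calibrated", {
  set.seed(76)
  n_subj <- 30
  subj <- rep(sprintf("S%02d", 1:n_subj), each = 2)
  lab <- rep(c("A", "B"), n_subj)
  X <- matrix(rnorm(2 * n_subj * 4, sd = 0.3), 2 * n_subj, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  X[lab == "B", 1] <- X[lab == "B", 1] + 4
  Xc <- sweep(X, 2, colMeans(X))
  cv <- cross_validate(Xc, subj, lab, folds = 5, repetitions = 3, ncomp = 2,
                       seed = 10)
  expect_lt(cv$error_mean, 0.05)
  cv2 <- cross_validate(Xc, subj, lab, folds = 5, repetitions = 3, ncomp = 2,
                        seed = 10)
  expect_equal(cv$errors, cv2$errors) # same seed, same folds, same errors

  # labels independent of X: balanced error ~ chance = 1 - 1/g
  set.seed(77)
  Xn <- matrix(rnorm(2 * n_subj * 4), 2 * n_subj, 4,
               dimnames = list(NULL, paste0("v", 1:4)))
  cvn <- cross_validate(sweep(Xn, 2, colMeans(Xn)), subj, lab, folds = 5,
                        repetitions = 10, ncomp = 2, seed = 11)
  expect_equal(cvn$error_mean, 0.5, tolerance = 0.15)
  expect_error(cross_validate(Xc, subj, lab, folds = 100), "folds")
})

test_that("scores, VIP and the within matrix agree with mixOmics", {
  library(mixOmics)
  set.seed(78)
  n_subj <- 12
  subj <- rep(sprintf("S%02d", 1:n_subj), each = 3)
  lab <- rep(c("t0", "t1", "t2"), n_subj)
  X <- matrix(rnorm(3 * n_subj * 6), 3 * n_subj, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  X[lab != "t0", 2] <- X[lab != "t0", 2] + 1.5
  Xc <- sweep(X, 2, colMeans(X))
  sp <- multilevel_split(Xc, subj)
  ref_within <- mixOmics::withinVariation(Xc, design = data.frame(sample = subj))
  expect_lt(max(abs(sp$within - ref_within)), 1e-10)
  ours <- mplsda(Xc, subj, lab, ncomp = 2)
  ref <- mixOmics::plsda(sp$within, factor(lab), ncomp = 2, scale = FALSE)
  expect_gt(abs(cor(ours$scores[, 1], ref$variates$X[, 1])), 1 - 1e-8)
  expect_gt(abs(cor(ours$scores[, 2], ref$variates$X[, 2])), 1 - 1e-8)
  ref_vip <- mixOmics::vip(ref)
  expect_equal(unname(vip_scores(ours)), unname(ref_vip[, 2]),
               tolerance = 1e-6)
})
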