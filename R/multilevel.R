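# Multilevel (within-subject) multivariate modelling: preprocessing,
# between/within decomposition, M-PCA, M-PLS-DA via NIPALS, VIP scores
# and subject-level repeated cross-validation.

#' Log-transform and mean-center a positive matrix
#'
#' @param x Samples-by-variables matrix, all values > 0 (LoD replacement
#'   guarantees this upstream).
#' @return Matrix of natural logs with column means removed (attribute
#'   `centers` holds the removed means).
#' @export
log_center <- function(x) {
  stopifnot(is.matrix(x))
  if (any(!is.finite(x)) || any(x <= 0)) {
    bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive value at sample ", bad[1], ", ion '",
         colnames(x)[bad[2]], "': apply LoD replacement before the log ",
         "transform")
  }
  lx <- log(x)
  ctr <- colMeans(lx)
  out <- sweep(lx, 2, ctr)
  attr(out, "centers") <- ctr
  out
}

#' Preprocess a study matrix for multilevel modelling
#'
#' Collapses duplicates to replicate means, drops the ions excluded from
#' the model (non-retained always; exogenous channels when
#' `drop_exogenous`), then log-transforms and mean-centers.
#'
#' @param sm A `study_matrix` (see [quantify_sessions()]).
#' @param subset Optional logical/integer row selector on the collapsed
#'   samples (e.g. one study group).
#' @param drop_exogenous Exclude exogenous-flagged channels from the
#'   model (they reflect diet, not exercise). Default FALSE.
#' @param collapse Average duplicates per participant-timepoint first
#'   (default TRUE).
#' @return List of class `prep_matrix`: `X` (log, centered), `subject`,
#'   `meta`, `centers`.
#' @export
preprocess <- function(sm, subset = NULL, drop_exogenous = FALSE,
                       collapse = TRUE) {
  stopifnot(inherits(sm, "study_matrix"))
  if (collapse && "replicate" %in% names(sm$meta)) sm <- collapse_replicates(sm)
  ions <- sm$retained
  if (drop_exogenous) {
    exo <- sm$ion_table$channel[sm$ion_table$role == "exogenous"]
    ions <- setdiff(ions, exo)
  }
  conc <- sm$conc[, ions, drop = FALSE]
  meta <- sm$meta
  if (!is.null(subset)) {
    conc <- conc[subset, , drop = FALSE]
    meta <- meta[subset, , drop = FALSE]
  }
  X <- log_center(conc)
  structure(list(X = X, subject = meta$participant, meta = meta,
                 centers = attr(X, "centers")), class = "prep_matrix")
}

.as_X_subject <- function(x, subject) {
  if (inherits(x, "prep_matrix")) list(X = x$X, subject = x$subject)
  else list(X = x, subject = subject)
}

#' Between/within-subject decomposition
#'
#' Splits a repeated-measures matrix into the between-subject part (each
#' row replaced by its subject's mean row) and the within-subject part
#' (deviations from the subject mean). The reconstruction
#' `between + within = X` is exact. Subjects with a single sample are
#' excluded with a warning (their within-row would be identically zero).
#'
#' @param X Samples-by-variables numeric matrix (or `prep_matrix`).
#' @param subject Subject id per row.
#' @return List with `between`, `within`, `subject`, `kept` (row index
#'   into the input).
#' @export
multilevel_split <- function(X, subject = NULL) {
  inp <- .as_X_subject(X, subject)
  X <- inp$X; subject <- as.character(inp$subject)
  stopifnot(is.matrix(X), length(subject) == nrow(X))
  tab <- table(subject)
  single <- names(tab)[tab < 2]
  keep <- !(subject %in% single)
  if (length(single)) {
    warning("excluding subject(s) with a single sample: ",
            paste(single, collapse = ", "))
    X <- X[keep, , drop = FALSE]
    subject <- subject[keep]
  }
  if (nrow(X) == 0) stop("no subjects with repeated measures")
  means <- rowsum(X, subject) / as.vector(table(subject)[sort(unique(subject))])
  between <- means[subject, , drop = FALSE]
  rownames(between) <- NULL
  list(between = between, within = X - between, subject = subject,
       kept = which(keep))
}

#' Multilevel principal component analysis
#'
#' PCA (via singular value decomposition) of the within-subject
#' variation: the between-subject offsets are removed first so the
#' components describe how samples move around their own subject's mean
#' (e.g. across timepoints), not who the subject is.
#'
#' @param X Samples-by-ions matrix (or `prep_matrix`), already log/
#'   centered.
#' @param subject Subject id per row (ignored for a `prep_matrix`).
#' @param ncomp Number of components.
#' @return List of class `mpca`: `scores`, `loadings` (orthonormal),
#'   `explained` (variance fractions, non-increasing), `split`.
#' @export
mpca <- function(X, subject = NULL, ncomp = 2) {
  sp <- multilevel_split(X, subject)
  W <- sp$within
  tot <- sum(W^2)
  if (tot == 0) stop("within-subject matrix has zero variance")
  ncomp <- min(ncomp, nrow(W) - 1L, ncol(W))
  pc <- prcomp(W, center = FALSE, scale. = FALSE)
  structure(list(
    scores = pc$x[, seq_len(ncomp), drop = FALSE],
    loadings = pc$rotation[, seq_len(ncomp), drop = FALSE],
    explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ncomp)],
    split = sp
  ), class = "mpca")
}

# one-hot dummy matrix for class labels
.dummy_y <- function(labels) {
  f <- factor(labels)
  Y <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y
}

#' Multilevel PLS-DA
#'
#' Between/within decomposition followed by PLS2 discriminant analysis
#' on the within-subject part against the one-hot class dummy matrix
#' (column-centered). Components are extracted with the iterative NIPALS
#' sequence; X is deflated after each component (Y is left alone, which
#' yields identical scores since score vectors are mutually orthogonal).
#' Initialization takes the dummy column of maximal variance, making the
#' fit deterministic.
#'
#' @param X Samples-by-ions matrix (or `prep_matrix`), log/centered.
#' @param subject Subject id per row.
#' @param labels Class label per row (>= 2 non-empty classes).
#' @param ncomp Number of latent variables.
#' @param tol,max_iter NIPALS convergence control.
#' @return List of class `mplsda`: `weights` (W), `loadings` (P),
#'   `scores` (T), `y_loadings` (Q), `ss` (Y-variance explained per
#'   component), `B` (regression coefficients), `y_means`, `levels`,
#'   `labels`, `split`, `ncomp`.
#' @export
mplsda <- function(X, subject = NULL, labels, ncomp = 2,
                   tol = 1e-12, max_iter = 1000) {
  inp <- .as_X_subject(X, subject)
  sp <- multilevel_split(inp$X, inp$subject)
  labels <- labels[sp$kept]
  f <- factor(labels)
  if (nlevels(f) < 2) stop("discrimination needs >= 2 classes")
  if (any(table(f) == 0)) stop("empty class")
  Y <- .dummy_y(f)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  Xd <- sp$within
  n <- nrow(Xd); p <- ncol(Xd); g <- ncol(Yc)
  ncomp <- min(ncomp, p, n - 1L)

  W <- matrix(0, p, ncomp, dimnames = list(colnames(Xd), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(Xd), NULL))
  Tm <- matrix(0, n, ncomp)
  Q <- matrix(0, g, ncomp, dimnames = list(colnames(Y), NULL))
  ss <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2, var))]
    w <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w_new <- crossprod(Xd, u) / c(crossprod(u))
      w_new <- w_new / sqrt(c(crossprod(w_new)))
      t_sc <- Xd %*% w_new
      q <- crossprod(Yc, t_sc) / c(crossprod(t_sc))
      u <- Yc %*% q / c(crossprod(q))
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
    }
    t_sc <- Xd %*% w
    q <- crossprod(Yc, t_sc) / c(crossprod(t_sc))
    p_load <- crossprod(Xd, t_sc) / c(crossprod(t_sc))
    W[, a] <- w; P[, a] <- p_load; Tm[, a] <- t_sc; Q[, a] <- q
    ss[a] <- c(crossprod(t_sc)) * c(crossprod(q))
    Xd <- Xd - tcrossprod(t_sc, p_load)
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = Q,
                 ss = ss, B = B, y_means = y_means, levels = levels(f),
                 labels = as.character(f), split = sp, ncomp = ncomp),
            class = "mplsda")
}

#' Predict classes from a fitted multilevel PLS-DA model
#'
#' `newdata` must already be on the model's scale (log, centered with
#' the training column means) and within-subject transformed. Each
#' sample is assigned to the class with the maximal predicted dummy
#' response.
#'
#' @param object A fitted [mplsda()] model.
#' @param newdata Samples-by-ions matrix (within-subject part).
#' @param ... Unused.
#' @return List with `pred` (predicted dummy responses) and `class`.
#' @export
predict.mplsda <- function(object, newdata, ...) {
  pred <- newdata %*% object$B +
    matrix(object$y_means, nrow(newdata), length(object$y_means),
           byrow = TRUE)
  cls <- object$levels[max.col(pred, ties.method = "first")]
  list(pred = pred, class = cls)
}

#' Variable Importance in the Projection
#'
#' `VIP_j = sqrt( p * sum_a SS_a (w_aj / ||w_a||)^2 / sum_a SS_a )`,
#' where `SS_a` is the Y-variance explained by component a. The mean
#' square VIP is 1 by construction (`sum_j VIP_j^2 = p`), so ions with
#' VIP > 1 contribute more than an average ion; those are the
#' model-selected compounds.
#'
#' @param model A fitted [mplsda()].
#' @return Named numeric vector of VIP scores (one per ion).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "mplsda"))
  if (sum(model$ss) == 0) stop("VIP undefined: no explained Y-variance")
  W <- model$weights
  p <- nrow(W)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  vip2 <- p * as.vector(wn2 %*% model$ss) / sum(model$ss)
  setNames(sqrt(vip2), rownames(W))
}

# stratified assignment of subjects to folds; subject-constant labels
# stratify, otherwise plain random
.assign_folds <- function(subjects, subj_class, folds) {
  fold <- setNames(integer(length(subjects)), subjects)
  for (cl in unique(subj_class)) {
    s <- sample(subjects[subj_class == cl])
    fold[s] <- rep_len(sample(folds), length(s))
  }
  fold
}

#' Subject-level repeated cross-validation of multilevel PLS-DA
#'
#' Folds partition subjects, never samples, so all repeated measures of
#' one participant land in the same fold (no leakage through the
#' within-subject split). Subjects are stratified by class when labels
#' are subject-constant. Per repetition the model — including the
#' multilevel decomposition and the column centering — is refit on the
#' training folds and held-out samples are classified by the maximal
#' predicted dummy response (test subjects' within-parts use their own
#' subject means, computable because whole subjects are held out). The
#' error metric is the balanced error rate (group sizes are unequal).
#' Should a training split lose a class entirely, the partition is
#' redrawn (logged).
#'
#' @param X Samples-by-ions matrix (or `prep_matrix`), log/centered.
#' @param subject Subject id per row.
#' @param labels Class label per row.
#' @param folds Number of folds (<= number of subjects).
#' @param repetitions Repetitions with fresh fold assignments.
#' @param ncomp Latent variables per fit.
#' @param seed Seed for the fold assignments.
#' @return List of class `mplsda_cv`: `error_mean`, `error_sd`, `errors`
#'   (per repetition), `folds`, `repetitions`, `ncomp`.
#' @export
cross_validate <- function(X, subject = NULL, labels, folds = 5,
                           repetitions = 10, ncomp = 2, seed = 1) {
  inp <- .as_X_subject(X, subject)
  X <- inp$X; subject <- as.character(inp$subject)
  stopifnot(length(labels) == nrow(X))
  subjects <- unique(subject)
  if (folds > length(subjects)) stop("more folds than subjects")
  subj_class <- vapply(subjects, function(s) {
    l <- unique(labels[subject == s])
    if (length(l) == 1) as.character(l) else "mixed"
  }, character(1))
  set.seed(seed)
  errors <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    for (try in seq_len(50)) {
      fold <- .assign_folds(subjects, subj_class, folds)
      ok <- all(vapply(seq_len(folds), function(k) {
        tr <- subject %in% subjects[fold[subjects] != k]
        length(unique(labels[tr])) == length(unique(labels))
      }, logical(1)))
      if (ok) break
      message("repartitioning: a class was absent from a training split")
    }
    truth <- character(0); pred <- character(0)
    for (k in seq_len(folds)) {
      te_subj <- subjects[fold[subjects] == k]
      te <- subject %in% te_subj
      if (!any(te)) next
      ctr <- colMeans(X[!te, , drop = FALSE])
      Xtr <- sweep(X[!te, , drop = FALSE], 2, ctr)
      Xte <- sweep(X[te, , drop = FALSE], 2, ctr)
      fit <- mplsda(Xtr, subject[!te], labels[!te], ncomp = ncomp)
      sp_te <- multilevel_split(Xte, subject[te])
      cls <- predict(fit, sp_te$within)$class
      truth <- c(truth, as.character(labels[te][sp_te$kept]))
      pred <- c(pred, cls)
    }
    per_class <- vapply(unique(truth), function(cl) {
      mean(pred[truth == cl] != cl)
    }, numeric(1))
    errors[r] <- mean(per_class)
  }
  structure(list(error_mean = mean(errors), error_sd = sd(errors),
                 errors = errors, folds = folds, repetitions = repetitions,
                 ncomp = ncomp), class = "mplsda_cv")
}

#' @export
print.mplsda_cv <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV, %d repetitions: balanced error %.3f +/- %.3f\n",
    x$folds, x$repetitions, x$error_mean, x$error_sd))
  invisible(x)
}
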