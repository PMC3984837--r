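# Evaluate `code` under a temporary seed, restoring the caller's RNG
# state afterwards, so seeded sub-computations (fold assignment, master
# lists) never perturb an enclosing seeded run.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Fitness weights for the accuracy / channel-count trade-off
#'
#' The fitness is `F = w1 * f1 + w2 * f2` with `f1` the geometric-mean
#' accuracy and `f2` the channel-count objective; only the ratio matters,
#' so weights are constrained to `w1 + w2 = 1`.  Eight named presets
#' (`"case1"` .. `"case8"`) span w1 = 1.00, 0.95, 0.90, 0.85, 0.75, 0.65,
#' 0.50, 0.35 (w2 the complement).
#'
#' @param w1 Accuracy weight, or a preset name.
#' @param w2 Channel weight; defaults to `1 - w1`.
#' @return An object of class `fitness_weights`.
#' @export
fitness_weights <- function(w1 = 0.5, w2 = NULL) {
  if (is.character(w1)) {
    presets <- weight_cases()
    if (!w1 %in% names(presets)) stop("unknown weight preset: ", w1)
    return(presets[[w1]])
  }
  if (is.null(w2)) w2 <- 1 - w1
  if (w1 < 0 || w2 < 0) stop("weights must be >= 0")
  if (abs(w1 + w2 - 1) > 1e-9) stop("weights must satisfy w1 + w2 = 1")
  structure(list(w1 = w1, w2 = w2), class = "fitness_weights")
}

#' @rdname fitness_weights
#' @export
weight_cases <- function() {
  w1 <- c(1.00, 0.95, 0.90, 0.85, 0.75, 0.65, 0.50, 0.35)
  out <- lapply(w1, function(w) structure(list(w1 = w, w2 = 1 - w),
                                          class = "fitness_weights"))
  names(out) <- paste0("case", seq_along(w1))
  out
}

#' Channel-count objective
#'
#' `f2 = (N_Ch - n + 1) / N_Ch`: equals 1 when a single channel is
#' selected and decreases linearly to `1/N_Ch` at the full montage.
#'
#' @param n Number of selected channels, `1 <= n <= n_total`.
#' @param n_total Montage size.
#' @return Scalar in `(0, 1]`.
#' @export
channel_objective <- function(n, n_total = 64L) {
  if (any(n < 1) || any(n > n_total))
    stop("n must be between 1 and ", n_total,
         " (an empty channel set is infeasible)")
  (n_total - n + 1) / n_total
}

#' Geometric-mean accuracy
#'
#' `sqrt((TP/Ps) * (TN/Ns))`: the geometric mean of the target and
#' nontarget accuracies.  Zero whenever either rate is zero, which
#' heavily penalizes unbalanced classifiers.
#'
#' @param TP,TN True positive / true negative counts.
#' @param Ps,Ns Class totals (positive, negative).
#' @return Scalar in `[0, 1]`.
#' @export
gm_accuracy <- function(TP, TN, Ps, Ns) {
  if (Ps <= 0 || Ns <= 0) stop("class totals must be positive")
  sqrt((TP / Ps) * (TN / Ns))
}

#' Aggregate multiobjective fitness
#'
#' `F = w1 * f1 + w2 * f2` where `f1` is the geometric-mean accuracy and
#' `f2` the channel-count objective.  A perfect classifier on a single
#' channel reaches F = 1 for any valid weights.
#'
#' @param gm Geometric-mean accuracy `f1`.
#' @param n Number of selected channels.
#' @param weights A [fitness_weights()].
#' @param n_total Montage size.
#' @return Scalar in `[0, 1]`.
#' @export
aggregate_fitness <- function(gm, n, weights = fitness_weights(), n_total = 64L) {
  weights$w1 * gm + weights$w2 * channel_objective(n, n_total)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `folds` folds such that every fold has
#' the same target/nontarget ratio up to one trial, deterministically
#' under `fold_seed`.
#'
#' @param y Labels in \{+1, -1\}.
#' @param folds Number of folds.
#' @param fold_seed Integer seed.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
stratified_folds <- function(y, folds = 10L, fold_seed = 1L) {
  y <- as.integer(y)
  if (min(sum(y == 1L), sum(y == -1L)) < folds)
    stop("need at least ", folds, " samples per class for ", folds,
         "-fold stratified CV")
  fold <- integer(length(y))
  with_seed(fold_seed, {
    for (cls in c(1L, -1L)) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Cross-validated confusion counts and fitness of one configuration
#'
#' 10-fold stratified cross-validation of the regularized FDA classifier
#' on the features of the selected channels: per fold the model is fitted
#' on the other nine folds and the Mahalanobis rule applied to the
#' held-out fold; confusion counts are pooled over folds before rates are
#' computed.  The fold assignment is a deterministic function of
#' `fold_seed` (or can be supplied precomputed via `fold`), so the
#' fitness landscape is stationary within one swarm run.
#'
#' @param features A `feature_matrix` over the full montage (from
#'   [extract_features()]), or a plain matrix.
#' @param y Labels in \{+1, -1\}.
#' @param channels Channel indices to use (columns are taken as the
#'   per-channel feature blocks); `NULL` uses all features as given.
#' @param lambda FDA regularization.
#' @param weights A [fitness_weights()] for the aggregate fitness.
#' @param n_total Montage size for the channel objective.
#' @param folds,fold_seed CV fold count and seed.
#' @param fold Optional precomputed fold assignment (overrides
#'   `fold_seed`).
#' @return A list of class `fitness_result`: `TP`, `TN`, `FP`, `FN`,
#'   `Ps`, `Ns`, `gm_accuracy`, `n_channels`, `f2`, `fitness`.
#' @export
cv_confusion <- function(features, y, channels = NULL, lambda = 1,
                         weights = fitness_weights(), n_total = NULL,
                         folds = 10L, fold_seed = 1L, fold = NULL) {
  Z <- subset_channel_features(features, channels)
  n_channels <- attr(Z, "n_channels")
  if (is.null(n_total))
    n_total <- if (inherits(features, "feature_matrix"))
      length(features$channel_ids) else n_channels
  y <- check_labels(Z, y)
  if (is.null(fold)) fold <- stratified_folds(y, folds, fold_seed)
  TP <- TN <- FP <- FN <- 0L
  for (k in sort(unique(fold))) {
    te <- fold == k
    fit <- fda_fit(Z[!te, , drop = FALSE], y[!te], lambda)
    pred <- predict(fit, Z[te, , drop = FALSE])
    yt <- y[te]
    TP <- TP + sum(pred == 1L & yt == 1L)
    TN <- TN + sum(pred == -1L & yt == -1L)
    FP <- FP + sum(pred == 1L & yt == -1L)
    FN <- FN + sum(pred == -1L & yt == 1L)
  }
  fitness_result(TP, TN, FP, FN, n_channels, weights, n_total)
}

# Columns of the selected channels' feature blocks.
subset_channel_features <- function(features, channels) {
  if (inherits(features, "feature_matrix")) {
    if (is.null(channels)) {
      Z <- features$values
      n_channels <- length(features$channel_ids)
    } else {
      pos <- match(as.integer(channels), features$channel_ids)
      if (any(is.na(pos))) stop("channels not present in feature matrix")
      npc <- features$n_per_channel
      cols <- as.vector(vapply(pos, function(p) (p - 1L) * npc + seq_len(npc),
                               integer(npc)))
      Z <- features$values[, cols, drop = FALSE]
      n_channels <- length(pos)
    }
  } else {
    Z <- as.matrix(features)
    n_channels <- if (is.null(channels)) 1L else length(channels)
  }
  if (ncol(Z) == 0L) stop("channel set must not be empty")
  attr(Z, "n_channels") <- n_channels
  Z
}

fitness_result <- function(TP, TN, FP, FN, n_channels,
                           weights = fitness_weights(), n_total = 64L) {
  Ps <- TP + FN
  Ns <- TN + FP
  gm <- gm_accuracy(TP, TN, Ps, Ns)
  f2 <- channel_objective(n_channels, n_total)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, Ps = Ps, Ns = Ns,
                 gm_accuracy = gm, n_channels = n_channels, f2 = f2,
                 fitness = weights$w1 * gm + weights$w2 * f2),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf(
    "Fitness %.4f  (gm accuracy %.4f on TP %d/%d, TN %d/%d; %d channels, f2 %.4f)\n",
    x$fitness, x$gm_accuracy, x$TP, x$Ps, x$TN, x$Ns, x$n_channels, x$f2))
  invisible(x)
}

#' Build the swarm's fitness function
#'
#' Precomputes the full-montage feature matrix's fold assignment once so
#' every particle evaluation sees the same folds, and returns a closure
#' `function(lambda, channels)` giving the `fitness_result` of that
#' configuration.
#'
#' @param features Full-montage `feature_matrix`.
#' @param y Labels in \{+1, -1\}.
#' @param weights A [fitness_weights()].
#' @param folds,fold_seed CV configuration.
#' @return A function `(lambda, channels) -> fitness_result`.
#' @export
make_fitness <- function(features, y, weights = fitness_weights(),
                         folds = 10L, fold_seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  y <- check_labels(features$values, y)
  fold <- stratified_folds(y, folds, fold_seed)
  n_total <- length(features$channel_ids)
  pre <- precompute_cv_grams(features$values, y, fold)
  npc <- features$n_per_channel
  function(lambda, channels) {
    pos <- match(as.integer(channels), features$channel_ids)
    if (any(is.na(pos))) stop("channels not present in feature matrix")
    cols <- as.vector(vapply(pos, function(p) (p - 1L) * npc + seq_len(npc),
                             integer(npc)))
    conf <- cv_confusion_grams(pre, cols, lambda)
    fitness_result(conf[["TP"]], conf[["TN"]], conf[["FP"]], conf[["FN"]],
                   length(pos), weights, n_total)
  }
}

# Per-fold, per-class Gram matrices and feature sums over the full
# montage, computed once per swarm run.  Lets each particle evaluation
# build every fold's within-class scatter for its channel subset by
# submatrix extraction and two rank-1 corrections instead of re-crossing
# the data, which is what makes the wrapper search affordable.
precompute_cv_grams <- function(Z, y, fold) {
  ks <- sort(unique(fold))
  out <- list(Z = Z, y = y, fold = fold, ks = ks)
  for (cls in c("pos", "neg")) {
    cy <- if (cls == "pos") 1L else -1L
    rows <- y == cy
    G_all <- crossprod(Z[rows, , drop = FALSE])
    s_all <- colSums(Z[rows, , drop = FALSE])
    out[[cls]] <- lapply(ks, function(k) {
      held <- rows & fold == k
      list(G = G_all - crossprod(Z[held, , drop = FALSE]),
           s = s_all - colSums(Z[held, , drop = FALSE]),
           n = sum(rows) - sum(held))
    })
  }
  out
}

# Pooled CV confusion for one (channel subset, lambda) from the
# precomputed per-fold Grams.  Numerically identical to running
# fda_fit/predict fold by fold; a test asserts the equivalence.
cv_confusion_grams <- function(pre, cols, lambda) {
  Zc <- pre$Z[, cols, drop = FALSE]
  y <- pre$y
  TP <- TN <- FP <- FN <- 0L
  for (ki in seq_along(pre$ks)) {
    k <- pre$ks[ki]
    gp <- pre$pos[[ki]]; gn <- pre$neg[[ki]]
    m_pos <- gp$s[cols] / gp$n
    m_neg <- gn$s[cols] / gn$n
    S <- gp$G[cols, cols, drop = FALSE] + gn$G[cols, cols, drop = FALSE] -
      gp$n * tcrossprod(m_pos) - gn$n * tcrossprod(m_neg)
    diag(S) <- diag(S) + lambda
    R <- tryCatch(chol(S), error = function(e)
      stop("scatter matrix not positive definite; increase lambda"))
    w <- backsolve(R, forwardsolve(t(R), m_pos - m_neg))
    s_all <- drop(Zc %*% w)
    tr <- pre$fold != k
    sp <- s_all[tr & y == 1L]
    sn <- s_all[tr & y == -1L]
    mu_p <- mean(sp); mu_n <- mean(sn)
    v_p <- stats::var(sp); v_n <- stats::var(sn)
    te <- !tr
    pred <- classify_scores(s_all[te], mu_p, mu_n, v_p, v_n)
    yt <- y[te]
    TP <- TP + sum(pred == 1L & yt == 1L)
    TN <- TN + sum(pred == -1L & yt == -1L)
    FP <- FP + sum(pred == 1L & yt == -1L)
    FN <- FN + sum(pred == -1L & yt == 1L)
  }
  c(TP = TP, TN = TN, FP = FP, FN = FN)
}
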