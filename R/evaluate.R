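#' Stratified train/test split of an epoch dataset
#'
#' Splits the trials into disjoint, exhaustive train and test subsets so
#' that every (class, direction, session) stratum is represented in both
#' subsets in the same proportion as in the full set.  Per-stratum counts
#' are split as evenly as integer rounding allows; when a stratum is odd,
#' the extra trial alternates between train and test across strata so the
#' totals stay balanced.  Deterministic under `seed`.
#'
#' @param epochs An `erp_epochs` object.
#' @param fraction_train Fraction of each stratum assigned to training.
#' @param seed Integer seed.
#' @return List with `train`, `test` (`erp_epochs`) and the trial index
#'   vectors `idx_train`, `idx_test`.
#' @export
stratified_split <- function(epochs, fraction_train = 0.5, seed = 1L) {
  stopifnot(inherits(epochs, "erp_epochs"))
  strata <- interaction(epochs$labels, epochs$direction, epochs$session,
                        drop = TRUE)
  idx_train <- integer(0)
  extra_to_train <- TRUE
  with_seed(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      if (length(idx) < 2L)
        warning("stratum ", s, " has fewer than 2 trials; ",
                "splitting proportionally anyway")
      n_tr <- fraction_train * length(idx)
      if (abs(n_tr - round(n_tr)) > 1e-9) {   # odd stratum: alternate
        n_tr <- if (extra_to_train) ceiling(n_tr) else floor(n_tr)
        extra_to_train <- !extra_to_train
      }
      n_tr <- as.integer(round(n_tr))
      idx_train <- c(idx_train, sort(sample(idx, n_tr)))
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(epochs$labels), idx_train)
  list(train = epochs[idx_train], test = epochs[idx_test],
       idx_train = idx_train, idx_test = idx_test)
}

#' Train the final classifier and test on held-out trials
#'
#' Fits the regularized FDA on all training trials using a decoded
#' configuration (regularization and channel set, typically the global
#' best of [select_channels()] run on the training set only), then
#' returns the geometric-mean accuracy and the raw discriminant scores on
#' the test set.
#'
#' @param train,test `erp_epochs` objects (disjoint).
#' @param lambda FDA regularization.
#' @param channels Selected channel indices (non-empty).
#' @param preproc A [preproc_spec()].
#' @return List: `gm` (test geometric-mean accuracy), `scores` (test
#'   discriminant scores), `pred` (test labels), `confusion`
#'   (`fitness_result` of the test confusion), `model` (the fitted
#'   `fda`), `channels`.
#' @export
train_final_and_test <- function(train, test, lambda, channels,
                                 preproc = preproc_spec()) {
  if (length(channels) == 0L) stop("channel set must not be empty")
  Ztr <- preprocess_epochs(train, preproc, channels = channels)
  Zte <- preprocess_epochs(test, preproc, channels = channels)
  model <- fda_fit(Ztr, train$labels, lambda)
  s <- predict(model, Zte, type = "score")
  pred <- classify_scores(s, model$mu_pos, model$mu_neg,
                          model$var_pos, model$var_neg)
  y <- test$labels
  conf <- fitness_result(sum(pred == 1L & y == 1L),
                         sum(pred == -1L & y == -1L),
                         sum(pred == 1L & y == -1L),
                         sum(pred == -1L & y == 1L),
                         n_channels = length(channels),
                         n_total = length(train$channel_names))
  list(gm = conf$gm_accuracy, scores = s, pred = pred, confusion = conf,
       model = model, channels = channels)
}

#' Master list of averaged-trial compositions
#'
#' For each averaging order `M` in `M_range`, draws as many index tuples
#' into the single-trial test set as there are test trials, preserving
#' the class ratio exactly; each tuple holds `M` same-class trial indices
#' sampled with replacement.  One master list, deterministic under
#' `seed`, is reused across all configurations so averaged-trial
#' comparisons always combine exactly the same information.
#'
#' @param labels Test-set labels in \{+1, -1\}.
#' @param M_range Averaging orders (default `2:10`).
#' @param seed Integer seed.
#' @return An object of class `master_list`: per `M`, a list with
#'   `tuples` (matrix, one row per fabricated trial, `M` columns) and
#'   `labels` (class of each fabricated trial).
#' @export
build_master_list <- function(labels, M_range = 2:10, seed = 1L) {
  labels <- as.integer(labels)
  if (!all(c(-1L, 1L) %in% labels))
    stop("both classes must be present in the test set")
  idx_pos <- which(labels == 1L)
  idx_neg <- which(labels == -1L)
  out <- list()
  with_seed(seed, {
    for (M in M_range) {
      tp <- matrix(sample(idx_pos, length(idx_pos) * M, replace = TRUE),
                   ncol = M)
      tn <- matrix(sample(idx_neg, length(idx_neg) * M, replace = TRUE),
                   ncol = M)
      out[[as.character(M)]] <- list(
        tuples = rbind(tp, tn),
        labels = c(rep(1L, nrow(tp)), rep(-1L, nrow(tn))))
    }
  })
  structure(list(M_range = as.integer(M_range), lists = out,
                 n_trials = length(labels)),
            class = "master_list")
}

#' Averaged-trial accuracy by score averaging
#'
#' Fabricates each averaged trial by averaging the single-trial
#' discriminant scores of its master-list tuple, applies the Mahalanobis
#' class rule with the single-trial training score statistics, and
#' returns the geometric-mean accuracy over the fabricated set.
#'
#' @param scores Single-trial test scores (from [train_final_and_test()]).
#' @param labels Single-trial test labels (same order).
#' @param model The fitted single-trial `fda` model.
#' @param master A [build_master_list()] result over these test trials.
#' @param M Averaging order; must be in the master list's range.
#' @return Geometric-mean accuracy of the averaged-trial set.
#' @export
averaged_trial_gm <- function(scores, labels, model, master, M) {
  key <- as.character(M)
  if (!key %in% names(master$lists))
    stop("M = ", M, " is outside the master list's range")
  if (length(scores) != master$n_trials)
    stop("scores length does not match the master list's test set")
  ml <- master$lists[[key]]
  avg <- rowMeans(matrix(scores[ml$tuples], nrow = nrow(ml$tuples)))
  pred <- classify_scores(avg, model$mu_pos, model$mu_neg,
                          model$var_pos, model$var_neg)
  y <- ml$labels
  gm_accuracy(sum(pred == 1L & y == 1L), sum(pred == -1L & y == -1L),
              sum(y == 1L), sum(y == -1L))
}

#' Pareto front of the accuracy / channel-count trade-off
#'
#' Returns the non-dominated subset of (channel count, accuracy) points:
#' a point survives iff no other point has accuracy at least as high and
#' channel count at most as low, with at least one strict.
#'
#' @param points Data frame with columns `n_channels` and `gm_accuracy`
#'   (an `mhpso` object's feasible history rows also work).
#' @return The non-dominated rows (duplicates collapsed).
#' @export
pareto_front <- function(points) {
  if (inherits(points, "mhpso"))
    points <- points$history[points$history$feasible &
                               !is.na(points$history$gm_accuracy), ]
  pts <- unique(points[, c("n_channels", "gm_accuracy")])
  if (nrow(pts) == 0L) stop("no feasible points")
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    dominated <- pts$gm_accuracy >= pts$gm_accuracy[i] &
      pts$n_channels <= pts$n_channels[i] &
      (pts$gm_accuracy > pts$gm_accuracy[i] |
         pts$n_channels < pts$n_channels[i])
    !any(dominated)
  }, logical(1))
  rownames(pts) <- NULL
  pts[keep, , drop = FALSE]
}

#' Channel selection frequency across repeated searches
#'
#' The fraction of search results whose global best includes each
#' channel, as plotted in selection-frequency scalp maps.
#'
#' @param results List of `mhpso` objects (or of channel index vectors).
#' @param n_channels_total Montage size.
#' @return Numeric vector of per-channel frequencies in `[0, 1]`, named
#'   if channel names are available.
#' @export
selection_frequency <- function(results, n_channels_total = 64L) {
  if (length(results) == 0L) stop("need at least one result")
  freq <- numeric(n_channels_total)
  nm <- NULL
  for (r in results) {
    ch <- if (inherits(r, "mhpso")) r$channels else as.integer(r)
    if (inherits(r, "mhpso") && !is.null(r$channel_names)) nm <- r$channel_names
    freq[ch] <- freq[ch] + 1
  }
  freq <- freq / length(results)
  if (!is.null(nm) && length(nm) == n_channels_total) names(freq) <- nm
  freq
}
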