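#' Within-class scatter statistics
#'
#' Computes the within-class scatter matrix
#' `S_W = sum_j sum_{i in K_j} (z_i - m_j)(z_i - m_j)^T` (summed outer
#' products, no 1/l normalization) and the class feature means.
#'
#' @param Z Numeric matrix, samples x features (or a `feature_matrix`).
#' @param y Labels in \{+1, -1\}.
#' @return A list of class `scatter_stats`: `S_W`, `m_pos`, `m_neg`,
#'   `n_pos`, `n_neg`.
#' @export
compute_scatter <- function(Z, y) {
  Z <- as_feature_values(Z)
  y <- check_labels(Z, y)
  pos <- y == 1L
  if (!any(pos) || all(pos)) stop("both classes must be present")
  Zp <- Z[pos, , drop = FALSE]
  Zn <- Z[!pos, , drop = FALSE]
  m_pos <- colMeans(Zp)
  m_neg <- colMeans(Zn)
  S_W <- crossprod(sweep(Zp, 2, m_pos)) + crossprod(sweep(Zn, 2, m_neg))
  structure(list(S_W = S_W, m_pos = m_pos, m_neg = m_neg,
                 n_pos = nrow(Zp), n_neg = nrow(Zn)),
            class = "scatter_stats")
}

as_feature_values <- function(Z) {
  if (inherits(Z, "feature_matrix")) Z$values else as.matrix(Z)
}

check_labels <- function(Z, y) {
  y <- as.integer(y)
  if (length(y) != nrow(Z)) stop("length(y) must equal nrow(Z)")
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1")
  y
}

# Shared solver: w such that (S_W + lambda I) w = m_pos - m_neg, by
# Cholesky (the matrix is symmetric positive definite for lambda > 0).
solve_fda_direction <- function(scatter, lambda) {
  A <- scatter$S_W
  diag(A) <- diag(A) + lambda
  R <- tryCatch(chol(A), error = function(e) NULL)
  d <- scatter$m_pos - scatter$m_neg
  if (is.null(R)) {
    if (lambda == 0)
      stop("within-class scatter matrix is singular; use lambda > 0 ",
           "(rank-deficient: more features than effective samples)")
    stop("scatter matrix not positive definite")
  }
  backsolve(R, forwardsolve(t(R), d))
}

#' Fit a regularized Fisher discriminant classifier
#'
#' Solves `(S_W + lambda I) w = m_pos - m_neg` for the projection `w`
#' (as a symmetric positive-definite linear system, never by explicit
#' inversion), then summarizes the training scores `s(z) = <w, z>` by
#' their per-class means and variances, which parameterize the
#' Mahalanobis class rule used by [predict.fda()].
#'
#' @param Z Training features, samples x features (or a `feature_matrix`).
#' @param y Labels in \{+1, -1\}; each class needs at least 2 samples.
#' @param lambda Regularization parameter, >= 0.  `lambda = 0` requires a
#'   nonsingular scatter matrix.
#' @return An object of class `fda` with elements `w`, `lambda`,
#'   `mu_pos`, `mu_neg`, `var_pos`, `var_neg`, `m_pos`, `m_neg`,
#'   `n_features`.
#' @seealso [predict.fda()], [fda_score()]
#' @export
fda_fit <- function(Z, y, lambda = 0) {
  Z <- as_feature_values(Z)
  y <- check_labels(Z, y)
  if (lambda < 0) stop("lambda must be >= 0")
  if (sum(y == 1L) < 2L || sum(y == -1L) < 2L)
    stop("each class needs at least 2 samples (score variance undefined)")
  sc <- compute_scatter(Z, y)
  w <- solve_fda_direction(sc, lambda)
  s <- drop(Z %*% w)
  sp <- s[y == 1L]
  sn <- s[y == -1L]
  model <- structure(list(
    w = w, lambda = lambda,
    mu_pos = mean(sp), mu_neg = mean(sn),
    var_pos = stats::var(sp), var_neg = stats::var(sn),
    m_pos = sc$m_pos, m_neg = sc$m_neg,
    n_features = ncol(Z)
  ), class = "fda")
  if (model$var_pos <= 0 || model$var_neg <= 0)
    stop("degenerate training scores: a class has zero score variance")
  model
}

#' Discriminant score
#'
#' The inner product `s(z) = <w, z>`: the signed distance of a sample to
#' the separating hyperplane, linear in `z`.
#'
#' @param model A fitted `fda` object.
#' @param z A feature vector, or a matrix with one sample per row.
#' @return Numeric score(s).
#' @export
fda_score <- function(model, z) {
  if (is.matrix(z)) {
    if (ncol(z) != model$n_features) stop("feature dimension mismatch")
    drop(z %*% model$w)
  } else {
    if (length(z) != model$n_features) stop("feature dimension mismatch")
    sum(model$w * z)
  }
}

# Mahalanobis class rule on precomputed scores; ties go to nontarget.
classify_scores <- function(s, mu_pos, mu_neg, var_pos, var_neg) {
  d_pos <- (s - mu_pos)^2 / var_pos
  d_neg <- (s - mu_neg)^2 / var_neg
  ifelse(d_pos < d_neg, 1L, -1L)
}

#' Predict classes or scores from a fitted discriminant
#'
#' Classification assigns the class whose training-score distribution
#' gives the smaller variance-normalized squared distance
#' `(s - mu_j)^2 / sigma_j^2` (Mahalanobis rule); exact ties break to
#' nontarget (-1).
#'
#' @param object A fitted `fda` object.
#' @param newdata Feature matrix (samples x features), feature vector, or
#'   `feature_matrix`.
#' @param type `"class"` for +1/-1 labels, `"score"` for raw scores.
#' @param ... Ignored.
#' @return Integer labels or numeric scores.
#' @export
predict.fda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  s <- fda_score(object, newdata)
  if (type == "score") return(s)
  classify_scores(s, object$mu_pos, object$mu_neg,
                  object$var_pos, object$var_neg)
}

#' @export
coef.fda <- function(object, ...) object$w

#' @export
print.fda <- function(x, ...) {
  cat(sprintf(
    "Regularized FDA: %d features, lambda = %.4g\n", x$n_features, x$lambda))
  cat(sprintf("  training scores: target N(%.3g, %.3g), nontarget N(%.3g, %.3g)\n",
              x$mu_pos, x$var_pos, x$mu_neg, x$var_neg))
  invisible(x)
}
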