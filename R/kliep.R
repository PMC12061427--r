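gauss_basis <- function(z, centers, bandwidth) {
  # unnormalized Gaussian kernels exp(-||z - c||^2 / (2 sigma^2)); n x k
  z <- as.matrix(z)
  centers <- as.matrix(centers)
  d2 <- outer(rowSums(z^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(z)), rowSums(centers^2)) - 2 * z %*% t(centers)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * bandwidth^2))
}

#' Median-heuristic kernel bandwidth
#'
#' Median pairwise Euclidean distance on (a subsample of) the numerator
#' samples — the standard default width for Gaussian kernel methods.
#'
#' @param z samples x K matrix.
#' @param max_n subsample cap for the pairwise distances.
#' @return Positive scalar bandwidth.
#' @export
median_bandwidth <- function(z, max_n = 500) {
  z <- as.matrix(z)
  if (nrow(z) > max_n) z <- z[seq(1, nrow(z), length.out = max_n), , drop = FALSE]
  d <- stats::dist(z)
  out <- stats::median(d[d > 0])
  if (!is.finite(out) || out <= 0) stop("cannot determine a bandwidth: degenerate samples")
  out
}

#' Fit a KLIEP density-ratio model
#'
#' Estimates w(z) = p_num(z) / p_den(z) as a non-negative linear combination
#' of Gaussian basis functions centered on a subsample of the numerator
#' samples,
#' \deqn{\hat w(z) = \sum_i a_i \exp(-\|z - c_i\|^2 / (2\sigma_b^2)),}
#' by maximizing the numerator log-likelihood
#' \eqn{J = (1/M)\sum_j \ln \hat w(z^{num}_j)} subject to \eqn{a_i \ge 0}
#' and the density normalization \eqn{(1/m)\sum_j \hat w(z^{den}_j) = 1}.
#' Optimization is projected gradient ascent with backtracking, so the
#' logged objective is non-decreasing.
#'
#' @param z_num numerator samples (single-cell embedding), M x K matrix.
#' @param z_den denominator samples (spatial reference embedding), m x K.
#' @param k number of basis centers, default `min(100, M)`.
#' @param bandwidth Gaussian width. Default: likelihood cross-validation
#'   ([select_bandwidth()]) over the [median_bandwidth()] of `z_num` scaled
#'   by 1, 1/2, 1/4, 1/8 — the plain median heuristic over-smooths in
#'   higher-dimensional embeddings. Samples too small to cross-validate
#'   fall back to the median heuristic.
#' @param max_iter,tol ascent iteration cap and objective tolerance.
#' @param seed integer seed for the center subsample.
#' @return A `kliep_model` with `centers`, `bandwidth`, non-negative
#'   coefficients `a`, and `fit_log` (the non-decreasing J trace).
#' @export
fit_kliep <- function(z_num, z_den, k = NULL, bandwidth = NULL,
                      max_iter = 2000, tol = 1e-6, seed = 1L) {
  z_num <- as.matrix(z_num)
  z_den <- as.matrix(z_den)
  if (ncol(z_num) != ncol(z_den)) stop("embedding dimension mismatch")
  M <- nrow(z_num)
  if (is.null(k)) k <- min(100L, M)
  if (k > M) stop("k (", k, ") exceeds the numerator sample count (", M, ")")
  if (is.null(bandwidth)) {
    md <- median_bandwidth(z_num)
    bandwidth <- if (M < 10) md else
      select_bandwidth(z_num, z_den, candidates = md * c(1, 0.5, 0.25, 0.125),
                       folds = 5, k = min(k, M - ceiling(M / 5)), seed = seed)
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")

  idx <- with_seed(seed, sample.int(M, k))
  centers <- z_num[idx, , drop = FALSE]

  Phi_num <- gauss_basis(z_num, centers, bandwidth)
  Phi_den <- gauss_basis(z_den, centers, bandwidth)
  b <- colMeans(Phi_den)                        # constraint: sum(a * b) = 1
  if (all(b == 0)) stop("all basis functions vanish on the denominator; increase bandwidth")

  bb <- sum(b * b)
  # gradient step, projection onto the constraint hyperplane, clip, rescale
  project <- function(a) {
    a <- a + b * (1 - sum(b * a)) / bb
    a <- pmax(a, 0)
    s <- sum(b * a)
    if (s <= 0) return(NULL)
    a / s
  }
  a <- project(rep(1, k))
  r <- as.vector(Phi_num %*% a)
  if (any(r <= 0))
    stop("a numerator sample has zero basis support; increase bandwidth")
  J <- mean(log(r))
  fit_log <- J
  step <- 1
  for (it in seq_len(max_iter)) {
    grad <- colMeans(Phi_num / r)
    improved <- FALSE
    while (step > 1e-12) {
      a_new <- project(a + step * grad)
      if (!is.null(a_new)) {
        r_new <- as.vector(Phi_num %*% a_new)
        if (all(r_new > 0)) {
          J_new <- mean(log(r_new))
          if (J_new > J) {
            improved <- TRUE
            break
          }
        }
      }
      step <- step / 2
    }
    if (!improved) break
    delta <- J_new - J
    a <- a_new; r <- r_new; J <- J_new
    fit_log <- c(fit_log, J)
    step <- step * 2
    if (delta < tol) break
  }
  structure(list(centers = centers, bandwidth = bandwidth, a = a, k = k,
                 b = b, seed = seed, fit_log = fit_log),
            class = "kliep_model")
}

#' @export
print.kliep_model <- function(x, ...) {
  cat(sprintf("kliep_model: k = %d bases, bandwidth = %.4g, J = %.5g (%d iterations)\n",
              x$k, x$bandwidth, x$fit_log[length(x$fit_log)], length(x$fit_log) - 1L))
  invisible(x)
}

#' Evaluate a fitted density ratio
#'
#' @param object a `kliep_model`.
#' @param z samples x K matrix (K matching the model's centers).
#' @param ... unused.
#' @return Non-negative vector of ratio estimates, one per row of `z`.
#' @export
predict.kliep_model <- function(object, z, ...) {
  z <- as.matrix(z)
  if (ncol(z) != ncol(object$centers))
    stop("dimension mismatch: z has ", ncol(z), " columns, model expects ",
         ncol(object$centers))
  as.vector(gauss_basis(z, object$centers, object$bandwidth) %*% object$a)
}

#' Cross-validated bandwidth selection for KLIEP
#'
#' Splits both samples into folds. For each candidate width the model is
#' fitted on the training folds and scored on the held-out folds by the
#' held-out objective with a held-out normalizer,
#' \deqn{\tilde J = \mathrm{mean}\,\log \hat w(z^{num}_{te}) -
#'   \log\,\mathrm{mean}\,\hat w(z^{den}_{te}).}
#' Renormalizing on unseen denominator samples matters: a spiky, overfitted
#' ratio has a high-variance denominator mean whose log is Jensen-penalized,
#' so widths that merely concentrate mass near the training numerator points
#' lose to widths that generalize. Selection follows the one-standard-error
#' rule: among candidates whose average score is within one standard error
#' of the best, the largest (smoothest) bandwidth wins — overfitted widths
#' score erratically across folds and are discarded by their own variance.
#'
#' @param z_num,z_den numerator / denominator samples.
#' @param candidates numeric vector of candidate bandwidths.
#' @param folds number of cross-validation folds (>= 2 when more than one
#'   candidate is supplied).
#' @param k basis count passed to [fit_kliep()].
#' @param seed integer seed (fold assignment and center subsampling).
#' @return The selected bandwidth (scalar).
#' @export
select_bandwidth <- function(z_num, z_den, candidates, folds = 5, k = NULL, seed = 1L) {
  z_num <- as.matrix(z_num)
  z_den <- as.matrix(z_den)
  if (length(candidates) < 1) stop("need at least one candidate")
  if (length(candidates) == 1) return(candidates[[1]])
  M <- nrow(z_num)
  if (folds < 2) stop("folds must be >= 2")
  if (folds > M) stop("folds (", folds, ") exceeds the sample count (", M, ")")
  fold_num <- with_seed(seed, sample(rep(seq_len(folds), length.out = M)))
  fold_den <- with_seed(seed + 1L, sample(rep(seq_len(folds), length.out = nrow(z_den))))
  fold_scores <- vapply(candidates, function(bw) {
    vapply(seq_len(folds), function(f) {
      tr <- z_num[fold_num != f, , drop = FALSE]
      fit <- tryCatch(
        fit_kliep(tr, z_den[fold_den != f, , drop = FALSE],
                  k = if (is.null(k)) min(100L, nrow(tr)) else k,
                  bandwidth = bw, seed = seed),
        error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      w_num <- predict(fit, z_num[fold_num == f, , drop = FALSE])
      w_den <- predict(fit, z_den[fold_den == f, , drop = FALSE])
      if (any(w_num <= 0) || mean(w_den) <= 0) return(-Inf)
      mean(log(w_num)) - log(mean(w_den))
    }, 0)
  }, numeric(folds))
  score <- colMeans(fold_scores)
  if (all(!is.finite(score))) stop("no candidate bandwidth produced a valid fit")
  best <- which.max(score)
  se_best <- stats::sd(fold_scores[, best]) / sqrt(folds)
  ok <- is.finite(score) & score >= score[best] - se_best
  max(candidates[ok])
}
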