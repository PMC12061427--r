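#' Reconstruction MSE and permutation-null accuracy
#'
#' `mse` is the mean squared Euclidean distance between predicted and true
#' positions. `accuracy` rescales it against a random-assignment null:
#' \deqn{\mathrm{accuracy} = \max(0,\; 1 - \mathrm{MSE}/\mathrm{MSE}_{null}),}
#' where the null is the average MSE over `n_null` random row permutations of
#' the truth. An exact reconstruction scores 1; a random guess scores about 0.
#'
#' @param pred,truth aligned m x 2 coordinate matrices (m >= 2).
#' @param n_null number of null permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @return List with `mse`, `accuracy`, `mse_null`.
#' @export
mse_accuracy <- function(pred, truth, n_null = 200, seed = 1L) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  stopifnot(ncol(pred) == 2, ncol(truth) == 2)
  if (nrow(pred) != nrow(truth)) stop("pred and truth must be aligned")
  m <- nrow(pred)
  if (m < 2) stop("need at least 2 points")
  if (n_null < 100) stop("n_null must be >= 100")
  mse <- mean(rowSums((pred - truth)^2))
  null <- with_seed(seed, vapply(seq_len(n_null), function(i) {
    mean(rowSums((pred - truth[sample.int(m), , drop = FALSE])^2))
  }, 0))
  mse_null <- mean(null)
  accuracy <- if (mse == 0) 1 else max(0, 1 - mse / mse_null)
  list(mse = mse, accuracy = accuracy, mse_null = mse_null)
}

#' Per-layer reconstruction indicators
#'
#' Four bounded-in-\[0,1\] indicators comparing a predicted arrangement with
#' the truth per label class (layer), each equal to 1 at perfect
#' reconstruction:
#' * `S_C` — intra-layer similarity: mean fraction of each cell's k nearest
#'   predicted neighbors sharing its label.
#' * `rho_C` — density overlap: \eqn{1 - \frac12\sum|\hat p - p|} between
#'   2-D histograms (`bins` x `bins` over the pooled bounding box) of the
#'   predicted and true positions of the layer.
#' * `A_C` — aggregative volume: min/max ratio of the convex-hull areas of
#'   predicted vs true layer positions.
#' * `P_C` — aggregative perimeter: the same ratio for hull perimeters.
#'
#' Layers with fewer than 3 cells (degenerate hull) are reported as `NA` and
#' excluded from the means.
#'
#' @param pred,truth aligned m x 2 coordinate matrices.
#' @param labels per-cell layer labels (>= 2 classes).
#' @param k neighbor count for `S_C` (default 30).
#' @param bins histogram resolution per axis for `rho_C` (default 20).
#' @return Data frame with one row per layer plus a `"mean"` row, columns
#'   `layer, n, S_C, rho_C, A_C, P_C`.
#' @export
layer_indicators <- function(pred, truth, labels, k = 30, bins = 20) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  labels <- as.character(labels)
  stopifnot(nrow(pred) == nrow(truth), length(labels) == nrow(pred))
  layers <- sort(unique(labels))
  if (length(layers) < 2) stop("need at least 2 label classes")
  m <- nrow(pred)
  if (k >= m) stop("k must be smaller than the cell count")

  nn <- knn_indices(pred, k)
  sc_cell <- vapply(seq_len(m), function(i) mean(labels[nn[i, ]] == labels[i]), 0)

  rng_x <- range(c(pred[, 1], truth[, 1]))
  rng_y <- range(c(pred[, 2], truth[, 2]))
  brk <- function(r, n) if (diff(r) == 0) c(r[1] - 0.5, r[1] + 0.5) else
    seq(r[1], r[2], length.out = n + 1)
  bx <- brk(rng_x, bins); by <- brk(rng_y, bins)
  hist2 <- function(xy) {
    ix <- pmin(pmax(findInterval(xy[, 1], bx, rightmost.closed = TRUE), 1L), length(bx) - 1L)
    iy <- pmin(pmax(findInterval(xy[, 2], by, rightmost.closed = TRUE), 1L), length(by) - 1L)
    h <- table(factor(ix, seq_len(length(bx) - 1L)), factor(iy, seq_len(length(by) - 1L)))
    h / sum(h)
  }

  rows <- lapply(layers, function(lay) {
    idx <- labels == lay
    n_l <- sum(idx)
    if (n_l < 3)
      return(data.frame(layer = lay, n = n_l, S_C = NA_real_, rho_C = NA_real_,
                        A_C = NA_real_, P_C = NA_real_))
    S <- mean(sc_cell[idx])
    rho <- 1 - sum(abs(hist2(pred[idx, , drop = FALSE]) -
                         hist2(truth[idx, , drop = FALSE]))) / 2
    hp <- hull_measures(pred[idx, , drop = FALSE])
    ht <- hull_measures(truth[idx, , drop = FALSE])
    ratio <- function(a, b) if (max(a, b) == 0) 1 else min(a, b) / max(a, b)
    data.frame(layer = lay, n = n_l, S_C = S, rho_C = rho,
               A_C = ratio(hp["area"], ht["area"]),
               P_C = ratio(hp["perimeter"], ht["perimeter"]))
  })
  out <- do.call(rbind, rows)
  means <- colMeans(out[, c("S_C", "rho_C", "A_C", "P_C")], na.rm = TRUE)
  rbind(out, data.frame(layer = "mean", n = sum(out$n),
                        S_C = means["S_C"], rho_C = means["rho_C"],
                        A_C = means["A_C"], P_C = means["P_C"],
                        row.names = NULL))
}

#' Moran's I spatial autocorrelation
#'
#' Standard global Moran's I with row-normalized k-nearest-neighbor weights:
#' \deqn{I = \frac{m}{\sum_{ij} w_{ij}} \cdot
#'   \frac{\sum_{ij} w_{ij}(v_i - \bar v)(v_j - \bar v)}{\sum_i (v_i - \bar v)^2}.}
#'
#' @param values per-sample numeric vector (non-constant).
#' @param coords m x 2 coordinate matrix (m >= 10).
#' @param k_neighbors neighbors per point (default 6).
#' @return Moran's I (scalar, approximately in \[-1, 1\]).
#' @export
morans_i <- function(values, coords, k_neighbors = 6) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (m < 10) stop("need at least 10 samples")
  if (length(values) != m) stop("values length does not match coords")
  v <- values - mean(values)
  if (all(v == 0)) stop("Moran's I is undefined for constant values")
  nn <- knn_indices(coords, k_neighbors)
  wsum <- m                                   # row-normalized: each row sums to 1
  num <- sum(vapply(seq_len(m), function(i) v[i] * mean(v[nn[i, ]]), 0))
  (m / wsum) * num / sum(v^2)
}

#' Full reconstruction report
#'
#' Convenience wrapper combining [mse_accuracy()] and, when labels are given,
#' [layer_indicators()].
#'
#' @inheritParams mse_accuracy
#' @inheritParams layer_indicators
#' @param labels optional per-cell labels.
#' @return List with `mse`, `accuracy`, `mse_null` and (optionally) `layers`.
#' @export
eval_report <- function(pred, truth, labels = NULL, n_null = 200, k = 30,
                        bins = 20, seed = 1L) {
  out <- mse_accuracy(pred, truth, n_null = n_null, seed = seed)
  if (!is.null(labels))
    out$layers <- layer_indicators(pred, truth, labels, k = k, bins = bins)
  out
}
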