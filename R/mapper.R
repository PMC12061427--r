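#' Estimate per-slice reference weights
#'
#' With several reference slices, a single density-ratio model is fitted with
#' the single-cell embedding as numerator and the pooled spots of all slices
#' as denominator; each slice's weight is proportional to the mean estimated
#' ratio over its own spots, normalized to sum to one. A slice resembling the
#' single-cell population therefore receives more weight than a shifted one.
#'
#' @param z_sc single-cell embedding, M x K matrix.
#' @param slice_embeddings list of m_s x K matrices (one per slice).
#' @param k,bandwidth,seed passed to [fit_kliep()].
#' @return Numeric vector of non-negative slice weights summing to 1.
#' @export
estimate_slice_weights <- function(z_sc, slice_embeddings, k = NULL,
                                   bandwidth = NULL, seed = 1L) {
  if (is.matrix(slice_embeddings)) slice_embeddings <- list(slice_embeddings)
  n_s <- length(slice_embeddings)
  stopifnot(n_s >= 1)
  if (n_s == 1) return(1)
  pooled <- do.call(rbind, slice_embeddings)
  fit <- fit_kliep(z_sc, pooled, k = k, bandwidth = bandwidth, seed = seed)
  means <- vapply(slice_embeddings, function(z) mean(predict(fit, z)), 0)
  if (sum(means) <= 0) stop("slice weight estimation degenerated (all ratios zero)")
  means / sum(means)
}

scale_coords <- function(coords) {
  mins <- apply(coords, 2, min)
  ranges <- apply(coords, 2, max) - mins
  if (any(ranges <= 0)) stop("degenerate coordinate range (zero extent)")
  list(scaled = sweep(sweep(coords, 2, mins), 2, ranges, "/"),
       scaler = list(min = mins, range = ranges))
}

unscale_coords <- function(coords, scaler) {
  sweep(sweep(coords, 2, scaler$range, "*"), 2, scaler$min, "+")
}

#' Fit the expression-to-coordinate neural mapper
#'
#' Minimizes the density-ratio-weighted mean squared error over the reference
#' spots,
#' \deqn{\sum_s u_s \frac{1}{m_s} \sum_j w_{js}\,\|g(z_{js}) - y_{js}\|^2 + \Omega(g),}
#' where \eqn{w_{js}} are per-spot KLIEP ratios, \eqn{u_s} per-slice weights,
#' and \eqn{\Omega} an L2 weight-decay penalty, with a ReLU multi-layer
#' perceptron for g. Coordinates are min-max scaled to the unit square per
#' slice before training (so slices with different physical frames combine
#' coherently) and mapped back at prediction.
#'
#' @param slices a `spatial_slice` (scaled expression) or list of them.
#' @param coembed a fitted `coembed_model` shared by all slices.
#' @param ratios per-spot density-ratio weights: a numeric vector (single
#'   slice) or list of vectors matching `slices`; default all-ones (plain
#'   MSE regression). Weights are clipped at `clip_quantile` before use.
#' @param slice_weights per-slice weights (default: estimated when several
#'   slices are given and `z_sc` is supplied, else uniform).
#' @param z_sc optional single-cell embedding used to estimate slice weights.
#' @param hidden hidden-layer widths of g.
#' @param dropout,lr,weight_decay,max_epochs,patience optimizer settings.
#' @param input_noise train-time input jitter as a fraction of each
#'   feature's sd (0 disables). Gaussian input noise acts as a Tikhonov
#'   penalty on the input gradients of the fitted map.
#' @param clip_quantile upper quantile at which spot weights are clipped
#'   (bounds the variance of the importance-weighted loss).
#' @param inverse_frame index of the slice whose physical frame predictions
#'   are returned in (default 1).
#' @param seed integer seed controlling initialization, batching and splits.
#' @return A `mapper_model` (network, coordinate scaler, slice weights,
#'   training log).
#' @export
fit_mapper <- function(slices, coembed, ratios = NULL, slice_weights = NULL,
                       z_sc = NULL, hidden = c(256L, 64L), dropout = 0.2,
                       lr = 1e-3, weight_decay = 1e-4, max_epochs = 1000L,
                       patience = 50L, input_noise = 0.2, clip_quantile = 0.995,
                       inverse_frame = 1L, seed = 1L) {
  if (inherits(slices, "spatial_slice")) slices <- list(slices)
  n_s <- length(slices)
  stopifnot(n_s >= 1, inherits(coembed, "coembed_model"))
  for (sl in slices) if (nrow(sl$expr) == 0) stop("empty slice: ", sl$slice_id)
  if (is.null(ratios)) ratios <- lapply(slices, function(sl) rep(1, nrow(sl$expr)))
  if (is.numeric(ratios)) ratios <- list(ratios)
  stopifnot(length(ratios) == n_s)

  emb <- lapply(slices, function(sl) embed_cells(coembed, sl$expr))
  if (is.null(slice_weights)) {
    slice_weights <- if (n_s == 1 || is.null(z_sc)) rep(1 / n_s, n_s)
      else estimate_slice_weights(z_sc, emb, seed = seed)
  }
  stopifnot(length(slice_weights) == n_s, all(slice_weights >= 0))
  slice_weights <- slice_weights / sum(slice_weights)

  Z <- NULL; Y <- NULL; w <- NULL
  scalers <- vector("list", n_s)
  for (s in seq_len(n_s)) {
    sc <- scale_coords(slices[[s]]$coords)
    scalers[[s]] <- sc$scaler
    ws <- ratios[[s]]
    if (length(ws) != nrow(slices[[s]]$expr))
      stop("ratio length mismatch for slice ", slices[[s]]$slice_id)
    if (any(ws < 0)) stop("negative spot weights for slice ", slices[[s]]$slice_id)
    cap <- stats::quantile(ws, clip_quantile, names = FALSE)
    ws <- pmin(ws, cap)
    # per-slice mean normalization, then the slice weight: u_s * w_js / m_s
    ws <- slice_weights[s] * ws / sum(ws)
    Z <- rbind(Z, emb[[s]])
    Y <- rbind(Y, sc$scaled)
    w <- c(w, ws)
  }
  fit <- mlp_train(Z, Y, w = w, hidden = hidden, dropout = dropout, lr = lr,
                   weight_decay = weight_decay, max_epochs = max_epochs,
                   patience = patience, input_noise = input_noise, seed = seed)
  structure(list(coembed = coembed, net = fit$net, hidden = hidden,
                 dropout = dropout,
                 coord_scaler = scalers[[inverse_frame]], scalers = scalers,
                 slice_weights = slice_weights, train_log = fit$train_log,
                 val_loss = fit$val_loss, seed = seed,
                 clamp = TRUE, clamp_margin = 0.05),
            class = "mapper_model")
}

#' @export
print.mapper_model <- function(x, ...) {
  cat(sprintf(
    "mapper_model: K = %d -> (%s) -> 2; %d epochs, final weighted loss %.4g\n",
    x$coembed$K, paste(x$hidden, collapse = ", "),
    length(x$train_log) - 2L, x$train_log[length(x$train_log)]))
  invisible(x)
}

#' Predict spatial locations for expression profiles
#'
#' Applies the full composition f = g(h(x)): co-embedding projection, neural
#' regression on the unit square, then the inverse coordinate scaling into
#' the reference slice's physical frame. Dropout is disabled at inference.
#' Trained mappers confine predictions to the reference frame (a 5% margin
#' around the training coordinate box): positions outside the slice are
#' extrapolation artifacts of inputs far from the training distribution,
#' e.g. heavy in-silico knockouts. The [linear_mapper()] diagnostic is
#' unbounded so closed-form checks hold exactly.
#'
#' @param model a `mapper_model`.
#' @param gm a `gene_matrix` with `stage = "scaled"` covering the model genes.
#' @return m x 2 matrix of predicted (x, y), rownames = cell ids.
#' @export
predict_locations <- function(model, gm) {
  stopifnot(inherits(model, "mapper_model"), inherits(gm, "gene_matrix"))
  if (gm_stage(gm) != "scaled")
    stop("predict_locations expects scaled expression (stage = 'scaled')")
  z <- embed_cells(model$coembed, gm)
  y <- mlp_forward(model$net, z)$out
  if (isTRUE(model$clamp)) {
    mg <- model$clamp_margin
    y <- pmin(pmax(y, -mg), 1 + mg)
  }
  y <- unscale_coords(y, model$coord_scaler)
  if (!all(is.finite(y))) stop("non-finite predicted coordinates")
  dimnames(y) <- list(rownames(gm), c("x", "y"))
  y
}
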