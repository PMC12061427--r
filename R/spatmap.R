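#' Fit a spatial reconstruction model
#'
#' End-to-end fit of the expression-to-coordinate transfer model. One or more
#' spatial reference slices and a single-cell query are preprocessed
#' (library-size log-normalization, per-dataset z-scoring, highly variable
#' gene selection and intersection), co-embedded through a reference-fitted
#' principal-axes basis, the covariate shift between query and reference is
#' estimated per slice by KLIEP density ratios, and a neural regressor is
#' trained on the ratio-weighted reference spots. The result predicts tissue
#' coordinates for any cell with matching genes.
#'
#' @param st a `spatial_slice` or list of them (the spatial reference(s)).
#' @param sc a `gene_matrix`: the single-cell query expression.
#' @param normalize apply [lognormalize()] to raw inputs first (set `FALSE`
#'   when the expression is already on a normalized continuous scale, e.g.
#'   the toy simulator output).
#' @param scale apply per-dataset z-scoring. Keep the default for count
#'   data; set `FALSE` for simulated continuous expression whose generative
#'   scale is meaningful (the ten-gene toy tissue), where equalizing gene
#'   variances would distort the gradient-based gene scores.
#' @param s library-size scaling factor for normalization.
#' @param n_hvg number of highly variable genes selected per dataset before
#'   intersecting; `NULL` uses all common genes.
#' @param K co-embedding dimension (default `min(50, H, m - 1)`).
#' @param kliep_k,bandwidth KLIEP basis count and kernel width (defaults:
#'   `min(100, M)` bases and cross-validated width, see [fit_kliep()]).
#' @param hidden,dropout,lr,weight_decay,max_epochs,patience,input_noise,clip_quantile
#'   mapper settings, see [fit_mapper()].
#' @param seed single integer seed controlling subsampling, initialization,
#'   batching and splits.
#' @return An object of class `spatmap` with components `mapper`, `coembed`,
#'   `kliep` (per-slice models), `ratios` (per-spot weights), `slice_weights`,
#'   `prep_sc`, `prep_st`, `genes`, and the scaled query `sc_scaled`.
#' @seealso [predict.spatmap()], [sog_index()], [spa_rna_velocity()],
#'   [knockout_predict()]
#' @examples
#' toy <- simulate_toy(n = 200, seed = 1)
#' fit <- spatmap(spatial_slice(toy$X, toy$coords), toy$X,
#'                normalize = FALSE, scale = FALSE, max_epochs = 50, seed = 1)
#' head(predict(fit))
#' @export
spatmap <- function(st, sc, normalize = TRUE, scale = TRUE, s = 10000, n_hvg = 2000,
                    K = NULL, kliep_k = NULL, bandwidth = NULL,
                    hidden = c(256L, 64L), dropout = 0.2, lr = 1e-3,
                    weight_decay = 1e-4, max_epochs = 1000L, patience = 50L,
                    input_noise = 0.2, clip_quantile = 0.995, seed = 1L) {
  if (inherits(st, "spatial_slice")) st <- list(st)
  stopifnot(length(st) >= 1, inherits(sc, "gene_matrix"))
  cl <- match.call()

  norm_one <- function(gm) {
    if (normalize) {
      if (gm_stage(gm) != "raw") stop("normalize = TRUE expects raw counts")
      lognormalize(gm, s = s)
    } else {
      if (gm_stage(gm) == "raw") stop("normalize = FALSE expects normalized input")
      gm
    }
  }
  sc_ln <- norm_one(sc)
  st_ln <- lapply(st, function(sl) norm_one(sl$expr))

  # HVG per dataset, then the common subset (ordered by the query list)
  if (is.null(n_hvg)) {
    lists <- c(list(colnames(sc_ln)), lapply(st_ln, colnames))
  } else {
    lists <- c(list(select_hvgs(sc_ln, min(n_hvg, ncol(sc_ln)))),
               lapply(st_ln, function(g) select_hvgs(g, min(n_hvg, ncol(g)))))
  }
  genes <- intersect_genes(lists)
  if (length(genes) < 2) stop("fewer than 2 common genes after selection")

  subset_gm <- function(gm) gene_matrix(gm_values(gm)[, genes, drop = FALSE],
                                        rownames(gm), genes, stage = gm_stage(gm))
  sc_ln <- subset_gm(sc_ln)
  st_ln <- lapply(st_ln, subset_gm)

  if (scale) {
    # drop genes that are zero-variance in any dataset, then z-score per dataset
    variable <- function(gm) {
      x <- gm_values(gm)
      colnames(x)[colMeans(sweep(x, 2, colMeans(x))^2) > 0]
    }
    genes <- Reduce(intersect, c(list(variable(sc_ln)), lapply(st_ln, variable)))
    if (length(genes) < 2) stop("fewer than 2 informative common genes")
    sc_ln <- subset_gm(sc_ln)
    st_ln <- lapply(st_ln, subset_gm)
  }

  identity_prep <- function() structure(
    list(mu = stats::setNames(rep(0, length(genes)), genes),
         sigma = stats::setNames(rep(1, length(genes)), genes),
         dropped = character(0), genes = genes, s = s),
    class = "preprocess_model")
  scale_one <- function(gm) {
    if (scale) zscore_scale(gm, s = s)
    else list(scaled = gene_matrix(gm_values(gm), rownames(gm), genes,
                                   stage = "scaled"),
              model = identity_prep())
  }

  zs <- scale_one(sc_ln)
  prep_sc <- zs$model
  sc_scaled <- zs$scaled
  prep_st <- vector("list", length(st))
  st_scaled <- vector("list", length(st))
  for (i in seq_along(st)) {
    zi <- scale_one(st_ln[[i]])
    prep_st[[i]] <- zi$model
    st_scaled[[i]] <- spatial_slice(zi$scaled, st[[i]]$coords,
                                    labels = st[[i]]$labels,
                                    slice_id = st[[i]]$slice_id)
  }

  coembed <- fit_coembed(st_scaled, K = K)
  z_sc <- embed_cells(coembed, sc_scaled)
  z_st <- lapply(st_scaled, function(sl) embed_cells(coembed, sl$expr))

  kliep <- vector("list", length(st))
  ratios <- vector("list", length(st))
  for (i in seq_along(st)) {
    kliep[[i]] <- tryCatch(
      fit_kliep(z_sc, z_st[[i]], k = kliep_k, bandwidth = bandwidth,
                seed = seed + i),
      error = function(e) stop("KLIEP fit failed for slice '",
                               st[[i]]$slice_id, "': ", conditionMessage(e)))
    ratios[[i]] <- predict(kliep[[i]], z_st[[i]])
  }
  slice_weights <- if (length(st) == 1) 1 else
    estimate_slice_weights(z_sc, z_st, k = kliep_k, bandwidth = bandwidth,
                           seed = seed)

  mapper <- fit_mapper(st_scaled, coembed, ratios = ratios,
                       slice_weights = slice_weights, hidden = hidden,
                       dropout = dropout, lr = lr, weight_decay = weight_decay,
                       max_epochs = max_epochs, patience = patience,
                       input_noise = input_noise,
                       clip_quantile = clip_quantile, seed = seed)

  structure(list(mapper = mapper, coembed = coembed, kliep = kliep,
                 ratios = ratios, slice_weights = slice_weights,
                 prep_sc = prep_sc, prep_st = prep_st, genes = genes,
                 sc_scaled = sc_scaled, st_scaled = st_scaled,
                 normalize = normalize, scale = scale, s = s, seed = seed,
                 call = cl),
            class = "spatmap")
}

prepare_query <- function(object, gm) {
  if (gm_stage(gm) == "scaled") return(gm)
  if (gm_stage(gm) == "raw") {
    if (!object$normalize)
      stop("model was fitted on pre-normalized data; supply normalized input")
    gm <- lognormalize(gm, s = object$s)
  }
  gm <- gene_matrix(gm_values(gm)[, object$genes, drop = FALSE],
                    rownames(gm), object$genes, stage = gm_stage(gm))
  zscore_scale(gm, model = object$prep_sc)$scaled
}

#' Predict tissue coordinates for single cells
#'
#' @param object a fitted `spatmap` model.
#' @param newdata a `gene_matrix` (raw, lognorm or scaled); default: the
#'   training single-cell query.
#' @param ... unused.
#' @return m x 2 matrix of predicted coordinates.
#' @export
predict.spatmap <- function(object, newdata = NULL, ...) {
  gm <- if (is.null(newdata)) object$sc_scaled else prepare_query(object, newdata)
  predict_locations(object$mapper, gm)
}

#' @export
fitted.spatmap <- function(object, ...) predict(object)

#' Training-reference residuals
#'
#' Residuals of the fitted map on the reference spots: predicted minus true
#' spot coordinates (first slice by default).
#'
#' @param object a `spatmap` model.
#' @param slice which reference slice (index).
#' @param ... unused.
#' @return m x 2 matrix of coordinate residuals.
#' @export
residuals.spatmap <- function(object, slice = 1L, ...) {
  sl <- object$st_scaled[[slice]]
  predict_locations(object$mapper, sl$expr) - sl$coords
}

#' @export
print.spatmap <- function(x, ...) {
  cat("Spatial reconstruction model (density-ratio-weighted neural mapping)\n")
  cat(sprintf("  reference: %d slice(s), %s spots; query: %d cells; %d genes\n",
              length(x$st_scaled),
              paste(vapply(x$st_scaled, function(s) nrow(s$expr), 0L), collapse = "+"),
              nrow(x$sc_scaled), length(x$genes)))
  cat(sprintf("  co-embedding K = %d; slice weights: %s\n", x$coembed$K,
              paste(sprintf("%.3f", x$slice_weights), collapse = ", ")))
  cat(sprintf("  final weighted training loss: %.4g\n",
              x$mapper$train_log[length(x$mapper$train_log)]))
  invisible(x)
}

#' @export
summary.spatmap <- function(object, ...) {
  w <- unlist(object$ratios)
  out <- list(
    n_slices = length(object$st_scaled),
    n_spots = vapply(object$st_scaled, function(s) nrow(s$expr), 0L),
    n_cells = nrow(object$sc_scaled),
    n_genes = length(object$genes),
    K = object$coembed$K,
    slice_weights = object$slice_weights,
    ratio_summary = stats::quantile(w, c(0, 0.25, 0.5, 0.75, 1)),
    kliep_J = vapply(object$kliep, function(k) k$fit_log[length(k$fit_log)], 0),
    train_loss = object$mapper$train_log[length(object$mapper$train_log)],
    val_loss = object$mapper$val_loss)
  class(out) <- "summary.spatmap"
  out
}

#' @export
print.summary.spatmap <- function(x, ...) {
  cat("Spatial reconstruction model summary\n")
  cat(sprintf("  %d reference slice(s) (%s spots), %d query cells, %d genes, K = %d\n",
              x$n_slices, paste(x$n_spots, collapse = "+"), x$n_cells,
              x$n_genes, x$K))
  cat(sprintf("  slice weights: %s\n", paste(sprintf("%.3f", x$slice_weights), collapse = ", ")))
  cat(sprintf("  KLIEP objective J per slice: %s\n",
              paste(sprintf("%.4g", x$kliep_J), collapse = ", ")))
  cat("  density-ratio weights (min/Q1/median/Q3/max): ",
      paste(sprintf("%.3g", x$ratio_summary), collapse = " / "), "\n", sep = "")
  cat(sprintf("  weighted training loss %.4g, validation loss %.4g\n",
              x$train_loss, x$val_loss))
  invisible(x)
}

#' Plot a fitted spatial reconstruction
#'
#' Scatter of the predicted single-cell positions, optionally next to the
#' reference spots.
#'
#' @param x a `spatmap` model.
#' @param labels optional per-cell labels used for point colors.
#' @param reference also draw the first reference slice.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spatmap <- function(x, labels = NULL, reference = TRUE, ...) {
  pred <- predict(x)
  op <- graphics::par(mfrow = c(1, if (reference) 2 else 1))
  on.exit(graphics::par(op))
  col <- if (is.null(labels)) "steelblue" else as.integer(factor(labels)) + 1L
  graphics::plot(pred, col = col, pch = 16, cex = 0.5,
                 xlab = "x", ylab = "y", main = "predicted cells", ...)
  if (reference) {
    sl <- x$st_scaled[[1]]
    rcol <- if (is.null(sl$labels)) "grey40" else as.integer(factor(sl$labels)) + 1L
    graphics::plot(sl$coords, col = rcol, pch = 16, cex = 0.5,
                   xlab = "x", ylab = "y", main = "reference spots", ...)
  }
  invisible(x)
}
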