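#' Spatial-organizing-gene (SOG) index
#'
#' Scores each gene g by the mean absolute sensitivity of the fitted
#' expression-to-coordinate map f to that gene,
#' \deqn{I_g = \mathrm{E}\left\{\tfrac12 \sum_{p=1}^{2}
#'   \left|\partial y_p / \partial x_g\right|\right\},}
#' the expectation taken as the arithmetic mean over the supplied cells.
#' Gradients are taken through the full composition (co-embedding, network,
#' coordinate unscaling). `"autodiff"` uses the exact reverse-mode Jacobian
#' of the network; `"finite_diff"` uses central differences with step `eps`
#' and serves as an independent numerical check.
#'
#' @param model a `mapper_model`.
#' @param gm a `gene_matrix` with `stage = "scaled"` matching the model genes.
#' @param method `"autodiff"` or `"finite_diff"`.
#' @param eps central-difference step (scaled-expression units).
#' @return A `sog_result`: data frame with columns `gene`, `I`, `rank`
#'   (descending I, ties broken by gene id).
#' @export
sog_index <- function(model, gm, method = c("autodiff", "finite_diff"), eps = 1e-4) {
  method <- match.arg(method)
  stopifnot(inherits(model, "mapper_model"), inherits(gm, "gene_matrix"))
  if (gm_stage(gm) != "scaled") stop("sog_index expects scaled expression")
  genes <- model$coembed$gene_ids
  missing <- setdiff(genes, colnames(gm))
  if (length(missing)) stop("missing model genes: ", paste(missing, collapse = ", "))
  x <- gm_values(gm)[, genes, drop = FALSE]
  ranges <- model$coord_scaler$range

  if (method == "autodiff") {
    z <- x %*% model$coembed$loadings
    J <- mlp_jacobian(model$net, z)            # list of m x K, per output dim
    yhat <- mlp_forward(model$net, z)$out
    acc <- 0
    for (p in 1:2) {
      Gp <- J[[p]] %*% t(model$coembed$loadings) * ranges[p]   # m x H
      if (isTRUE(model$clamp)) {
        mg <- model$clamp_margin               # zero gradient where output saturates
        Gp <- Gp * as.numeric(yhat[, p] >= -mg & yhat[, p] <= 1 + mg)
      }
      if (!all(is.finite(Gp))) {
        bad <- which(!is.finite(Gp), arr.ind = TRUE)[1, ]
        stop("non-finite gradient for cell ", rownames(gm)[bad[1]],
             ", gene ", genes[bad[2]])
      }
      acc <- acc + colMeans(abs(Gp))
    }
    I <- acc / 2
  } else {
    I <- numeric(length(genes))
    for (gi in seq_along(genes)) {
      xp <- x; xp[, gi] <- xp[, gi] + eps
      xm <- x; xm[, gi] <- xm[, gi] - eps
      fp <- predict_locations(model, gene_matrix(xp, rownames(gm), genes, stage = "scaled"))
      fm <- predict_locations(model, gene_matrix(xm, rownames(gm), genes, stage = "scaled"))
      d <- (fp - fm) / (2 * eps)
      if (!all(is.finite(d)))
        stop("non-finite finite-difference gradient for gene ", genes[gi])
      I[gi] <- mean((abs(d[, 1]) + abs(d[, 2])) / 2)
    }
  }
  names(I) <- genes
  ord <- order(-I, genes)
  out <- data.frame(gene = genes[ord], I = unname(I[ord]),
                    rank = seq_along(genes), stringsAsFactors = FALSE)
  class(out) <- c("sog_result", "data.frame")
  out
}

#' In-silico gene knockout
#'
#' Sets the selected genes to the scaled value a zero raw count maps to under
#' the stored preprocessing, i.e. \eqn{(0 - \mu_g)/\sigma_g}, and re-predicts
#' cell locations with the unchanged model (default). With `refit = TRUE`
#' the mapper is retrained on reference slices carrying the same masking
#' before predicting.
#'
#' @param model a `mapper_model`.
#' @param prep the `preprocess_model` whose \eqn{\mu, \sigma} defined the
#'   scaling of `gm`.
#' @param gm scaled `gene_matrix` to predict for.
#' @param genes character vector of gene ids to knock out (may be empty).
#' @param refit retrain the mapper on masked references instead of masking
#'   the query only.
#' @param slices,ratios reference slices (scaled) and per-spot weights,
#'   required when `refit = TRUE`.
#' @return m x 2 matrix of predicted coordinates after knockout.
#' @export
knockout_predict <- function(model, prep, gm, genes, refit = FALSE,
                             slices = NULL, ratios = NULL) {
  stopifnot(inherits(model, "mapper_model"), inherits(prep, "preprocess_model"),
            inherits(gm, "gene_matrix"))
  genes <- as.character(genes)
  unknown <- setdiff(genes, colnames(gm))
  if (length(unknown)) stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(genes, prep$genes)
  if (length(unknown))
    stop("gene(s) absent from the preprocessing model: ", paste(unknown, collapse = ", "))
  ko_value <- (0 - prep$mu[genes]) / prep$sigma[genes]
  mask <- function(g) {
    x <- gm_values(g)
    for (i in seq_along(genes)) x[, genes[i]] <- ko_value[i]
    gm_replace(g, x)
  }
  gm2 <- mask(gm)
  if (refit) {
    if (is.null(slices)) stop("refit = TRUE requires the reference slices")
    if (inherits(slices, "spatial_slice")) slices <- list(slices)
    slices <- lapply(slices, function(sl) {
      spatial_slice(mask(sl$expr), sl$coords, sl$labels, sl$slice_id)
    })
    model <- fit_mapper(slices, model$coembed, ratios = ratios,
                        slice_weights = model$slice_weights,
                        hidden = model$hidden, dropout = model$dropout,
                        seed = model$seed)
  }
  predict_locations(model, gm2)
}

#' Project RNA velocity onto tissue coordinates
#'
#' Computes the spatial velocity of each cell as the displacement of its
#' predicted position induced by one RNA-velocity step in gene space:
#' \deqn{v_{st} = f(x + v_{RNA}) - f(x).}
#' `v_rna` must live in the same preprocessed (scaled) gene space as `gm`;
#' for velocities exported in the log-normalized space by external tools,
#' pass `sigma` (the per-gene sd of the preprocessing model) and each column
#' is divided by it first.
#'
#' @param model a `mapper_model`.
#' @param gm scaled `gene_matrix` (cells x genes).
#' @param v_rna m x H velocity matrix aligned with `gm` rows and model genes.
#' @param sigma optional named per-gene sd for the raw-to-scaled adapter.
#' @return A `velocity_field`: list with `positions` (f(x)), `v_st`,
#'   `v_rna` and `cell_ids`.
#' @export
spa_rna_velocity <- function(model, gm, v_rna, sigma = NULL) {
  stopifnot(inherits(model, "mapper_model"), inherits(gm, "gene_matrix"))
  v_rna <- as.matrix(v_rna)
  genes <- model$coembed$gene_ids
  if (is.null(colnames(v_rna))) {
    if (ncol(v_rna) != length(genes)) stop("v_rna gene dimension mismatch")
    colnames(v_rna) <- genes
  }
  if (!all(genes %in% colnames(v_rna))) stop("v_rna missing model genes")
  v_rna <- v_rna[, genes, drop = FALSE]
  if (nrow(v_rna) != nrow(gm)) stop("v_rna row count does not match cells")
  if (!is.null(sigma)) {
    if (is.null(names(sigma))) names(sigma) <- genes
    v_rna <- sweep(v_rna, 2, sigma[genes], "/")
  }
  x <- gm_values(gm)[, genes, drop = FALSE]
  pos <- predict_locations(model, gene_matrix(x, rownames(gm), genes, stage = "scaled"))
  moved <- predict_locations(model, gene_matrix(x + v_rna, rownames(gm), genes,
                                                stage = "scaled"))
  structure(list(cell_ids = rownames(gm), positions = pos,
                 v_st = moved - pos, v_rna = v_rna),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- sqrt(rowSums(x$v_st^2))
  cat(sprintf("velocity_field: %d cells, mean spatial speed %.4g\n",
              length(x$cell_ids), mean(sp)))
  invisible(x)
}

#' Write a velocity field as CSV (`cell_id,x,y,vx,vy`)
#' @param vf a `velocity_field`.
#' @param path output CSV path.
#' @export
write_velocity <- function(vf, path) {
  utils::write.csv(data.frame(cell_id = vf$cell_ids,
                              x = vf$positions[, 1], y = vf$positions[, 2],
                              vx = vf$v_st[, 1], vy = vf$v_st[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Exactly linear mapper (diagnostic constructor)
#'
#' Builds a `mapper_model` whose f is the exact linear map y = x A' (identity
#' co-embedding, no hidden layers, identity coordinate frame). Used to verify
#' gradient-based scores and velocity projection against closed forms.
#'
#' @param A 2 x H coefficient matrix (rows = output coordinates).
#' @param gene_ids gene ids (default `gene1..geneH`).
#' @return A `mapper_model`.
#' @export
linear_mapper <- function(A, gene_ids = NULL) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == 2)
  H <- ncol(A)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(H))
  loadings <- diag(H)
  rownames(loadings) <- gene_ids
  colnames(loadings) <- paste0("PC", seq_len(H))
  coembed <- structure(list(gene_ids = gene_ids, loadings = loadings, K = H,
                            fitted_on = "linear"), class = "coembed_model")
  net <- list(W = list(t(A)), b = list(rep(0, 2)), dims = c(H, 2))
  structure(list(coembed = coembed, net = net, hidden = integer(0), dropout = 0,
                 coord_scaler = list(min = c(0, 0), range = c(1, 1)),
                 scalers = list(list(min = c(0, 0), range = c(1, 1))),
                 slice_weights = 1, train_log = c(0, 0), val_loss = 0, seed = 0L,
                 clamp = FALSE, clamp_margin = 0),
            class = "mapper_model")
}
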