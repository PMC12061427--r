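#' Fit the reference-based co-embedding
#'
#' Learns the shared latent map z = h(x): a principal-axes projection fitted
#' on the spatial reference slice(s) only. The single-cell query is later
#' projected through the identical basis, so the transfer premise — cells
#' with similar latent features have similar positions regardless of origin —
#' holds by construction. When the common gene count H does not exceed K the
#' basis degenerates to the identity on the scaled genes.
#'
#' @param references a `spatial_slice` (scaled expression) or list of them,
#'   all sharing the same gene set.
#' @param K latent dimension; default `min(50, H, m - 1)` where m is the
#'   total reference spot count.
#' @return A `coembed_model` with orthonormal `loadings` (H x K), `gene_ids`,
#'   `K` and `fitted_on` slice ids. Each loading column's largest-magnitude
#'   entry is made positive so the basis is deterministic.
#' @export
fit_coembed <- function(references, K = NULL) {
  if (inherits(references, "spatial_slice")) references <- list(references)
  stopifnot(length(references) >= 1)
  genes <- colnames(references[[1]]$expr)
  for (sl in references) {
    if (!inherits(sl, "spatial_slice")) stop("references must be spatial_slice objects")
    if (!identical(colnames(sl$expr), genes))
      stop("reference slices have mismatched gene lists")
  }
  X <- do.call(rbind, lapply(references, function(sl) gm_values(sl$expr)))
  H <- ncol(X)
  m <- nrow(X)
  if (is.null(K)) K <- min(50L, H, m - 1L)
  if (K > H) stop("K (", K, ") exceeds the common gene count H (", H, ")")
  if (K < 1) stop("K must be >= 1")
  if (H <= K) {
    loadings <- diag(H)
    K <- H
  } else {
    sv <- svd(X, nu = 0, nv = K)
    loadings <- sv$v
    # sign convention: largest-|.| entry of each column positive
    for (j in seq_len(ncol(loadings))) {
      i <- which.max(abs(loadings[, j]))
      if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
    }
  }
  rownames(loadings) <- genes
  colnames(loadings) <- paste0("PC", seq_len(K))
  structure(list(gene_ids = genes, loadings = loadings, K = K,
                 fitted_on = vapply(references, function(sl) sl$slice_id, "")),
            class = "coembed_model")
}

#' @export
print.coembed_model <- function(x, ...) {
  cat(sprintf("coembed_model: %d genes -> K = %d (fitted on %s)\n",
              length(x$gene_ids), x$K, paste(x$fitted_on, collapse = ", ")))
  invisible(x)
}

#' Project expression through a fitted co-embedding
#'
#' @param model a `coembed_model`.
#' @param gm a `gene_matrix` with `stage = "scaled"` whose genes cover the
#'   model's gene list (subset and reorder are applied).
#' @return samples x K matrix of latent coordinates with sample rownames.
#' @export
embed_cells <- function(model, gm) {
  stopifnot(inherits(model, "coembed_model"), inherits(gm, "gene_matrix"))
  missing <- setdiff(model$gene_ids, colnames(gm))
  if (length(missing))
    stop("genes required by the co-embedding are missing: ",
         paste(missing, collapse = ", "))
  x <- gm_values(gm)[, model$gene_ids, drop = FALSE]
  z <- x %*% model$loadings
  rownames(z) <- rownames(gm)
  z
}
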