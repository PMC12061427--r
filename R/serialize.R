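#' Save a fitted model as a JSON archive
#'
#' Writes everything needed to predict, score genes and project velocities
#' (preprocessing statistics, co-embedding loadings, network weights,
#' coordinate scaler, slice and spot weights) to a single plain-text JSON
#' file at full precision.
#'
#' @param object a `spatmap` model.
#' @param path output `.json` path.
#' @export
save_spatmap <- function(object, path) {
  stopifnot(inherits(object, "spatmap"))
  m <- object$mapper
  payload <- list(
    format = "spatmap-model-1",
    genes = object$genes,
    normalize = object$normalize,
    s = object$s,
    seed = object$seed,
    slice_weights = object$slice_weights,
    ratios = object$ratios,
    prep_sc = list(mu = as.list(object$prep_sc$mu),
                   sigma = as.list(object$prep_sc$sigma),
                   dropped = object$prep_sc$dropped,
                   genes = object$prep_sc$genes, s = object$prep_sc$s),
    coembed = list(gene_ids = m$coembed$gene_ids, K = m$coembed$K,
                   fitted_on = m$coembed$fitted_on,
                   loadings = m$coembed$loadings),
    mapper = list(W = m$net$W, b = m$net$b, dims = m$net$dims,
                  hidden = m$hidden, dropout = m$dropout,
                  coord_scaler = m$coord_scaler,
                  slice_weights = m$slice_weights,
                  train_log = m$train_log, val_loss = m$val_loss,
                  seed = m$seed, clamp = isTRUE(m$clamp),
                  clamp_margin = m$clamp_margin))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by [save_spatmap()]
#'
#' @param path `.json` archive path.
#' @return A `spatmap` model (prediction-capable components; training
#'   internals such as the scaled training data are not round-tripped).
#' @export
load_spatmap <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "spatmap-model-1")) stop("not a spatmap model archive")
  loadings <- matrix(unlist(p$coembed$loadings), ncol = p$coembed$K, byrow = FALSE)
  if (is.matrix(p$coembed$loadings)) loadings <- p$coembed$loadings
  rownames(loadings) <- p$coembed$gene_ids
  colnames(loadings) <- paste0("PC", seq_len(p$coembed$K))
  coembed <- structure(list(gene_ids = p$coembed$gene_ids, loadings = loadings,
                            K = p$coembed$K, fitted_on = p$coembed$fitted_on),
                       class = "coembed_model")
  W <- lapply(p$mapper$W, function(w) as.matrix(w))
  b <- lapply(p$mapper$b, as.numeric)
  scaler <- list(min = as.numeric(p$mapper$coord_scaler$min),
                 range = as.numeric(p$mapper$coord_scaler$range))
  mapper <- structure(list(coembed = coembed,
                           net = list(W = W, b = b, dims = as.integer(p$mapper$dims)),
                           hidden = as.integer(p$mapper$hidden),
                           dropout = p$mapper$dropout,
                           coord_scaler = scaler, scalers = list(scaler),
                           slice_weights = p$mapper$slice_weights,
                           train_log = p$mapper$train_log,
                           val_loss = p$mapper$val_loss,
                           seed = p$mapper$seed,
                           clamp = isTRUE(p$mapper$clamp),
                           clamp_margin = p$mapper$clamp_margin),
                      class = "mapper_model")
  mu <- unlist(p$prep_sc$mu); sigma <- unlist(p$prep_sc$sigma)
  prep_sc <- structure(list(mu = mu, sigma = sigma,
                            dropped = as.character(p$prep_sc$dropped),
                            genes = p$prep_sc$genes, s = p$prep_sc$s),
                       class = "preprocess_model")
  structure(list(mapper = mapper, coembed = coembed, kliep = NULL,
                 ratios = p$ratios, slice_weights = p$slice_weights,
                 prep_sc = prep_sc, prep_st = NULL, genes = p$genes,
                 sc_scaled = NULL, st_scaled = NULL,
                 normalize = p$normalize, s = p$s, seed = p$seed,
                 call = NULL),
            class = "spatmap")
}
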