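#' Library-size normalize and log-transform raw counts
#'
#' Each raw count \eqn{d_{ij}} (gene i, cell j) is mapped to
#' \deqn{x_{ij} = \ln(s \cdot d_{ij} / \sum_k d_{kj} + 1),}
#' i.e. counts are scaled to a common library size `s` and log1p-transformed.
#'
#' @param gm a `gene_matrix` with `stage = "raw"`.
#' @param s positive scaling factor (target library size), default 10000.
#' @return A `gene_matrix` with `stage = "lognorm"`; zeros map to zero.
#' @export
lognormalize <- function(gm, s = 10000) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm_stage(gm) != "raw") stop("lognormalize expects a raw-stage gene_matrix")
  if (!is.numeric(s) || length(s) != 1 || s <= 0) stop("s must be a positive scalar")
  totals <- rowSums(gm_values(gm))
  if (any(totals == 0))
    stop("zero library size for cell(s): ",
         paste(rownames(gm)[totals == 0], collapse = ", "))
  out <- log1p(s * gm_values(gm) / totals)
  gm_replace(gm, out, stage = "lognorm")
}

#' Per-gene z-score scaling
#'
#' Scales each gene to mean 0, sd 1 across cells (population sd, i.e.
#' denominator n). In fit mode the per-gene mean and sd are estimated from
#' `gm` and zero-variance genes are dropped (the z-score is undefined for
#' them) and recorded. In apply mode a previously fitted `preprocess_model`
#' supplies the statistics unchanged, so a query dataset is placed on the
#' reference scale.
#'
#' @param gm a `gene_matrix` (typically `stage = "lognorm"`).
#' @param model optional `preprocess_model` from a previous fit (apply mode).
#' @param s scaling factor to record in the model (bookkeeping only).
#' @return A list with `scaled` (a `gene_matrix`, `stage = "scaled"`) and
#'   `model` (a `preprocess_model` with fields `mu`, `sigma`, `dropped`, `s`).
#' @export
zscore_scale <- function(gm, model = NULL, s = 10000) {
  stopifnot(inherits(gm, "gene_matrix"))
  x <- gm_values(gm)
  if (is.null(model)) {
    mu <- colMeans(x)
    sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))     # population sd
    keep <- sigma > 0
    dropped <- colnames(x)[!keep]
    mu <- mu[keep]
    sigma <- sigma[keep]
    model <- structure(list(mu = mu, sigma = sigma, dropped = dropped,
                            genes = names(mu), s = s),
                       class = "preprocess_model")
  } else {
    stopifnot(inherits(model, "preprocess_model"))
    missing <- setdiff(model$genes, colnames(x))
    if (length(missing))
      stop("genes absent from input but present in model: ",
           paste(missing, collapse = ", "))
  }
  x <- x[, model$genes, drop = FALSE]
  scaled <- sweep(sweep(x, 2, model$mu), 2, model$sigma, "/")
  list(scaled = gene_matrix(scaled, cell_ids = rownames(gm),
                            gene_ids = model$genes, stage = "scaled"),
       model = model)
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat(sprintf("preprocess_model: %d genes (s = %g, %d zero-variance dropped)\n",
              length(x$genes), x$s, length(x$dropped)))
  invisible(x)
}

#' Select highly variable genes
#'
#' Ranks genes by a Seurat-style dispersion statistic on log-normalized
#' expression: per-gene dispersion (variance / mean) is z-scored within 20
#' equal-width bins of the per-gene mean, so highly expressed genes are
#' compared with their expression peers. Ties are broken by lexicographic
#' gene id, making the ranking deterministic.
#'
#' @param gm a `gene_matrix` (log-normalized values recommended; raw counts
#'   are log-normalized internally first).
#' @param n_top number of genes to return, `1 <= n_top <= ncol(gm)`.
#' @param n_bins number of mean-expression bins (default 20, reduced for
#'   small gene panels so each bin holds several genes).
#' @return Character vector of `n_top` gene ids, most variable first.
#' @export
select_hvgs <- function(gm, n_top, n_bins = 20) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (!is.numeric(n_top) || n_top <= 0) stop("n_top must be a positive integer")
  if (n_top > ncol(gm)) stop("n_top (", n_top, ") exceeds gene count (", ncol(gm), ")")
  if (gm_stage(gm) == "raw") gm <- lognormalize(gm)
  x <- gm_values(gm)
  mu <- colMeans(x)
  v <- colMeans(sweep(x, 2, mu)^2)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1L, min(n_bins, floor(ncol(x) / 5)))
  bins <- if (n_bins < 2 || diff(range(mu)) == 0) rep(1L, length(mu)) else
    cut(mu, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  z <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    m <- mean(disp[idx]); sd_b <- stats::sd(disp[idx])
    z[idx] <- if (is.na(sd_b) || sd_b == 0) 0 else (disp[idx] - m) / sd_b
  }
  ord <- order(-z, colnames(x))
  colnames(x)[ord][seq_len(n_top)]
}

#' Intersect gene lists
#'
#' Set intersection of two or more gene-id vectors, ordered by the first
#' list. An empty intersection is returned with a warning.
#'
#' @param ... two or more character vectors, or a single list of them.
#' @return Character vector of common gene ids.
#' @export
intersect_genes <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]])) lists <- lists[[1]]
  if (length(lists) < 2) stop("need at least two gene lists")
  if (any(vapply(lists, length, 1L) == 0)) stop("gene lists must be non-empty")
  common <- Reduce(intersect, lists)
  out <- lists[[1]][lists[[1]] %in% common]
  if (length(out) == 0) warning("gene lists have an empty intersection")
  out
}

#' Reversible polar transform for annular tissues
#'
#' Forward mode maps each point (x, y) to \eqn{(\bar r \theta, r)} about a
#' center (default: centroid), with \eqn{\theta \in [0, 2\pi)} and
#' \eqn{\bar r} the mean radius, unrolling an annulus into a band while
#' preserving scale. Inverse mode undoes it; the round trip is exact to
#' floating-point accuracy except across the \eqn{\theta = 0/2\pi} seam.
#'
#' @param coords m x 2 numeric matrix.
#' @param center optional length-2 center; forward default is the centroid,
#'   inverse default is the center stored on a forward result.
#' @param inverse logical; apply the inverse transform.
#' @param rbar mean radius for the inverse (default: stored attribute).
#' @return m x 2 matrix; forward results carry `center` and `rbar`
#'   attributes consumed by the inverse.
#' @export
polar_transform <- function(coords, center = NULL, inverse = FALSE, rbar = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  if (!inverse) {
    if (is.null(center)) center <- colMeans(coords)
    dx <- coords[, 1] - center[1]
    dy <- coords[, 2] - center[2]
    r <- sqrt(dx^2 + dy^2)
    if (any(r == 0))
      stop("point(s) at the transform center: row ", which(r == 0)[1])
    theta <- atan2(dy, dx) %% (2 * pi)
    rb <- mean(r)
    out <- cbind(rb * theta, r)
    rownames(out) <- rownames(coords)
    attr(out, "center") <- center
    attr(out, "rbar") <- rb
    out
  } else {
    if (is.null(center)) center <- attr(coords, "center")
    if (is.null(rbar)) rbar <- attr(coords, "rbar")
    if (is.null(center) || is.null(rbar))
      stop("inverse transform needs `center` and `rbar` (or a forward result)")
    theta <- coords[, 1] / rbar
    r <- coords[, 2]
    out <- cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
    rownames(out) <- rownames(coords)
    out
  }
}
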