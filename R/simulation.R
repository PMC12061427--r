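#' Coarse-grain a single-cell slice into spot-resolution data
#'
#' Emulates a low-resolution spot array (Visium-like) from single-cell
#' resolution data: a uniform grid is laid over the slice bounding box with
#' the grid intersections as spot centers, each spot has radius
#' `spacing / 4`, the spot expression is the sum over all cells within the
#' radius, and spots with zero total expression are dropped. When the input
#' carries labels, each retained spot gets the majority label of its cells.
#'
#' @param slice a `spatial_slice` with raw-stage expression.
#' @param spacing center-to-center spot spacing (same units as coordinates).
#' @param offset optional (x, y) shift of the grid origin from the bounding
#'   box minimum corner.
#' @return A `spatial_slice` of spots (raw counts), spot ids `spot_<i>_<j>`.
#' @export
coarse_grain <- function(slice, spacing, offset = c(0, 0)) {
  stopifnot(inherits(slice, "spatial_slice"))
  if (gm_stage(slice$expr) != "raw") stop("coarse_grain expects raw-stage expression")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  co <- slice$coords
  ext <- apply(co, 2, function(v) diff(range(v)))
  if (spacing > max(ext))
    stop("spacing (", spacing, ") exceeds the bounding box; no spot would exist")
  origin <- apply(co, 2, min) + offset
  radius <- spacing / 4
  # nearest grid intersection per cell; radius < spacing/2 so it is unique
  gi <- round((co[, 1] - origin[1]) / spacing)
  gj <- round((co[, 2] - origin[2]) / spacing)
  gx <- origin[1] + gi * spacing
  gy <- origin[2] + gj * spacing
  inside <- sqrt((co[, 1] - gx)^2 + (co[, 2] - gy)^2) <= radius
  if (!any(inside)) stop("no cell falls within any spot radius")
  key <- paste0("spot_", gi[inside], "_", gj[inside])
  x <- gm_values(slice$expr)[inside, , drop = FALSE]
  spots <- unique(key)
  agg <- rowsum(x, group = key, reorder = FALSE)
  coords <- cbind(x = unname(gx[inside][match(rownames(agg), key)]),
                  y = unname(gy[inside][match(rownames(agg), key)]))
  rownames(coords) <- rownames(agg)
  keep <- rowSums(agg) > 0
  agg <- agg[keep, , drop = FALSE]
  coords <- coords[keep, , drop = FALSE]
  labels <- NULL
  if (!is.null(slice$labels)) {
    lab_in <- slice$labels[inside]
    labels <- vapply(rownames(agg), function(k) {
      tb <- sort(table(lab_in[key == k]), decreasing = TRUE)
      names(tb)[1]
    }, "")
  }
  spatial_slice(gene_matrix(agg, cell_ids = rownames(agg),
                            gene_ids = colnames(slice$expr), stage = "raw"),
                coords, labels = labels,
                slice_id = paste0(slice$slice_id, "_coarse"))
}

#' Add gene-wise Gaussian noise to expression
#'
#' For each gene j with per-gene variance Var(X_j) (population variance over
#' cells), adds noise \eqn{N_{ij} \sim N(0, \sigma \cdot Var(X_j))} and clips
#' the result at zero: \eqn{X'_{ij} = \max(X_{ij} + N_{ij}, 0)}. `sigma` is a
#' noise ratio relative to each gene's intrinsic variance; `sigma = 0`
#' returns the input unchanged.
#'
#' @param gm a `gene_matrix`.
#' @param sigma non-negative noise ratio.
#' @param seed integer seed.
#' @return A `gene_matrix` of the same stage, values >= 0.
#' @export
add_noise <- function(gm, sigma, seed = 1L) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(gm)
  x <- gm_values(gm)
  v <- colMeans(sweep(x, 2, colMeans(x))^2)
  noise <- with_seed(seed, {
    n <- matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
    sweep(n, 2, sqrt(sigma * v), "*")
  })
  gm_replace(gm, pmax(x + noise, 0))
}

#' Ten-gene toy tissue with known coordinate-determining genes
#'
#' Simulates the benchmark toy tissue separating spatial-organizing genes
#' from merely spatially variable genes. Genes 1-4 are i.i.d. U(0, 2) and
#' alone determine the cell coordinates:
#' \deqn{y_1 = 2\sin(X_1) + 1.5 X_2^2 + N(0, R), \qquad
#'       y_2 = -e^{-X_3} + 2.5\cos(X_4) + N(0, R).}
#' Genes 5-10 are generated from the coordinates through the spatial kernel
#' \eqn{w_{ij} = \exp(-d_{ij}/W)} as \eqn{X_g = b + w\,\epsilon_g} with
#' \eqn{\epsilon_g} an independent standard-normal vector per gene, giving
#' them strong spatial autocorrelation (high Moran's I) but no causal role
#' in the positions.
#'
#' @param n cells (>= 10), default 500.
#' @param R coordinate noise variance, default 0.1.
#' @param W spatial correlation scale, default 0.6.
#' @param b baseline expression of genes 5-10, default 1.
#' @param seed integer seed; the dataset is bit-reproducible given it.
#' @return A `toy_dataset`: `X` (a `gene_matrix`, stage `"lognorm"` — the toy
#'   expression is treated as already normalized), `coords`, `params`,
#'   `sog_truth` (1:4) and `svg_truth` (5:10). Gene ids are zero-padded
#'   (`gene01..gene10`) so lexicographic order matches gene number.
#' @export
simulate_toy <- function(n = 500, R = 0.1, W = 0.6, b = 1, seed = 1L) {
  if (n < 10) stop("n must be >= 10")
  if (R < 0) stop("R must be non-negative")
  if (W <= 0) stop("W must be positive")
  with_seed(seed, {
    X <- matrix(0, n, 10)
    X[, 1:4] <- stats::runif(4L * n, 0, 2)
    y1 <- 2 * sin(X[, 1]) + 1.5 * X[, 2]^2 + stats::rnorm(n, sd = sqrt(R))
    y2 <- -exp(-X[, 3]) + 2.5 * cos(X[, 4]) + stats::rnorm(n, sd = sqrt(R))
    coords <- cbind(x = y1, y = y2)
    w <- exp(-as.matrix(stats::dist(coords)) / W)
    for (g in 5:10) X[, g] <- b + as.vector(w %*% stats::rnorm(n))
    ids <- sprintf("gene%02d", 1:10)
    gm <- gene_matrix(X, cell_ids = sprintf("cell%04d", seq_len(n)),
                      gene_ids = ids, stage = "lognorm")
    rownames(coords) <- rownames(gm)
    structure(list(X = gm, coords = coords,
                   params = list(n = n, R = R, W = W, b = b, seed = seed),
                   sog_truth = ids[1:4], svg_truth = ids[5:10]),
              class = "toy_dataset")
  })
}

#' @export
print.toy_dataset <- function(x, ...) {
  cat(sprintf("toy_dataset: n = %d cells, 10 genes (R = %g, W = %g, b = %g, seed = %d)\n",
              x$params$n, x$params$R, x$params$W, x$params$b, x$params$seed))
  invisible(x)
}

#' Layered-tissue fixture (reference slice + matched single-cell query)
#'
#' Emulates a laminar cortex-like tissue for end-to-end tests: `n_layers`
#' horizontal bands in the unit square, each layer carrying a block of
#' elevated marker genes (log-normal counts with the marker effect
#' `marker_strength` on the log scale). Four additional genes follow smooth
#' coordinate gradients (two per axis, amplitude also `marker_strength`),
#' emulating the graded spatial expression real tissue carries on top of
#' discrete layer identity; remaining genes are unstructured housekeeping
#' noise. A matched "scRNA-seq" cohort is drawn from the same generative
#' process with configurable layer proportions, so a proportion shift
#' exercises the density-ratio correction.
#'
#' @param n_layers number of layers (>= 2), default 5.
#' @param cells_per_layer spots per layer in the reference, default 200.
#' @param n_genes total genes (>= n_layers + 4), default 50.
#' @param marker_strength log-scale effect size of markers and gradients;
#'   0 yields no spatial signal at all.
#' @param sc_props optional single-cell layer proportions (length
#'   `n_layers`, summing to 1); default uniform.
#' @param sc_cells total single-cell cohort size, default
#'   `n_layers * cells_per_layer`.
#' @param seed integer seed.
#' @return List with `st` (labeled `spatial_slice`, raw counts), `sc`
#'   (raw `gene_matrix`), `sc_coords`, `sc_labels` (ground truth for
#'   evaluation) and `params` (incl. marker/gradient gene assignments).
#' @export
simulate_layers <- function(n_layers = 5, cells_per_layer = 200, n_genes = 50,
                            marker_strength = 2, sc_props = NULL,
                            sc_cells = n_layers * cells_per_layer, seed = 1L) {
  if (n_layers < 2) stop("n_layers must be >= 2")
  if (n_genes < n_layers + 4) stop("n_genes must be at least n_layers + 4")
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  grad_genes <- gene_ids[1:4]                       # 2 x-gradient, 2 y-gradient
  block <- floor((n_genes - 4) / n_layers)
  marker_of <- lapply(seq_len(n_layers), function(l)
    gene_ids[4 + ((l - 1) * block + 1):(l * block)])

  draw <- function(n_cells, props, prefix) {
    layer <- sample(seq_len(n_layers), n_cells, replace = TRUE, prob = props)
    x <- stats::runif(n_cells)
    y <- (layer - 1 + stats::runif(n_cells)) / n_layers
    meanlog <- matrix(1, n_cells, n_genes, dimnames = list(NULL, gene_ids))
    for (l in seq_len(n_layers))
      meanlog[layer == l, marker_of[[l]]] <- 1 + marker_strength
    meanlog[, grad_genes[1:2]] <- 1 + marker_strength * x
    meanlog[, grad_genes[3:4]] <- 1 + marker_strength * y
    counts <- matrix(round(stats::rlnorm(n_cells * n_genes,
                                         meanlog = as.vector(meanlog),
                                         sdlog = 0.4)),
                     n_cells, n_genes)
    list(gm = gene_matrix(counts, cell_ids = sprintf("%s%04d", prefix, seq_len(n_cells)),
                          gene_ids = gene_ids, stage = "raw"),
         coords = cbind(x = x, y = y),
         labels = paste0("L", layer))
  }

  with_seed(seed, {
    st_raw <- draw(n_layers * cells_per_layer, rep(1 / n_layers, n_layers), "spot")
    if (is.null(sc_props)) sc_props <- rep(1 / n_layers, n_layers)
    if (length(sc_props) != n_layers) stop("sc_props length must equal n_layers")
    sc_raw <- draw(sc_cells, sc_props / sum(sc_props), "cell")
    rownames(st_raw$coords) <- rownames(st_raw$gm)
    rownames(sc_raw$coords) <- rownames(sc_raw$gm)
    list(st = spatial_slice(st_raw$gm, st_raw$coords, labels = st_raw$labels,
                            slice_id = "laminar_ref"),
         sc = sc_raw$gm,
         sc_coords = sc_raw$coords,
         sc_labels = sc_raw$labels,
         params = list(n_layers = n_layers, cells_per_layer = cells_per_layer,
                       n_genes = n_genes, marker_strength = marker_strength,
                       sc_props = sc_props, seed = seed,
                       gradient_genes = grad_genes, marker_genes = marker_of))
  })
}
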