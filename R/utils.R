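# Run an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Indices of the k nearest neighbors (self excluded) for each row of coords.
knn_indices <- function(coords, k) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (k >= m) stop("k (", k, ") must be smaller than the number of points (", m, ")")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

# Convex hull area and perimeter of a 2-D point set (0 for degenerate sets).
hull_measures <- function(pts) {
  pts <- as.matrix(pts)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(unique(pts)) < 3) return(c(area = 0, perimeter = 0))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  nxt <- c(2:n, 1)
  area <- abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
  per <- sum(sqrt(rowSums((hp[nxt, , drop = FALSE] - hp)^2)))
  c(area = area, perimeter = per)
}
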