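test_that("coarse graining matches a brute-force membership oracle", {
  withr::with_seed(1, {
    coords <- matrix(runif(200, 0, 10), 100, 2)
    counts <- matrix(rpois(100 * 5, 4), 100, 5)
  })
  sl <- spatial_slice(gene_matrix(counts, gene_ids = paste0("g", 1:5)), coords)
  spacing <- 1
  cg <- coarse_grain(sl, spacing)

  # oracle: scan every grid intersection, sum cells within spacing/4
  origin <- apply(coords, 2, min)
  radius <- spacing / 4
  gx <- seq(origin[1], max(coords[, 1]) + spacing, by = spacing)
  gy <- seq(origin[2], max(coords[, 2]) + spacing, by = spacing)
  expected <- list()
  for (x0 in gx) for (y0 in gy) {
    inside <- sqrt((coords[, 1] - x0)^2 + (coords[, 2] - y0)^2) <= radius
    if (any(inside)) {
      v <- colSums(counts[inside, , drop = FALSE])
      if (sum(v) > 0) expected[[sprintf("%.3f_%.3f", x0, y0)]] <- v
    }
  }
  expect_equal(nrow(cg$expr), length(expected))
  key <- sprintf("%.3f_%.3f", cg$coords[, 1], cg$coords[, 2])
  for (i in seq_along(key))
    expect_equal(unname(unclass(cg$expr)[i, ]), unname(expected[[key[i]]]))

  # conservation: retained spots never exceed the total cell expression
  expect_lte(sum(unclass(cg$expr)), sum(counts))
})

test_that("coarse graining respects the quarter-spacing radius and contracts", {
  # one cell exactly at a grid intersection is captured alone
  coords <- rbind(c(0, 0), c(5, 5))
  counts <- rbind(c(3, 1), c(2, 2))
  sl <- spatial_slice(gene_matrix(counts, gene_ids = c("a", "b")), coords)
  cg <- coarse_grain(sl, spacing = 4)              # (5,5) sits outside every radius
  expect_equal(nrow(cg$expr), 1)
  expect_equal(unname(unclass(cg$expr)[1, ]), c(3, 1))

  # 0.2 x spacing inside the radius, 0.3 x spacing outside (radius = 0.25)
  coords2 <- rbind(c(0, 0), c(0.2, 0), c(0.3, 0), c(1, 1))
  counts2 <- matrix(1, 4, 2)
  sl2 <- spatial_slice(gene_matrix(counts2, gene_ids = c("a", "b")), coords2)
  cg2 <- coarse_grain(sl2, spacing = 1)
  spot0 <- which(cg2$coords[, 1] == 0 & cg2$coords[, 2] == 0)
  expect_equal(unname(unclass(cg2$expr)[spot0, 1]), 2)   # center + 0.2 only

  expect_error(coarse_grain(sl2, spacing = 100), "bounding box")
})

test_that("expression noise follows its stated gene-wise variance law", {
  gm <- make_counts(n = 20, g = 3, seed = 2)
  expect_identical(add_noise(gm, 0), gm)                 # sigma = 0 identity

  const <- gene_matrix(cbind(g1 = rep(5, 30), g2 = 1:30), stage = "lognorm")
  noisy <- add_noise(const, sigma = 2, seed = 3)
  expect_equal(unclass(noisy)[, "g1"], unclass(const)[, "g1"])  # Var = 0 untouched
  expect_true(all(unclass(noisy) >= 0))

  # Monte-Carlo check at n = 5000, offset high enough that clipping never fires
  withr::with_seed(4, x <- matrix(rnorm(5000 * 4, mean = 100, sd = c(1, 2, 4, 8)),
                                  5000, 4, byrow = TRUE))
  gm_big <- gene_matrix(x, gene_ids = paste0("g", 1:4), stage = "lognorm")
  out <- add_noise(gm_big, sigma = 1, seed = 5)
  delta <- unclass(out) - x
  v_gene <- apply(x, 2, function(col) mean((col - mean(col))^2))
  ratio <- apply(delta, 2, var) / v_gene
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("the toy tissue reproduces its generative equations and is bit-reproducible", {
  toy0 <- simulate_toy(n = 50, R = 0, seed = 6)
  X <- unclass(toy0$X)
  expect_equal(unname(toy0$coords[, 1]), unname(2 * sin(X[, 1]) + 1.5 * X[, 2]^2),
               tolerance = 1e-12)
  expect_equal(unname(toy0$coords[, 2]), unname(-exp(-X[, 3]) + 2.5 * cos(X[, 4])),
               tolerance = 1e-12)
  expect_true(all(X[, 1:4] >= 0 & X[, 1:4] <= 2))

  again <- simulate_toy(n = 50, R = 0, seed = 6)
  expect_identical(unclass(again$X)[, ], X[, ])
  expect_identical(again$coords, toy0$coords)

  expect_error(simulate_toy(n = 50, R = -1), "non-negative")
  expect_error(simulate_toy(n = 50, W = 0), "positive")

  # W -> 0 limit: spatially mixed genes lose their autocorrelation
  toy_w0 <- simulate_toy(n = 500, W = 1e-3, seed = 7)
  mi <- vapply(toy_w0$svg_truth, function(g)
    morans_i(unclass(toy_w0$X)[, g], toy_w0$coords), 0)
  expect_true(all(abs(mi) < 0.1))
})

test_that("the laminar fixture carries signal only through marker strength", {
  lay <- simulate_layers(n_layers = 3, cells_per_layer = 50, n_genes = 20,
                         marker_strength = 2, seed = 8)
  expect_equal(nrow(lay$st$expr), 150)
  expect_identical(gm_stage(lay$st$expr), "raw")
  expect_equal(sort(unique(lay$st$labels)), c("L1", "L2", "L3"))

  # markers of a layer are elevated inside it
  m1 <- lay$params$marker_genes[[1]]
  in1 <- lay$st$labels == "L1"
  expect_gt(mean(unclass(lay$st$expr)[in1, m1]),
            2 * mean(unclass(lay$st$expr)[!in1, m1]))

  # no-signal control: marker_strength = 0 gives layer-independent expression
  flat <- simulate_layers(n_layers = 3, cells_per_layer = 50, n_genes = 20,
                          marker_strength = 0, seed = 9)
  f1 <- flat$params$marker_genes[[1]]
  g1 <- mean(unclass(flat$st$expr)[flat$st$labels == "L1", f1])
  g2 <- mean(unclass(flat$st$expr)[flat$st$labels != "L1", f1])
  expect_lt(abs(g1 - g2) / g2, 0.15)
})

test_that("proportion-shifted queries bend the density-ratio weights the right way", {
  lay <- simulate_layers(n_layers = 4, cells_per_layer = 100, n_genes = 24,
                         marker_strength = 2,
                         sc_props = c(0.55, 0.15, 0.15, 0.15), seed = 10)
  fit <- spatmap(lay$st, lay$sc, n_hvg = NULL, max_epochs = 5, seed = 10)
  w <- fit$ratios[[1]]
  w_l1 <- mean(w[lay$st$labels == "L1"])
  w_rest <- mean(w[lay$st$labels != "L1"])
  expect_gt(w_l1, w_rest)                          # oversampled layer upweighted
})
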