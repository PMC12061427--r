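test_that("slice weights normalize, respect symmetry, and favor the matched slice", {
  expect_equal(estimate_slice_weights(matrix(rnorm(20), ncol = 2),
                                      matrix(rnorm(20), ncol = 2)), 1)
  withr::with_seed(5, {
    z_sc <- matrix(rnorm(2000), ncol = 2)
    zA <- matrix(rnorm(1000), ncol = 2)            # matches query
    zB <- matrix(rnorm(1000, 1.5), ncol = 2)       # shifted
  })
  w_same <- estimate_slice_weights(z_sc, list(zA, zA), seed = 1)
  expect_equal(w_same, c(0.5, 0.5), tolerance = 1e-12)
  w <- estimate_slice_weights(z_sc, list(zA, zB), seed = 1)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_gt(w[1], w[2])
})

test_that("uniform weights reduce to ordinary regression with small held-out error", {
  withr::with_seed(7, {
    X <- matrix(rnorm(600 * 5), 600, 5)
    A <- matrix(rnorm(10, sd = 0.3), 5, 2)
    Y <- plogis(X %*% A)                           # smooth map into (0,1)^2
  })
  tr <- 1:500; te <- 501:600
  gm <- gene_matrix(X[tr, ], gene_ids = letters[1:5], stage = "scaled")
  sl <- spatial_slice(gm, Y[tr, ])
  ce <- fit_coembed(sl, K = 5)
  mp <- fit_mapper(sl, ce, seed = 1)
  gm_te <- gene_matrix(X[te, ], gene_ids = letters[1:5], stage = "scaled")
  pred <- predict_locations(mp, gm_te)
  expect_lt(mean(rowSums((pred - Y[te, ])^2)), 0.01)
  # training loss trace: final <= initial
  expect_lte(mp$train_log[length(mp$train_log)], mp$train_log[1])
})

test_that("rescaling all spot weights leaves the fit unchanged", {
  withr::with_seed(8, {
    X <- matrix(rnorm(200 * 4), 200, 4)
    Y <- cbind(plogis(X[, 1]), plogis(X[, 2]))
    w <- runif(200, 0.5, 2)
  })
  gm <- gene_matrix(X, gene_ids = letters[1:4], stage = "scaled")
  sl <- spatial_slice(gm, Y)
  ce <- fit_coembed(sl, K = 4)
  m1 <- fit_mapper(sl, ce, ratios = w, weight_decay = 0, max_epochs = 50, seed = 2)
  m2 <- fit_mapper(sl, ce, ratios = 2 * w, weight_decay = 0, max_epochs = 50, seed = 2)
  expect_equal(predict_locations(m1, gm), predict_locations(m2, gm),
               tolerance = 1e-12)
})

test_that("concentrating all weight on one spot collapses predictions to it", {
  withr::with_seed(9, {
    X <- matrix(rnorm(50 * 3), 50, 3)
    Y <- matrix(runif(100), 50, 2)
  })
  gm <- gene_matrix(X, gene_ids = c("a", "b", "c"), stage = "scaled")
  sl <- spatial_slice(gm, Y)
  ce <- fit_coembed(sl, K = 3)
  w <- c(1, rep(0, 49))
  mp <- fit_mapper(sl, ce, ratios = w, dropout = 0, max_epochs = 300,
                   patience = 300, seed = 3)
  pred <- predict_locations(mp, gm)
  expect_lt(max(abs(pred[1, ] - Y[1, ])), 0.15)
})

test_that("prediction is deterministic, stage-checked, and accurate on training spots", {
  fx <- fit_toy_mapper(n = 300, seed = 4, max_epochs = 300)
  pred <- predict_locations(fx$mapper, fx$gm)
  resid <- pred - fx$toy$coords
  expect_lt(mean(rowSums(resid^2)), 1)             # far below the ~18 null scale

  two <- gene_matrix(unclass(fx$gm)[c(1, 1), ], cell_ids = c("u", "v"),
                     gene_ids = colnames(fx$gm), stage = "scaled")
  p2 <- predict_locations(fx$mapper, two)
  expect_equal(unname(p2[1, ]), unname(p2[2, ]))

  raw_gm <- gene_matrix(abs(unclass(fx$gm)[, ]), gene_ids = colnames(fx$gm),
                        stage = "raw")
  expect_error(predict_locations(fx$mapper, raw_gm), "scaled")
})

test_that("held-out toy cells are recovered with high per-axis correlation", {
  toy <- simulate_toy(n = 500, seed = 1)
  idx <- withr::with_seed(1, sample.int(500, 400))
  gm_all <- gene_matrix(unclass(toy$X)[, ], cell_ids = rownames(toy$X),
                        gene_ids = colnames(toy$X), stage = "scaled")
  tr_gm <- gene_matrix(unclass(toy$X)[idx, ], cell_ids = rownames(toy$X)[idx],
                       gene_ids = colnames(toy$X), stage = "scaled")
  sl <- spatial_slice(tr_gm, toy$coords[idx, ])
  ce <- fit_coembed(sl)
  mp <- fit_mapper(sl, ce, seed = 1)
  te <- setdiff(seq_len(500), idx)
  pred <- predict_locations(mp, gm_all)[te, ]
  expect_gt(cor(pred[, 1], toy$coords[te, 1]), 0.9)
  expect_gt(cor(pred[, 2], toy$coords[te, 2]), 0.9)
})

test_that("ratio weighting beats unweighted fits when capacity forces a trade-off", {
  # importance weighting pays off when the regressor cannot fit all regions
  # equally well; a small network under a strong proportion shift is that regime
  res <- t(vapply(1:5, function(sd) {
    lay <- simulate_layers(sc_props = c(0.7, 0.075, 0.075, 0.075, 0.075),
                           seed = sd)
    fit_w <- spatmap(lay$st, lay$sc, n_hvg = NULL, hidden = 8L, seed = sd)
    map_u <- fit_mapper(fit_w$st_scaled, fit_w$coembed,
                        ratios = list(rep(1, nrow(lay$st$expr))), hidden = 8L,
                        seed = sd)
    pw <- predict(fit_w)
    pu <- predict_locations(map_u, fit_w$sc_scaled)
    c(weighted = mean(rowSums((pw - lay$sc_coords)^2)),
      unweighted = mean(rowSums((pu - lay$sc_coords)^2)))
  }, c(weighted = 0, unweighted = 0)))
  expect_lte(mean(res[, "weighted"]), mean(res[, "unweighted"]))
})
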