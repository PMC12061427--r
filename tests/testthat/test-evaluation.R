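test_that("accuracy endpoints: exact reconstruction scores 1, permutation scores ~0", {
  truth <- withr::with_seed(1, matrix(runif(2000), 1000, 2))
  exact <- mse_accuracy(truth, truth, seed = 1)
  expect_equal(exact$mse, 0)
  expect_equal(exact$accuracy, 1)

  perm <- withr::with_seed(2, truth[sample.int(1000), ])
  rand <- mse_accuracy(perm, truth, seed = 1)
  expect_lt(abs(rand$accuracy), 0.05)

  noisy <- truth + withr::with_seed(3, matrix(rnorm(2000, sd = 0.01), 1000, 2))
  expect_gt(mse_accuracy(noisy, truth, seed = 1)$accuracy, 0.95)

  expect_error(mse_accuracy(truth[1, , drop = FALSE], truth[1, , drop = FALSE]),
               "at least 2")
})

test_that("accuracy decreases monotonically with noise and is rigid-motion invariant", {
  truth <- withr::with_seed(4, matrix(runif(800), 400, 2))
  levels <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  acc <- sapply(levels, function(s) {
    mean(sapply(1:5, function(sd) {
      pred <- truth + withr::with_seed(100 * sd + round(1000 * s),
                                       matrix(rnorm(800, sd = s), 400, 2))
      mse_accuracy(pred, truth, seed = sd)$accuracy
    }))
  })
  expect_true(all(diff(acc) < 0))
  expect_true(all(acc >= 0 & acc <= 1))

  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  pred <- truth + withr::with_seed(5, matrix(rnorm(800, sd = 0.05), 400, 2))
  a1 <- mse_accuracy(pred, truth, seed = 9)
  a2 <- mse_accuracy(pred %*% t(R) + 3, truth %*% t(R) + 3, seed = 9)
  expect_equal(a1$accuracy, a2$accuracy, tolerance = 1e-10)
})

test_that("layer indicators are 1 at self-comparison and degrade as specified", {
  withr::with_seed(6, {
    truth <- matrix(runif(1200), 600, 2)
    labels <- rep(c("A", "B"), each = 300)
    truth[labels == "B", 2] <- truth[labels == "B", 2] + 2
  })
  perfect <- layer_indicators(truth, truth, labels)
  expect_equal(unlist(perfect[perfect$layer == "mean", c("S_C", "rho_C", "A_C", "P_C")]),
               c(S_C = 1, rho_C = 1, A_C = 1, P_C = 1), tolerance = 1e-12)

  # random labels over one mixed cloud: S_C near 1/2 for two equal classes
  withr::with_seed(7, {
    cloud <- matrix(runif(1200), 600, 2)
    rnd_lab <- sample(rep(c("A", "B"), each = 300))
  })
  mixed <- layer_indicators(cloud, cloud, rnd_lab, k = 30)
  expect_equal(mixed$S_C[mixed$layer == "mean"], 0.5, tolerance = 0.05)

  # a layer collapsed to a point has zero hull area and perimeter
  pred <- truth
  pred[labels == "B", ] <- matrix(rep(c(0.5, 2.5), each = 300), ncol = 2)
  coll <- layer_indicators(pred, truth, labels)
  expect_equal(coll$A_C[coll$layer == "B"], 0)
  expect_equal(coll$P_C[coll$layer == "B"], 0)

  # tiny layers are excluded from the means rather than breaking the hull
  lab3 <- labels; lab3[1:2] <- "C"
  out <- layer_indicators(truth, truth, lab3)
  expect_true(is.na(out$A_C[out$layer == "C"]))
  expect_equal(out$S_C[out$layer == "mean"],
               mean(out$S_C[out$layer %in% c("A", "B")]), tolerance = 1e-12)
})

test_that("S_C, A_C, P_C are invariant to a common rigid transformation", {
  withr::with_seed(8, {
    truth <- matrix(runif(600), 300, 2)
    pred <- truth + matrix(rnorm(600, sd = 0.1), 300, 2)
    labels <- rep(c("A", "B", "C"), each = 100)
  })
  th <- -0.4
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  a <- layer_indicators(pred, truth, labels)
  b <- layer_indicators(pred %*% t(R) - 5, truth %*% t(R) - 5, labels)
  expect_equal(a$S_C, b$S_C, tolerance = 1e-10)
  expect_equal(a$A_C, b$A_C, tolerance = 1e-10)
  expect_equal(a$P_C, b$P_C, tolerance = 1e-10)
})

test_that("Moran's I separates alternation, gradients, and noise", {
  grid <- as.matrix(expand.grid(x = 1:20, y = 1:20))
  checker <- (-1)^(grid[, 1] + grid[, 2])
  expect_lt(morans_i(checker, grid, k_neighbors = 4), 0)

  gradient <- grid[, 1] + grid[, 2]
  expect_gt(morans_i(gradient, grid, k_neighbors = 6), 0.8)

  noise <- withr::with_seed(9, rnorm(400))
  expect_lt(abs(morans_i(noise, grid, k_neighbors = 6)), 0.15)

  expect_error(morans_i(rep(1, 400), grid), "constant")
  expect_error(morans_i(1:5, grid[1:5, ]), "at least 10")
})

test_that("Moran's I matches the independent reference implementation", {
  skip_if_not_installed("ape")
  withr::with_seed(10, {
    coords <- matrix(runif(160), 80, 2)
    vals <- coords[, 1] * 2 + rnorm(80, sd = 0.3)
  })
  k <- 6
  # build the same row-normalized k-NN weight matrix by brute force
  d <- as.matrix(dist(coords)); diag(d) <- Inf
  W <- matrix(0, 80, 80)
  for (i in 1:80) W[i, order(d[i, ])[1:k]] <- 1 / k
  ref <- ape::Moran.I(vals, W, scaled = FALSE)
  expect_equal(morans_i(vals, coords, k_neighbors = k), ref$observed,
               tolerance = 1e-10)
})
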