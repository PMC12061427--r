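test_that("gene sensitivity scores match closed forms on linear maps", {
  A <- rbind(c(1, 0), c(0, 2))
  mp <- linear_mapper(A, gene_ids = c("gA", "gB"))
  gm <- gene_matrix(withr::with_seed(1, matrix(rnorm(40), 20, 2)),
                    gene_ids = c("gA", "gB"), stage = "scaled")
  s_ad <- sog_index(mp, gm)
  expect_equal(s_ad$I[match(c("gA", "gB"), s_ad$gene)], c(0.5, 1.0),
               tolerance = 1e-6)
  s_fd <- sog_index(mp, gm, method = "finite_diff")
  expect_equal(s_fd$I[match(c("gA", "gB"), s_fd$gene)], c(0.5, 1.0),
               tolerance = 1e-4)
  expect_identical(s_ad$gene[1], "gB")             # ranking by descending I

  zero <- linear_mapper(matrix(0, 2, 2), gene_ids = c("gA", "gB"))
  s0 <- sog_index(zero, gm)
  expect_equal(s0$I, c(0, 0))
  expect_identical(s0$gene, c("gA", "gB"))         # lexicographic tie break
})

test_that("autodiff and central differences agree through the trained network", {
  fx <- fit_toy_mapper(n = 200, seed = 2, max_epochs = 80)
  s_ad <- sog_index(fx$mapper, fx$gm)
  s_fd <- sog_index(fx$mapper, fx$gm, method = "finite_diff", eps = 1e-6)
  m <- merge(s_ad, s_fd, by = "gene")
  expect_lt(max(abs(m$I.x - m$I.y) / pmax(abs(m$I.x), 1e-8)), 1e-4)
})

test_that("sensitivity scores ignore cell order and duplication", {
  fx <- fit_toy_mapper(n = 120, seed = 3, max_epochs = 60)
  base <- sog_index(fx$mapper, fx$gm)
  x <- unclass(fx$gm)[, ]
  perm <- withr::with_seed(4, sample.int(nrow(x)))
  gm_perm <- gene_matrix(x[perm, ], cell_ids = rownames(x)[perm],
                         gene_ids = colnames(x), stage = "scaled")
  expect_equal(sog_index(fx$mapper, gm_perm)$I, base$I, tolerance = 1e-12)
  gm_dup <- gene_matrix(rbind(x, x), cell_ids = c(rownames(x), paste0(rownames(x), "_d")),
                        gene_ids = colnames(x), stage = "scaled")
  expect_equal(sog_index(fx$mapper, gm_dup)$I, base$I, tolerance = 1e-12)
})

test_that("knockout masks genes through the stored preprocessing", {
  fx <- fit_toy_mapper(n = 120, seed = 5, max_epochs = 60)
  prep <- structure(list(mu = setNames(rep(0, 10), colnames(fx$gm)),
                         sigma = setNames(rep(1, 10), colnames(fx$gm)),
                         dropped = character(0), genes = colnames(fx$gm),
                         s = 10000),
                    class = "preprocess_model")
  p0 <- predict_locations(fx$mapper, fx$gm)
  expect_identical(knockout_predict(fx$mapper, prep, fx$gm, character(0)), p0)

  p_all <- knockout_predict(fx$mapper, prep, fx$gm, colnames(fx$gm))
  expect_equal(max(apply(p_all, 2, function(v) diff(range(v)))), 0,
               tolerance = 1e-12)                  # constant input, constant output

  expect_error(knockout_predict(fx$mapper, prep, fx$gm, "nope"), "unknown gene")

  # masking with a non-trivial mu/sigma lands at (0 - mu)/sigma
  prep2 <- prep; prep2$mu[] <- 2; prep2$sigma[] <- 4
  mp_id <- linear_mapper(diag(2), gene_ids = colnames(fx$gm)[1:2])
  gm2 <- gene_matrix(matrix(1, 3, 2), gene_ids = colnames(fx$gm)[1:2],
                     stage = "scaled")
  prep2$genes <- colnames(fx$gm)[1:2]
  prep2$mu <- prep2$mu[1:2]; prep2$sigma <- prep2$sigma[1:2]
  pk <- knockout_predict(mp_id, prep2, gm2, colnames(fx$gm)[1])
  expect_equal(unname(pk[, 1]), rep((0 - 2) / 4, 3))
})

test_that("velocity projection is exact for null and linear cases", {
  A <- rbind(c(2, 1), c(0, -1))
  mp <- linear_mapper(A, gene_ids = c("u", "v"))
  gm <- gene_matrix(withr::with_seed(6, matrix(rnorm(30), 15, 2)),
                    gene_ids = c("u", "v"), stage = "scaled")
  vf0 <- spa_rna_velocity(mp, gm, matrix(0, 15, 2))
  expect_true(all(vf0$v_st == 0))                  # bitwise zero

  v <- withr::with_seed(7, matrix(rnorm(30), 15, 2))
  colnames(v) <- c("u", "v")
  vf <- spa_rna_velocity(mp, gm, v)
  expect_equal(unname(vf$v_st), unname(v %*% t(A)), tolerance = 1e-6)

  # raw-space adapter divides per-gene by sigma
  sig <- c(u = 2, v = 4)
  vf_s <- spa_rna_velocity(mp, gm, v, sigma = sig)
  expect_equal(unname(vf_s$v_st), unname(sweep(v, 2, sig, "/") %*% t(A)),
               tolerance = 1e-10)

  expect_error(spa_rna_velocity(mp, gm, v[1:3, ]), "row count")
})

test_that("velocity along a generative expression gradient points the right way", {
  fx <- fit_toy_mapper(n = 300, seed = 8, max_epochs = 300)
  # raising gene 2 raises y1 = 2 sin(X1) + 1.5 X2^2 (X2 >= 0): expect +x drift
  v <- matrix(0, nrow(fx$gm), 10, dimnames = list(NULL, colnames(fx$gm)))
  v[, "gene02"] <- 0.1
  vf <- spa_rna_velocity(fx$mapper, fx$gm, v)
  dir <- colMeans(vf$v_st)
  expect_gt(dir[1] / sqrt(sum(dir^2)), 0.8)        # cosine with +x
})
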