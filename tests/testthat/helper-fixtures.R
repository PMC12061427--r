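# Shared fixture builders (all data generated in code at test time).

# small raw count matrix with controllable values
make_counts <- function(n = 6, g = 4, seed = 1, max_count = 20) {
  withr::with_seed(seed, {
    vals <- matrix(rpois(n * g, lambda = 5), n, g)
    vals[1, 1] <- max_count            # guarantee variability
    gene_matrix(vals, cell_ids = sprintf("c%02d", seq_len(n)),
                gene_ids = sprintf("g%02d", seq_len(g)), stage = "raw")
  })
}

# random annulus point cloud
make_annulus <- function(n = 100, r0 = 1, r1 = 2, seed = 1) {
  withr::with_seed(seed, {
    r <- sqrt(runif(n, r0^2, r1^2))
    th <- runif(n, 0, 2 * pi)
    cbind(x = r * cos(th), y = r * sin(th))
  })
}

# scaled-stage slice + coembed + mapper on the toy tissue (moderate budget)
fit_toy_mapper <- function(n = 300, seed = 1, max_epochs = 150) {
  toy <- simulate_toy(n = n, seed = seed)
  gm <- gene_matrix(unclass(toy$X)[, ], cell_ids = rownames(toy$X),
                    gene_ids = colnames(toy$X), stage = "scaled")
  sl <- spatial_slice(gm, toy$coords)
  ce <- fit_coembed(sl)
  mp <- fit_mapper(sl, ce, max_epochs = max_epochs, seed = seed)
  list(toy = toy, gm = gm, slice = sl, coembed = ce, mapper = mp)
}
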