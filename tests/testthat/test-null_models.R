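test_that("patristic distances are path sums", {
  cherry <- ape::read.tree(text = "(A:1,B:2);")
  d <- patristic_distances(cherry)
  expect_equal(d["A", "B"], 3)
  expect_equal(diag(d), c(A = 0, B = 0))

  d4 <- patristic_distances(balanced_tree4())
  expect_equal(d4["A", "C"], 4)
  expect_equal(d4["A", "B"], 2)
  expect_error(patristic_distances(cherry, c("A", "Z")), "Z")
})

test_that("betaMNTD matches hand computations and the double-loop oracle", {
  tree <- balanced_tree4()
  D <- patristic_distances(tree)

  # one-taxon communities on opposite clades: 0.5 * (4 + 4)
  tab <- make_counts(matrix(c(3, 0, 0, 0, 0, 0, 5, 0), 2, 4, byrow = TRUE),
                     taxa = c("A", "B", "C", "D"))
  expect_equal(beta_mntd(tab, D)[1, 2], 4)

  # identical communities: nearest taxon is itself
  same <- make_counts(matrix(c(2, 1, 0, 1, 2, 1, 0, 1), 2, 4, byrow = TRUE),
                      taxa = tree$tip.label)
  expect_equal(beta_mntd(same, D)[1, 2], 0)

  # oracle equivalence on random 6-taxon, 4-sample instances, both weightings
  for (s in 1:50) {
    tr <- simulate_yule_tree(6, seed = 1000 + s)
    D6 <- patristic_distances(tr)
    tab <- random_table(4, 6, seed = 2000 + s, lambda = 2)
    colnames(tab) <- tr$tip.label
    for (w in c(TRUE, FALSE)) {
      expect_lt(max(abs(beta_mntd(tab, D6, w) - bmntd_oracle(tab, D6, w))),
                1e-10)
    }
  }
})

test_that("betaMNTD agrees with the independent picante implementation", {
  skip_if_not_installed("picante")
  # abundance-weighted only: for the unweighted variant picante pools both
  # communities' nearest-taxon distances into a single mean, which differs
  # from the per-community average used here whenever richness differs
  tr <- simulate_yule_tree(12, seed = 42)
  tab <- random_table(5, 12, seed = 43, lambda = 2)
  colnames(tab) <- tr$tip.label
  D <- patristic_distances(tr)
  ours <- beta_mntd(tab, D, abundance_weighted = TRUE)
  ref <- as.matrix(picante::comdistnt(tab, D, abundance.weighted = TRUE))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("betaNTI flags degenerate nulls and cancels branch-length scale", {
  # star phylogeny: every tip permutation leaves all distances unchanged
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  tab <- random_table(3, 6, seed = 7, lambda = 3)
  colnames(tab) <- star$tip.label
  expect_warning(z <- beta_nti(tab, star, null_model_config(99, seed = 1)),
                 "degenerate")
  expect_true(all(is.na(z)))

  # z-scores are invariant to globally rescaling branch lengths
  tr <- simulate_yule_tree(15, seed = 3)
  tab <- random_table(4, 15, seed = 8, lambda = 2)
  colnames(tab) <- tr$tip.label
  cfg <- null_model_config(n_null = 99, seed = 5)
  z1 <- beta_nti(tab, tr, cfg)
  tr10 <- tr
  tr10$edge.length <- tr$edge.length * 10
  z10 <- beta_nti(tab, tr10, cfg)
  expect_equal(z1, z10, tolerance = 1e-10)

  # determinism: identical config and seed give identical matrices
  expect_identical(z1, beta_nti(tab, tr, cfg))
})

test_that("RC-Bray pins the extremes of its null distribution", {
  # identical pair drawn from a rich pool: observed dissimilarity of 0 sits
  # at the bottom of every null draw
  set.seed(1)
  pool <- random_table(6, 40, seed = 10, lambda = 4)
  pool[2, ] <- pool[1, ]
  rc <- rc_bray(otu_table(pool), null_model_config(n_null = 999, seed = 2))
  expect_lte(rc[1, 2], -0.9)

  # fully disjoint occupancy: observed dissimilarity of 1 tops the null.
  # richness (12) is a quarter of the pool (48), so two null assemblies
  # almost surely share taxa and fall below 1
  n <- 4
  rich <- 12
  disj <- matrix(0, n, n * rich)
  for (k in seq_len(n)) {
    disj[k, ((k - 1) * rich + 1):(k * rich)] <- rich:1
  }
  disj <- make_counts(disj)
  rc <- rc_bray(otu_table(disj), null_model_config(n_null = 999, seed = 3))
  expect_gte(rc[1, 2], 0.9)

  # bounded, symmetric, deterministic on random tables
  for (s in 1:5) {
    tab <- random_table(4, 20, seed = 300 + s)
    cfg <- null_model_config(n_null = 49, seed = s)
    rc <- rc_bray(tab, cfg)
    ut <- upper.tri(rc)
    expect_true(all(rc[ut] >= -1 & rc[ut] <= 1))
    expect_equal(rc, t(rc))
    expect_identical(rc, rc_bray(tab, cfg))
  }
})
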