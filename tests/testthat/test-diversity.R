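test_that("alpha-diversity estimators match hand-computed values", {
  a <- alpha_diversity(make_counts(matrix(c(1, 1), 1, 2)), shannon_base = 2)
  expect_equal(a$shannon, 1)
  expect_equal(a$simpson, 0.5)

  # F1 = 2, F2 = 1 -> classic Chao1 = 5 + 4/2
  a <- alpha_diversity(make_counts(matrix(c(5, 5, 1, 1, 2), 1, 5)))
  expect_equal(a$chao1, 7)
  expect_equal(a$observed_otus, 5)

  a <- alpha_diversity(make_counts(matrix(c(9, 1), 1, 2)))
  expect_equal(a$goods_coverage, 0.9)

  # no doubletons -> bias-corrected fallback S + F1 (F1 - 1) / 2
  a <- alpha_diversity(make_counts(matrix(c(5, 1, 1, 1), 1, 4)))
  expect_equal(a$chao1, 4 + 3 * 2 / 2)

  # Shannon/Simpson agree with the standard ecology implementation
  tab <- random_table(6, 30, seed = 2)
  a <- alpha_diversity(tab, shannon_base = exp(1))
  expect_equal(a$shannon, unname(vegan::diversity(tab)), tolerance = 1e-12)
  expect_equal(a$simpson, unname(vegan::diversity(tab, "simpson")),
               tolerance = 1e-12)

  expect_error(alpha_diversity(make_counts(matrix(c(0, 0, 1, 1), 2, 2,
                                                  byrow = TRUE))),
               "zero total")
  # all rare reads singletons -> ACE undefined, flagged not invented
  expect_warning(a <- alpha_diversity(make_counts(matrix(c(1, 1, 1), 1, 3))),
                 "ACE undefined")
  expect_true(is.na(a$ace))
})

test_that("Chao1 dominates observed richness, with equality iff no singletons", {
  for (s in 1:25) {
    tab <- random_table(3, 25, seed = s, lambda = 1.5)
    a <- alpha_diversity(tab)
    f1 <- apply(tab, 1, function(x) sum(x == 1))
    expect_true(all(a$chao1 >= a$observed_otus))
    expect_equal(a$chao1 == a$observed_otus, unname(f1 == 0))
  }
})

test_that("Shannon entropy is maximal at the uniform composition", {
  # exhaustive sweep over 3-taxon compositions of 12 reads
  grid <- do.call(rbind, lapply(0:12, function(i) {
    do.call(rbind, lapply(0:(12 - i), function(j) c(i, j, 12 - i - j)))
  }))
  grid <- grid[rowSums(grid > 0) == 3, ]
  H <- apply(grid, 1, function(x) {
    alpha_diversity(make_counts(matrix(x, 1, 3)))$shannon
  })
  expect_equal(unname(grid[which.max(H), ]), c(4, 4, 4))
})

test_that("rarefaction subsamples without replacement, reproducibly", {
  tab <- make_counts(matrix(c(8, 2, 0, 4, 4, 2), 2, 3, byrow = TRUE))
  expect_equal(unclass(rarefy(tab, 10, seed = 1)), unclass(tab))  # exhaustive
  r <- rarefy(tab, 5, seed = 3)
  expect_equal(unname(rowSums(r)), c(5, 5))
  expect_true(all(r <= tab))
  expect_identical(unclass(rarefy(tab, 5, seed = 3)),
                   unclass(rarefy(tab, 5, seed = 3)))
  expect_error(rarefy(tab, 0), "positive")
  expect_error(rarefy(tab, 11), "below depth")
  expect_equal(nrow(rarefy(make_counts(matrix(c(9, 3, 3, 1), 2, 2)), 10,
                           drop_small = TRUE)),
               1)

  # mean rarefied count matches the hypergeometric expectation depth * p_i
  x <- make_counts(matrix(c(60, 30, 10), 1, 3))
  depth <- 20
  draws <- sapply(1:200, function(s) rarefy(x, depth, seed = s)[1, ])
  p <- c(0.6, 0.3, 0.1)
  se <- sqrt(depth * p * (1 - p) * (100 - depth) / 99) / sqrt(200)
  expect_true(all(abs(rowMeans(draws) - depth * p) < 3.5 * se + 1e-9))
})

test_that("rarefaction curves are anchored and monotone", {
  tab <- random_table(4, 25, seed = 9)
  depths <- c(1, 5, 10, 20, min(rowSums(tab)))
  rc <- rarefaction_curve(tab, depths, reps = 20, seed = 2)
  expect_equal(unname(rc[, "1"]), rep(1, 4))
  for (sm in rownames(tab)) {
    N <- sum(tab[sm, ])
    full <- rarefaction_curve(tab[sm, , drop = FALSE], N, reps = 2, seed = 1)
    expect_equal(full[1, 1], sum(tab[sm, ] > 0))
    expect_true(all(diff(rc[sm, !is.na(rc[sm, ])]) >= 0))
  }
  expect_warning(rarefaction_curve(tab, c(5, 1e6), reps = 2, seed = 1),
                 "skipped")
})

test_that("beta diversity matches the defining formulas and stays bounded", {
  x <- make_counts(matrix(c(5, 3, 0, 2, 0, 4), 2, 3, byrow = TRUE))
  bc <- beta_diversity(x, "braycurtis")
  expect_equal(bc[1, 2], 10 / 14)

  pres <- make_counts(matrix(c(1, 1, 1, 0, 0, 1, 1, 1), 2, 4, byrow = TRUE))
  jc <- beta_diversity(pres, "jaccard")
  expect_equal(jc[1, 2], 0.5)  # 1 - 2/4

  same <- make_counts(matrix(c(3, 1, 3, 1), 2, 2, byrow = TRUE))
  expect_equal(beta_diversity(same, "jaccard")[1, 2], 0)
  expect_equal(beta_diversity(same, "braycurtis")[1, 2], 0)

  for (s in 1:10) {
    tab <- random_table(5, 15, seed = 100 + s)
    for (metric in c("jaccard", "braycurtis")) {
      d <- beta_diversity(tab, metric)
      expect_true(all(d >= 0 & d <= 1))
      expect_equal(d, t(d))
    }
    # triangle inequality for binary Jaccard, spot-checked over all triples
    d <- beta_diversity(tab, "jaccard")
    for (tri in combn(5, 3, simplify = FALSE)) {
      expect_lte(d[tri[1], tri[3]],
                 d[tri[1], tri[2]] + d[tri[2], tri[3]] + 1e-12)
    }
  }
  expect_error(beta_diversity(make_counts(matrix(c(0, 0, 1, 1), 2, 2,
                                                 byrow = TRUE))),
               "zero total")
})
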