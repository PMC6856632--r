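test_that("PCoA recovers Euclidean configurations exactly", {
  # three collinear points: one-dimensional configuration
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  ord <- pcoa(d, n_axes = 1)
  expect_equal(unname(ord$axis_proportions[1]), 1, tolerance = 1e-12)

  set.seed(4)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, n_axes = 2)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)

  expect_true(all(diff(ord$axis_proportions) <= 1e-12))
  expect_error(pcoa(d, n_axes = 10), "below the number of samples")
  # collinear input has one positive eigenvalue: extra axes are truncated
  dcol <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(ord1 <- pcoa(dcol, n_axes = 2), "truncated")
  expect_equal(ord1$n_axes, 1)
})

test_that("NMDS reaches near-zero stress on rank-embeddable input", {
  pts <- seq_len(8)
  d <- abs(outer(pts, pts, "-"))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  ord <- nmds(d, k = 1, n_restarts = 10, seed = 2)
  expect_lt(ord$stress, 0.01)
  expect_identical(ord$coordinates,
                   nmds(d, k = 1, n_restarts = 10, seed = 2)$coordinates)
})

test_that("ANOSIM saturates at complete separation and wraps the permutation p", {
  # all between-group distances strictly exceed all within-group distances
  d <- matrix(5, 6, 6)
  d[1:3, 1:3] <- 1
  d[4:6, 4:6] <- 1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- setNames(rep(c("a", "b"), each = 3), rownames(d))
  res <- anosim(d, g, n_perm = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p, 1 / 200)  # permutation p floor
  expect_error(anosim(d, setNames(c("a", rep("b", 5)), rownames(d))),
               "fewer than 2")
})

test_that("PERMDISP contrasts group dispersions around centroids", {
  set.seed(9)
  a <- matrix(rnorm(20), 10, 2)
  mirror <- rbind(a, a %*% diag(c(-1, 1)) + 10)  # same dispersion by symmetry
  d <- as.matrix(dist(mirror))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  g <- setNames(rep(c("x", "y"), each = 10), rownames(d))

  null_ok <- vapply(1:60, function(s) {
    permdisp(d, g, n_perm = 199, seed = s)$p > 0.05
  }, logical(1))
  expect_gte(mean(null_ok), 0.9)

  # statistic flips sign when the labels swap
  r1 <- permdisp(d, g, n_perm = 99, seed = 1)
  g2 <- setNames(ifelse(g == "x", "y", "x"), names(g))
  r2 <- permdisp(d, g2, n_perm = 99, seed = 1)
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)

  # power: one group inflated fivefold around its centroid
  power_ok <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    a <- matrix(rnorm(20), 10, 2)
    b <- matrix(rnorm(20), 10, 2) * 5
    d <- as.matrix(dist(rbind(a, b + 10)))
    dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
    permdisp(d, g, n_perm = 199, seed = s)$p <= 0.05
  }, logical(1))
  expect_gte(mean(power_ok), 0.9)
})

test_that("Mantel correlations respect identity, monotonicity and labels", {
  set.seed(11)
  pts <- matrix(rnorm(16), 8, 2)
  d1 <- as.matrix(dist(pts))
  dimnames(d1) <- list(paste0("s", 1:8), paste0("s", 1:8))
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$r, 1)
  d2 <- sqrt(d1)  # monotone transform: rank correlation stays perfect
  expect_equal(mantel_test(d1, d2, method = "spearman",
                           n_perm = 99, seed = 1)$r, 1)
  d3 <- d1
  dimnames(d3) <- list(paste0("x", 1:8), paste0("x", 1:8))
  expect_error(mantel_test(d1, d3), "mismatched labels")
})

test_that("geographic distances follow the haversine closed form", {
  md <- data.frame(sample = c("a", "b"), latitude = c(-70, -71),
                   longitude = c(170, 170))
  d <- geo_distance_matrix(md)
  expect_equal(d["a", "b"], 6371 * pi / 180, tolerance = 1e-4)
  expect_equal(diag(d), c(a = 0, b = 0))

  md2 <- data.frame(sample = c("a", "b"), latitude = c(-70, NA),
                    longitude = c(170, 170))
  expect_error(geo_distance_matrix(md2), "b")
})

test_that("environmental Spearman correlations match a rank-then-Pearson oracle", {
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(12)
    y <- rnorm(12)
    ours <- suppressWarnings(cor.test(x, y, method = "spearman"))$estimate
    oracle <- cor(rank(x), rank(y), method = "pearson")
    expect_lt(abs(ours - oracle), 1e-12)
  }

  md <- generate_environment(seed = 2)
  alpha <- data.frame(sample = md$sample,
                      chao1 = 2 * md$temperature + 5,  # monotone in temp
                      ace = -md$temperature,
                      shannon = rnorm(13), simpson = runif(13))
  res <- env_correlations(alpha, md)
  expect_equal(res$rho[res$var_a == "temperature" & res$var_b == "chao1"], 1)
  expect_equal(res$rho[res$var_a == "temperature" & res$var_b == "ace"], -1)
  expect_true(all(c("diversity", "environment") %in% res$type))

  md$pH <- 8  # constant: undefined, flagged for every pair it enters
  w <- capture_warnings(res <- env_correlations(alpha, md))
  expect_true(all(grepl("constant", w)) && length(w) > 0)
  expect_true(anyNA(res$rho[res$var_a == "pH"]))
})

test_that("ANCOM flags the planted taxon and respects compositionality", {
  set.seed(5)
  base <- matrix(rpois(10 * 12, 50), 10, 12)
  shifted <- base
  shifted[6:10, 1] <- shifted[6:10, 1] * 100  # lone 100-fold shift in group b
  tab <- make_counts(shifted)
  g <- setNames(rep(c("a", "b"), each = 5), rownames(tab))
  res <- ancom(tab, g)
  expect_equal(res$taxon[which.max(res$W)], "t1")
  expect_equal(max(res$W), max(res$W[res$taxon == "t1"]))

  # identical compositions: nothing significant
  same <- make_counts(matrix(rep(c(30, 20, 10, 5), each = 8), 8, 4))
  gs <- setNames(rep(c("a", "b"), each = 4), rownames(same))
  expect_true(all(!ancom(same, gs)$significant))

  # per-sample scaling leaves W unchanged (log-ratio invariance)
  scaled <- tab
  scaled[3, ] <- scaled[3, ] * 10
  expect_equal(ancom(make_counts(scaled), g)$W, res$W)

  expect_error(ancom(tab, setNames(c(rep("a", 2), rep("b", 8)), rownames(tab))),
               ">= 3")
})
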