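check_groups <- function(dist, groups, min_size = 2L) {
  d <- as_dist_matrix(dist)
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  if (length(groups) != nrow(d) || anyNA(groups)) {
    stop("groups must cover every sample in the distance matrix", call. = FALSE)
  }
  sizes <- table(groups)
  if (any(sizes < min_size)) {
    stop("group(s) with fewer than ", min_size, " members: ",
         paste(names(sizes)[sizes < min_size], collapse = ", "), call. = FALSE)
  }
  list(d = d, groups = as.character(groups))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between- versus within-group dissimilarities
#' (via [vegan::anosim]); `R = 1` means all between-group distances exceed
#' all within-group ones, `R = 0` means no separation. The permutation p is
#' `(1 + #{perm R >= R_obs}) / (1 + n_perm)`.
#'
#' @param dist square symmetric distance matrix.
#' @param groups group label per sample (named vectors are aligned by name);
#'   >= 2 groups, each with >= 2 members.
#' @param n_perm label permutations.
#' @param seed integer seed.
#' @return list with `R` and `p`.
#' @export
anosim <- function(dist, groups, n_perm = 999L, seed = 1L) {
  ck <- check_groups(dist, groups)
  if (length(unique(ck$groups)) < 2L) stop("need >= 2 groups", call. = FALSE)
  set.seed(derive_seed(seed, "anosim"))
  fit <- vegan::anosim(as.dist(ck$d), grouping = factor(ck$groups),
                       permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif)
}

#' Permutation test of multivariate group dispersion (PERMDISP)
#'
#' Embeds the distance matrix by principal coordinates (with the standard
#' signed handling of negative eigenvalues, via [vegan::betadisper] with
#' centroid centering), measures each sample's distance to its group
#' centroid, and contrasts the two groups with a two-sample t statistic whose
#' p-value comes from permuting group labels over those distances.
#'
#' @param dist square symmetric distance matrix.
#' @param groups exactly 2 groups, each with >= 2 members.
#' @param n_perm label permutations.
#' @param seed integer seed.
#' @return list with `statistic` (t), `p`, and per-sample `distances` to the
#'   group centroid.
#' @export
permdisp <- function(dist, groups, n_perm = 999L, seed = 1L) {
  ck <- check_groups(dist, groups)
  lev <- unique(ck$groups)
  if (length(lev) != 2L) {
    stop("t-statistic PERMDISP requires exactly 2 groups", call. = FALSE)
  }
  bd <- vegan::betadisper(as.dist(ck$d), group = factor(ck$groups, levels = lev),
                          type = "centroid")
  z <- bd$distances
  tstat <- function(g) {
    a <- z[g == lev[1L]]
    b <- z[g == lev[2L]]
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  t_obs <- tstat(ck$groups)
  set.seed(derive_seed(seed, "permdisp"))
  t_perm <- vapply(seq_len(n_perm), function(i) tstat(sample(ck$groups)),
                   numeric(1))
  p <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + n_perm)
  list(statistic = unname(t_obs), p = p, distances = z)
}

#' Mantel test between two distance matrices
#'
#' Correlates the off-diagonal entries of two distance matrices over the same
#' samples (via [vegan::mantel]); significance by jointly permuting the rows
#' and columns of one matrix.
#'
#' @param d1,d2 square symmetric distance matrices with identical labels in
#'   identical order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  d1 <- as_dist_matrix(d1)
  d2 <- as_dist_matrix(d2)
  if (!identical(rownames(d1), rownames(d2))) {
    stop("distance matrices have mismatched labels", call. = FALSE)
  }
  set.seed(derive_seed(seed, "mantel"))
  fit <- vegan::mantel(as.dist(d1), as.dist(d2), method = method,
                       permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif)
}

#' Great-circle distance matrix between samples, in km
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param metadata data.frame with `sample`, `latitude`, `longitude`.
#' @return square symmetric matrix of distances in km.
#' @export
geo_distance_matrix <- function(metadata) {
  need <- c("sample", "latitude", "longitude")
  stopifnot(all(need %in% names(metadata)))
  bad <- metadata$sample[!is.finite(metadata$latitude) |
                           !is.finite(metadata$longitude)]
  if (length(bad)) {
    stop("missing coordinates for sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pts <- cbind(metadata$longitude, metadata$latitude)
  d <- geosphere::distm(pts, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371000)
  }) / 1000
  dimnames(d) <- list(metadata$sample, metadata$sample)
  as_dist_matrix(d, tol = 1e-6, what = "geographic distance matrix")
}

#' Absolute-difference distance matrix of a scalar variable
#'
#' The standard single-variable design for Mantel tests against community
#' dissimilarity.
#'
#' @param values named numeric vector (names are sample labels).
#' @return square symmetric matrix of `|x_i - x_j|`.
#' @export
env_distance_matrix <- function(values) {
  stopifnot(!is.null(names(values)))
  d <- abs(outer(values, values, "-"))
  dimnames(d) <- list(names(values), names(values))
  as_dist_matrix(d)
}

#' Spearman correlations of environmental variables with diversity indices
#'
#' Every environmental variable against every alpha-diversity index, plus
#' every variable-variable pair. p-values follow [stats::cor.test]
#' (exact where the sample size and ties allow, asymptotic otherwise).
#' Constant vectors yield `NA` correlations with a warning.
#'
#' @param alpha data.frame from [alpha_diversity].
#' @param metadata metadata data.frame covering the same samples.
#' @param variables environmental columns to use; defaults to the standard
#'   set intersected with what `metadata` carries.
#' @param indices alpha columns to use.
#' @return data.frame with `var_a`, `var_b`, `type` (`"diversity"` or
#'   `"environment"`), `rho`, `p`.
#' @export
env_correlations <- function(alpha, metadata,
                             variables = c("salinity", "temperature", "pH",
                                           "depth", "chlorophyll", "cdom"),
                             indices = c("chao1", "ace", "shannon", "simpson")) {
  variables <- intersect(variables, names(metadata))
  stopifnot(length(variables) > 0L, all(indices %in% names(alpha)))
  common <- intersect(alpha$sample, metadata$sample)
  if (length(common) < 4L) stop("need >= 4 samples in common", call. = FALSE)
  alpha <- alpha[match(common, alpha$sample), , drop = FALSE]
  metadata <- metadata[match(common, metadata$sample), , drop = FALSE]
  one <- function(x, y, a, b, type) {
    if (length(unique(x[!is.na(x)])) < 2L || length(unique(y[!is.na(y)])) < 2L) {
      warning("constant variable in pair ", a, " / ", b, "; rho undefined")
      return(data.frame(var_a = a, var_b = b, type = type,
                        rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    data.frame(var_a = a, var_b = b, type = type,
               rho = unname(ct$estimate), p = ct$p.value)
  }
  rows <- list()
  for (v in variables) for (ix in indices) {
    rows[[length(rows) + 1L]] <- one(metadata[[v]], alpha[[ix]], v, ix,
                                     "diversity")
  }
  if (length(variables) > 1L) {
    for (i in seq_len(length(variables) - 1L)) {
      for (j in (i + 1L):length(variables)) {
        rows[[length(rows) + 1L]] <- one(metadata[[variables[i]]],
                                         metadata[[variables[j]]],
                                         variables[i], variables[j],
                                         "environment")
      }
    }
  }
  do.call(rbind, rows)
}
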