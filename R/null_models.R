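#' Configure the null models
#'
#' @param n_null number of null iterations (default 999, giving 0.001
#'   resolution on the Raup-Crick scale).
#' @param abundance_weighted weight betaMNTD by within-sample relative
#'   abundances (default) or treat all present taxa equally.
#' @param seed integer seed controlling all null draws.
#' @param tie_epsilon tolerance within which a null Bray-Curtis value counts
#'   as tied with the observed one (half weight in the empirical CDF).
#' @return a list of class `"null_model_config"`.
#' @export
null_model_config <- function(n_null = 999L, abundance_weighted = TRUE,
                              seed = 1L, tie_epsilon = 1e-10) {
  stopifnot(n_null >= 1L, tie_epsilon >= 0)
  structure(list(n_null = as.integer(n_null),
                 abundance_weighted = isTRUE(abundance_weighted),
                 seed = as.integer(seed), tie_epsilon = tie_epsilon),
            class = "null_model_config")
}

#' Patristic (path-length) distances between tree tips
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param taxa tip labels to include; defaults to all tips.
#' @return square symmetric matrix of path branch-length sums.
#' @export
patristic_distances <- function(tree, taxa = tree$tip.label) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)[taxa, taxa, drop = FALSE]
  as_dist_matrix(d, tol = 1e-8, what = "patristic matrix")
}

# relative abundances per sample, checking coverage of the distance matrix
rel_abund <- function(table, dists = NULL) {
  table <- otu_table(table)
  if (any(rowSums(table) == 0)) {
    stop("sample(s) with zero total count", call. = FALSE)
  }
  if (!is.null(dists)) {
    present <- colnames(table)[colSums(table) > 0]
    missing <- setdiff(present, rownames(dists))
    if (length(missing)) {
      stop("taxa missing from distance matrix: ",
           paste(head(missing, 5L), collapse = ", "), call. = FALSE)
    }
  }
  unclass(table) / rowSums(table)
}

#' Beta mean nearest-taxon distance (betaMNTD)
#'
#' For samples k and m with present-taxon sets `Tk`, `Tm` and within-sample
#' relative abundances `f`:
#' `betaMNTD = 0.5 * [sum_{i in Tk} f_ik min_{j in Tm} d_ij +
#'                    sum_{j in Tm} f_jm min_{i in Tk} d_ij]`.
#' The unweighted variant replaces `f` with `1/|T|`.
#'
#' @param table an [otu_table].
#' @param dists taxon distance matrix covering every taxon present in the
#'   table (usually [patristic_distances]).
#' @param abundance_weighted logical.
#' @return square symmetric samples x samples matrix.
#' @export
beta_mntd <- function(table, dists, abundance_weighted = TRUE) {
  table <- otu_table(table)
  rel <- rel_abund(table, dists)
  D <- as_dist_matrix(dists, tol = 1e-8, what = "taxon distance matrix")
  D <- D[colnames(table), colnames(table), drop = FALSE]
  out <- cpp_bmntd(rel, D, abundance_weighted)
  dimnames(out) <- list(rownames(table), rownames(table))
  out
}

#' Beta nearest-taxon index (betaNTI)
#'
#' z-score of the observed [beta_mntd] against a null distribution obtained
#' by shuffling taxon identities across the patristic distance matrix
#' (permuting tip labels over the table's whole taxon pool) with abundances
#' held fixed. The same permutation is applied to every sample pair within an
#' iteration, so all pairs are tested against one common metacommunity
#' randomization. `|betaNTI| > 2` is the conventional evidence threshold for
#' deterministic selection.
#'
#' Pairs whose null distribution has zero spread (e.g. a star phylogeny,
#' where every permutation leaves all distances unchanged) are returned as
#' `NA` with a warning.
#'
#' @param table an [otu_table].
#' @param tree an [ape::phylo] tree whose tips cover the table's taxa.
#' @param config a [null_model_config].
#' @return square symmetric z-score matrix (`NA` diagonal).
#' @export
beta_nti <- function(table, tree, config = null_model_config()) {
  stopifnot(inherits(config, "null_model_config"))
  table <- otu_table(table)
  D <- patristic_distances(tree, colnames(table))
  rel <- rel_abund(table, D)
  n_taxa <- ncol(table)
  set.seed(derive_seed(config$seed, "bnti"))
  perms <- matrix(0L, config$n_null, n_taxa)
  for (it in seq_len(config$n_null)) {
    perms[it, ] <- sample.int(n_taxa) - 1L  # 0-based for the C++ kernel
  }
  nul <- cpp_bnti_null(rel, D, perms, config$abundance_weighted)
  z <- (nul$obs - nul$mean) / nul$sd
  # zero within floating-point accumulation noise counts as degenerate; any
  # genuine null spread is orders of magnitude above this floor
  degen <- nul$sd <= 1e-7 * (1 + abs(nul$mean))
  if (any(degen & upper.tri(degen))) {
    warning(sum(degen & upper.tri(degen)),
            " pair(s) have a degenerate null (sd = 0); betaNTI reported as NA")
    z[degen] <- NA_real_
  }
  diag(z) <- NA_real_
  dimnames(z) <- list(rownames(table), rownames(table))
  z
}

# one null community: S distinct taxa chosen proportional to occupancy, one
# read each, remaining reads filled proportional to pool-wide relative
# abundance among the chosen taxa
rc_null_community <- function(n_taxa, richness, reads, occupancy, relab_total) {
  sel <- sample.int(n_taxa, richness, prob = occupancy)
  x <- numeric(n_taxa)
  x[sel] <- 1
  if (reads > richness) {
    x[sel] <- x[sel] + rmultinom(1, reads - richness, relab_total[sel])
  }
  x
}

#' Raup-Crick index on Bray-Curtis dissimilarity (RC-Bray)
#'
#' For each sample pair, the observed Bray-Curtis dissimilarity is ranked
#' within a null distribution of dissimilarities between probabilistically
#' assembled communities that preserve each sample's observed richness and
#' read total: taxa are drawn without replacement with probability
#' proportional to occupancy (number of samples containing the taxon), seeded
#' with one read each, and the remaining reads are distributed proportional
#' to each taxon's pool-wide relative abundance. The empirical CDF position
#' (ties at half weight within `tie_epsilon`) is rescaled to `[-1, 1]`;
#' `|RC| > 0.95` flags a significant departure from this null.
#'
#' Null draws stream pair-by-pair on per-pair derived seeds, so results do
#' not depend on evaluation order.
#'
#' @param table an [otu_table] with >= 2 non-empty samples.
#' @param config a [null_model_config].
#' @return square symmetric matrix of RC values in `[-1, 1]` (`NA` diagonal).
#' @export
rc_bray <- function(table, config = null_model_config()) {
  stopifnot(inherits(config, "null_model_config"))
  table <- otu_table(table)
  if (nrow(table) < 2L) stop("need at least 2 samples", call. = FALSE)
  counts <- unclass(table)
  if (any(rowSums(counts) == 0)) stop("sample(s) with zero total count", call. = FALSE)
  n_taxa <- ncol(counts)
  occupancy <- colSums(counts > 0)
  relab_total <- colSums(counts) / sum(counts)
  richness <- rowSums(counts > 0)
  reads <- rowSums(counts)
  if (any(richness > sum(occupancy > 0))) {
    stop("observed richness exceeds the occupied taxon pool", call. = FALSE)
  }
  samples <- rownames(counts)
  n <- length(samples)
  bc <- function(x, y) sum(abs(x - y)) / sum(x + y)
  out <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  for (k in seq_len(n - 1L)) {
    for (m in (k + 1L):n) {
      bc_obs <- bc(counts[k, ], counts[m, ])
      set.seed(derive_seed(config$seed, paste("rc", samples[k], samples[m])))
      bc_null <- vapply(seq_len(config$n_null), function(it) {
        xk <- rc_null_community(n_taxa, richness[k], reads[k], occupancy,
                                relab_total)
        xm <- rc_null_community(n_taxa, richness[m], reads[m], occupancy,
                                relab_total)
        bc(xk, xm)
      }, numeric(1))
      ties <- abs(bc_null - bc_obs) <= config$tie_epsilon
      rc_raw <- (sum(bc_null < bc_obs & !ties) + 0.5 * sum(ties)) / config$n_null
      out[k, m] <- out[m, k] <- 2 * (rc_raw - 0.5)
    }
  }
  out
}
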