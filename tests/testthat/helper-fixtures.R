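# Shared fixtures and independent oracles used across test files.

# small labelled count matrix
make_counts <- function(mat, samples = NULL, taxa = NULL) {
  samples <- samples %||% paste0("S", seq_len(nrow(mat)))
  taxa <- taxa %||% paste0("t", seq_len(ncol(mat)))
  dimnames(mat) <- list(samples, taxa)
  mat
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random table with guaranteed non-empty samples
random_table <- function(n_samples, n_taxa, seed, lambda = 3) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
    if (all(rowSums(m) > 0)) break
  }
  make_counts(m)
}

# four-tip balanced tree used in the hand-worked examples
balanced_tree4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# Independent betaMNTD oracle: explicit double loop over taxa, written from
# the definition, sharing no code with the package implementation.
bmntd_oracle <- function(counts, D, weighted = TRUE) {
  rel <- counts / rowSums(counts)
  n <- nrow(counts)
  out <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (k in seq_len(n)) for (m in seq_len(n)) {
    if (k >= m) next
    tk <- colnames(counts)[counts[k, ] > 0]
    tm <- colnames(counts)[counts[m, ] > 0]
    s1 <- 0
    for (i in tk) {
      dmin <- min(sapply(tm, function(j) D[i, j]))
      s1 <- s1 + (if (weighted) rel[k, i] else 1 / length(tk)) * dmin
    }
    s2 <- 0
    for (j in tm) {
      dmin <- min(sapply(tk, function(i) D[i, j]))
      s2 <- s2 + (if (weighted) rel[m, j] else 1 / length(tm)) * dmin
    }
    out[k, m] <- out[m, k] <- 0.5 * (s1 + s2)
  }
  out
}

# reduced-size simulation shared by calibration-style tests
small_sim_config <- function(regime, seed, ...) {
  simulation_config(regime, n_taxa = 100L,
                    group_sizes = c(inshore = 8L, offshore = 5L),
                    depth = 5000L, seed = seed, ...)
}
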