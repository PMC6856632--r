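#' @useDynLib microassembly, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test cmdscale p.adjust rnorm runif rlnorm
#'   rmultinom sd setNames t.test wilcox.test var as.dist
#' @importFrom utils read.delim write.table head
NULL

#' Derive a stage-specific RNG seed from a global seed
#'
#' One top-level integer seed is expanded into independent per-stage seeds by
#' hashing the stage label into the multiplicative congruential orbit of the
#' seed. This keeps every stochastic stage reproducible on its own while all
#' stages remain controlled by a single user-facing seed.
#'
#' @param seed integer global seed.
#' @param label character stage label (e.g. `"tree"`, `"rc:JB01:R02"`).
#' @return an integer in `[0, 2^31 - 2]`, suitable for `set.seed()`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed %% m)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% m
  }
  as.integer((h * 48271 + 11) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a square labelled distance-like matrix; returns it with dimnames.
as_dist_matrix <- function(x, tol = 1e-9, what = "distance matrix") {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop(what, " must be square", call. = FALSE)
  }
  if (is.null(rownames(x)) && is.null(colnames(x))) {
    rownames(x) <- colnames(x) <- paste0("item", seq_len(nrow(x)))
  }
  if (is.null(rownames(x))) rownames(x) <- colnames(x)
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  if (!identical(rownames(x), colnames(x))) {
    stop(what, ": row and column labels disagree", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(what, ": duplicate labels", call. = FALSE)
  }
  off <- x[is.finite(x) & is.finite(t(x))]
  if (max(abs(x - t(x)), na.rm = TRUE) > tol) {
    stop(what, " is not symmetric within tolerance ", tol, call. = FALSE)
  }
  if (any(diag(x) != 0, na.rm = TRUE)) {
    stop(what, " has a non-zero diagonal", call. = FALSE)
  }
  x
}

# Upper-triangle (i < j) index pairs of an n x n matrix, as a 2-column matrix.
pair_indices <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
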