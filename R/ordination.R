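#' Principal coordinates analysis (PCoA)
#'
#' Double-centers `-D^2 / 2` and eigendecomposes it (via [stats::cmdscale]);
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues, and axis proportions are positive eigenvalues over their sum.
#' Negative eigenvalues are reported, not corrected.
#'
#' @param dist square symmetric distance matrix.
#' @param n_axes axes to return (must be < number of samples).
#' @return list of class `"ordination_result"`: `method`, `coordinates`
#'   (samples x axes), `axis_proportions`, `eigenvalues` (all, including
#'   negatives), `n_axes`.
#' @export
pcoa <- function(dist, n_axes = 2L) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (n_axes >= n) stop("n_axes must be below the number of samples", call. = FALSE)
  fit <- withCallingHandlers(
    cmdscale(as.dist(d), k = n - 1L, eig = TRUE),
    # negative eigenvalues of semi-metric input are expected and reported
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  eig <- fit$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  k <- min(n_axes, length(pos))
  if (k < n_axes) {
    warning("only ", length(pos), " positive eigenvalue(s); axes truncated")
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(method = "pcoa", coordinates = coords,
                 axis_proportions = pos[seq_len(k)] / sum(pos),
                 eigenvalues = eig, n_axes = k),
            class = "ordination_result")
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Minimizes Kruskal stress-1 with monotone regression on distance ranks
#' (via [vegan::monoMDS], global model), keeping the best of `n_restarts`
#' random initial configurations. Stress is reported as a proportion.
#'
#' @param dist square symmetric distance matrix.
#' @param k number of axes (>= 1).
#' @param n_restarts random restarts.
#' @param seed integer seed; identical seeds give identical coordinates.
#' @return list of class `"ordination_result"`: `method`, `coordinates`,
#'   `stress`, `converged`, `n_axes`.
#' @export
nmds <- function(dist, k = 2L, n_restarts = 20L, seed = 1L) {
  d <- as_dist_matrix(dist)
  stopifnot(k >= 1L, n_restarts >= 1L)
  n <- nrow(d)
  set.seed(derive_seed(seed, "nmds"))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- matrix(rnorm(n * k), n, k)
    fit <- vegan::monoMDS(as.dist(d), y = init, k = k, model = "global")
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$points
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(method = "nmds", coordinates = coords, stress = best$stress,
                 converged = best$maxits > best$iters, n_axes = k),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n", toupper(x$method),
              nrow(x$coordinates), x$n_axes))
  if (x$method == "pcoa") {
    cat("axis proportions:",
        paste(sprintf("%.2f%%", 100 * x$axis_proportions), collapse = " "), "\n")
  } else {
    cat(sprintf("stress: %.4f\n", x$stress))
  }
  invisible(x)
}
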