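#' Per-sample alpha-diversity estimators
#'
#' Computes, per sample: observed OTUs, Chao1 (classic form, with the
#' bias-corrected fallback `S + F1 (F1 - 1) / 2` when no doubletons are
#' present), ACE with the conventional 10-read rare/abundant split, Shannon
#' entropy (log base 2 by default), the Gini-Simpson index `1 - sum(p^2)`,
#' and Good's coverage `1 - F1 / N`.
#'
#' ACE is undefined when every rare-class read is a singleton (its sample
#' coverage term hits zero); such samples get `NA` with a warning rather than
#' an invented value.
#'
#' @param table an [otu_table] (or samples x taxa count matrix).
#' @param shannon_base logarithm base for Shannon entropy.
#' @param rare_threshold maximum count for the ACE "rare" class.
#' @return data.frame with one row per sample: `sample`, `observed_otus`,
#'   `chao1`, `ace`, `shannon`, `simpson`, `goods_coverage`.
#' @export
alpha_diversity <- function(table, shannon_base = 2, rare_threshold = 10) {
  table <- otu_table(table)
  out <- lapply(rownames(table), function(sm) {
    x <- table[sm, ]
    N <- sum(x)
    if (N == 0) stop("sample '", sm, "' has zero total count", call. = FALSE)
    x <- x[x > 0]
    p <- x / N
    s_obs <- length(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
    rare <- x[x <= rare_threshold]
    s_rare <- length(rare)
    s_abund <- s_obs - s_rare
    n_rare <- sum(rare)
    if (s_rare == 0) {
      ace <- s_obs
    } else {
      c_ace <- 1 - f1 / n_rare
      if (c_ace <= 0) {
        warning("sample '", sm, "': ACE undefined (all rare reads are singletons)")
        ace <- NA_real_
      } else {
        fk <- tabulate(rare, nbins = rare_threshold)
        gamma2 <- max(
          (s_rare / c_ace) *
            sum(seq_len(rare_threshold) * (seq_len(rare_threshold) - 1) * fk) /
            (n_rare * (n_rare - 1)) - 1,
          0)
        ace <- s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
      }
    }
    data.frame(sample = sm, observed_otus = s_obs, chao1 = chao1, ace = ace,
               shannon = -sum(p * log(p, base = shannon_base)),
               simpson = 1 - sum(p^2),
               goods_coverage = 1 - f1 / N)
  })
  out <- do.call(rbind, out)
  rownames(out) <- out$sample
  out
}

#' Rarefy an OTU table by subsampling without replacement
#'
#' @param table an [otu_table].
#' @param depth target reads per sample (> 0).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param drop_small drop samples whose total is below `depth` (default
#'   errors instead).
#' @return a rarefied [otu_table] whose row sums all equal `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L, drop_small = FALSE) {
  table <- otu_table(table)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  totals <- rowSums(table)
  small <- totals < depth
  if (any(small)) {
    if (!drop_small) {
      stop("samples below depth ", depth, ": ",
           paste(rownames(table)[small], collapse = ", "), call. = FALSE)
    }
    table <- table[!small, , drop = FALSE]
    if (nrow(table) == 0L) stop("no samples at or above depth", call. = FALSE)
  }
  set.seed(derive_seed(seed, "rarefy"))
  out <- withCallingHandlers(
    vegan::rrarefy(unclass(table), depth),
    # vegan guesses at non-count input from the smallest count; our
    # constructor already guarantees integer counts
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  otu_table(out)
}

#' Mean rarefied richness across subsampling depths
#'
#' For each sample and each requested depth, draws `reps` independent
#' subsamples without replacement and records the mean observed richness.
#' Depths exceeding a sample's total are skipped (returned as `NA`) with a
#' warning.
#'
#' @param table an [otu_table].
#' @param depths integer vector of subsampling depths.
#' @param reps subsamples per depth (>= 1).
#' @param seed integer seed.
#' @return matrix, samples x depths, of mean observed richness.
#' @export
rarefaction_curve <- function(table, depths, reps = 10L, seed = 1L) {
  table <- otu_table(table)
  stopifnot(reps >= 1L, all(depths >= 1))
  depths <- as.integer(sort(unique(depths)))
  set.seed(derive_seed(seed, "rarecurve"))
  out <- matrix(NA_real_, nrow(table), length(depths),
                dimnames = list(rownames(table), as.character(depths)))
  skipped <- FALSE
  for (sm in rownames(table)) {
    x <- table[sm, ]
    N <- sum(x)
    pool <- rep.int(seq_along(x), x)
    for (d in seq_along(depths)) {
      if (depths[d] > N) { skipped <- TRUE; next }
      out[sm, d] <- mean(vapply(seq_len(reps), function(r) {
        length(unique(pool[sample.int(N, depths[d])]))
      }, numeric(1)))
    }
  }
  if (skipped) warning("some depths exceed a sample total and were skipped")
  out
}

#' Taxonomic beta-diversity distance matrix
#'
#' Binary Jaccard (`1 - |intersection| / |union|` on presence/absence) or
#' abundance-based Bray-Curtis (`sum |x - y| / sum (x + y)`), both in
#' `[0, 1]`.
#'
#' @param table an [otu_table] with >= 2 samples, all totals > 0.
#' @param metric `"jaccard"` or `"braycurtis"`.
#' @return square symmetric distance matrix with sample labels.
#' @export
beta_diversity <- function(table, metric = c("jaccard", "braycurtis")) {
  table <- otu_table(table)
  metric <- match.arg(metric)
  if (nrow(table) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(rowSums(table) == 0)) {
    stop("sample(s) with zero total: ",
         paste(rownames(table)[rowSums(table) == 0], collapse = ", "),
         call. = FALSE)
  }
  d <- switch(metric,
              jaccard = vegan::vegdist(unclass(table), method = "jaccard",
                                       binary = TRUE),
              braycurtis = vegan::vegdist(unclass(table), method = "bray"))
  as_dist_matrix(as.matrix(d))
}
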