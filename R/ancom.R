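#' Analysis of composition of microbiomes (ANCOM)
#'
#' Compositional differential-abundance screen between two groups. After a
#' pseudocount of 1, every ordered taxon pair (i, j) is tested for a group
#' difference in `log((x_i + 1) / (x_j + 1))` with a two-sample Wilcoxon rank
#' test at level `alpha`; `W_i` counts how many of the `m - 1` tests
#' involving taxon i reject. Taxa with `W > w_fraction * (m - 1)` are flagged
#' significant. Because the statistic lives on log-ratios, it is insensitive
#' to per-sample scaling (library size).
#'
#' @param table an [otu_table]; taxa with zero total are dropped.
#' @param groups group label per sample (named vectors aligned by name);
#'   exactly 2 groups, each with >= 3 samples.
#' @param alpha per-pair test level.
#' @param w_fraction fraction of possible rejections needed to flag a taxon.
#' @return data.frame per taxon: `taxon`, `W`, `significant`.
#' @export
ancom <- function(table, groups, alpha = 0.05, w_fraction = 0.7) {
  table <- otu_table(table)
  if (!is.null(names(groups))) groups <- groups[rownames(table)]
  if (length(groups) != nrow(table) || anyNA(groups)) {
    stop("groups must cover every sample", call. = FALSE)
  }
  lev <- unique(as.character(groups))
  if (length(lev) != 2L) stop("exactly 2 groups required", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 3L)) stop("each group needs >= 3 samples", call. = FALSE)
  keep <- colSums(table) > 0
  counts <- unclass(table)[, keep, drop = FALSE]
  m <- ncol(counts)
  if (m < 2L) stop("need >= 2 non-empty taxa", call. = FALSE)
  lg <- log(counts + 1)
  g1 <- groups == lev[1L]
  W <- setNames(integer(m), colnames(counts))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      d <- lg[, i] - lg[, j]
      p <- suppressWarnings(wilcox.test(d[g1], d[!g1], exact = FALSE)$p.value)
      if (!is.na(p) && p < alpha) {
        W[i] <- W[i] + 1L
        W[j] <- W[j] + 1L
      }
    }
  }
  data.frame(taxon = names(W), W = unname(W),
             significant = unname(W) > w_fraction * (m - 1L),
             row.names = NULL)
}
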