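#' Build a Spearman co-occurrence network over taxa
#'
#' Taxa passing a prevalence floor are correlated pairwise (Spearman, on
#' within-sample relative abundances); p-values are Benjamini-Hochberg
#' adjusted and edges kept when `|rho| >= rho_threshold` and
#' `q <= q_threshold`, recording the correlation sign (positive =
#' co-occurrence, negative = competition/exclusion).
#'
#' @param table an [otu_table] with >= 5 samples.
#' @param rho_threshold minimum absolute Spearman correlation for an edge.
#' @param q_threshold maximum BH-adjusted p for an edge.
#' @param prevalence fraction of samples a taxon must occupy to enter the
#'   network (floor, default 1/3).
#' @return list of class `"cooccurrence_network"`: `nodes` (taxon, mean
#'   relative abundance, prevalence), `edges` (taxon_a, taxon_b, rho, p, q,
#'   sign), and the thresholds used.
#' @export
build_cooccurrence_network <- function(table, rho_threshold = 0.6,
                                       q_threshold = 0.05,
                                       prevalence = 1 / 3) {
  table <- otu_table(table)
  if (nrow(table) < 5L) stop("need >= 5 samples for a network", call. = FALSE)
  rel <- unclass(table) / rowSums(table)
  occ <- colMeans(unclass(table) > 0)
  keep <- occ >= prevalence & apply(rel, 2, function(v) length(unique(v)) > 1L)
  rel <- rel[, keep, drop = FALSE]
  m <- ncol(rel)
  nodes <- data.frame(taxon = colnames(rel),
                      mean_relab = colMeans(rel),
                      prevalence = occ[keep], row.names = NULL)
  edges <- data.frame(taxon_a = character(), taxon_b = character(),
                      rho = numeric(), p = numeric(), q = numeric(),
                      sign = character())
  if (m >= 2L) {
    idx <- pair_indices(m)
    rho <- p <- numeric(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      ct <- suppressWarnings(cor.test(rel[, idx[r, 1L]], rel[, idx[r, 2L]],
                                      method = "spearman"))
      rho[r] <- unname(ct$estimate)
      p[r] <- ct$p.value
    }
    q <- p.adjust(p, method = "BH")
    keep_e <- abs(rho) >= rho_threshold & q <= q_threshold & !is.na(rho)
    if (any(keep_e)) {
      edges <- data.frame(taxon_a = colnames(rel)[idx[keep_e, 1L]],
                          taxon_b = colnames(rel)[idx[keep_e, 2L]],
                          rho = rho[keep_e], p = p[keep_e], q = q[keep_e],
                          sign = ifelse(rho[keep_e] > 0, "positive",
                                        "negative"),
                          row.names = NULL)
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 rho_threshold = rho_threshold, q_threshold = q_threshold,
                 prevalence = prevalence),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (%d positive)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "positive")))
  invisible(x)
}

#' Detect network modules by seed-and-grow density clustering
#'
#' Each node is weighted by its core-clustering coefficient (the edge density
#' of the highest k-core of its closed neighborhood, which ignores weakly
#' attached pendant neighbors) times that core's k-core number. The
#' highest-weight unassigned node seeds a module, which grows by repeatedly
#' absorbing neighbors whose weight is at least `(1 - node_score_cutoff)`
#' times the seed weight; single-node "modules" are discarded, so isolated or
#' weakly embedded nodes stay unassigned.
#'
#' @param network a [build_cooccurrence_network] result.
#' @param node_score_cutoff growth tolerance in `[0, 1)`; larger values admit
#'   weaker neighbors.
#' @return data.frame per assigned node: `taxon`, `module` (integer id),
#'   `is_seed`. Zero rows when no module of size >= 2 exists.
#' @export
detect_modules <- function(network, node_score_cutoff = 0.2) {
  stopifnot(inherits(network, "cooccurrence_network"),
            node_score_cutoff >= 0, node_score_cutoff < 1)
  empty <- data.frame(taxon = character(), module = integer(),
                      is_seed = logical())
  if (nrow(network$edges) == 0L) return(empty)
  g <- igraph::graph_from_data_frame(
    network$edges[, c("taxon_a", "taxon_b")], directed = FALSE,
    vertices = data.frame(name = network$nodes$taxon))
  weight <- vapply(igraph::V(g)$name, function(v) {
    nb <- igraph::neighbors(g, v)$name
    if (length(nb) == 0L) return(0)
    sub <- igraph::induced_subgraph(g, c(v, nb))
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) return(0)
    core_sub <- igraph::induced_subgraph(sub, names(core)[core == kmax])
    igraph::edge_density(core_sub) * kmax
  }, numeric(1))
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- igraph::V(g)$name
  unassigned <- names(weight)
  out <- empty
  module_id <- 0L
  while (length(unassigned) > 0L && max(weight[unassigned]) > 0) {
    seed <- unassigned[which.max(weight[unassigned])]
    members <- seed
    floor_w <- (1 - node_score_cutoff) * weight[seed]
    repeat {
      nb <- unique(unlist(adj[members], use.names = FALSE))
      nb <- intersect(setdiff(nb, members), unassigned)
      grow <- nb[weight[nb] >= floor_w]
      if (length(grow) == 0L) break
      members <- c(members, grow)
    }
    unassigned <- setdiff(unassigned, members)
    if (length(members) >= 2L) {
      module_id <- module_id + 1L
      out <- rbind(out, data.frame(taxon = members, module = module_id,
                                   is_seed = members == seed))
    }
  }
  rownames(out) <- NULL
  out
}

#' Write network edges as a tab-separated edge list
#' @param network a [build_cooccurrence_network] result.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
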