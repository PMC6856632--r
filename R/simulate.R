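#' Configure a synthetic metacommunity simulation
#'
#' Bundles every parameter of the forward model under one seed. Defaults
#' mirror the design of the reference survey: 370 taxa in the regional pool,
#' 13 samples split 8 inshore / 5 offshore, and roughly 2e4 reads per sample.
#'
#' @param regime assembly regime: `"drift"`, `"heterogeneous_selection"`,
#'   `"homogeneous_selection"` or `"dispersal_limitation"`.
#' @param n_taxa size of the regional taxon pool (>= 4).
#' @param group_sizes named integer vector of samples per group; each >= 2.
#' @param depth reads drawn per sample.
#' @param selection_sd Gaussian environmental-filter width, trait units.
#' @param optima_gap distance between the two group trait optima under
#'   heterogeneous selection, trait units; default `3 * selection_sd`.
#' @param bm_rate Brownian-motion trait variance per unit branch length.
#' @param birth_rate speciation rate of the pure-birth tree.
#' @param dispersal_pool_fraction fraction of the pool reachable per sample
#'   under dispersal limitation, in `(0, 1]`.
#' @param lognormal_sigma log-scale SD of metacommunity abundances.
#' @param drift_sd log-scale SD of the independent per-sample abundance
#'   scatter (ecological drift) applied in every regime; 0 makes samples
#'   replicate multinomial draws from identical weights.
#' @param seed integer; the single seed controlling tree, traits,
#'   environment and counts.
#' @return a list of class `"simulation_config"`.
#' @export
simulation_config <- function(regime = c("drift", "heterogeneous_selection",
                                         "homogeneous_selection",
                                         "dispersal_limitation"),
                              n_taxa = 370L,
                              group_sizes = c(inshore = 8L, offshore = 5L),
                              depth = 20000L,
                              selection_sd = 1,
                              optima_gap = 3 * selection_sd,
                              bm_rate = 1,
                              birth_rate = 1,
                              dispersal_pool_fraction = 0.3,
                              lognormal_sigma = 2,
                              drift_sd = 0.3,
                              seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_taxa >= 4L, length(group_sizes) == 2L, all(group_sizes >= 2L),
            depth >= 1L, selection_sd > 0, bm_rate >= 0, birth_rate > 0,
            dispersal_pool_fraction > 0, dispersal_pool_fraction <= 1,
            lognormal_sigma >= 0, drift_sd >= 0)
  if (is.null(names(group_sizes))) names(group_sizes) <- c("inshore", "offshore")
  structure(list(regime = regime, n_taxa = as.integer(n_taxa),
                 group_sizes = group_sizes,
                 n_samples = as.integer(sum(group_sizes)),
                 depth = as.integer(depth), selection_sd = selection_sd,
                 optima_gap = optima_gap, bm_rate = bm_rate,
                 birth_rate = birth_rate,
                 dispersal_pool_fraction = dispersal_pool_fraction,
                 lognormal_sigma = lognormal_sigma, drift_sd = drift_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate an ultrametric pure-birth (Yule) phylogeny
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed integer seed; identical seeds give identical trees.
#' @return an [ape::phylo] tree with tips `OTU001`, `OTU002`, ...
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2L) stop("need at least 2 tips", call. = FALSE)
  stopifnot(birth_rate > 0)
  set.seed(derive_seed(seed, "tree"))
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("OTU%03d", seq_len(n_tips))
  tree
}

#' Evolve a continuous trait by Brownian motion along a tree
#'
#' Each node inherits its parent value plus a Normal(0, sigma2 * branch
#' length) increment; tip values are returned. With `sigma2 = 0` all tips
#' equal the root value.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param sigma2 trait variance per unit branch length (>= 0).
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
evolve_trait_bm <- function(tree, sigma2 = 1, root_value = 0, seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be non-negative", call. = FALSE)
  set.seed(derive_seed(seed, "traits"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  x <- numeric(n_tip + tree$Nnode)
  x[n_tip + 1L] <- root_value
  inc <- rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  for (e in seq_len(nrow(tree$edge))) {
    x[tree$edge[e, 2L]] <- x[tree$edge[e, 1L]] + inc[e]
  }
  setNames(x[seq_len(n_tip)], tree$tip.label)
}

#' Generate per-sample environmental metadata for two sample groups
#'
#' Temperature, chlorophyll and CDOM are monotone functions of one latent
#' inshore-offshore gradient plus independent noise, so they are strongly
#' rank-correlated with each other (Spearman rho(temperature, chlorophyll)
#' around 0.95) and systematically higher inshore. Salinity is weakly coupled
#' to the gradient; pH and depth are independent of it. Coordinates are laid
#' out on a line along the same gradient so geographic distance and group
#' structure coincide.
#'
#' @param group_sizes named integer vector of length 2 (inshore first);
#'   each >= 2.
#' @param seed integer seed.
#' @param noise_sd latent-noise SD for temperature/chlorophyll; CDOM gets
#'   three times this value.
#' @return metadata data.frame (sample, group, latitude, longitude, salinity,
#'   temperature, pH, depth, chlorophyll, cdom).
#' @export
generate_environment <- function(group_sizes = c(inshore = 8L, offshore = 5L),
                                 seed = 1L, noise_sd = 0.15) {
  if (length(group_sizes) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(group_sizes < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  if (is.null(names(group_sizes))) names(group_sizes) <- c("inshore", "offshore")
  set.seed(derive_seed(seed, "environment"))
  n <- sum(group_sizes)
  group <- rep(names(group_sizes), group_sizes)
  sample_id <- c(sprintf("IN%02d", seq_len(group_sizes[[1L]])),
                 sprintf("OF%02d", seq_len(group_sizes[[2L]])))
  # latent inshore-offshore gradient: inshore high, offshore low
  g <- rnorm(n, mean = ifelse(group == names(group_sizes)[1L], 1, -1), sd = 0.4)
  temperature <- -1.2 + 0.9 * (g + rnorm(n, 0, noise_sd))
  chlorophyll <- exp(0.5 * (g + rnorm(n, 0, noise_sd)))
  cdom        <- exp(0.4 * (g + rnorm(n, 0, 3 * noise_sd)))
  salinity    <- 34.3 + 0.15 * g + rnorm(n, 0, 0.25)
  pH          <- 7.95 + rnorm(n, 0, 0.08)
  depth       <- round(runif(n, 200, 900), 0)
  data.frame(sample = sample_id, group = group,
             latitude = -74.5 - 1.2 * g,
             longitude = 169 + 1.0 * g,
             salinity = salinity, temperature = temperature, pH = pH,
             depth = depth, chlorophyll = chlorophyll, cdom = cdom,
             row.names = sample_id)
}

#' Assemble OTU count tables under an explicit ecological regime
#'
#' Per sample k, `depth` reads are drawn from a multinomial with weights
#' `w_ki = m_i * exp(eps_ki) * s_ki * a_ki`: `m_i` a log-normal metacommunity
#' abundance shared across samples; `eps_ki ~ Normal(0, drift_sd^2)` an
#' independent per-sample log-abundance scatter (ecological drift, present in
#' every regime; `drift_sd = 0` makes samples replicate multinomial draws
#' from identical weights); `s_ki` a Gaussian environmental filter on the
#' Brownian trait (`exp(-(trait_i - optimum_k)^2 / (2 sd^2))`) whose optimum
#' differs by group under heterogeneous selection and is shared under
#' homogeneous selection; and `a_ki` an availability indicator under
#' dispersal limitation, where each sample can only reach a contiguous window
#' of a randomly ordered taxon axis so that nearby samples share species
#' pools. Under drift all `s_ki = a_ki = 1`. The window ordering, drift
#' scatter, metacommunity abundances and multinomial draws use separate
#' derived seed streams, so setting `dispersal_pool_fraction = 1` reproduces
#' the drift output exactly at the same seed.
#'
#' @param tree [ape::phylo]; its tips define the taxon pool.
#' @param traits named trait vector covering all tips.
#' @param env metadata data.frame covering all samples (needs `sample`,
#'   `group`).
#' @param config a [simulation_config].
#' @return an [otu_table] with `rowSums` equal to `config$depth` exactly.
#' @export
assemble_communities <- function(tree, traits, env, config) {
  stopifnot(inherits(config, "simulation_config"))
  taxa <- tree$tip.label
  if (!all(taxa %in% names(traits))) stop("traits must cover all tips", call. = FALSE)
  traits <- traits[taxa]
  n_taxa <- length(taxa)
  samples <- env$sample
  groups <- env$group
  n_samples <- length(samples)

  set.seed(derive_seed(config$seed, "metacommunity"))
  m <- rlnorm(n_taxa, meanlog = 0, sdlog = config$lognormal_sigma)

  set.seed(derive_seed(config$seed, "driftnoise"))
  eps <- matrix(rnorm(n_samples * n_taxa, 0, config$drift_sd),
                n_samples, n_taxa)

  s <- matrix(1, n_samples, n_taxa)
  if (config$regime %in% c("heterogeneous_selection", "homogeneous_selection")) {
    center <- mean(traits)
    if (config$regime == "heterogeneous_selection") {
      lev <- unique(groups)
      opt <- ifelse(groups == lev[1L], center + config$optima_gap / 2,
                    center - config$optima_gap / 2)
    } else {
      opt <- rep(center, n_samples)
    }
    for (k in seq_len(n_samples)) {
      s[k, ] <- exp(-(traits - opt[k])^2 / (2 * config$selection_sd^2))
    }
  }

  a <- matrix(1, n_samples, n_taxa)
  if (config$regime == "dispersal_limitation") {
    set.seed(derive_seed(config$seed, "dispersal"))
    ordering <- sample.int(n_taxa)  # dispersal axis, decoupled from phylogeny
    w <- max(2L, round(config$dispersal_pool_fraction * n_taxa))
    if (w < n_taxa) {
      a[] <- 0
      centers <- if (n_samples > 1L) (seq_len(n_samples) - 1) / (n_samples - 1) else 0.5
      for (k in seq_len(n_samples)) {
        start <- round(centers[k] * (n_taxa - w))
        a[k, ordering[(start + 1L):(start + w)]] <- 1
      }
    }
  }

  set.seed(derive_seed(config$seed, "counts"))
  counts <- matrix(0, n_samples, n_taxa, dimnames = list(samples, taxa))
  for (k in seq_len(n_samples)) {
    wts <- m * exp(eps[k, ]) * s[k, ] * a[k, ]
    if (all(wts <= 0)) stop("sample ", samples[k], ": empty species pool", call. = FALSE)
    counts[k, ] <- rmultinom(1, config$depth, wts)
  }
  otu_table(counts)
}

#' Run the full synthetic-community forward model
#'
#' Tree, traits, environment and counts are generated from the one seed in
#' `config`, each on its own derived stream.
#'
#' @param config a [simulation_config].
#' @return list with `table` ([otu_table]), `tree`, `traits`, `metadata`,
#'   and the `config` itself.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- simulate_yule_tree(config$n_taxa, config$birth_rate, config$seed)
  traits <- evolve_trait_bm(tree, config$bm_rate, 0, config$seed)
  env <- generate_environment(config$group_sizes, config$seed)
  table <- assemble_communities(tree, traits, env, config)
  list(table = table, tree = tree, traits = traits, metadata = env,
       config = config)
}
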