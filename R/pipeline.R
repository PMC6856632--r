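pipeline_defaults <- function() {
  list(
    seed = NULL,
    output_dir = "microassembly_out",
    log_level = "info",
    input = NULL,       # list(otu_table=, tree=, metadata=)
    simulation = NULL,  # passed to simulation_config()
    null_model = list(n_null = 999L, abundance_weighted = TRUE,
                      tie_epsilon = 1e-10),
    thresholds = list(bnti = 2, rc = 0.95, network_rho = 0.6,
                      network_q = 0.05, ancom_alpha = 0.05, ancom_w = 0.7),
    rarefy_depth = NULL,
    shannon_base = 2)
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config (or accepts an equivalent list), rejects unknown keys,
#' fills defaults, and enforces that exactly one of `input` (paths to OTU
#' table / tree / metadata TSVs) or `simulation` (a [simulation_config]
#' parameter block) is present and that a seed is set whenever any stage is
#' stochastic.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return normalized config list of class `"pipeline_config"`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  check_keys(config, names(defaults), "top level")
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) {
    stop("missing seed: all stochastic stages require one", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulation)
  if (has_input == has_sim) {
    stop("exactly one of 'input' and 'simulation' must be present",
         call. = FALSE)
  }
  if (has_input) {
    check_keys(cfg$input, c("otu_table", "tree", "metadata"), "input")
    if (is.null(cfg$input$otu_table)) stop("input.otu_table required", call. = FALSE)
  } else {
    check_keys(cfg$simulation,
               c("regime", "n_taxa", "group_sizes", "depth", "selection_sd",
                 "optima_gap", "bm_rate", "birth_rate",
                 "dispersal_pool_fraction", "lognormal_sigma"),
               "simulation")
  }
  check_keys(cfg$null_model, c("n_null", "abundance_weighted", "tie_epsilon"),
             "null_model")
  check_keys(cfg$thresholds, names(pipeline_defaults()$thresholds),
             "thresholds")
  class(cfg) <- "pipeline_config"
  cfg
}

pipe_log <- function(cfg, stage, msg) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[microassembly:%s] %s", stage, msg))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> alpha and beta diversity -> betaNTI and
#' RC-Bray null models -> process classification -> ordination, group tests
#' and network construction, writing every result as TSV under
#' `config$output_dir` together with a JSON manifest (config echo, config
#' hash, seed, stage status). Reruns with the same config and seed reproduce
#' identical numeric outputs.
#'
#' @param config a [validate_config] result, a config list, or a YAML path.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  norm_yaml <- file.path(cfg$output_dir, "config_normalized.yaml")
  yaml::write_yaml(unclass(cfg), norm_yaml)
  manifest <- list(package = "microassembly",
                   version = as.character(utils::packageVersion("microassembly")),
                   seed = cfg$seed,
                   config_hash = unname(tools::md5sum(norm_yaml)),
                   stages = list())
  done <- function(stage) manifest$stages[[stage]] <<- "ok"
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- paste("failed:", conditionMessage(e))
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  res <- list()

  tryCatch({
    if (!is.null(cfg$simulation)) {
      pipe_log(cfg, "data", "simulating synthetic communities")
      sim_cfg <- do.call(simulation_config, c(cfg$simulation, list(seed = cfg$seed)))
      sim <- simulate_dataset(sim_cfg)
      res$table <- sim$table
      res$tree <- sim$tree
      res$metadata <- sim$metadata
      write_otu_table(res$table, file.path(cfg$output_dir, "otu_table.tsv"))
      ape::write.tree(res$tree, file.path(cfg$output_dir, "tree.nwk"))
      write_metadata(res$metadata, file.path(cfg$output_dir, "metadata.tsv"))
    } else {
      pipe_log(cfg, "data", "reading input tables")
      res$table <- read_otu_table(cfg$input$otu_table)
      res$tree <- if (!is.null(cfg$input$tree)) read_newick(cfg$input$tree)
      res$metadata <- if (!is.null(cfg$input$metadata)) {
        read_metadata(cfg$input$metadata, groups = NULL)
      }
    }
  }, error = function(e) fail("data", e))
  done("data")

  tryCatch({
    pipe_log(cfg, "diversity", "alpha and beta diversity")
    tab <- res$table
    if (!is.null(cfg$rarefy_depth)) {
      tab <- rarefy(tab, cfg$rarefy_depth, seed = cfg$seed, drop_small = TRUE)
    }
    res$alpha <- alpha_diversity(tab, shannon_base = cfg$shannon_base)
    res$jaccard <- beta_diversity(tab, "jaccard")
    res$braycurtis <- beta_diversity(tab, "braycurtis")
    write.table(res$alpha, file.path(cfg$output_dir, "alpha_diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$jaccard, file.path(cfg$output_dir, "beta_jaccard.tsv"),
                sep = "\t", quote = FALSE)
    write.table(res$braycurtis,
                file.path(cfg$output_dir, "beta_braycurtis.tsv"),
                sep = "\t", quote = FALSE)
  }, error = function(e) fail("diversity", e))
  done("diversity")

  nm_cfg <- null_model_config(n_null = cfg$null_model$n_null,
                              abundance_weighted = cfg$null_model$abundance_weighted,
                              seed = cfg$seed,
                              tie_epsilon = cfg$null_model$tie_epsilon)

  if (!is.null(res$tree) && !is.null(res$metadata)) {
    tryCatch({
      pipe_log(cfg, "nullmodels", sprintf("betaNTI and RC-Bray (%d iterations)",
                                          nm_cfg$n_null))
      asm <- run_assembly_analysis(res$table, res$tree, res$metadata, nm_cfg,
                                   bnti_threshold = cfg$thresholds$bnti,
                                   rc_threshold = cfg$thresholds$rc)
      res$bnti <- asm$bnti
      res$rc <- asm$rc
      res$records <- asm$records
      res$summary <- asm$summary
      write.table(asm$bnti, file.path(cfg$output_dir, "bnti.tsv"),
                  sep = "\t", quote = FALSE)
      write.table(asm$rc, file.path(cfg$output_dir, "rcbray.tsv"),
                  sep = "\t", quote = FALSE)
      write.table(asm$records,
                  file.path(cfg$output_dir, "turnover_records.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(asm$summary,
                  file.path(cfg$output_dir, "assembly_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("assembly", e))
    done("assembly")
  }

  tryCatch({
    pipe_log(cfg, "stats", "ordination, group tests, network")
    res$pcoa <- pcoa(res$jaccard, n_axes = 2L)
    write.table(res$pcoa$coordinates,
                file.path(cfg$output_dir, "pcoa_coordinates.tsv"),
                sep = "\t", quote = FALSE)
    if (!is.null(res$metadata)) {
      groups <- setNames(res$metadata$group, res$metadata$sample)
      res$anosim <- anosim(res$jaccard, groups, seed = cfg$seed)
      res$permdisp <- permdisp(res$jaccard, groups, seed = cfg$seed)
      geo <- geo_distance_matrix(res$metadata)
      res$mantel_geo <- mantel_test(geo, res$jaccard, seed = cfg$seed)
      tests <- data.frame(
        test = c("anosim_R", "anosim_p", "permdisp_t", "permdisp_p",
                 "mantel_geo_r", "mantel_geo_p"),
        value = c(res$anosim$R, res$anosim$p, res$permdisp$statistic,
                  res$permdisp$p, res$mantel_geo$r, res$mantel_geo$p))
      write.table(tests, file.path(cfg$output_dir, "group_tests.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res$network <- build_cooccurrence_network(
      res$table, rho_threshold = cfg$thresholds$network_rho,
      q_threshold = cfg$thresholds$network_q)
    res$modules <- detect_modules(res$network)
    write_edge_list(res$network,
                    file.path(cfg$output_dir, "network_edges.tsv"))
    write.table(res$modules, file.path(cfg$output_dir, "network_modules.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }, error = function(e) fail("stats", e))
  done("stats")

  manifest$outputs <- list.files(cfg$output_dir)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
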