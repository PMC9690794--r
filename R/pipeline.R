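#' Pipeline configuration
#'
#' One place for every tunable of the full analysis, with the published
#' methodology's settings as defaults.  Pass the result (possibly modified)
#' to [run_pipeline()].  `read_pipeline_config()` loads overrides from a
#' YAML file containing any subset of these keys.
#'
#' @param gamma EBIC hyperparameter.
#' @param n_lambda,lambda_min_ratio graphical-lasso penalty grid.
#' @param walktrap_steps random-walk length for community detection.
#' @param clustering weighted clustering variant.
#' @param n_boot_edges nonparametric edge-bootstrap replicates.
#' @param n_boot_communities parametric community-bootstrap replicates.
#' @param drop_grid case-dropping proportions for the CS coefficient.
#' @param n_per_level subsamples per drop proportion.
#' @param cor_threshold,cs_prob CS decision rule.
#' @param mst_absolute use absolute weights in the MST distance.
#' @param run_stability run the (expensive) bootstrap stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gamma = 0.5, n_lambda = 100L,
                            lambda_min_ratio = 0.01, walktrap_steps = 4L,
                            clustering = c("zhang", "onnela", "barrat"),
                            n_boot_edges = 2500L, n_boot_communities = 2500L,
                            drop_grid = seq(0.05, 0.75, by = 0.05),
                            n_per_level = 250L, cor_threshold = 0.7,
                            cs_prob = 0.95, mst_absolute = FALSE,
                            run_stability = TRUE) {
  structure(list(gamma = gamma, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 walktrap_steps = walktrap_steps,
                 clustering = match.arg(clustering),
                 n_boot_edges = n_boot_edges,
                 n_boot_communities = n_boot_communities,
                 drop_grid = drop_grid, n_per_level = n_per_level,
                 cor_threshold = cor_threshold, cs_prob = cs_prob,
                 mst_absolute = mst_absolute,
                 run_stability = run_stability),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with configuration overrides.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_ordnet("reading config files requires the 'yaml' package")
  overrides <- yaml::read_yaml(path)
  base <- pipeline_config()
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown))
    stop_ordnet("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, overrides)
}

#' Run the full network analysis
#'
#' Executes the complete pipeline on an ordinal dataset: polychoric
#' correlation matrix (pairwise deletion), EBIC-glasso network, walktrap
#' communities with parametric-bootstrap uncertainty, centrality table
#' (strength, eigencentrality, bridge strength, z-standardised), RMSEW
#' block connectivity, MST backbone, and (optionally) the nonparametric
#' edge bootstrap and CS stability coefficients.  A single master seed
#' fans out to per-stage seeds, so identical input, config and seed give
#' identical reports.
#'
#' @param data an `ordinal_data` object, or a path to a CSV readable by
#'   [read_ordinal_csv()].
#' @param config a [pipeline_config()] list.
#' @param outdir optional directory; when given, every table is written
#'   there (`edges.csv`, `network.graphml`, `centrality.csv`,
#'   `communities.csv`, `rmsew.csv`, `mst.csv`, `bootstrap_edges.csv`,
#'   `report.json`).  Partial outputs are removed if a stage fails.
#' @param seed integer master seed.
#' @return An object of class `analysis_report`: list with `network`,
#'   `edge_density`, `global_clustering`, `communities`,
#'   `community_bootstrap`, `rmsew`, `centrality`, `mst`, `edge_bootstrap`,
#'   `cs_edges`, `cs_strength`, and `provenance`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), outdir = NULL,
                         seed = 1L) {
  if (is.character(data)) data <- read_ordinal_csv(data)
  stopifnot(inherits(data, "ordinal_data"),
            inherits(config, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  stage <- "polychoric correlations"
  report <- tryCatch({
    R <- polychoric_matrix(data)

    stage <- "network estimation"
    net <- select_network(R, gamma = config$gamma,
                          n_lambda = config$n_lambda,
                          lambda_min_ratio = config$lambda_min_ratio)

    stage <- "community detection"
    comm <- walktrap_communities(net, steps = config$walktrap_steps)
    thr <- lapply(seq_len(ncol(data$values)), function(j) {
      t <- margin_thresholds(tabulate(data$values[, j], data$n_categories))
      unique(t[is.finite(t)])  # unobserved categories drop out
    })
    cboot <- bootstrap_communities(net, thr, n = nrow(data$values),
                                   n_boot = config$n_boot_communities,
                                   seed = derive_seed(seed, 2L),
                                   steps = config$walktrap_steps,
                                   gamma = config$gamma,
                                   n_lambda = config$n_lambda,
                                   lambda_min_ratio = config$lambda_min_ratio)

    stage <- "centrality and backbone"
    cent <- centrality_table(net, comm)
    blocks <- rmsew(net, comm)
    tree <- mst_backbone(net, absolute = config$mst_absolute)

    stage <- "stability bootstrap"
    eboot <- cs_e <- cs_s <- NULL
    if (config$run_stability) {
      eboot <- bootstrap_edges(data, n_boot = config$n_boot_edges,
                               seed = derive_seed(seed, 3L),
                               gamma = config$gamma,
                               n_lambda = config$n_lambda,
                               lambda_min_ratio = config$lambda_min_ratio)
      cs_e <- cs_coefficient(data, "edges", config$drop_grid,
                             config$n_per_level, config$cor_threshold,
                             config$cs_prob, seed = derive_seed(seed, 4L),
                             gamma = config$gamma,
                             n_lambda = config$n_lambda,
                             lambda_min_ratio = config$lambda_min_ratio)
      cs_s <- cs_coefficient(data, "strength", config$drop_grid,
                             config$n_per_level, config$cor_threshold,
                             config$cs_prob, seed = derive_seed(seed, 5L),
                             gamma = config$gamma,
                             n_lambda = config$n_lambda,
                             lambda_min_ratio = config$lambda_min_ratio)
    }

    structure(list(network = net,
                   edge_density = edge_density(net),
                   global_clustering = global_clustering(net,
                                                         config$clustering),
                   communities = comm,
                   community_bootstrap = cboot,
                   rmsew = blocks,
                   centrality = cent,
                   mst = tree,
                   edge_bootstrap = eboot,
                   cs_edges = if (!is.null(cs_e)) cs_e$cs,
                   cs_strength = if (!is.null(cs_s)) cs_s$cs,
                   provenance = list(
                     seed = as.integer(seed),
                     n = nrow(data$values), p = ncol(data$values),
                     config = unclass(config),
                     package_version =
                       as.character(utils::packageVersion("ordnet")),
                     schema = "ordnet-report/1")),
              class = "analysis_report")
  }, error = function(e) {
    if (!is.null(outdir)) unlink(pipeline_files(outdir))
    stop_ordnet("pipeline failed at stage '", stage, "': ",
                conditionMessage(e))
  })

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

pipeline_files <- function(outdir) {
  file.path(outdir, c("edges.csv", "network.graphml", "centrality.csv",
                      "communities.csv", "rmsew.csv", "mst.csv",
                      "bootstrap_edges.csv", "report.json"))
}

write_report <- function(report, outdir) {
  write_network_edges(report$network, file.path(outdir, "edges.csv"))
  write_network_graphml(report$network, file.path(outdir, "network.graphml"))
  write.csv(report$centrality, file.path(outdir, "centrality.csv"),
            row.names = FALSE)
  write.csv(data.frame(node = names(report$communities$labels),
                       community = unname(report$communities$labels)),
            file.path(outdir, "communities.csv"), row.names = FALSE)
  write.csv(report$rmsew, file.path(outdir, "rmsew.csv"), row.names = FALSE)
  write_tree_edges(report$mst, file.path(outdir, "mst.csv"))
  if (!is.null(report$edge_bootstrap))
    write.csv(report$edge_bootstrap$edges,
              file.path(outdir, "bootstrap_edges.csv"), row.names = FALSE)
  json <- list(schema = report$provenance$schema,
               n = report$provenance$n, p = report$provenance$p,
               seed = report$provenance$seed,
               edge_density = report$edge_density,
               global_clustering = report$global_clustering,
               n_communities = report$communities$n_communities,
               modularity = report$communities$modularity,
               community_count_median = report$community_bootstrap$median,
               community_count_ci =
                 c(report$community_bootstrap$ci_low,
                   report$community_bootstrap$ci_high),
               community_count_mean_ci =
                 c(report$community_bootstrap$mean_ci_low,
                   report$community_bootstrap$mean_ci_high),
               cs_edges = report$cs_edges,
               cs_strength = report$cs_strength,
               config = report$provenance$config,
               package_version = report$provenance$package_version)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Network analysis report (n =", x$provenance$n, ", p =",
      x$provenance$p, ")\n")
  cat("  edge density:", format(round(x$edge_density, 3)),
      "; global clustering:", format(round(x$global_clustering, 3)), "\n")
  cat("  communities:", x$communities$n_communities,
      "(bootstrap median", x$community_bootstrap$median, ")\n")
  if (!is.null(x$cs_edges))
    cat("  CS(edges):", format(x$cs_edges),
        "; CS(strength):", format(x$cs_strength), "\n")
  invisible(x)
}
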