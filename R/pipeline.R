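# Configuration handling and the end-to-end pipeline chaining the stages:
# simulate -> rhythm -> dynamic PPIs -> topology -> hubs -> process network
# -> phenotyping. Each stage is an exported function; run_pipeline() wires
# them on one config so a whole synthetic study is a single reproducible
# call.

#' Default run configuration
#'
#' Thresholds, permutation counts, and simulation parameters for a full
#' synthetic run, with the field-standard settings as defaults: rhythm FDR
#' 0.05, dynamic-call FDR as configured (1e-5 at genome scale), PCC cutoff
#' 0.5, dynamic-degree cut 5, phase grid 0.1 h, arrhythmicity r 0.8,
#' 10-of-1000 process display rule.
#'
#' @param seed Global integer seed; child seeds for each stochastic stage
#'   are derived from it deterministically.
#' @return Named list of class `dynppi_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    n_genes = 1000, frac_rhythmic = 0.3, noise_sd = 0.1,
    n_nodes = 500, attachment_edges = 3, planted_dynamic_edges = 50,
    planted_phase_offset_max = 2,
    rhythm_B = 200, rhythm_fdr = 0.05,
    dynamic_B = 200, dynamic_fdr = 0.05,
    pcc_cutoff = 0.5, n_random_pairs = 1000,
    hub_degree = 10, n_background = 1000,
    dynamic_degree_cut = 5, phase_grid_step = 0.1,
    n_categories = 12, genes_per_category = 40, n_networks = 1000,
    arrhythmic_r = 0.8
  ), class = "dynppi_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so config typos fail loudly; absent keys fall
#' back to [default_config()] values.
#'
#' @param path YAML file.
#' @return `dynppi_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  base[names(cfg)] <- cfg
  base
}

#' Run the full synthetic pipeline
#'
#' Simulates an expression matrix, a scale-free network with planted
#' co-phase edges, and a category annotation; detects rhythmic genes; calls
#' dynamic interactions; summarizes topology; classifies co-expression and
#' hubs; builds the process network; and writes all result TSVs plus the
#' serialized configuration to `out_dir`.
#'
#' @param config `dynppi_config` list (see [default_config()]).
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return List with every intermediate object (sim, net, scan, dyn,
#'   topology, coexpr, process, annotation).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seeds <- derive_seeds(config$seed, 6)
  sim <- simulate_expression(config$n_genes, config$frac_rhythmic,
                             noise_sd = config$noise_sd, seed = seeds[[1]])
  net <- simulate_network(sim$truth, n_nodes = config$n_nodes,
                          attachment_edges = config$attachment_edges,
                          planted_dynamic_edges = config$planted_dynamic_edges,
                          planted_phase_offset_max =
                            config$planted_phase_offset_max,
                          seed = seeds[[2]])
  ann <- simulate_annotation(rownames(sim$expr), config$n_categories,
                             config$genes_per_category, seed = seeds[[3]])
  scan <- detect_rhythms(sim$expr, B = config$rhythm_B,
                         fdr_threshold = config$rhythm_fdr,
                         grid_step = config$phase_grid_step,
                         seed = seeds[[4]])
  dyn <- call_dynamic_edges(net$edges, sim$expr,
                            fdr_threshold = config$dynamic_fdr,
                            B = config$dynamic_B,
                            grid_step = config$phase_grid_step,
                            seed = seeds[[5]])
  topo <- topology_summary(net$graph)
  coexpr <- coexpression_enrichment(sim$expr, net$edges,
                                    n_random = config$n_random_pairs,
                                    pcc_cutoff = config$pcc_cutoff,
                                    seed = seeds[[6]])
  proc <- permutation_process_test(dyn$edges, dyn$edges$dynamic, ann,
                                   n_networks = config$n_networks,
                                   seed = seeds[[6]])
  out <- list(sim = sim, net = net, annotation = ann, scan = scan, dyn = dyn,
              topology = topo, coexpr = coexpr, process = proc,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_tsv(sim$expr, file.path(out_dir, "expression.tsv"))
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_interactions_tsv(net$edges, file.path(out_dir, "network.tsv"))
    write_rhythm_tsv(scan, file.path(out_dir, "rhythm.tsv"))
    write_interactions_tsv(dyn$edges, file.path(out_dir, "dynamic_edges.tsv"))
    utils::write.table(proc, file.path(out_dir, "process_network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  out
}
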