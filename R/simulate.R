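# Simulators for every input class the pipeline consumes: circadian
# expression matrices, scale-free interaction networks with planted
# co-expressed edges, gene-category annotations, and damped oscillatory
# reporter traces.

#' Simulate a circadian expression matrix
#'
#' Generates hourly 48-h profiles: a fraction of genes carries a 24-h cosine
#' component, the rest are flat. The model per gene g is
#' \deqn{x_g(t) = b_g (1 + a_g \cos(2\pi (t - \phi_g)/24)) + \epsilon,}
#' with log-normal baselines \eqn{b_g}, relative amplitudes \eqn{a_g} drawn
#' uniformly from `rel_amplitude_range`, phases uniform on \[0, 24) h, and
#' Gaussian noise with sd `noise_sd * b_g`. Values are truncated below at
#' `0.01 * b_g` so the matrix is strictly positive, which the
#' product-of-profiles interaction statistic requires.
#'
#' @param n_genes Number of genes (> 0).
#' @param frac_rhythmic Fraction of genes with a cosine component, in \[0,1\].
#'   Exactly `round(n_genes * frac_rhythmic)` genes are rhythmic.
#' @param timepoints Sampling times in hours (>= 8 points).
#' @param baseline_log_mean,baseline_log_sd Log-scale parameters of the
#'   baseline abundance distribution.
#' @param rel_amplitude_range Range of the relative amplitude a_g (fraction
#'   of baseline), within \[0, 1\].
#' @param noise_sd Noise sd as a fraction of each gene's baseline.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return List with `expr` (matrix, genes x timepoints, columns "CT<h>") and
#'   `truth` (data.frame: gene_id, rhythmic, phase, rel_amplitude, baseline).
#' @examples
#' sim <- simulate_expression(100, frac_rhythmic = 0.3, seed = 1)
#' table(sim$truth$rhythmic)
#' @export
simulate_expression <- function(n_genes, frac_rhythmic = 0.3,
                                timepoints = 0:47,
                                baseline_log_mean = log(100),
                                baseline_log_sd = 0.5,
                                rel_amplitude_range = c(0.2, 0.6),
                                noise_sd = 0.1, seed = NULL) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (length(timepoints) < 8) stop("need at least 8 timepoints")
  if (frac_rhythmic < 0 || frac_rhythmic > 1) stop("frac_rhythmic not in [0,1]")
  with_seed(seed, {
    ids <- sprintf("g%04d", seq_len(n_genes))
    n_r <- round(n_genes * frac_rhythmic)
    rhythmic <- rep(FALSE, n_genes)
    rhythmic[sample.int(n_genes, n_r)] <- TRUE
    b <- exp(stats::rnorm(n_genes, baseline_log_mean, baseline_log_sd))
    a <- ifelse(rhythmic,
                stats::runif(n_genes, rel_amplitude_range[1],
                             rel_amplitude_range[2]), 0)
    phi <- ifelse(rhythmic, stats::runif(n_genes, 0, 24), NA_real_)
    mu <- b * (1 + a * cos(2 * pi * outer(ifelse(rhythmic, phi, 0), timepoints,
                                          function(p, t) (t - p) / 24)))
    eps <- matrix(stats::rnorm(n_genes * length(timepoints), 0, 1),
                  n_genes) * (noise_sd * b)
    expr <- pmax(mu + eps, b * 0.01)
    dimnames(expr) <- list(ids, paste0("CT", timepoints))
    truth <- data.frame(gene_id = ids, rhythmic = rhythmic, phase = phi,
                        rel_amplitude = a, baseline = b,
                        stringsAsFactors = FALSE)
    list(expr = expr, truth = truth)
  })
}

#' Simulate a scale-free interaction network with planted dynamic edges
#'
#' Grows a simple connected graph by preferential attachment (heavy-tailed
#' degree distribution, as observed for protein interaction networks), labels
#' nodes with gene identifiers from an expression truth table, and plants a
#' requested number of extra edges between rhythmic genes whose peak phases
#' differ by at most `planted_phase_offset_max` circadian hours. Planted
#' edges are the ground truth that the dynamic-interaction caller should
#' recover.
#'
#' @param truth Truth table from [simulate_expression()].
#' @param n_nodes Number of network nodes (<= number of genes in `truth`).
#' @param attachment_edges Edges added per new node during growth.
#' @param planted_dynamic_edges Number of co-phase edges to plant.
#' @param planted_phase_offset_max Maximal circular phase offset (h) between
#'   the two endpoints of a planted edge.
#' @param seed Optional integer seed.
#' @return List with `graph` (igraph, vertex names = gene ids), `edges`
#'   (data.frame idA, idB, source), and `planted` (data.frame of planted
#'   edges with both phases).
#' @export
simulate_network <- function(truth, n_nodes = nrow(truth),
                             attachment_edges = 3,
                             planted_dynamic_edges = 0,
                             planted_phase_offset_max = 2, seed = NULL) {
  stopifnot(n_nodes >= 2, attachment_edges >= 1)
  if (n_nodes > nrow(truth)) stop("n_nodes exceeds number of genes in truth")
  with_seed(seed, {
    nodes <- sample(truth$gene_id, n_nodes)
    g <- igraph::sample_pa(n_nodes, m = attachment_edges, directed = FALSE)
    igraph::V(g)$name <- nodes

    planted <- data.frame(idA = character(0), idB = character(0),
                          phaseA = numeric(0), phaseB = numeric(0),
                          stringsAsFactors = FALSE)
    if (planted_dynamic_edges > 0) {
      rh <- truth[truth$rhythmic & truth$gene_id %in% nodes, ]
      cand <- which(outer(rh$phase, rh$phase,
                          function(a, b) circ_diff(a, b)) <=
                      planted_phase_offset_max, arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      if (nrow(cand) > 0) {
        # drop candidate pairs already wired in the attachment graph
        present <- apply(cand, 1L, function(ij) {
          igraph::are_adjacent(g, rh$gene_id[ij[1]], rh$gene_id[ij[2]])
        })
        cand <- cand[!present, , drop = FALSE]
      }
      if (nrow(cand) < planted_dynamic_edges) {
        stop("insufficient rhythmic gene pairs within the phase-offset bound")
      }
      pick <- cand[sample.int(nrow(cand), planted_dynamic_edges), ,
                   drop = FALSE]
      planted <- data.frame(idA = rh$gene_id[pick[, 1]],
                            idB = rh$gene_id[pick[, 2]],
                            phaseA = rh$phase[pick[, 1]],
                            phaseB = rh$phase[pick[, 2]],
                            stringsAsFactors = FALSE)
      g <- igraph::add_edges(g, rbind(planted$idA, planted$idB))
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    list(graph = g,
         edges = data.frame(idA = el[, 1], idB = el[, 2], source = "SIM",
                            stringsAsFactors = FALSE),
         planted = planted)
  })
}

#' Simulate a bioluminescence reporter trace
#'
#' Damped cosine plus polynomial trend plus Gaussian noise, emulating a
#' dexamethasone-synchronized reporter cell line monitored in a plate
#' luminometer: \eqn{y(t) = A e^{-\lambda t}\cos(2\pi t/\tau) + trend(t) +
#' \epsilon}. Defaults match 30-min sampling over 6 days.
#'
#' @param period_h Oscillation period tau in hours (> 0).
#' @param amplitude Initial amplitude A in counts.
#' @param damping_rate Exponential damping lambda per hour.
#' @param trend Polynomial trend coefficients, ascending order (constant
#'   first); `0` for none.
#' @param noise_sd Gaussian noise sd in counts.
#' @param sampling_interval Sampling interval in hours (default 0.5).
#' @param duration Total duration in hours (default 144, i.e. 6 days);
#'   must cover at least two periods.
#' @param seed Optional integer seed.
#' @return data.frame with columns `time_h` and `counts`
#'   (`duration / sampling_interval + 1` rows).
#' @export
simulate_reporter <- function(period_h = 24, amplitude = 1000,
                              damping_rate = 0.01, trend = 0,
                              noise_sd = 0, sampling_interval = 0.5,
                              duration = 144, seed = NULL) {
  stopifnot(period_h > 0)
  if (sampling_interval <= 0) stop("sampling interval must be positive")
  if (duration < 2 * period_h) stop("duration must cover at least 2 periods")
  t <- seq(0, duration, by = sampling_interval)
  y <- amplitude * exp(-damping_rate * t) * cos(2 * pi * t / period_h)
  y <- y + as.vector(outer(t, seq_along(trend) - 1, `^`) %*% trend)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  data.frame(time_h = t, counts = y)
}

#' Simulate a gene-to-category annotation table
#'
#' Assigns genes to functional categories (a reduced GO-style set). Genes may
#' carry multiple categories; every category is non-empty.
#'
#' @param genes Character vector of gene identifiers.
#' @param n_categories Number of categories (>= 2).
#' @param genes_per_category Genes drawn per category (capped at the number
#'   of genes).
#' @param seed Optional integer seed.
#' @return data.frame with columns `gene` and `category`.
#' @export
simulate_annotation <- function(genes, n_categories, genes_per_category,
                                seed = NULL) {
  if (n_categories < 2) stop("need at least 2 categories")
  stopifnot(genes_per_category >= 1, length(genes) >= 1)
  k <- min(genes_per_category, length(genes))
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_categories), function(i) {
      data.frame(gene = sample(genes, k),
                 category = sprintf("C%03d", i),
                 stringsAsFactors = FALSE)
    }))
  })
}
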