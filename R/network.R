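# Compilation of the multi-source interaction network and its topology:
# shortest paths, clustering, topological coefficients, degree distribution,
# and degree-preserving randomization as the null model.

#' Compile a multi-source interaction network
#'
#' Merges one or more edge tables (columns `idA`, `idB`, `source`) into a
#' single simple undirected graph, retaining per-edge source provenance as
#' the union of contributing sources (e.g. Y2H / MAN / UniHI / EXT). Node
#' class labels (core / regulatory / neighborhood) come from `node_classes`;
#' nodes without a stated class are admitted as "neighborhood" with a
#' warning.
#'
#' @param edge_tables A data.frame or list of data.frames with columns
#'   `idA`, `idB` and optionally `source`.
#' @param node_classes Optional data.frame with columns `id`, `class`.
#' @return igraph object with vertex attribute `class` and edge attribute
#'   `sources` (comma-separated source set); merge statistics are attached
#'   as graph attribute `merge_stats`.
#' @export
compile_network <- function(edge_tables, node_classes = NULL) {
  if (is.data.frame(edge_tables)) edge_tables <- list(edge_tables)
  ed <- do.call(rbind, lapply(edge_tables, function(d) {
    stopifnot(all(c("idA", "idB") %in% names(d)))
    if (is.null(d$source)) d$source <- "UNKNOWN"
    d[, c("idA", "idB", "source")]
  }))
  ed <- ed[ed$idA != ed$idB, , drop = FALSE]
  key <- paste(pmin(ed$idA, ed$idB), pmax(ed$idA, ed$idB))
  src <- vapply(split(ed$source, key), function(s)
    paste(sort(unique(s)), collapse = ","), character(1))
  uk <- !duplicated(key)
  edges <- data.frame(idA = pmin(ed$idA, ed$idB)[uk],
                      idB = pmax(ed$idA, ed$idB)[uk],
                      sources = src[key[uk]], stringsAsFactors = FALSE)

  nodes <- sort(unique(c(edges$idA, edges$idB)))
  cls <- rep("neighborhood", length(nodes))
  if (!is.null(node_classes)) {
    m <- match(nodes, node_classes$id)
    known <- !is.na(m)
    cls[known] <- node_classes$class[m[known]]
    if (any(!known)) {
      warning(sum(!known), " node(s) without class label admitted as",
              " 'neighborhood'")
    }
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, class = cls, stringsAsFactors = FALSE))
  n_multi <- vapply(strsplit(edges$sources, ","), length, integer(1))
  g <- igraph::set_graph_attr(g, "merge_stats", c(
    n_input_rows = nrow(ed), n_edges = nrow(edges),
    n_multi_source = sum(n_multi > 1)))
  g
}

#' Topology summary of an interaction network
#'
#' Computes the descriptive topology of a (typically small-world,
#' scale-free) interaction network: mean shortest path length over unordered
#' reachable pairs within the largest connected component, mean degree,
#' mean local clustering coefficient \eqn{C_n = 2 e_n / (k_n (k_n - 1))}
#' (nodes of degree < 2 contribute 0), per-node topological coefficients
#' \eqn{T_n = mean_m |shared(n, m)| / k_n} over nodes m sharing at least one
#' neighbor with n, the degree-frequency table, and the power-law exponent
#' fitted by least squares on log(count) vs log(degree).
#'
#' @param g igraph object.
#' @param paths One of "reachable" (default: average over unordered pairs in
#'   the largest component) or "all" (unreachable pairs included as `Inf`,
#'   giving `Inf` for disconnected graphs).
#' @return Object of class `topology_summary` (a list; see fields above).
#' @export
topology_summary <- function(g, paths = c("reachable", "all")) {
  paths <- match.arg(paths)
  if (igraph::vcount(g) == 0) stop("empty graph")
  deg <- igraph::degree(g)

  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  gl <- igraph::induced_subgraph(g, keep)
  D <- igraph::distances(gl)
  msp <- mean(D[upper.tri(D)])
  if (paths == "all" && comp$no > 1) msp <- Inf

  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0

  tc <- topological_coefficients(g)

  df <- as.data.frame(table(degree = deg), stringsAsFactors = FALSE)
  df$degree <- as.numeric(df$degree)
  df <- df[df$degree > 0, , drop = FALSE]
  slope <- if (nrow(df) >= 2) {
    unname(stats::coef(stats::lm(log(Freq) ~ log(degree), data = df))[2])
  } else NA_real_

  # Fig-S3-style curves: average over all nodes with the same degree
  cbd <- tapply(cc[deg >= 2], deg[deg >= 2], mean)
  tbd <- tapply(tc[!is.na(tc)], deg[!is.na(tc)], mean)

  structure(list(
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    mean_shortest_path = msp, mean_degree = mean(deg),
    clustering_coefficient = mean(cc),
    clustering_by_node = stats::setNames(cc, igraph::V(g)$name),
    clustering_by_degree = cbd,
    topological_coefficients = stats::setNames(tc, igraph::V(g)$name),
    topological_by_degree = tbd,
    degree_frequency = df, powerlaw_slope = slope,
    largest_component_size = max(comp$csize), n_components = comp$no
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Network topology: ", x$n_nodes, " nodes, ", x$n_edges, " edges (",
      x$n_components, " component(s))\n", sep = "")
  cat(sprintf("  mean shortest path : %.2f links (largest component, %d nodes)\n",
              x$mean_shortest_path, x$largest_component_size))
  cat(sprintf("  mean degree        : %.2f partners/node\n", x$mean_degree))
  cat(sprintf("  clustering coeff.  : %.3f (mean local)\n",
              x$clustering_coefficient))
  cat(sprintf("  power-law slope    : %.2f (log count vs log degree)\n",
              x$powerlaw_slope))
  invisible(x)
}

# T_n = mean over nodes m (m != n) sharing >= 1 neighbor with n of
# |shared neighbors(n, m)| / k_n; NA for nodes with no such partner.
topological_coefficients <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- rowSums(A)
  S <- A %*% A  # S[n, m] = number of shared neighbors
  diag(S) <- 0
  vapply(seq_len(nrow(A)), function(n) {
    m <- which(S[n, ] > 0)
    if (length(m) == 0 || k[n] == 0) return(NA_real_)
    mean(S[n, m]) / k[n]
  }, numeric(1))
}

#' Degree-preserving network randomization
#'
#' Randomizes a graph by repeated double-edge swaps (pick two independent
#' edges a-b, c-d; rewire to a-d, c-b), rejecting swaps that would create
#' self-loops or multi-edges. The degree sequence is preserved exactly;
#' clustering and other higher-order structure is destroyed, making the
#' rewired ensemble the standard topology null model.
#'
#' @param g igraph object.
#' @param n_swaps Number of attempted swaps (default `10 * ecount(g)`).
#' @param seed Optional integer seed.
#' @return Rewired igraph. A graph with no legal swap (fewer than 2
#'   independent edges) is returned unchanged with a warning.
#' @export
rewire_preserving_degrees <- function(g, n_swaps = 10 * igraph::ecount(g),
                                      seed = NULL) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) < 2 || length(unique(as.vector(el))) < 4) {
    warning("no legal degree-preserving swap exists; graph returned unchanged")
    return(g)
  }
  with_seed(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps)))
}

#' Hub proteins by degree threshold
#'
#' @param g igraph object.
#' @param threshold Minimal degree (>= 1).
#' @param strict Use strictly greater than `threshold` (the "more than 20
#'   interactions" convention) instead of the default `>=`.
#' @return Character vector of hub node names, most connected first.
#' @export
hub_set <- function(g, threshold, strict = FALSE) {
  stopifnot(threshold >= 1)
  deg <- igraph::degree(g)
  if (is.null(names(deg))) names(deg) <- as.character(seq_along(deg))
  keep <- if (strict) deg > threshold else deg >= threshold
  names(sort(deg[keep], decreasing = TRUE))
}

#' Clustering coefficient of a rewired ensemble
#'
#' Mean and sd of the mean local clustering coefficient over `n` independent
#' degree-preserving rewirings; the reference value for judging whether the
#' observed clustering exceeds its topology null.
#'
#' @param g igraph object.
#' @param n Ensemble size (default 100).
#' @param n_swaps Swaps per replicate (default `10 * ecount(g)`).
#' @param seed Optional integer seed.
#' @return List with `mean`, `sd`, `values`, and `observed`.
#' @export
clustering_null <- function(g, n = 100, n_swaps = 10 * igraph::ecount(g),
                            seed = NULL) {
  obs_cc <- function(gr) {
    cc <- igraph::transitivity(gr, type = "localundirected", isolates = "zero")
    mean(cc)
  }
  vals <- with_seed(seed, vapply(seq_len(n), function(i) {
    obs_cc(rewire_preserving_degrees(g, n_swaps))
  }, numeric(1)))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals,
       observed = obs_cc(g))
}
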