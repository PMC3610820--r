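# The "process network": pairs of functional categories significantly
# connected by dynamic interactions, judged against label-permutation null
# networks, plus per-category enrichment of dynamically interacting genes.

# Map each edge to the unordered category pairs it connects. An edge
# contributes to pair (A, B) iff one endpoint carries A and the other B;
# multi-annotated endpoints contribute to every qualifying pair, each edge
# counted once per pair. Returns a list of integer vectors (pair indices per
# edge) plus the pair universe.
edge_pair_incidence <- function(edges, annotation) {
  stopifnot(nrow(annotation) > 0)
  cats <- sort(unique(annotation$category))
  nc <- length(cats)
  ann <- split(match(annotation$category, cats), annotation$gene)
  pair_id <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    (lo - 1L) * nc - (lo - 1L) * (lo - 2L) / 2L + hi - lo + 1L
  }
  inc <- lapply(seq_len(nrow(edges)), function(i) {
    ca <- ann[[edges$idA[i]]]
    cb <- ann[[edges$idB[i]]]
    if (is.null(ca) || is.null(cb)) return(integer(0))
    unique(as.integer(pair_id(rep(ca, each = length(cb)),
                              rep(cb, length(ca)))))
  })
  pairs <- expand_pairs(cats)
  list(incidence = inc, categories = cats, pairs = pairs)
}

expand_pairs <- function(cats) {
  nc <- length(cats)
  idx <- which(upper.tri(matrix(0, nc, nc), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(catA = cats[idx[, 1]], catB = cats[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Count total and dynamic interactions between category pairs
#'
#' For every unordered pair of annotated categories (including self-pairs
#' A = A), counts the network edges linking a protein carrying the first
#' category to a protein carrying the second, and how many of those edges
#' are dynamic. Multi-annotated endpoints contribute to every qualifying
#' pair; each edge counts once per pair.
#'
#' @param edges data.frame with columns `idA`, `idB`.
#' @param dynamic Logical vector flagging dynamic edges, aligned with
#'   `edges` rows.
#' @param annotation data.frame with columns `gene`, `category`.
#' @return data.frame: catA, catB, n_interactions, n_dynamic (all category
#'   pairs, zero counts included).
#' @export
count_category_links <- function(edges, dynamic, annotation) {
  ep <- edge_pair_incidence(edges, annotation)
  np <- nrow(ep$pairs)
  cbind(ep$pairs,
        n_interactions = tabulate_ids(ep$incidence, np),
        n_dynamic = tabulate_ids(ep$incidence[dynamic], np))
}

tabulate_ids <- function(l, nbins) {
  v <- unlist(l, use.names = FALSE)
  tabulate(if (is.null(v)) integer(0) else v, nbins = nbins)
}

#' Permutation test for dynamic coupling of category pairs
#'
#' Tests, for each category pair, whether dynamic interactions are
#' over-represented among the interactions linking the two categories. The
#' null model redistributes the dynamic label uniformly over all edges,
#' preserving the total dynamic count, `n_networks` times;
#' \eqn{p_{perm}} is the fraction of random networks with a strictly larger
#' dynamic count for the pair. A pair is displayed when no more than
#' `display_max` of the random networks beat it
#' (\eqn{p_{perm} \le display\_max / n\_networks}).
#'
#' @param edges data.frame with columns `idA`, `idB`.
#' @param dynamic Logical vector of dynamic flags aligned with `edges`.
#' @param annotation data.frame `gene`, `category`.
#' @param n_networks Number of randomized networks (>= 100; default 1000).
#' @param display_max Displayed if at most this many random networks exceed
#'   the observed count (default 10, i.e. the 10-of-1000 rule).
#' @param seed Optional integer seed.
#' @return data.frame: catA, catB, n_interactions, n_dynamic, p_perm,
#'   displayed.
#' @export
permutation_process_test <- function(edges, dynamic, annotation,
                                     n_networks = 1000, display_max = 10,
                                     seed = NULL) {
  if (n_networks < 100) stop("n_networks must be >= 100")
  ep <- edge_pair_incidence(edges, annotation)
  np <- nrow(ep$pairs)
  obs <- tabulate_ids(ep$incidence[dynamic], np)
  n_dyn_total <- sum(dynamic)
  n_edges <- nrow(edges)
  if (n_dyn_total == 0) {
    exceed <- rep(n_networks, np)  # p_perm = 1 everywhere
  } else {
    exceed <- with_seed(seed, {
      ex <- integer(np)
      for (r in seq_len(n_networks)) {
        sel <- sample.int(n_edges, n_dyn_total)
        cnt <- tabulate_ids(ep$incidence[sel], np)
        ex <- ex + (cnt > obs)
      }
      ex
    })
  }
  p_perm <- exceed / n_networks
  out <- cbind(ep$pairs,
               n_interactions = tabulate_ids(ep$incidence, np),
               n_dynamic = obs, p_perm = p_perm,
               displayed = p_perm <= display_max / n_networks)
  out
}

#' Category enrichment in dynamically interacting genes
#'
#' Hypergeometric enrichment, per category, of genes involved in at least
#' one dynamic interaction, with Benjamini-Hochberg correction across
#' categories. The background is the set of all annotated genes.
#'
#' @param annotation data.frame `gene`, `category`.
#' @param dynamic_degree Named vector of per-gene dynamic-interaction counts
#'   (genes absent are treated as 0).
#' @return data.frame: category, n_genes, n_dynamic_genes, p, fdr.
#' @export
category_node_enrichment <- function(annotation, dynamic_degree) {
  genes <- unique(annotation$gene)
  dyn <- genes %in% names(dynamic_degree)[dynamic_degree > 0]
  names(dyn) <- genes
  N <- length(genes)
  K <- sum(dyn)
  by_cat <- split(annotation$gene, annotation$category)
  rows <- lapply(names(by_cat), function(cat) {
    g <- unique(by_cat[[cat]])
    n <- length(g)
    if (n == 0) stop("category of size 0: ", cat)
    k <- sum(dyn[g])
    # upper-tail hypergeometric: P(X >= k)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, n_genes = n, n_dynamic_genes = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}
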