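# Predicting rhythmic ("dynamic") interactions: the abundance of the complex
# formed by two interacting proteins is approximated by the pointwise product
# of their expression profiles; the product is standardized and scored for
# 24-h periodicity exactly like a single-gene profile.

#' Complex abundance profile of an interacting pair
#'
#' Approximates the temporal abundance of the complex C = P1:P2 as
#' \eqn{A_C(t_i) = E_{P1}(t_i) \cdot E_{P2}(t_i)}, computed on the raw
#' non-negative profiles. Raw profiles are used because the product of two
#' zero-mean sinusoids has no 24-h component (only a 12-h harmonic): the
#' 24-h information in the complex profile comes from the baseline-times-
#' oscillation cross terms. Only the product is standardized before scoring.
#'
#' @param x1,x2 Raw (non-negative) expression vectors on the same time grid.
#' @param t Shared sampling times (hours); only used for validation here.
#' @return Numeric vector A_C. If the product is constant (e.g. both inputs
#'   flat) the result carries attribute `testable = FALSE`.
#' @export
complex_abundance <- function(x1, x2, t = NULL) {
  if (length(x1) != length(x2)) stop("profiles are on different time grids")
  if (!is.null(t) && length(t) != length(x1)) stop("time grid mismatch")
  a <- x1 * x2
  attr(a, "testable") <- pop_sd(a) > 0
  a
}

#' Call dynamic interactions across a network
#'
#' For every network edge whose two endpoints both have complete expression
#' profiles, forms the complex-abundance product profile, standardizes it,
#' scores 24-h periodicity with the Fourier score against a pooled
#' permutation background, assigns an empirical FDR q and a peak phase, and
#' flags edges with q below `fdr_threshold` as dynamic.
#'
#' Edges are undirected: duplicate A-B/B-A rows and self-loops are collapsed
#' or dropped (counted in the summary). Edges with an endpoint absent from
#' the matrix are reported as untested, not errors.
#'
#' @param edges data.frame with columns `idA`, `idB` (or an igraph object).
#' @param expr Expression matrix, genes x timepoints, rownames = gene ids.
#' @param t Sampling times (hours); parsed from column names by default.
#' @param fdr_threshold q threshold for the dynamic call (default 1e-5, the
#'   stringent genome-scale setting; relax for small runs).
#' @param B Permutation replicates for the pooled background.
#' @param grid_step Phase grid resolution (hours).
#' @param seed Optional integer seed.
#' @return Object of class `dynamic_network`: list with `edges` (data.frame:
#'   idA, idB, score, p, q, phase, dynamic, status), `counts`
#'   (tested/untested/non_testable/dynamic/duplicates_dropped), `scan`
#'   parameters.
#' @examples
#' sim <- simulate_expression(60, frac_rhythmic = 0.5, noise_sd = 0.02, seed = 1)
#' net <- simulate_network(sim$truth, n_nodes = 40, planted_dynamic_edges = 5,
#'                         seed = 2)
#' dn <- call_dynamic_edges(net$edges, sim$expr, fdr_threshold = 0.05,
#'                          B = 100, seed = 3)
#' dn
#' @export
call_dynamic_edges <- function(edges, expr, t = NULL, fdr_threshold = 1e-5,
                               B = 200, grid_step = 0.1, seed = NULL) {
  if (inherits(edges, "igraph")) {
    el <- igraph::as_edgelist(edges)
    edges <- data.frame(idA = el[, 1], idB = el[, 2], stringsAsFactors = FALSE)
  }
  stopifnot(all(c("idA", "idB") %in% names(edges)))
  expr <- as.matrix(expr)
  t <- t %||% parse_timepoints(colnames(expr), ncol(expr))

  n_in <- nrow(edges)
  self <- edges$idA == edges$idB
  edges <- edges[!self, , drop = FALSE]
  key <- paste(pmin(edges$idA, edges$idB), pmax(edges$idA, edges$idB))
  dup <- duplicated(key)
  edges <- edges[!dup, , drop = FALSE]
  n_dropped <- sum(self) + sum(dup)

  mapped <- edges$idA %in% rownames(expr) & edges$idB %in% rownames(expr)
  if (!any(mapped)) stop("no edge has both endpoints in the expression matrix")

  A <- expr[edges$idA[mapped], , drop = FALSE] *
       expr[edges$idB[mapped], , drop = FALSE]
  sds <- apply(A, 1L, pop_sd)
  testable_sub <- sds > 0

  status <- rep("tested", nrow(edges))
  status[!mapped] <- "unmapped"
  status[mapped][!testable_sub] <- "non_testable"

  score <- p <- q <- phase <- rep(NA_real_, nrow(edges))
  if (any(testable_sub)) {
    Z <- A[testable_sub, , drop = FALSE]
    Z <- (Z - rowMeans(Z)) / sds[testable_sub]
    obs <- fourier_score_matrix(Z, t, period = 24)
    bg <- with_seed(seed, {
      unlist(lapply(seq_len(B), function(b) {
        fourier_score_matrix(permute_rows(Z), t, period = 24)
      }), use.names = FALSE)
    })
    sb <- sort(bg)
    idx <- which(mapped)[testable_sub]
    score[idx] <- obs
    p[idx] <- (1 + length(bg) - findInterval(obs - 1e-12, sb)) / (length(bg) + 1)
    q[idx] <- empirical_fdr(obs, bg, n_sets = B)
    w <- 2 * pi / 24
    alphas <- seq(0, 24 - grid_step / 2, by = grid_step)
    ov <- outer(as.vector(Z %*% cos(w * t)), cos(w * alphas)) +
          outer(as.vector(Z %*% sin(w * t)), sin(w * alphas))
    phase[idx] <- alphas[max.col(ov, ties.method = "first")]
  }

  res <- data.frame(idA = edges$idA, idB = edges$idB, score = score, p = p,
                    q = q, phase = phase,
                    dynamic = !is.na(q) & q < fdr_threshold,
                    status = status, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(
    list(edges = res,
         counts = c(input = n_in, duplicates_dropped = n_dropped,
                    tested = sum(status == "tested"),
                    unmapped = sum(status == "unmapped"),
                    non_testable = sum(status == "non_testable"),
                    dynamic = sum(res$dynamic)),
         fdr_threshold = fdr_threshold, B = B, t = t, seed = seed),
    class = "dynamic_network"
  )
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat("Dynamic interaction calls (FDR < ", format(x$fdr_threshold),
      ", B = ", x$B, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
summary.dynamic_network <- function(object, ...) {
  e <- object$edges[object$edges$dynamic, ]
  cat("Dynamic edges: ", nrow(e), " of ", object$counts[["tested"]],
      " tested\n", sep = "")
  if (nrow(e) > 0) {
    cat("Phase distribution (h):\n")
    print(summary(e$phase))
  }
  invisible(object)
}

#' Per-protein count of dynamic interactions
#'
#' The "dynamic degree": how many predicted rhythmic interactions each
#' protein participates in. Proteins listed in `proteins` but absent from
#' every dynamic edge get a count of 0.
#'
#' @param dyn A `dynamic_network` object (or its `edges` data.frame).
#' @param proteins Optional character vector fixing the universe of proteins
#'   reported; defaults to every protein seen in the edge table.
#' @return Named integer vector of dynamic degrees.
#' @export
dynamic_degree <- function(dyn, proteins = NULL) {
  e <- if (inherits(dyn, "dynamic_network")) dyn$edges else dyn
  stopifnot(nrow(e) > 0)
  proteins <- proteins %||% sort(unique(c(e$idA, e$idB)))
  d <- e[which(e$dynamic), , drop = FALSE]
  cnt <- table(factor(c(d$idA, d$idB), levels = proteins))
  stats::setNames(as.integer(cnt), proteins)
}
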