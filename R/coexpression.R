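# Temporal co-expression of interacting pairs, enrichment against random
# pairs, party/date hub classification, and degree-vs-rhythmicity tests.

#' Pearson co-expression of interacting pairs
#'
#' Pearson correlation coefficient (PCC) of the two partners' expression
#' profiles for each pair; the measure of temporal co-expression.
#'
#' @param expr Expression matrix, genes x timepoints.
#' @param pairs data.frame with columns `idA`, `idB`.
#' @return data.frame `idA`, `idB`, `pcc`, `status`; pairs with an unmapped
#'   endpoint or a constant profile get `NA` with an explanatory status.
#' @export
pair_pcc <- function(expr, pairs) {
  expr <- as.matrix(expr)
  pcc <- rep(NA_real_, nrow(pairs))
  status <- rep("ok", nrow(pairs))
  mapped <- pairs$idA %in% rownames(expr) & pairs$idB %in% rownames(expr)
  status[!mapped] <- "unmapped"
  if (any(mapped)) {
    a <- expr[pairs$idA[mapped], , drop = FALSE]
    b <- expr[pairs$idB[mapped], , drop = FALSE]
    const <- apply(a, 1, pop_sd) == 0 | apply(b, 1, pop_sd) == 0
    r <- rep(NA_real_, nrow(a))
    if (any(!const)) {
      r[!const] <- vapply(which(!const), function(i)
        stats::cor(a[i, ], b[i, ]), numeric(1))
    }
    pcc[mapped] <- r
    status[mapped][const] <- "constant"
  }
  data.frame(idA = pairs$idA, idB = pairs$idB, pcc = pcc, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Co-expression enrichment of interacting pairs over random pairs
#'
#' Tests whether co-expressed pairs (PCC strictly greater than `pcc_cutoff`)
#' are over-represented among interacting pairs relative to random pairs of
#' profiled genes, with a 2x2 chi-squared test on counts above/below the
#' cutoff. Random pairs are drawn uniformly from genes in the matrix,
#' excluding the true interacting pairs.
#'
#' @param expr Expression matrix.
#' @param pairs Interacting pairs (data.frame `idA`, `idB`).
#' @param n_random Number of random pairs (>= 1000).
#' @param pcc_cutoff Co-expression cutoff (default 0.5; boundary values
#'   count as not co-expressed).
#' @param seed Optional integer seed.
#' @return List with `observed_fraction`, `random_fraction`, `p_value`,
#'   `table` (the 2x2 counts), and the two PCC vectors.
#' @export
coexpression_enrichment <- function(expr, pairs, n_random = 1000,
                                    pcc_cutoff = 0.5, seed = NULL) {
  if (n_random < 1000) stop("n_random must be >= 1000")
  genes <- rownames(expr)
  if (length(genes) < 2) stop("fewer than 2 profiled genes")
  obs <- pair_pcc(expr, pairs)
  obs <- obs$pcc[!is.na(obs$pcc)]
  taken <- paste(pmin(pairs$idA, pairs$idB), pmax(pairs$idA, pairs$idB))
  rnd <- with_seed(seed, {
    out <- matrix(character(0), 0, 2)
    while (nrow(out) < n_random) {
      a <- sample(genes, 2 * n_random, replace = TRUE)
      b <- sample(genes, 2 * n_random, replace = TRUE)
      ok <- a != b & !(paste(pmin(a, b), pmax(a, b)) %in% taken)
      out <- rbind(out, cbind(a[ok], b[ok]))
    }
    out[seq_len(n_random), , drop = FALSE]
  })
  rp <- pair_pcc(expr, data.frame(idA = rnd[, 1], idB = rnd[, 2],
                                  stringsAsFactors = FALSE))
  rnd_pcc <- rp$pcc[!is.na(rp$pcc)]
  tab <- rbind(interacting = c(sum(obs > pcc_cutoff), sum(obs <= pcc_cutoff)),
               random = c(sum(rnd_pcc > pcc_cutoff), sum(rnd_pcc <= pcc_cutoff)))
  colnames(tab) <- c("coexpressed", "not_coexpressed")
  test <- suppressWarnings(stats::chisq.test(tab))
  list(observed_fraction = tab[1, 1] / sum(tab[1, ]),
       random_fraction = tab[2, 1] / sum(tab[2, ]),
       p_value = test$p.value, table = tab,
       pcc_interacting = obs, pcc_random = rnd_pcc)
}

#' Classify a hub as party or date hub
#'
#' A party hub interacts with partners co-expressed with each other and with
#' the hub at similar times; a date hub meets its partners at different
#' times. The hub's mean PCC with its true partners is compared with
#' `n_background` random partner sets of equal size drawn from profiled
#' genes; empirical FDRs for "higher than chance" (`fdr_high`) and "lower
#' than chance" (`fdr_low`) yield the label: party if `fdr_high < fdr`, date
#' if `fdr_low < fdr`, otherwise unclassified.
#'
#' @param protein Hub identifier.
#' @param partners Character vector of interaction partners.
#' @param expr Expression matrix.
#' @param n_background Number of random partner sets (default 1000).
#' @param fdr Classification threshold (default 0.01).
#' @param background "random" draws all partners at random; "partial" keeps a
#'   uniformly chosen half of the true partners and resamples the rest.
#' @param seed Optional integer seed.
#' @return data.frame row: protein, k, mean_pcc, fdr_high, fdr_low, label.
#' @export
classify_hub <- function(protein, partners, expr, n_background = 1000,
                         fdr = 0.01, background = c("random", "partial"),
                         seed = NULL) {
  background <- match.arg(background)
  partners <- intersect(partners, rownames(expr))
  partners <- setdiff(partners, protein)
  if (length(partners) < 2 || !(protein %in% rownames(expr))) {
    stop("hub needs a profile and at least 2 profiled partners")
  }
  mean_partner_pcc <- function(set) {
    pp <- pair_pcc(expr, data.frame(idA = protein, idB = set,
                                    stringsAsFactors = FALSE))
    mean(pp$pcc, na.rm = TRUE)
  }
  obs <- mean_partner_pcc(partners)
  pool <- setdiff(rownames(expr), protein)
  k <- length(partners)
  bg <- with_seed(seed, vapply(seq_len(n_background), function(i) {
    set <- if (background == "random") {
      sample(pool, k)
    } else {
      keep <- sample(partners, floor(k / 2))
      c(keep, sample(setdiff(pool, keep), k - length(keep)))
    }
    mean_partner_pcc(set)
  }, numeric(1)))
  fdr_high <- (1 + sum(bg >= obs)) / (n_background + 1)
  fdr_low <- (1 + sum(bg <= obs)) / (n_background + 1)
  label <- if (fdr_high < fdr) "party" else if (fdr_low < fdr) "date"
           else "unclassified"
  data.frame(protein = protein, k = k, mean_pcc = obs, fdr_high = fdr_high,
             fdr_low = fdr_low, label = label, stringsAsFactors = FALSE)
}

#' Degree versus rhythmicity association tests
#'
#' Two complementary tests of the observation that highly connected proteins
#' tend to be rhythmically expressed: (a) a Wilcoxon rank test comparing the
#' degree of rhythmic vs non-rhythmic proteins; (b) a chi-squared test of
#' the rhythmic fraction between high-degree and low-degree strata, cut at a
#' degree quantile.
#'
#' @param degrees Named numeric vector of degrees.
#' @param rhythmic Named logical vector of rhythmicity calls (same names).
#' @param cut_quantile Degree quantile for the high/low stratification
#'   (default 0.5, the median).
#' @return List with `wilcoxon` and `chisq` htest objects plus the 2x2
#'   `table` and group sizes.
#' @export
degree_vs_rhythmicity_tests <- function(degrees, rhythmic,
                                        cut_quantile = 0.5) {
  common <- intersect(names(degrees), names(rhythmic))
  deg <- degrees[common]
  rh <- rhythmic[common]
  if (all(rh) || !any(rh)) stop("one rhythmicity stratum is empty")
  wt <- stats::wilcox.test(deg[rh], deg[!rh], exact = FALSE)
  cut <- stats::quantile(deg, cut_quantile)
  hi <- deg > cut
  if (all(hi) || !any(hi)) stop("one degree stratum is empty")
  tab <- table(high_degree = hi, rhythmic = rh)
  ct <- suppressWarnings(stats::chisq.test(tab))
  list(wilcoxon = wt, chisq = ct, table = tab,
       n_rhythmic = sum(rh), n_high_degree = sum(hi))
}

#' Rhythmic-fraction enrichment of a gene set
#'
#' Chi-squared test comparing the rhythmic fraction of a gene set (e.g. the
#' network, or its neighborhood alone) against the rhythmic fraction of the
#' whole expression data set.
#'
#' @param set_rhythmic,set_total Rhythmic count and size of the gene set.
#' @param pool_rhythmic,pool_total Rhythmic count and size of the pool.
#' @return htest object.
#' @export
rhythmic_enrichment <- function(set_rhythmic, set_total,
                                pool_rhythmic, pool_total) {
  tab <- rbind(set = c(set_rhythmic, set_total - set_rhythmic),
               pool = c(pool_rhythmic, pool_total - pool_rhythmic))
  suppressWarnings(stats::chisq.test(tab))
}
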