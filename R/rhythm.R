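#' Standardize an expression profile
#'
#' Centers and scales a time series to mean 0 and standard deviation 1 using
#' the population convention (divide by N). Rhythmicity scoring operates on
#' standardized profiles, so the score is invariant to baseline shifts and
#' overall scale.
#'
#' @param x Numeric vector of abundances, length >= 2.
#' @return The standardized vector. A constant profile cannot be standardized:
#'   it is returned as all-`NA` with attribute `testable = FALSE`, so callers
#'   can distinguish "flat, hence untestable" from a numeric failure.
#' @examples
#' standardize(c(1, 2, 3))
#' attr(standardize(c(5, 5, 5)), "testable")
#' @export
standardize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (anyNA(x)) stop("profile contains missing values")
  s <- pop_sd(x)
  if (s == 0) {
    out <- rep(NA_real_, length(x))
    attr(out, "testable") <- FALSE
    return(out)
  }
  out <- (x - mean(x)) / s
  attr(out, "testable") <- TRUE
  out
}

is_testable <- function(x) !isFALSE(attr(x, "testable")) && !anyNA(x)

#' Fourier score for periodicity at a fixed period
#'
#' The rhythmicity statistic: the magnitude of the frequency component of a
#' standardized time series at period `period`,
#' \deqn{F = \sqrt{\left(\sum_i x_i \cos\frac{2\pi t_i}{T}\right)^2 +
#'                 \left(\sum_i x_i \sin\frac{2\pi t_i}{T}\right)^2}.}
#' The unnormalized sum is used (no 1/N factor); any fixed scale convention
#' cancels in the permutation test, which compares scores of permuted copies
#' of the same series.
#'
#' @param x Standardized numeric vector (see [standardize()]).
#' @param t Sampling times in hours, same length as `x`.
#' @param period Test period in hours; 24 for circadian rhythmicity.
#' @return Non-negative scalar score.
#' @examples
#' t <- 0:47
#' fourier_score(standardize(cos(2 * pi * t / 24)), t)  # 24 * sqrt(2)
#' @export
fourier_score <- function(x, t, period = 24) {
  if (length(x) != length(t)) stop("x and t must have equal length")
  stopifnot(period > 0)
  if (!is_testable(x)) return(NA_real_)
  Mod(sum(x * exp(2i * pi * t / period)))
}

# Vectorized scorer: rows of X are profiles on the common grid t.
fourier_score_matrix <- function(X, t, period = 24) {
  as.vector(Mod(X %*% exp(2i * pi * t / period)))
}

# One permutation replicate: independently permute each row of X.
permute_rows <- function(X) {
  n <- ncol(X)
  t(apply(X, 1L, function(r) r[sample.int(n)]))
}

#' Permutation null distribution and p-value for the Fourier score
#'
#' Compares the observed score of a standardized profile with scores of
#' randomly permuted copies of the same series. The p-value uses the
#' add-one estimator \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\})/(B + 1)}.
#'
#' In pooled mode (`pool_with` supplied as a matrix of further standardized
#' profiles on the same grid) the background concatenates permuted scores
#' across all profiles; standardized profiles are exchangeable under the
#' null, and pooling raises the background resolution from B to B x G, which
#' is what makes very small empirical FDR thresholds attainable.
#'
#' @param x Standardized profile.
#' @param t Sampling times (hours).
#' @param period Test period (hours).
#' @param B Number of permutation replicates, >= 1.
#' @param pool_with Optional matrix (profiles x timepoints) of additional
#'   standardized profiles whose permuted scores join the background.
#' @param seed Optional integer seed.
#' @return List with `score`, `background` (numeric vector), and `p`.
#' @export
permutation_null <- function(x, t, period = 24, B = 1000, pool_with = NULL,
                             seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  obs <- fourier_score(x, t, period)
  X <- rbind(x, pool_with)
  bg <- with_seed(seed, {
    unlist(lapply(seq_len(B), function(b) {
      fourier_score_matrix(permute_rows(X), t, period)
    }), use.names = FALSE)
  })
  list(score = obs, background = bg,
       p = (1 + sum(bg >= obs)) / (length(bg) + 1))
}

#' Empirical false discovery rate from a permutation background
#'
#' For each observed score s, estimates
#' \deqn{q(s) = \frac{\#\{background \ge s\} / n_{sets}}{\#\{observed \ge s\}},}
#' i.e. the expected number of null scores reaching s per permutation
#' replicate divided by the number of observations reaching s, clipped to
#' \[0, 1\] and monotonized (step-up, as in Benjamini-Hochberg) so q is
#' non-increasing in the score.
#'
#' @param observed Numeric vector of observed scores.
#' @param background Numeric vector of pooled permuted scores.
#' @param n_sets Number of permutation replicates the background comprises;
#'   defaults to `length(background) / length(observed)`.
#' @return Numeric vector of q-values aligned with `observed`.
#' @export
empirical_fdr <- function(observed, background,
                          n_sets = length(background) / length(observed)) {
  if (length(background) == 0) stop("empty background")
  ok <- !is.na(observed)
  q <- rep(NA_real_, length(observed))
  obs <- observed[ok]
  sb <- sort(background)
  so <- sort(obs)
  n_bg_ge <- length(background) - findInterval(obs - 1e-12, sb)
  n_obs_ge <- length(obs) - findInterval(obs - 1e-12, so)
  raw <- pmin(1, pmax(0, (n_bg_ge / n_sets) / n_obs_ge))
  # enforce monotone non-increasing q in the score (step-up)
  o <- order(obs, decreasing = TRUE)
  raw[o] <- rev(cummin(rev(raw[o])))
  q[ok] <- raw
  q
}

#' Peak phase by cosine shifting
#'
#' Slides a cosine of the test period along the time axis and returns the
#' shift maximising the overlap \eqn{\sum_i x_i \cos(2\pi(t_i - \alpha)/T)}.
#' The best shift is the circadian phase of the profile, on \[0, 24) h for
#' T = 24. Ties are broken toward the smallest shift.
#'
#' @param x Standardized profile.
#' @param t Sampling times (hours).
#' @param period Test period (hours).
#' @param grid_step Shift grid resolution in hours (default 0.1).
#' @return Phase in hours, in \[0, period); `NA` for untestable profiles.
#' @export
assign_phase <- function(x, t, period = 24, grid_step = 0.1) {
  stopifnot(grid_step > 0)
  if (!is_testable(x)) return(NA_real_)
  alphas <- seq(0, period - grid_step / 2, by = grid_step)
  w <- 2 * pi / period
  # overlap(alpha) = C cos(w a) + S sin(w a), with C,S the Fourier sums
  C <- sum(x * cos(w * t))
  S <- sum(x * sin(w * t))
  overlap <- C * cos(w * alphas) + S * sin(w * alphas)
  alphas[which.max(overlap)]
}

#' Genome-wide rhythmicity scan
#'
#' Scores every row of an expression matrix for periodicity at `period`
#' hours, computes permutation p-values, empirical FDR q-values, and peak
#' phases, and flags rhythmic genes at a q threshold. This is the scan the
#' dynamic-interaction caller reuses for complex (product) profiles.
#'
#' Profiles with missing values are excluded and reported, not imputed;
#' constant profiles are flagged non-testable. By default the permutation
#' background is pooled across genes (see [permutation_null()]).
#'
#' @param expr Numeric matrix, genes x timepoints, with rownames.
#' @param t Sampling times in hours; defaults to hours parsed from column
#'   names (`"CT0"`..) or `0:(ncol-1)`.
#' @param period Test period (hours).
#' @param B Permutation replicates.
#' @param pooled Pool permuted scores across genes (default) or use each
#'   gene's own B-score background.
#' @param fdr_threshold q threshold for the `is_rhythmic` call.
#' @param grid_step Phase grid resolution (hours).
#' @param seed Optional integer seed for the permutations.
#' @return Object of class `rhythm_scan`: list with `results` (data.frame:
#'   gene_id, score, p, q, phase, is_rhythmic, status), `background`,
#'   and the call parameters.
#' @examples
#' sim <- simulate_expression(n_genes = 40, frac_rhythmic = 0.5, seed = 1)
#' rs <- detect_rhythms(sim$expr, B = 50, seed = 2)
#' summary(rs)
#' @export
detect_rhythms <- function(expr, t = NULL, period = 24, B = 200,
                           pooled = TRUE, fdr_threshold = 0.05,
                           grid_step = 0.1, seed = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  t <- t %||% parse_timepoints(colnames(expr), ncol(expr))
  if (length(t) != ncol(expr)) stop("length(t) must match ncol(expr)")
  if (B < 1) stop("B must be >= 1")

  status <- rep("ok", nrow(expr))
  status[apply(expr, 1L, anyNA)] <- "missing"
  sds <- apply(expr, 1L, pop_sd)
  status[status == "ok" & (is.na(sds) | sds == 0)] <- "constant"
  testable <- status == "ok"

  Z <- expr[testable, , drop = FALSE]
  Z <- (Z - rowMeans(Z)) / apply(Z, 1L, pop_sd)

  score <- p <- q <- phase <- rep(NA_real_, nrow(expr))
  bg <- numeric(0)
  if (any(testable)) {
    score[testable] <- fourier_score_matrix(Z, t, period)
    bg <- with_seed(seed, {
      unlist(lapply(seq_len(B), function(b) {
        fourier_score_matrix(permute_rows(Z), t, period)
      }), use.names = FALSE)
    })
    obs <- score[testable]
    if (pooled) {
      sb <- sort(bg)
      p[testable] <- (1 + length(bg) - findInterval(obs - 1e-12, sb)) /
        (length(bg) + 1)
      q[testable] <- empirical_fdr(obs, bg, n_sets = B)
    } else {
      G <- nrow(Z)
      bgm <- matrix(bg, nrow = G)  # G x B, per-gene backgrounds
      p[testable] <- (1 + rowSums(bgm >= obs)) / (B + 1)
      q[testable] <- empirical_fdr(obs, bg, n_sets = B)
    }
    w <- 2 * pi / period
    Cc <- as.vector(Z %*% cos(w * t))
    Ss <- as.vector(Z %*% sin(w * t))
    alphas <- seq(0, period - grid_step / 2, by = grid_step)
    ov <- outer(Cc, cos(w * alphas)) + outer(Ss, sin(w * alphas))
    phase[testable] <- alphas[max.col(ov, ties.method = "first")]
  }

  res <- data.frame(
    gene_id = rownames(expr), score = score, p = p, q = q, phase = phase,
    is_rhythmic = !is.na(q) & q < fdr_threshold, status = status,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(results = res, background = bg, period = period, B = B,
         pooled = pooled, fdr_threshold = fdr_threshold, t = t, seed = seed),
    class = "rhythm_scan"
  )
}

#' @export
print.rhythm_scan <- function(x, ...) {
  r <- x$results
  cat("Rhythmicity scan (period ", x$period, " h, B = ", x$B,
      if (x$pooled) ", pooled background" else ", per-gene background",
      ")\n", sep = "")
  cat("  profiles:  ", nrow(r), " (", sum(r$status != "ok"),
      " untestable)\n", sep = "")
  cat("  rhythmic:  ", sum(r$is_rhythmic), " at q < ", x$fdr_threshold,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.rhythm_scan <- function(object, ...) {
  r <- object$results
  out <- list(
    n = nrow(r),
    n_untestable = sum(r$status != "ok"),
    n_rhythmic = sum(r$is_rhythmic),
    fdr_threshold = object$fdr_threshold,
    score_quantiles = stats::quantile(r$score, na.rm = TRUE),
    phase_table = table(cut(r$phase[r$is_rhythmic],
                            breaks = seq(0, object$period, by = object$period / 4),
                            include.lowest = TRUE))
  )
  class(out) <- "summary.rhythm_scan"
  out
}

#' @export
print.summary.rhythm_scan <- function(x, ...) {
  cat("Profiles: ", x$n, " (", x$n_untestable, " untestable); rhythmic: ",
      x$n_rhythmic, " at q < ", x$fdr_threshold, "\n", sep = "")
  cat("Score quantiles:\n")
  print(x$score_quantiles)
  cat("Peak-phase distribution of rhythmic genes (h):\n")
  print(x$phase_table)
  invisible(x)
}

#' @export
coef.rhythm_scan <- function(object, ...) object$results

#' @export
plot.rhythm_scan <- function(x, ...) {
  r <- x$results[x$results$is_rhythmic, ]
  graphics::hist(r$phase, breaks = seq(0, x$period, by = 1),
                 main = "Peak phases of rhythmic profiles",
                 xlab = "phase (h)", ...)
  invisible(x)
}

# Parse "CT0".."CT47" or numeric column headers into hours.
parse_timepoints <- function(nm, n) {
  if (is.null(nm)) return(seq_len(n) - 1)
  hrs <- suppressWarnings(as.numeric(sub("^[Cc][Tt]", "", nm)))
  if (anyNA(hrs)) stop("cannot parse timepoints from column names")
  hrs
}
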