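t48 <- 0:47

make_expr <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- paste0("CT", t48)
  m
}

test_that("pair PCC matches the textbook covariance-ratio oracle", {
  set.seed(1)
  expr <- simulate_expression(20, frac_rhythmic = 0.5, seed = 2)$expr
  pairs <- data.frame(idA = rownames(expr)[1:10], idB = rownames(expr)[11:20])
  out <- pair_pcc(expr, pairs)
  for (i in 1:10) {
    a <- expr[pairs$idA[i], ]; b <- expr[pairs$idB[i], ]
    oracle <- mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
    expect_equal(out$pcc[i], oracle, tolerance = 1e-12)
  }
})

test_that("PCC endpoints: identity 1, antiphase -1, quadrature 0", {
  expr <- make_expr(a = cosine_profile(t48, 4), b = cosine_profile(t48, 4),
                    c = cosine_profile(t48, 16), d = cosine_profile(t48, 10),
                    e = rep(7, 48))
  out <- pair_pcc(expr, data.frame(idA = c("a", "a", "a", "a", "zz"),
                                   idB = c("b", "c", "d", "e", "a")))
  expect_equal(out$pcc[1], 1.0, tolerance = 1e-12)
  expect_equal(out$pcc[2], -1.0, tolerance = 1e-12)
  expect_equal(out$pcc[3], 0.0, tolerance = 1e-9)
  expect_equal(out$status[4], "constant")
  expect_equal(out$status[5], "unmapped")
})

test_that("co-expression enrichment is null for random pair construction", {
  sim <- simulate_expression(150, frac_rhythmic = 0.3, seed = 3)
  set.seed(4)
  fake <- data.frame(idA = sample(rownames(sim$expr), 200, replace = TRUE),
                     idB = sample(rownames(sim$expr), 200, replace = TRUE))
  fake <- fake[fake$idA != fake$idB, ]
  out <- coexpression_enrichment(sim$expr, fake, n_random = 1000, seed = 5)
  expect_gt(out$p_value, 0.05)
  expect_lt(abs(out$observed_fraction - out$random_fraction), 0.1)
})

test_that("planted co-phase pairs are strongly enriched in co-expression", {
  sim <- simulate_expression(300, frac_rhythmic = 0.25, noise_sd = 0.05,
                             seed = 6)
  net <- simulate_network(sim$truth, n_nodes = 200,
                          planted_dynamic_edges = 60,
                          planted_phase_offset_max = 1, seed = 7)
  planted <- net$planted[, c("idA", "idB")]
  out <- coexpression_enrichment(sim$expr, planted, n_random = 2000, seed = 8)
  expect_gt(out$observed_fraction, out$random_fraction + 0.3)
  expect_lt(out$p_value, 1e-6)
})

test_that("the 0.5 boundary counts as not co-expressed (strict >)", {
  # two gene pairs engineered to sit exactly at PCC 0.5 would be fragile;
  # instead verify the counting convention on the contingency construction
  expr <- make_expr(a = cosine_profile(t48, 0), b = cosine_profile(t48, 0),
                    c = cosine_profile(t48, 12))
  pairs <- data.frame(idA = "a", idB = "b")  # PCC exactly 1 > 0.5
  out <- coexpression_enrichment(expr, pairs, n_random = 1000,
                                 pcc_cutoff = 1, seed = 9)
  expect_equal(out$observed_fraction, 0)  # PCC == cutoff is not co-expressed
})

test_that("party and date hubs are recovered from engineered neighborhoods", {
  set.seed(10)
  n_bg <- 60
  bg_rows <- lapply(1:n_bg, function(i)
    cosine_profile(t48, runif(1, 0, 24)) + rnorm(48, 0, 5))
  names(bg_rows) <- paste0("bg", 1:n_bg)
  hub_prof <- cosine_profile(t48, 6)
  partners_party <- lapply(1:6, function(i) hub_prof + rnorm(48, 0, 2))
  names(partners_party) <- paste0("pp", 1:6)
  partners_date <- lapply(1:6, function(i)
    cosine_profile(t48, 18) + rnorm(48, 0, 2))  # antiphase to the hub
  names(partners_date) <- paste0("pd", 1:6)
  expr <- do.call(make_expr, c(list(hub = hub_prof), partners_party,
                               partners_date, bg_rows))
  party <- classify_hub("hub", paste0("pp", 1:6), expr, n_background = 500,
                        seed = 11)
  expect_equal(party$label, "party")
  date <- classify_hub("hub", paste0("pd", 1:6), expr, n_background = 500,
                       seed = 12)
  expect_equal(date$label, "date")
  expect_error(classify_hub("hub", "pp1", expr), "2 profiled partners")
})

test_that("randomly chosen partner sets stay unclassified at FDR 0.01", {
  sim <- simulate_expression(200, frac_rhythmic = 0.3, seed = 13)
  genes <- rownames(sim$expr)
  set.seed(14)
  labs <- vapply(1:20, function(i) {
    classify_hub(genes[i], sample(setdiff(genes, genes[i]), 8), sim$expr,
                 n_background = 200, seed = 100 + i)$label
  }, character(1))
  expect_gte(mean(labs == "unclassified"), 0.95)
})

test_that("degree-rhythmicity tests are null when independent, hot when planted", {
  set.seed(15)
  deg <- stats::setNames(rpois(200, 6) + 1, paste0("p", 1:200))
  rh_indep <- stats::setNames(runif(200) < 0.4, names(deg))
  null_out <- degree_vs_rhythmicity_tests(deg, rh_indep)
  expect_gt(null_out$wilcoxon$p.value, 0.01)

  rh_planted <- stats::setNames(runif(200) < ifelse(deg > stats::median(deg),
                                                    0.8, 0.15), names(deg))
  hot <- degree_vs_rhythmicity_tests(deg, rh_planted)
  expect_lt(hot$wilcoxon$p.value, 0.01)
  expect_lt(hot$chisq$p.value, 0.01)
  expect_error(degree_vs_rhythmicity_tests(deg, stats::setNames(
    rep(TRUE, 200), names(deg))), "stratum")
})

test_that("rhythmic-fraction enrichment chi-squared behaves at both poles", {
  enr <- rhythmic_enrichment(65, 134, 2000, 20000)
  expect_lt(enr$p.value, 1e-6)
  null_enr <- rhythmic_enrichment(40, 400, 2000, 20000)
  expect_gt(null_enr$p.value, 0.05)
})
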