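test_that("category-pair counting follows the stated conventions", {
  ann <- data.frame(gene = c("a1", "a2", "b1", "b2"),
                    category = c("A", "A", "B", "B"))
  ed <- data.frame(idA = c("a1", "a2", "a1"), idB = c("b1", "b2", "b2"))
  out <- count_category_links(ed, dynamic = c(TRUE, TRUE, TRUE), ann)
  ab <- out[out$catA == "A" & out$catB == "B", ]
  expect_equal(ab$n_interactions, 3)
  expect_equal(ab$n_dynamic, 3)
  expect_equal(sum(out$n_interactions) - ab$n_interactions, 0)

  none <- count_category_links(ed, dynamic = rep(FALSE, 3), ann)
  expect_true(all(none$n_dynamic == 0))
})

test_that("multi-annotated endpoints contribute to every qualifying pair", {
  ann <- data.frame(gene = c("x", "x", "y", "y"),
                    category = c("A", "B", "A", "B"))
  ed <- data.frame(idA = "x", idB = "y")
  out <- count_category_links(ed, dynamic = TRUE, ann)
  expect_equal(nrow(out), 3)  # (A,A), (A,B), (B,B)
  expect_true(all(out$n_interactions == 1))
  expect_true(all(out$n_dynamic == 1))
})

test_that("a pair holding every dynamic edge gets p_perm = 0", {
  ann <- data.frame(gene = c(paste0("a", 1:5), paste0("b", 1:5),
                             paste0("c", 1:10)),
                    category = c(rep("A", 5), rep("B", 5), rep("C", 10)))
  ed <- rbind(data.frame(idA = paste0("a", 1:5), idB = paste0("b", 1:5)),
              data.frame(idA = paste0("c", 1:9), idB = paste0("c", 2:10)))
  dyn <- c(rep(TRUE, 5), rep(FALSE, 9))
  out <- permutation_process_test(ed, dyn, ann, n_networks = 500, seed = 1)
  ab <- out[out$catA == "A" & out$catB == "B", ]
  expect_equal(ab$p_perm, 0)
  expect_true(ab$displayed)
})

test_that("zero dynamic edges give p_perm = 1 everywhere", {
  ann <- data.frame(gene = c("a", "b", "c"), category = c("A", "B", "A"))
  ed <- data.frame(idA = c("a", "b"), idB = c("b", "c"))
  out <- permutation_process_test(ed, c(FALSE, FALSE), ann,
                                  n_networks = 200, seed = 2)
  expect_true(all(out$p_perm == 1))
  expect_false(any(out$displayed))
  expect_error(permutation_process_test(ed, c(TRUE, FALSE), ann,
                                        n_networks = 10), "100")
})

test_that("p resolution changes with n_networks but observed counts do not", {
  ann <- simulate_annotation(sprintf("g%02d", 1:30), 4, 10, seed = 3)
  set.seed(4)
  ed <- data.frame(idA = sprintf("g%02d", sample(1:30, 40, TRUE)),
                   idB = sprintf("g%02d", sample(1:30, 40, TRUE)))
  ed <- ed[ed$idA != ed$idB, ]
  dyn <- seq_len(nrow(ed)) %% 3 == 0
  a <- permutation_process_test(ed, dyn, ann, n_networks = 200, seed = 5)
  b <- permutation_process_test(ed, dyn, ann, n_networks = 400, seed = 5)
  expect_identical(a$n_dynamic, b$n_dynamic)
  expect_identical(a$n_interactions, b$n_interactions)
})

test_that("permutation p matches a hypergeometric oracle for two categories", {
  # single-annotated genes, two categories: the number of dynamic edges in
  # pair (A,B) under label permutation is hypergeometric
  ann <- data.frame(gene = c(paste0("a", 1:6), paste0("b", 1:6)),
                    category = c(rep("A", 6), rep("B", 6)))
  set.seed(6)
  ed <- rbind(
    data.frame(idA = paste0("a", sample(1:6, 10, TRUE)),
               idB = paste0("b", sample(1:6, 10, TRUE))),
    data.frame(idA = paste0("a", c(1, 2, 3)), idB = paste0("a", c(4, 5, 6))))
  key <- paste(pmin(ed$idA, ed$idB), pmax(ed$idA, ed$idB))
  ed <- ed[!duplicated(key), ]
  m_ab <- sum(substr(ed$idA, 1, 1) != substr(ed$idB, 1, 1))
  n_e <- nrow(ed)
  dyn <- rep(FALSE, n_e); dyn[seq_len(5)] <- TRUE  # first 5 edges are A-B
  obs_ab <- sum(dyn & substr(ed$idA, 1, 1) != substr(ed$idB, 1, 1))
  out <- permutation_process_test(ed, dyn, ann, n_networks = 4000, seed = 7)
  ab <- out[out$catA == "A" & out$catB == "B", ]
  oracle <- stats::phyper(obs_ab, m_ab, n_e - m_ab, sum(dyn),
                          lower.tail = FALSE)
  expect_equal(ab$p_perm, oracle, tolerance = 0.02)
})

test_that("p_perm is invariant to category relabeling", {
  ann <- simulate_annotation(sprintf("g%02d", 1:20), 3, 8, seed = 8)
  set.seed(9)
  ed <- data.frame(idA = sprintf("g%02d", sample(1:20, 30, TRUE)),
                   idB = sprintf("g%02d", sample(1:20, 30, TRUE)))
  ed <- ed[ed$idA != ed$idB, ]
  dyn <- seq_len(nrow(ed)) %% 2 == 0
  a <- permutation_process_test(ed, dyn, ann, n_networks = 300, seed = 10)
  relab <- ann
  relab$category <- chartr("123", "312", relab$category)  # permute ids
  b <- permutation_process_test(ed, dyn, relab, n_networks = 300, seed = 10)
  bkey <- paste(pmin(chartr("312", "123", b$catA),
                     chartr("312", "123", b$catB)),
                pmax(chartr("312", "123", b$catA),
                     chartr("312", "123", b$catB)))
  akey <- paste(pmin(a$catA, a$catB), pmax(a$catA, a$catB))
  expect_equal(a$p_perm[order(akey)], b$p_perm[order(bkey)])
})

test_that("multi-annotation only inflates the dynamic pair total", {
  ann1 <- data.frame(gene = letters[1:6], category = rep(c("A", "B"), 3))
  ed <- data.frame(idA = letters[1:5], idB = letters[2:6])
  dyn <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  single <- count_category_links(ed, dyn, ann1)
  expect_equal(sum(single$n_dynamic), sum(dyn))  # equality, single-annotated
  ann2 <- rbind(ann1, data.frame(gene = "a", category = "B"))
  multi <- count_category_links(ed, dyn, ann2)
  expect_gte(sum(multi$n_dynamic), sum(dyn))
})

test_that("category enrichment finds planted categories and BH-corrects", {
  genes <- sprintf("g%03d", 1:100)
  ann <- rbind(data.frame(gene = genes[1:20], category = "DYN"),
               data.frame(gene = genes[21:60], category = "X"),
               data.frame(gene = genes[61:100], category = "Y"))
  dd <- stats::setNames(c(rep(2, 20), rep(0, 80)), genes)
  out <- category_node_enrichment(ann, dd)
  expect_equal(out$category[1], "DYN")
  expect_lt(out$p[1], 1e-10)
  expect_true(all(out$fdr >= out$p))

  all_dyn <- stats::setNames(rep(1, 100), genes)
  flat <- category_node_enrichment(ann, all_dyn)
  expect_true(all(flat$p == 1))
})
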