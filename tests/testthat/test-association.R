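test_that("mean_pcc averages present members and excludes the query itself", {
  r <- corr_from_pairs(c("Q", "a", "b"),
                       list(list("Q", "a", 0.5), list("Q", "b", 0.3),
                            list("a", "b", 0.1)))
  fit <- toy_fit(r)
  res <- mean_pcc(fit, "Q", c("a", "b"))
  expect_equal(res$mean_pcc, 0.4)
  expect_equal(res$n_genes_used, 2)

  # self-exclusion
  r2 <- corr_from_pairs(c("Q", "a"), list(list("Q", "a", 0.6)))
  res2 <- mean_pcc(toy_fit(r2), "Q", c("Q", "a"))
  expect_equal(res2$mean_pcc, 0.6)
  expect_equal(res2$n_genes_used, 1)

  # absent members are dropped silently but counted out
  res3 <- mean_pcc(fit, "Q", c("a", "missing_gene"))
  expect_equal(res3$mean_pcc, 0.5)
  expect_equal(res3$n_genes_used, 1)

  expect_error(mean_pcc(fit, "Q", "missing_gene"), "empty effective set")
})

test_that("score_library reproduces the hand-computed per-term z and tail p-values", {
  # background mean PCCs with the term gene t1 are r(g, t1) = 0.1, 0.2, 0.3;
  # query g3 sits at 0.3 -> mu = 0.2, sd (ddof=1) = 0.1, z = 1
  r <- corr_from_pairs(c("g1", "g2", "g3", "t1"),
                       list(list("g1", "t1", 0.1), list("g2", "t1", 0.2),
                            list("g3", "t1", 0.3), list("g1", "g2", 0),
                            list("g1", "g3", 0), list("g2", "g3", 0)))
  fit <- toy_fit(r)
  sc <- score_library(fit, "g3", gene_set_library(list(term1 = "t1")),
                      background = c("g1", "g2", "g3"))
  expect_equal(sc$mean_pcc, 0.3)
  expect_equal(sc$z, 1)
  expect_equal(sc$p_right, 1 - pnorm(1), tolerance = 1e-12)
  expect_equal(sc$p_right, 0.158655, tolerance = 1e-5)
  expect_equal(sc$p_right + sc$p_left, 1, tolerance = 1e-12)

  # query at the null mean -> z = 0, both tails 0.5
  sc2 <- score_library(fit, "g2", gene_set_library(list(term1 = "t1")),
                       background = c("g1", "g2", "g3"))
  expect_equal(sc2$z, 0)
  expect_equal(sc2$p_right, 0.5)
  expect_equal(sc2$p_left, 0.5)
})

test_that("score_library z-scores match a from-scratch recomputation on a 10-term library", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:30)
  m <- matrix(rnorm(30 * 40, mean = 4), 30, 40,
              dimnames = list(genes, sprintf("s%02d", 1:40)))
  fit <- coexpression(expr_matrix(m, "quantile_normalized"), theta = 0.01)
  lib <- random_library(10, genes, seed = 22, min_size = 3, max_size = 8)
  query <- "g05"
  sc <- score_library(fit, query, lib, background = genes)
  for (term in names(lib)) {
    all_mp <- vapply(genes, function(g) {
      eff <- setdiff(intersect(lib[[term]], genes), g)
      mean(fit$r[g, eff])
    }, 0)
    z_hand <- (all_mp[query] - mean(all_mp)) / sd(all_mp)
    expect_equal(sc$z[sc$term == term], unname(z_hand), tolerance = 1e-12)
  }
  expect_equal(sc$p_right + sc$p_left, rep(1, nrow(sc)), tolerance = 1e-12)
  # results come back sorted by right-tail p
  expect_false(is.unsorted(sc$p_right))
})

test_that("degenerate per-term null (sd = 0) is flagged with half p-values", {
  # every background gene has the same correlation with the term gene
  r <- corr_from_pairs(c("g1", "g2", "t1"),
                       list(list("g1", "t1", 0.4), list("g2", "t1", 0.4),
                            list("g1", "g2", 0)))
  sc <- score_library(toy_fit(r), "g1", gene_set_library(list(T = "t1")),
                      background = c("g1", "g2"))
  expect_true(sc$degenerate)
  expect_equal(sc$p_right, 0.5)
  expect_equal(sc$p_left, 0.5)
})

test_that("predict() on a coexpression fit dispatches to score_library", {
  r <- corr_from_pairs(c("g1", "g2", "g3", "t1"),
                       list(list("g1", "t1", 0.1), list("g2", "t1", 0.2),
                            list("g3", "t1", 0.3)))
  fit <- toy_fit(r)
  lib <- gene_set_library(list(term1 = "t1"))
  expect_identical(predict(fit, "g3", lib, background = c("g1", "g2", "g3")),
                   score_library(fit, "g3", lib, background = c("g1", "g2", "g3")))
})

test_that("rank_genes_for_set sorts by mean PCC with lexicographic ties", {
  r <- corr_from_pairs(c("X", "Y", "B", "A", "t1"),
                       list(list("X", "t1", 0.4), list("Y", "t1", 0.1),
                            list("B", "t1", 0.2), list("A", "t1", 0.2)))
  fit <- toy_fit(r)
  rk <- rank_genes_for_set(fit, c("X", "Y"), "t1")
  expect_equal(rk$gene, c("X", "Y"))
  tied <- rank_genes_for_set(fit, c("B", "A"), "t1")
  expect_equal(tied$gene, c("A", "B"))
  # a candidate inside the target set is still ranked, via self-exclusion
  rk2 <- rank_genes_for_set(fit, c("X", "t1"), c("t1", "X"))
  expect_true("t1" %in% rk2$gene)
  expect_error(rank_genes_for_set(fit, character(0), "t1"), "no candidate")
})

test_that("deg_filter applies all three thresholds, splits by sign, truncates", {
  rec <- data.frame(
    gene = c("fc_low", "fdr_high", "z_low", "up_ok", "down_ok"),
    log2FC = c(0.4, 1.2, 0.8, 0.9, -1.2),
    FDR = c(0.01, 0.2, 0.01, 0.03, 0.04),
    zscore = c(2.0, 3.0, 1.0, 2.5, -1.7))
  sets <- deg_filter(rec)
  expect_identical(sets$up, "up_ok")
  expect_identical(sets$down, "down_ok")

  # truncation: 300 passing up-records -> exactly 200 kept, largest |FC| first
  many <- data.frame(gene = sprintf("g%03d", 1:300),
                     log2FC = seq(0.6, 3, length.out = 300),
                     FDR = 0.01, zscore = 3)
  kept <- deg_filter(many, top_n = 200)
  expect_length(kept$up, 200)
  expect_identical(kept$up[1], "g300")
  expect_length(kept$down, 0)
})

test_that("overlap significance equals the hypergeometric tail enumeration", {
  u <- paste0("u", 1:20)
  res <- overlap_significance(u[1:5], u[1:5], u)
  expect_equal(res$overlap, 5)
  expect_equal(res$fisher_p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$fisher_p, hyper_tail_p(5, 5, 5, 20), tolerance = 1e-12)

  # degenerate: both sets are the whole universe
  res2 <- overlap_significance(u, u, u)
  expect_equal(res2$fisher_p, 1)

  # randomized 2x2 tables on universes <= 100 against the brute-force oracle
  set.seed(33)
  for (i in 1:25) {
    n_u <- sample(10:100, 1)
    uni <- paste0("x", seq_len(n_u))
    a <- sample(uni, sample.int(n_u, 1))
    b <- sample(uni, sample.int(n_u, 1))
    got <- overlap_significance(a, b, uni)
    want <- hyper_tail_p(length(intersect(a, b)), length(a), length(b), n_u)
    expect_equal(got$fisher_p, want, tolerance = 1e-9)
  }
  expect_error(overlap_significance("a", "b", character(0)), "empty universe")
})

test_that("auroc equals exhaustive pair counting, including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(c(0.8, 0.2, 0.6, 0.4), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(auroc(rep(1, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)

  set.seed(44)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    l <- runif(n) < 0.4
    if (!any(l) || all(l)) next
    expect_identical(auroc(s, l), pairs_auroc(s, l))
  }
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "at least one")
})

test_that("roc_points starts at (0,0), ends at (1,1), and is monotone", {
  set.seed(55)
  s <- runif(50); l <- runif(50) < 0.5
  rp <- roc_points(s, l)
  expect_equal(unlist(rp[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rp[nrow(rp), ]), c(fpr = 1, tpr = 1))
  expect_false(is.unsorted(rp$fpr))
  expect_false(is.unsorted(rp$tpr))
})
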