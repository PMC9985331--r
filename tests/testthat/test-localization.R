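# Toy geometry used below: 4 weight genes with RCIs {+2, +2, -2, -2}; query A
# correlates perfectly with the cytoplasmic pair, query B with the nuclear
# pair, so after min-max normalization A must land at +0.5 and B at -0.5.
toy_localization <- function() {
  genes <- c("A", "B", "c1", "c2", "n1", "n2")
  pairs <- list(list("A", "c1", 0.9), list("A", "c2", 0.8),
                list("A", "n1", -0.8), list("A", "n2", -0.9),
                list("B", "c1", -0.8), list("B", "c2", -0.9),
                list("B", "n1", 0.9), list("B", "n2", 0.8),
                list("A", "B", -0.5))
  fit <- toy_fit(corr_from_pairs(genes, pairs))
  rci <- structure(matrix(c(2, 2, -2, -2, NA, NA), ncol = 1,
                          dimnames = list(c("c1", "c2", "n1", "n2", "A", "B"), "CL1")),
                   class = c("rci_table", "matrix", "array"))
  list(fit = fit, rci = rci)
}

test_that("rank-weighted RCI sums separate cytoplasmic from nuclear queries", {
  toy <- toy_localization()
  pred <- predict_localization(toy$fit, toy$rci, queries = c("A", "B"))
  expect_equal(pred$score["A", "CL1"], 0.5)
  expect_equal(pred$score["B", "CL1"], -0.5)
  expect_gt(pred$raw_sum["A", "CL1"], pred$raw_sum["B", "CL1"])
  # missing RCI entries (A, B have none) contribute nothing
  expect_equal(unname(pred$n_weights[, "CL1"]), c(4L, 4L))
})

test_that("scores stay in [-0.5, 0.5] with per-cell-line extremes attained", {
  set.seed(88)
  cfg <- synthetic_config(n_genes = 200, n_samples = 120, n_modules = 2,
                          module_size = 25, random_seed = 88)
  sim <- generate_counts(cfg)
  fit <- coexpression(sim$counts)
  rci <- generate_rci(sim$truth, cfg)
  queries <- sim$truth$gene_id[sim$truth$module %in% 1:2]
  pred <- predict_localization(fit, rci, queries)
  expect_true(all(pred$score >= -0.5 & pred$score <= 0.5))
  for (cl in colnames(pred$score)) {
    expect_equal(min(pred$score[, cl]), -0.5)
    expect_equal(max(pred$score[, cl]), 0.5)
  }
})

test_that("the query's own RCI never leaks into its weighted sum", {
  toy <- toy_localization()
  # give query A an extreme measured RCI; its prediction must not move
  rci_leak <- toy$rci
  base <- predict_localization(toy$fit, toy$rci, queries = c("A", "B"))
  rci_leak["A", "CL1"] <- 50
  leak <- predict_localization(toy$fit, rci_leak, queries = c("A", "B"))
  expect_equal(leak$raw_sum["A", "CL1"], base$raw_sum["A", "CL1"])
  # but it does contribute to OTHER queries' sums
  expect_false(leak$raw_sum["B", "CL1"] == base$raw_sum["B", "CL1"])
})

test_that("rank01 spans exactly {0, 1/(G-2), ..., 1} and is monotone in r", {
  toy <- toy_localization()
  fit <- toy$fit
  G <- 6
  # uniform +1 RCI turns the raw sum into the sum of rank01 values
  rci1 <- structure(matrix(1, 6, 1, dimnames = list(fit$gene_ids, "CL")),
                    class = c("rci_table", "matrix", "array"))
  pred <- predict_localization(fit, rci1, queries = c("A", "B"))
  expect_equal(unname(pred$raw_sum[, "CL"]),
               rep(sum((seq_len(G - 1) - 1) / (G - 2)), 2))

  # raising a query's correlation with a positive-RCI gene never lowers raw_sum
  r_hi <- corr_from_pairs(fit$gene_ids,
                          list(list("A", "c1", 0.95), list("A", "c2", 0.8),
                               list("A", "n1", -0.8), list("A", "n2", -0.9),
                               list("B", "c1", -0.8), list("B", "c2", -0.9),
                               list("B", "n1", 0.9), list("B", "n2", 0.8),
                               list("A", "B", -0.5)))
  pred_hi <- predict_localization(toy_fit(r_hi), toy$rci, queries = c("A", "B"))
  base <- predict_localization(fit, toy$rci, queries = c("A", "B"))
  expect_gte(pred_hi$raw_sum["A", "CL1"], base$raw_sum["A", "CL1"])
})

test_that("planted nuclear/cytoplasmic structure is recovered with high AUROC", {
  cfg <- synthetic_config(n_genes = 500, n_samples = 200, n_modules = 2,
                          module_size = 100, rci_effect = 2, random_seed = 9)
  sim <- generate_counts(cfg)
  fit <- coexpression(sim$counts)
  rci <- generate_rci(sim$truth, cfg)
  queries <- sim$truth$gene_id[sim$truth$module %in% 1:2]  # 200 queries
  pred <- predict_localization(fit, rci, queries)
  ev <- evaluate_localization(pred, rci)
  expect_true(all(!ev$skipped))
  expect_true(all(ev$auroc >= 0.95))

  # perfect ordering gives AUROC exactly 1; shuffled scores sit near 0.5
  measured <- intersect(queries, rownames(rci))
  cl <- ev$cell_line[1]
  v <- unclass(rci)[measured, cl]
  lab <- v[!is.na(v) & abs(v) > 1] > 1
  set.seed(10)
  expect_equal(auroc(ifelse(lab, 2, 1), lab), 1)
  expect_lt(abs(auroc(rnorm(length(lab)), lab) - 0.5), 0.15)
})

test_that("cell lines are reported by descending AUROC with lexicographic ties", {
  ev <- data.frame(cell_line = c("F", "E", "D", "C", "B", "A"),
                   auroc = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                   n_pos = 5, n_neg = 5, skipped = FALSE)
  expect_identical(select_reporting_cell_lines(ev, 5), c("F", "E", "D", "C", "B"))

  tie <- data.frame(cell_line = c("B", "A"), auroc = c(0.9, 0.9),
                    n_pos = 5, n_neg = 5, skipped = FALSE)
  expect_identical(select_reporting_cell_lines(tie, 1), "A")
  expect_warning(all_of_them <- select_reporting_cell_lines(tie, 5), "only 2")
  expect_identical(all_of_them, c("A", "B"))
})

test_that("degenerate inputs are handled: single query and empty cell line", {
  toy <- toy_localization()
  expect_warning(one <- predict_localization(toy$fit, toy$rci, queries = "A"),
                 "single query")
  expect_equal(unname(one$score["A", "CL1"]), 0)

  rci_empty <- toy$rci
  rci_empty[, 1] <- NA
  expect_error(predict_localization(toy$fit, rci_empty, queries = c("A", "B")),
               "no measured RCI")
})
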