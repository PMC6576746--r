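test_that("cell-line classification keeps the printed boundary inclusivity", {
  lab <- classify_cell_lines(c(a = 5.0, b = 1.95, c = 1.3, d = 1.5, e = 0.1))
  expect_equal(as.character(lab$label),
               c("sensitive", "sensitive", "resistant", "intermediate",
                 "resistant"))
})

test_that("pooled t-test matches hand arithmetic and the reference implementation", {
  expr <- rbind(gene1 = c(3, 4, 5, 1, 2, 3))
  colnames(expr) <- c("s1", "s2", "s3", "r1", "r2", "r3")
  labels <- setNames(c(rep("sensitive", 3), rep("resistant", 3)),
                     colnames(expr))
  st <- gene_t_test(expr, labels)
  expect_equal(st$t, 2 * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(st$p, 2 * pt(-2 * sqrt(3 / 2), 4), tolerance = 1e-12)
  expect_equal(round(st$p, 4), 0.0705)

  # random matrices against stats::t.test with pooled variance
  set.seed(8)
  expr2 <- matrix(rnorm(50 * 12), 50, 12,
                  dimnames = list(paste0("g", 1:50), paste0("l", 1:12)))
  labels2 <- setNames(rep(c("sensitive", "resistant"), each = 6),
                      colnames(expr2))
  st2 <- gene_t_test(expr2, labels2)
  for (g in c(1, 17, 50)) {
    ref <- t.test(expr2[g, 1:6], expr2[g, 7:12], var.equal = TRUE)
    expect_equal(st2$t[g], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(st2$p[g], ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and undersized groups follow the contract", {
  expr <- rbind(same = rep(2, 6), diff = c(2, 2, 2, 0, 0, 0))
  colnames(expr) <- paste0("l", 1:6)
  labels <- setNames(rep(c("sensitive", "resistant"), each = 3),
                     colnames(expr))
  st <- gene_t_test(expr, labels)
  expect_equal(st[st$gene == "same", ]$t, 0)
  expect_equal(st[st$gene == "same", ]$p, 1)
  expect_equal(st[st$gene == "diff", ]$t, Inf)
  expect_equal(st[st$gene == "diff", ]$p, 0)

  small <- setNames(c("sensitive", "sensitive", "resistant",
                      rep("intermediate", 3)), colnames(expr))
  expect_error(gene_t_test(expr, small), "resistant group")
})

test_that("intermediate cell lines are excluded from the comparison", {
  set.seed(30)
  expr <- matrix(rnorm(10 * 9), 10, 9,
                 dimnames = list(paste0("g", 1:10), paste0("l", 1:9)))
  labs_all <- setNames(c(rep("sensitive", 3), rep("resistant", 3),
                         rep("intermediate", 3)), colnames(expr))
  st_with <- gene_t_test(expr, labs_all)
  st_without <- gene_t_test(expr[, 1:6], labs_all[1:6])
  expect_equal(st_with$t, st_without$t)
})

test_that("fold change follows the printed piecewise ratio convention", {
  expect_equal(fold_change(4, 2), 2)
  expect_equal(fold_change(2, 4), -2)
  expect_equal(fold_change(3, 3), 1)
  # antisymmetry away from ties
  set.seed(10)
  es <- runif(20, 1, 10); er <- runif(20, 1, 10)
  off_tie <- es != er
  expect_equal(fold_change(es, er)[off_tie], -fold_change(er, es)[off_tie],
               tolerance = 1e-12)
  # non-positive applicable denominator is flagged as NA
  expect_warning(fc <- fold_change(c(4, 5), c(0, 2)), "non-positive")
  expect_identical(is.na(fc), c(TRUE, FALSE))
  # conventional log-difference variant behind the flag
  expect_equal(fold_change(4, 2, log_ratio = TRUE), 2)
})

test_that("q-values implement the rank-scaled formula without step-up", {
  expect_equal(q_values(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(q_values(0.2), 0.2)
  # ties share the mean rank and get identical q
  expect_equal(q_values(rep(0.05, 4)), rep(0.05 / 2.5 * 4, 4))
  # permutation equivariance
  set.seed(12)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(q_values(p)[perm], q_values(p[perm]))
})

test_that("gene selection is strict in q and split by fold-change sign", {
  st <- data.frame(gene = c("a", "b", "c", "d"),
                   q = c(1.0e-3, 9e-4, 5e-4, 2e-4),
                   fold_change = c(3, 2, -2, NA))
  sel <- select_genes(st)
  expect_equal(sel$sensitivity, "b")  # a excluded: q == cutoff
  expect_equal(sel$resistance, "c")   # d excluded: NA fold change
  empty <- select_genes(st[0, ])
  expect_length(empty$sensitivity, 0)
})

test_that("over-representation matches exact hypergeometric enumeration", {
  uni <- paste0("g", 1:20)
  res <- overrepresentation(uni[1:8], list(hit = uni[1:5]), uni)
  expect_equal(res$p, choose(15, 3) / choose(20, 8), tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (5 / 8) / (5 / 20))
  # selection == term: fold enrichment is N/K
  res2 <- overrepresentation(uni[1:5], list(hit = uni[1:5]), uni)
  expect_equal(res2$fold_enrichment, 20 / 5)
  expect_error(overrepresentation(c("zzz"), list(hit = uni[1:5]), uni),
               "subset")
  expect_message(
    res3 <- overrepresentation(uni[1:8], list(hit = uni[1:5],
                                              ghost = "not_here"), uni),
    "skipped")
  expect_equal(nrow(res3), 1L)
  expect_equal(res3$bonferroni, pmin(1, res3$p * 1))
})

test_that("over-representation p-values are uniform under null selections", {
  set.seed(17)
  uni <- paste0("g", 1:200)
  term <- list(t1 = uni[1:40])
  ps <- replicate(1000,
    overrepresentation(sample(uni, 30), term, uni)$p)
  # discrete conservative test: rejection rate at 0.05 must not exceed it
  # by more than binomial noise, and p-values must not concentrate low
  expect_lt(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("the full sensitivity screen finds planted differential genes", {
  sim <- simulate_expression(n_genes = 300, n_sensitive = 20,
                             n_resistant = 20, n_de_genes = 20,
                             effect_size = 2, seed = 19)
  scr <- sensitivity_screen(sim$expr, sim$activity_areas)
  de_stats <- scr$stats[match(sim$de_genes, scr$stats$gene), ]
  # a two-log2 shift at n = 20 per group is detected essentially always ...
  expect_true(all(de_stats$p < 0.05))
  expect_true(all(de_stats$fold_change > 0))
  # ... and most planted genes survive the strict q < 1e-3 selection,
  # which stays far from selecting everything
  expect_gte(mean(sim$de_genes %in% scr$selected$sensitivity), 0.8)
  expect_lt(length(scr$selected$sensitivity), 60)
})
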