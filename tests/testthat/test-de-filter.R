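test_that("pooled t-test matches the closed form and stats::t.test", {
  sym <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  res <- student_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$p, 0.2879, tolerance = 2e-4)
  expect_equal(res$df, 4)
  # dual route: vectorised implementation vs stats::t.test on random input
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    ours <- student_t_test(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # degenerate zero-variance inputs
  expect_warning(zv <- student_t_test(c(1, 1, 1), c(2, 2, 2)), "sentinel")
  expect_true(is.infinite(zv$t))
  expect_equal(zv$p, 0)
  expect_error(student_t_test(1, c(1, 2)), ">= 2")
})

test_that("t p-values agree with an exhaustive permutation oracle on average", {
  set.seed(21)
  diffs <- replicate(40, {
    x <- rnorm(6); y <- rnorm(6)
    abs(student_t_test(x, y)$p - exact_perm_p(x, y))
  })
  expect_lte(mean(diffs), 0.02)
})

test_that("test_all_genes is calibrated under the null and powered on planted effects", {
  nul <- simulate_expression(1000, n_per_group = 3, n_de = 0, seed = 2)
  de0 <- test_all_genes(nul$matrix, nul$labels)
  expect_equal(nrow(de0), 1000)
  expect_lt(abs(mean(de0$significant) - 0.05), 0.02)
  expect_true(all(de0$p >= 0 & de0$p <= 1))
  expect_identical(de0$significant, de0$p < 0.05)
  eff <- simulate_expression(1000, n_per_group = 3, n_de = 100,
                             effect_size = 3, seed = 11)
  de <- test_all_genes(eff$matrix, eff$labels)
  expect_gt(mean(eff$ground_truth$de_gene_ids %in%
                   de$gene[de$significant]), 0.5)
  one <- simulate_expression(1, n_per_group = 3, seed = 1)
  expect_equal(nrow(test_all_genes(one$matrix, one$labels)), 1)
})

test_that("permutation FDR is near 1 under the null and small with planted signal", {
  # pure null, averaged over derived seeds (3 MC-SE discipline)
  null_fdrs <- vapply(101:103, function(s) {
    sim <- simulate_expression(1000, n_per_group = 3, n_de = 0, seed = s)
    permutation_fdr(sim$matrix, sim$labels, n_perm = 100, seed = s)$fdr
  }, numeric(1))
  expect_gte(mean(null_fdrs), 0.8)
  # planted 5-sigma effects shrink the estimate well below the null
  sim <- simulate_expression(1000, n_per_group = 3, n_de = 100,
                             effect_size = 5, seed = 13)
  f <- permutation_fdr(sim$matrix, sim$labels, n_perm = 100, seed = 13)
  expect_lt(f$fdr, 0.5)
  # 3v3 permutation space is enumerated exhaustively: 19 relabelings
  expect_equal(f$n_perm_used, 19)
  f2 <- permutation_fdr(sim$matrix, sim$labels, n_perm = 100, seed = 13)
  expect_identical(f, f2)
  # no significant genes -> flagged not-estimable
  flat <- sim
  flat$matrix[] <- 1
  ne <- suppressWarnings(permutation_fdr(flat$matrix, flat$labels,
                                         n_perm = 100, seed = 1))
  expect_false(ne$estimable)
  expect_true(is.na(ne$fdr))
})

test_that("candidate refinement keeps responsive proteins and reports the rest", {
  cat_ <- toy_catalogue()
  pool <- query_candidates(cat_, mw_window(5456), include_chains = TRUE)
  # ACC1 (glycine 80-mer, ~4582 Da), ACC2 (5456), ACC4 chain (4950)
  expect_setequal(unique(pool$candidates$accession),
                  c("ACC1", "ACC2", "ACC4"))
  probe_map <- data.frame(probe_id = c("pr1", "pr2a", "pr2b"),
                          accession = c("ACC1", "ACC2", "ACC2"))
  de_noise <- data.frame(gene = c("pr1", "pr2a", "pr2b"),
                         t = 0, p = c(0.5, 0.9, 0.01))
  de_noise$significant <- de_noise$p < 0.05
  de_ouab <- data.frame(gene = c("pr1", "pr2a", "pr2b"), t = 0, p = 0.9)
  de_ouab$significant <- de_ouab$p < 0.05
  out <- refine_candidates(pool, de_noise, de_ouab, probe_map)
  # any-mapped-probe rule: ACC2 kept through pr2b; ACC4 unmapped, reported
  expect_setequal(unique(out$refined$candidates$accession), "ACC2")
  expect_setequal(out$unmapped, "ACC4")
  expect_equal(out$summary$either_n, 1)
  expect_true(all(out$refined$candidates$accession %in%
                    pool$candidates$accession))
  # no significant probes anywhere -> empty pool, reduction 100
  none <- de_noise; none$significant <- FALSE
  out2 <- refine_candidates(pool, none, de_ouab, probe_map)
  expect_equal(nrow(out2$refined$candidates), 0)
  expect_equal(out2$summary$reduction_pct, 100L)
  # everything significant -> pool unchanged among mapped, reduction from
  # unmapped only
  all_sig <- de_noise; all_sig$significant <- TRUE
  out3 <- refine_candidates(pool, all_sig, de_ouab, probe_map)
  expect_setequal(unique(out3$refined$candidates$accession),
                  c("ACC1", "ACC2"))
})

test_that("refinement summary arithmetic reproduces the published percentages", {
  t2 <- load_reference_tables()$table2
  for (i in seq_len(nrow(t2))) {
    s <- summarize_refinement(t2$signal[i], t2$candidates[i], t2$noise_n[i],
                              t2$ouabain_n[i], t2$either_n[i])
    expect_identical(s$noise_pct, t2$noise_pct[i])
    expect_identical(s$ouabain_pct, t2$ouabain_pct[i])
    expect_identical(s$either_pct, t2$either_pct[i])
    expect_identical(s$reduction_pct, t2$reduction_pct[i])
    # count coherence holds on every published row
    expect_lte(t2$either_n[i], t2$noise_n[i] + t2$ouabain_n[i])
    expect_gte(t2$either_n[i], max(t2$noise_n[i], t2$ouabain_n[i]))
  }
  expect_error(summarize_refinement(1000, 10, 5, 5, 20), "either_count")
})
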