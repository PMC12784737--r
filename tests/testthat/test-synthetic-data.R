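test_that("locus frequency draws are simplex points, reproducible, and Dirichlet-centred", {
  cfg <- sim_config(seed = 9, alleles_per_locus = c(6, 6),
                    dirichlet_concentration = 1)
  p <- draw_locus_frequencies(cfg, 1)
  expect_true(all(p >= 0))
  expect_lt(abs(sum(p) - 1), 1e-12)
  expect_identical(p, draw_locus_frequencies(cfg, 1))
  expect_false(identical(p, draw_locus_frequencies(cfg, 2)))

  # moment oracle: symmetric Dirichlet(1) over k=6 has mean 1/k and
  # var (1/k)(1-1/k)/(k+1); check the first-component mean over many draws
  draws <- vapply(seq_len(4000), function(j)
    draw_locus_frequencies(cfg, j)[1], numeric(1))
  se <- sqrt((1 / 6) * (5 / 6) / 7 / 4000)
  expect_lt(abs(mean(draws) - 1 / 6), 3 * se)
})

test_that("founder genotypes follow the partial-selfing copy model", {
  set.seed(42)
  # degenerate frequency vector: all copies are the single allele
  expect_equal(simulate_founder_genotype(c(A = 1), 6, 0), rep(1L, 6))

  # multinomial oracle at s = 0: expected copy count of allele a is 6 p_a
  p <- c(0.5, 0.3, 0.2)
  n <- 10000
  cnt <- numeric(3)
  for (i in seq_len(n)) {
    g <- simulate_founder_genotype(p, 6, 0)
    cnt <- cnt + tabulate(g, 3)
  }
  for (a in 1:3) {
    se <- sqrt(6 * p[a] * (1 - p[a]) * n)  # conservative binomial bound
    expect_lt(abs(cnt[a] - 6 * p[a] * n), 3 * se)
  }

  # near-complete selfing: almost every genotype collapses to one allele
  mono <- mean(vapply(seq_len(2000), function(i)
    length(unique(simulate_founder_genotype(p, 6, 0.9999))) == 1, logical(1)))
  expect_gt(mono, 0.99)
})

test_that("phenotypes are the distinct-allele sets of their genotypes", {
  expect_equal(phenotype_from_genotype(rep(3L, 6)), 3L)
  expect_equal(phenotype_from_genotype(c(1L, 1L, 2L, 2L, 3L, 3L)), 1:3)
  for (i in 1:20) {
    g <- sample(1:8, 6, replace = TRUE)
    ph <- phenotype_from_genotype(g)
    expect_lte(length(ph), 6)
    expect_gte(length(ph), 1)
  }
})

test_that("scoring noise hits cells at the configured rates and respects the no-empty rule", {
  big <- make_matrix(matrix(rep(c(1L, 0L), each = 4, times = 2500), 100, 200,
                            byrow = TRUE),
                     locus = rep(sprintf("L%02d", 1:25), each = 8))
  cfg0 <- sim_config(dropout_rate = 0, false_allele_rate = 0,
                     locus_missing_rate = 0)
  expect_identical(apply_errors(big, cfg0, seed = 1)$calls, big$calls)

  cfg <- sim_config(dropout_rate = 0.05, false_allele_rate = 0.02,
                    locus_missing_rate = 0)
  noisy <- apply_errors(big, cfg, seed = 7)
  n_pres <- sum(big$calls == 1L)
  n_abs <- sum(big$calls == 0L)
  dropped <- sum(big$calls == 1L & noisy$calls == 0L)
  gained <- sum(big$calls == 0L & noisy$calls == 1L)
  expect_lt(abs(dropped / n_pres - 0.05), 3 * sqrt(0.05 * 0.95 / n_pres))
  expect_lt(abs(gained / n_abs - 0.02), 3 * sqrt(0.02 * 0.98 / n_abs))
  # dropout alone never empties a scored sample-locus
  heavy <- apply_errors(big, sim_config(dropout_rate = 0.95,
                                        false_allele_rate = 0,
                                        locus_missing_rate = 0), seed = 3)
  for (ln in locus_names(heavy)) {
    sub <- heavy$calls[, heavy$locus == ln, drop = FALSE]
    expect_true(all(rowSums(sub == 1L, na.rm = TRUE) >= 1))
  }

  all_missing <- apply_errors(big, sim_config(locus_missing_rate = 1), seed = 2)
  expect_true(all(is.na(all_missing$calls)))
})

test_that("simulated datasets are reproducible, valid, and clones are exact pre-error copies", {
  cfg <- sim_config(seed = 4, dropout_rate = 0, false_allele_rate = 0,
                    locus_missing_rate = 0)
  sim <- simulate_dataset(cfg)
  expect_identical(sim, simulate_dataset(cfg))
  expect_equal(nrow(validate_ssr_matrix(sim$matrix)), 0L)
  expect_equal(nrow(sim$matrix$calls), length(sim$truth$clone_group))
  # with zero noise, within-clone Jaccard distances are exactly 0
  d <- jaccard_matrix(sim$matrix)
  for (f in unique(sim$truth$clone_group)) {
    ids <- names(sim$truth$clone_group)[sim$truth$clone_group == f]
    if (length(ids) > 1) expect_true(all(d[ids, ids] == 0))
  }
  # truth frequencies are simplex vectors; genotypes carry full dosage
  expect_true(all(vapply(sim$truth$true_frequencies,
                         function(p) abs(sum(p) - 1) < 1e-12, logical(1))))
  expect_true(all(vapply(sim$truth$founder_genotypes[[1]], length,
                         integer(1)) == cfg$ploidy))
})

test_that("clone groups are recovered at the 0.05 threshold under dropout-only noise", {
  sim <- simulate_dataset(sim_config(seed = 1, dropout_rate = 0.01,
                                     false_allele_rate = 0,
                                     locus_missing_rate = 0))
  rep <- find_duplicates(jaccard_matrix(sim$matrix), threshold = 0.05)
  met <- duplicate_metrics(rep, sim$truth$clone_group)
  expect_gte(met$recall, 0.95)
  expect_gte(met$precision, 0.95)
})

test_that("within-clone distances grow with the dropout rate", {
  mean_within <- vapply(c(0.01, 0.05, 0.15), function(rate) {
    sim <- simulate_dataset(sim_config(seed = 8, dropout_rate = rate,
                                       false_allele_rate = 0,
                                       locus_missing_rate = 0))
    d <- jaccard_matrix(sim$matrix)
    cg <- sim$truth$clone_group
    within <- c()
    for (f in unique(cg)) {
      ids <- names(cg)[cg == f]
      if (length(ids) > 1) within <- c(within, d[ids, ids][upper.tri(d[ids, ids])])
    }
    mean(within)
  }, numeric(1))
  expect_true(all(diff(mean_within) > 0))
})
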