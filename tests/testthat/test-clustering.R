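test_that("Jaccard dissimilarity matches hand counts and the co-scored-locus policy", {
  m <- make_matrix(rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(0L, 0L, 1L)),
                   locus = rep("L1", 3))
  d <- jaccard_matrix(m)
  expect_equal(d["S1", "S2"], 0)
  expect_equal(d["S1", "S3"], 1)   # disjoint presence sets

  # 20 shared presences, one extra band in one sample: 1 - 20/21
  a <- rep(1L, 21); b <- c(rep(1L, 20), 0L)
  m2 <- make_matrix(rbind(a, b), locus = rep(sprintf("L%02d", 1:7), each = 3),
                    ploidy = 6)
  d2 <- jaccard_matrix(m2)
  expect_equal(d2[1, 2], 1 - 20 / 21)

  # a locus missing in one sample is excluded for that pair only
  m3 <- make_matrix(rbind(c(1L, 0L, 1L, 0L), c(1L, 0L, NA, NA),
                          c(0L, 1L, 0L, 1L)),
                    locus = c("A", "A", "B", "B"))
  d3 <- jaccard_matrix(m3)
  expect_equal(d3["S1", "S2"], 0)      # only locus A comparable, identical
  expect_equal(d3["S1", "S3"], 1)
  # pair with no co-scored locus is undefined and reported
  m4 <- make_matrix(rbind(c(1L, 0L, NA, NA), c(NA, NA, 1L, 0L)),
                    locus = c("A", "A", "B", "B"))
  d4 <- jaccard_matrix(m4)
  expect_true(is.na(d4[1, 2]))
  expect_equal(nrow(attr(d4, "undefined")), 1L)
})

test_that("Jaccard agrees with vegan on complete binary data and is a metric", {
  skip_if_not_installed("vegan")
  set.seed(33)
  calls <- matrix(rbinom(10 * 24, 1, 0.4), 10, 24)
  calls[rowSums(calls) == 0, 1] <- 1L
  m <- make_matrix(calls, locus = rep(sprintf("L%d", 1:4), each = 6),
                   ploidy = 12)
  d <- jaccard_matrix(m)
  ref <- as.matrix(vegan::vegdist(calls, method = "jaccard", binary = TRUE))
  expect_equal(unname(as.matrix(d)), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)

  # triangle inequality on random binary triples
  for (i in 1:100) {
    tri <- matrix(rbinom(3 * 15, 1, 0.5), 3, 15)
    tri[rowSums(tri) == 0, 1] <- 1L
    dt <- jaccard_matrix(make_matrix(tri, locus = rep("L1", 15), ploidy = 15))
    expect_lte(dt[1, 3], dt[1, 2] + dt[2, 3] + 1e-12)
    expect_lte(dt[1, 2], dt[1, 3] + dt[2, 3] + 1e-12)
    expect_lte(dt[2, 3], dt[1, 2] + dt[1, 3] + 1e-12)
  }
})

test_that("NJ reproduces the 3-taxon closed form and additive 4-taxon trees", {
  d3 <- matrix(c(0, 0.4, 0.6, 0.4, 0, 0.8, 0.6, 0.8, 0), 3, 3,
               dimnames = rep(list(c("A", "B", "C")), 2))
  tr <- nj_tree(d3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.1)
  expect_equal(bl[["B"]], 0.3)
  expect_equal(bl[["C"]], 0.5)

  # additive matrix from a known tree: path lengths are recovered exactly
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
  dd <- ape::cophenetic.phylo(ref)
  tr4 <- nj_tree(dd)
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(dd), colnames(dd)], dd,
               tolerance = 1e-12)

  # identical samples become zero-length sister leaves
  d0 <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5, 0), 3, 3,
               dimnames = rep(list(c("X1", "X2", "Y")), 2))
  tr0 <- nj_tree(d0)
  bl0 <- setNames(tr0$edge.length, tr0$tip.label[tr0$edge[, 2]])
  expect_equal(bl0[["X1"]], 0)
  expect_equal(bl0[["X2"]], 0)

  expect_error(nj_tree(matrix(NA_real_, 3, 3)), "undefined")
})

test_that("Newick serialisation round-trips topology, lengths, supports and quoted labels", {
  d <- matrix(c(0, .1, .4, .5, .1, 0, .4, .5, .4, .4, 0, .3, .5, .5, .3, 0),
              4, 4, dimnames = rep(list(c("a b", "c", "d e", "f")), 2))
  tr <- nj_tree(d)
  tr$node.label <- c("", "95")
  txt <- to_newick(tr)
  expect_match(txt, "'a b'", fixed = TRUE)
  back <- from_newick(txt)
  expect_setequal(back$tip.label, rownames(d))
  expect_true("95" %in% back$node.label)
  # same bipartitions and branch lengths
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
  expect_equal(ape::cophenetic.phylo(back)[rownames(d), rownames(d)],
               ape::cophenetic.phylo(tr)[rownames(d), rownames(d)],
               tolerance = 1e-9)

  f <- withr::local_tempfile(fileext = ".nwk")
  to_newick(tr, f)
  expect_setequal(from_newick(path = f)$tip.label, rownames(d))
})

test_that("bootstrap supports are deterministic under a seed and certain for replicated signal", {
  # one two-group signal duplicated across every locus: no resampling variance
  block <- rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 1L), c(1L, 1L))
  calls <- do.call(cbind, rep(list(block), 5))
  m <- make_matrix(calls, locus = rep(sprintf("L%d", 1:5), each = 2))
  tr <- bootstrap_support(m, n_reps = 30, seed = 5)
  sup <- attr(tr, "support")
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  expect_true(any(sup == 100))

  sim <- simulate_dataset(sim_config(seed = 12, n_founders = 6))
  t1 <- bootstrap_support(sim$matrix, n_reps = 25, seed = 11)
  t2 <- bootstrap_support(sim$matrix, n_reps = 25, seed = 11)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  expect_true(all(attr(t1, "support") >= 0 & attr(t1, "support") <= 100))
})

test_that("well-separated clone groups get strong deep support", {
  sim <- simulate_dataset(sim_config(seed = 15, n_founders = 5,
                                     clones_per_founder = c(3, 3),
                                     dropout_rate = 0.01,
                                     false_allele_rate = 0.005,
                                     locus_missing_rate = 0))
  tr <- bootstrap_support(sim$matrix, n_reps = 200, seed = 2)
  # every clone triple is a bipartition of the true grouping; collect the
  # support of the edges separating complete clone groups
  cg <- sim$truth$clone_group
  sup <- attr(tr, "support")
  nt <- length(tr$tip.label)
  # scan every internal node for the bipartition separating one clone group
  found <- c()
  for (f in unique(cg)) {
    ids <- names(cg)[cg == f]
    for (nd in (nt + 1):(nt + tr$Nnode)) {
      tips <- ape::extract.clade(tr, nd)$tip.label
      if (setequal(tips, ids) || setequal(setdiff(tr$tip.label, tips), ids)) {
        found <- c(found, sup[nd - nt])
        break
      }
    }
  }
  expect_gt(length(found), 0)
  expect_true(mean(found > 90) >= 0.8)
})

test_that("duplicate flagging is strict at the threshold and groups by single linkage", {
  ids <- c("P", "Q", "R", "S")
  d <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["P", "Q"] <- d["Q", "P"] <- 1 - 20 / 21  # 0.0476... -> flagged
  d["R", "S"] <- d["S", "R"] <- 0.05         # exactly at threshold -> not
  rep <- find_duplicates(d, threshold = 0.05)
  expect_equal(nrow(rep$pairs), 1L)
  expect_equal(sort(c(rep$pairs$sample1, rep$pairs$sample2)), c("P", "Q"))
  expect_equal(rep$groups, list(c("P", "Q")))

  none <- find_duplicates(matrix(0.8, 3, 3,
                                 dimnames = rep(list(letters[1:3]), 2)) -
                            diag(0.8, 3))
  expect_equal(nrow(none$pairs), 0L)
  expect_equal(length(none$groups), 0L)

  # chained pairs form one group
  d2 <- matrix(0.5, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  diag(d2) <- 0
  d2["a", "b"] <- d2["b", "a"] <- 0.01
  d2["b", "c"] <- d2["c", "b"] <- 0.02
  rep2 <- find_duplicates(d2)
  expect_equal(rep2$groups, list(c("a", "b", "c")))
})

test_that("per-locus verification lists differing alleles and skips missing loci", {
  calls <- rbind(c(1L, 0L, 1L, 0L), c(1L, 0L, 1L, 0L))
  m <- make_matrix(calls, locus = c("A", "A", "B", "B"))
  v <- verify_profiles(m, c("S1", "S2"))
  expect_true(all(v$match))
  expect_equal(attr(v, "mismatch_count"), 0L)

  calls2 <- rbind(c(1L, 0L, 1L, 0L), c(1L, 1L, NA, NA))
  m2 <- make_matrix(calls2, locus = c("A", "A", "B", "B"))
  v2 <- verify_profiles(m2, c("S1", "S2"))
  expect_equal(v2$comparable, c(TRUE, FALSE))
  expect_false(v2$match[1])
  expect_equal(v2$differing_alleles[1], "104")
  expect_equal(attr(v2, "mismatch_count"), 1L)
  expect_error(verify_profiles(m2, c("S1", "nope")), "nope")
})

test_that("ROC separates perfect data, is chance-level on random labels, and matches pROC", {
  sim <- simulate_dataset(sim_config(seed = 20, dropout_rate = 0,
                                     false_allele_rate = 0,
                                     locus_missing_rate = 0))
  d <- jaccard_matrix(sim$matrix)
  roc <- threshold_roc(d, sim$truth$clone_group)
  expect_equal(attr(roc, "auc"), 1)
  expect_true(all(diff(roc$specificity) <= 1e-12))   # non-increasing
  expect_true(all(roc$sensitivity >= 0 & roc$sensitivity <= 1))

  # random labels: AUC near 1/2
  set.seed(77)
  rand <- setNames(sample(rep(letters[1:10], length.out = nrow(as.matrix(d)))),
                   rownames(as.matrix(d)))
  auc_r <- attr(threshold_roc(d, rand), "auc")
  expect_lt(abs(auc_r - 0.5), 0.15)

  skip_if_not_installed("pROC")
  m <- as.matrix(d)
  ut <- upper.tri(m)
  lab <- sim$truth$clone_group[rownames(m)]
  same <- outer(lab, lab, "==")[ut]
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(same, c(FALSE, TRUE)),
    predictor = -m[ut], quiet = TRUE)))
  expect_equal(attr(roc, "auc"), as.numeric(ref), tolerance = 1e-9)
})
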