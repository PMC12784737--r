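# small construction helpers shared across test files

# build an ssr_matrix from a plain 0/1/NA matrix; default: one locus per
# column unless a locus vector is given
make_matrix <- function(calls, locus = NULL, allele = NULL, ids = NULL,
                        groups = NULL, ploidy = 6L) {
  calls <- as.matrix(calls)
  if (is.null(locus)) locus <- rep("L1", ncol(calls))
  if (is.null(allele)) {
    allele <- integer(ncol(calls))
    for (ln in unique(locus))
      allele[locus == ln] <- 100L + 2L * seq_len(sum(locus == ln))
  }
  if (is.null(ids))
    ids <- if (nrow(calls)) paste0("S", seq_len(nrow(calls))) else character(0)
  if (nrow(calls) > 0) rownames(calls) <- ids
  samples <- data.frame(sample_id = ids,
                        group = if (is.null(groups))
                          rep("study", length(ids)) else groups,
                        stringsAsFactors = FALSE)
  ssr_matrix(calls, locus = locus, allele = allele, samples = samples,
             ploidy = ploidy)
}

# genotype matrix of n hexaploid samples drawn from one locus with known
# frequencies, under the partial-selfing model
sample_locus_matrix <- function(n, p, s = 0, ploidy = 6L, seed = 1L) {
  set.seed(seed)
  labels <- if (is.null(names(p))) as.character(seq_along(p)) else names(p)
  calls <- t(vapply(seq_len(n), function(i) {
    g <- simulate_founder_genotype(p, ploidy, s)
    as.integer(seq_along(p) %in% g)
  }, integer(length(p))))
  make_matrix(calls, locus = rep("L1", length(p)),
              allele = 100L + 2L * seq_along(p), ploidy = ploidy)
}

# pairwise precision/recall of a duplicate report against true clone labels,
# using the report's groups (connected components) as the prediction
duplicate_metrics <- function(report, clone_group) {
  ids <- names(clone_group)
  grp <- setNames(rep(seq_along(report$groups), lengths(report$groups)),
                  unlist(report$groups))
  pred <- grp[ids]
  pairs <- utils::combn(length(ids), 2)
  same_true <- clone_group[pairs[1, ]] == clone_group[pairs[2, ]]
  same_pred <- !is.na(pred[pairs[1, ]]) & !is.na(pred[pairs[2, ]]) &
    pred[pairs[1, ]] == pred[pairs[2, ]]
  list(recall = sum(same_true & same_pred) / sum(same_true),
       precision = if (any(same_pred))
         sum(same_true & same_pred) / sum(same_pred) else NA_real_)
}

# exhaustive unordered-pair collision fraction, the oracle for the
# confusion-probability formula
collision_fraction <- function(counts) {
  v <- rep(seq_along(counts), times = counts)
  eq <- outer(v, v, "==")
  sum(eq[upper.tri(eq)]) / choose(length(v), 2)
}
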