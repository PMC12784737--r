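#' Flag candidate duplicate samples below a dissimilarity threshold
#'
#' Pairs with Jaccard dissimilarity strictly below the threshold (default
#' 0.05, the operational cut-off for clonal duplicates in germplasm
#' collections) are flagged, and duplicate groups are formed as connected
#' components of the flagged-pair graph (single linkage). Pairs with no
#' defined distance are excluded from flagging and reported separately.
#'
#' @param d an \code{ssr_dist} from [jaccard_matrix()] (or a symmetric
#'   matrix with sample-id dimnames)
#' @param threshold strict upper bound for flagging (default 0.05)
#' @return a \code{duplicate_report}: list with \code{pairs} (data.frame
#'   \code{sample1, sample2, d}), \code{groups} (list of sample-id vectors),
#'   \code{threshold} and \code{undefined} (pairs without a defined distance)
#' @export
find_duplicates <- function(d, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  m <- as.matrix(d)
  ids <- rownames(m)
  idx <- which(upper.tri(m) & !is.na(m) & m < threshold, arr.ind = TRUE)
  pairs <- data.frame(sample1 = ids[idx[, 1]], sample2 = ids[idx[, 2]],
                      d = m[idx], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$d, pairs$sample1, pairs$sample2), , drop = FALSE]
  rownames(pairs) <- NULL
  # connected components via union-find over flagged pairs
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    i <- find(match(pairs$sample1[r], ids))
    j <- find(match(pairs$sample2[r], ids))
    if (i != j) parent[j] <- i
  }
  root <- vapply(seq_along(ids), find, integer(1))
  in_pair <- ids %in% c(pairs$sample1, pairs$sample2)
  groups <- split(ids[in_pair], root[in_pair])
  groups <- unname(groups[order(vapply(groups, `[`, character(1), 1L))])
  undefined <- if (!is.null(attr(d, "undefined"))) attr(d, "undefined") else
    data.frame(sample1 = character(), sample2 = character())
  structure(list(pairs = pairs, groups = groups, threshold = threshold,
                 undefined = undefined),
            class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat(sprintf("duplicate_report: %d flagged pairs in %d groups (d < %g)\n",
              nrow(x$pairs), length(x$groups), x$threshold))
  for (g in x$groups) cat("  [", paste(g, collapse = ", "), "]\n", sep = "")
  if (nrow(x$undefined))
    cat(sprintf("  %d pairs with no co-scored locus excluded\n",
                nrow(x$undefined)))
  invisible(x)
}

#' Per-locus verification of a candidate duplicate pair
#'
#' Compares the allele profiles of two samples locus by locus: loci missing
#' in either sample are reported as not comparable and excluded from the
#' mismatch count; for comparable loci the differing allele labels are
#' listed.
#'
#' @param x an [ssr_matrix()]
#' @param pair character vector of two sample ids
#' @return data.frame with columns \code{locus}, \code{comparable},
#'   \code{match}, \code{differing_alleles}; attribute
#'   \code{"mismatch_count"} gives the number of mismatching comparable loci
#' @export
verify_profiles <- function(x, pair) {
  stopifnot(inherits(x, "ssr_matrix"), length(pair) == 2)
  miss <- setdiff(pair, rownames(x$calls))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  i <- match(pair[1], rownames(x$calls))
  j <- match(pair[2], rownames(x$calls))
  rows <- lapply(locus_names(x), function(ln) {
    cols <- locus_cols(x, ln)
    a <- x$calls[i, cols]; b <- x$calls[j, cols]
    if (anyNA(a) || anyNA(b))
      return(data.frame(locus = ln, comparable = FALSE, match = NA,
                        differing_alleles = "", stringsAsFactors = FALSE))
    diff <- x$allele[cols][a != b]
    data.frame(locus = ln, comparable = TRUE, match = length(diff) == 0,
               differing_alleles = paste(diff, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mismatch_count") <- sum(out$comparable & !out$match)
  out
}

#' ROC evaluation of duplicate detection against known clone labels
#'
#' Treats every pair of samples as a classification instance (positive =
#' same clone group) and sweeps the flagging threshold over the observed
#' dissimilarities: at threshold t a pair is flagged when d < t. Reports
#' sensitivity and specificity per threshold and the area under the ROC
#' curve (the Mann-Whitney pair-ranking probability; ties count 1/2).
#'
#' @param d an \code{ssr_dist} (or symmetric matrix with id dimnames)
#' @param clone_labels named vector mapping every sample id to its clone
#'   group
#' @return data.frame with columns \code{threshold}, \code{sensitivity},
#'   \code{specificity}; attribute \code{"auc"} holds the AUC
#' @export
threshold_roc <- function(d, clone_labels) {
  m <- as.matrix(d)
  ids <- rownames(m)
  if (!all(ids %in% names(clone_labels)))
    stop("clone_labels must cover all samples")
  lab <- clone_labels[ids]
  ut <- upper.tri(m)
  dv <- m[ut]
  same <- outer(lab, lab, "==")[ut]
  keep <- !is.na(dv)
  dv <- dv[keep]; same <- same[keep]
  n_pos <- sum(same); n_neg <- sum(!same)
  if (n_pos == 0) stop("no positive (same-clone) pairs")
  if (n_neg == 0)
    warning("all pairs share one clone group; specificity undefined")
  thr <- sort(unique(c(dv, max(dv) + 1e-9)))
  sens <- vapply(thr, function(t) sum(same & dv < t) / n_pos, numeric(1))
  spec <- if (n_neg > 0)
    vapply(thr, function(t) sum(!same & dv >= t) / n_neg, numeric(1))
  else rep(NA_real_, length(thr))
  auc <- if (n_neg > 0) {
    dp <- dv[same]; dn <- dv[!same]
    (sum(outer(dp, dn, "<")) + 0.5 * sum(outer(dp, dn, "=="))) /
      (n_pos * n_neg)
  } else NA_real_
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  attr(out, "auc") <- auc
  out
}

#' Write a duplicate report as CSV and JSON
#'
#' The CSV lists flagged pairs with their dissimilarity and mismatching
#' loci (from [verify_profiles()] when a matrix is supplied); the JSON holds
#' the groups.
#'
#' @param report a \code{duplicate_report}
#' @param csv_path,json_path output files (either may be \code{NULL})
#' @param x optional [ssr_matrix()] for per-pair locus verification
#' @return invisibly, the pair table written
#' @export
write_duplicate_report <- function(report, csv_path = NULL, json_path = NULL,
                                   x = NULL) {
  stopifnot(inherits(report, "duplicate_report"))
  pairs <- report$pairs
  if (!is.null(x) && nrow(pairs)) {
    pairs$mismatching_loci <- vapply(seq_len(nrow(pairs)), function(r) {
      v <- verify_profiles(x, c(pairs$sample1[r], pairs$sample2[r]))
      paste(v$locus[v$comparable & !v$match], collapse = ";")
    }, character(1))
  }
  if (!is.null(csv_path)) utils::write.csv(pairs, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(threshold = report$threshold,
                              groups = report$groups,
                              pairs = pairs),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(pairs)
}
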