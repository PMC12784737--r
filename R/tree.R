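#' Unweighted neighbor-joining tree from a dissimilarity matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]. Negative branch lengths, which
#' NJ can produce on non-additive input, are retained by default so that the
#' tree reproduces additive inputs exactly; set \code{clamp_negative = TRUE}
#' to truncate them at zero for display.
#'
#' @param d an \code{ssr_dist}, \code{dist} or symmetric matrix; must contain
#'   no undefined (\code{NA}) entries
#' @param clamp_negative truncate negative branch lengths at zero
#' @return an unrooted \code{phylo} tree
#' @export
nj_tree <- function(d, clamp_negative = FALSE) {
  m <- as.matrix(d)
  if (anyNA(m))
    stop("dissimilarity matrix has undefined entries; NJ needs a complete matrix")
  if (nrow(m) < 3) stop("NJ needs at least 3 samples")
  tr <- ape::nj(stats::as.dist(m))
  if (clamp_negative) tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# distances for one locus-resampled replicate; undefined pairs (no co-scored
# locus in the draw) are imputed with the mean defined distance
resample_distance <- function(x, loci_drawn) {
  cols <- unlist(lapply(loci_drawn, function(ln) locus_cols(x, ln)),
                 use.names = FALSE)
  xb <- ssr_matrix(x$calls[, cols, drop = FALSE],
                   locus = paste0(x$locus[cols], "#",
                                  rep(seq_along(loci_drawn),
                                      times = vapply(loci_drawn, function(ln)
                                        length(locus_cols(x, ln)), integer(1)))),
                   allele = x$allele[cols], samples = x$samples,
                   ploidy = x$ploidy)
  d <- jaccard_matrix(xb)
  if (anyNA(d)) d[is.na(d)] <- mean(d[upper.tri(d)], na.rm = TRUE)
  d
}

#' Locus-level bootstrap support for the NJ tree
#'
#' Resamples loci with replacement (allele columns travel with their locus,
#' preserving within-locus dependence), recomputes the Jaccard matrix and NJ
#' tree for each replicate, and reports for every internal edge of the
#' reference tree the percentage of replicates containing the same
#' bipartition.
#'
#' @param x an [ssr_matrix()]
#' @param n_reps number of bootstrap replicates
#' @param seed optional integer seed for the resampling
#' @param ref_tree optional reference tree; defaults to NJ on the full data
#' @return the reference \code{phylo} tree with support percentages in
#'   \code{node.label} and, as attribute \code{"support"}, the numeric
#'   vector of supports per internal node
#' @export
bootstrap_support <- function(x, n_reps = 1000L, seed = NULL,
                              ref_tree = NULL) {
  stopifnot(inherits(x, "ssr_matrix"), n_reps >= 1)
  if (is.null(ref_tree)) {
    d0 <- jaccard_matrix(x)
    if (anyNA(d0)) d0[is.na(d0)] <- mean(d0[upper.tri(d0)], na.rm = TRUE)
    ref_tree <- nj_tree(d0)
  }
  loci <- locus_names(x)
  run <- function() {
    reps <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      drawn <- sample(loci, length(loci), replace = TRUE)
      reps[[r]] <- nj_tree(resample_distance(x, drawn))
    }
    class(reps) <- "multiPhylo"
    cnt <- ape::prop.clades(ref_tree, reps, rooted = FALSE)
    cnt[is.na(cnt)] <- 0L
    100 * cnt / n_reps
  }
  support <- if (is.null(seed)) run() else with_derived_seed(seed, run())
  ref_tree$node.label <- formatC(support, format = "f", digits = 1)
  attr(ref_tree, "support") <- support
  ref_tree
}

# labels needing Newick quoting
needs_newick_quote <- function(lab) grepl("[][ ,:;()']", lab)

#' Serialise a tree to Newick text
#'
#' Standard Newick with branch lengths and any support values as internal
#' node labels. Labels containing Newick metacharacters (spaces, commas,
#' parentheses, quotes, ...) are single-quoted, with embedded quotes doubled,
#' per the Newick convention. Round-trips through [from_newick()].
#'
#' @param tree a \code{phylo} tree
#' @param path optional file; when given the text is also written there
#' @return the Newick string, invisibly when \code{path} is given
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tr <- tree
  quote_lab <- function(lab) paste0("'", gsub("'", "''", lab), "'")
  tokens <- character(); originals <- character()
  protect <- function(labs, prefix) {
    idx <- which(needs_newick_quote(labs))
    if (length(idx)) {
      tok <- sprintf("@@%s%d@@", prefix, idx)
      tokens <<- c(tokens, tok)
      originals <<- c(originals, quote_lab(labs[idx]))
      labs[idx] <- tok
    }
    labs
  }
  tr$tip.label <- protect(tr$tip.label, "T")
  if (!is.null(tr$node.label)) tr$node.label <- protect(tr$node.label, "N")
  txt <- ape::write.tree(tr)
  for (i in seq_along(tokens))
    txt <- sub(tokens[i], originals[i], txt, fixed = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse Newick text
#'
#' Inverse of [to_newick()]: reads with [ape::read.tree()] and unquotes
#' single-quoted labels.
#'
#' @param text Newick string (ignored when \code{path} is given)
#' @param path optional file to read instead
#' @return a \code{phylo} tree
#' @export
from_newick <- function(text = NULL, path = NULL) {
  if (!is.null(path)) text <- paste(readLines(path), collapse = "")
  tr <- ape::read.tree(text = text)
  unquote <- function(lab) {
    q <- grepl("^'.*'$", lab)
    lab[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab[q]))
    lab
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}
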