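#' Jaccard dissimilarity matrix over binary SSR profiles
#'
#' For each pair of samples, allele columns are restricted to the loci scored
#' in both samples; with a = shared presences and b + c = mismatched
#' presences, the dissimilarity is \eqn{d = 1 - a / (a + b + c)}. Alleles are
#' treated as independent dominant markers. A pair with no co-scored locus
#' has no defined distance; such pairs are set to \code{NA} and listed in the
#' \code{undefined} attribute.
#'
#' @param x an [ssr_matrix()]
#' @return an \code{ssr_dist}: symmetric numeric matrix with zero diagonal,
#'   sample ids as dimnames, attribute \code{undefined} (data.frame of pairs
#'   with no co-scored locus).
#' @export
jaccard_matrix <- function(x) {
  stopifnot(inherits(x, "ssr_matrix"), nrow(x$calls) >= 2)
  a01 <- x$calls
  a01[is.na(a01)] <- 0L
  # scored indicator per allele column (locus-level missingness)
  sc <- 1L - is.na(x$calls)
  shared <- tcrossprod(a01)                 # co-scored shared presences
  pres_vs_scored <- tcrossprod(a01, sc)     # presences of i over loci scored in j
  mism <- pres_vs_scored + t(pres_vs_scored) - 2 * shared
  coscored <- tcrossprod(sc)
  union <- shared + mism
  d <- ifelse(union > 0, mism / union, 0)
  d[coscored == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(x$calls), rownames(x$calls))
  und <- which(upper.tri(d) & is.na(d), arr.ind = TRUE)
  undef <- data.frame(sample1 = rownames(d)[und[, 1]],
                      sample2 = rownames(d)[und[, 2]],
                      stringsAsFactors = FALSE)
  structure(d, undefined = undef, class = c("ssr_dist", "matrix", "array"))
}

#' @export
print.ssr_dist <- function(x, ...) {
  cat(sprintf("ssr_dist: %d samples, mean d = %.3f", nrow(x),
              mean(x[upper.tri(x)], na.rm = TRUE)))
  nu <- nrow(attr(x, "undefined"))
  if (nu) cat(sprintf(" (%d undefined pairs)", nu))
  cat("\n")
  invisible(x)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d distance matrix (an \code{ssr_dist} or plain matrix)
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_phylip <- function(d, path) {
  n <- nrow(d)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i)
               paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.6f", d[i, ])), collapse = " "),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
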