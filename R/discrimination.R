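#' Banding-pattern profile of one locus
#'
#' Tallies the distinct presence/absence vectors ("banding patterns") shown
#' by the scored samples at a locus. Samples with the locus missing are
#' excluded from N.
#'
#' @param x an [ssr_matrix()]
#' @param locus locus name
#' @return a \code{pattern_profile}: list with \code{scope}, \code{N},
#'   \code{counts} (named pattern counts), \code{p} (pattern frequencies)
#'   and \code{I} (number of distinct patterns)
#' @export
banding_patterns <- function(x, locus) {
  stopifnot(inherits(x, "ssr_matrix"))
  sub <- x$calls[, locus_cols(x, locus), drop = FALSE]
  scored <- rowSums(is.na(sub)) == 0
  if (!any(scored)) stop("all samples missing at locus ", locus)
  key <- apply(sub[scored, , drop = FALSE], 1L, paste, collapse = "")
  counts <- table(key)
  new_pattern_profile(locus, counts)
}

new_pattern_profile <- function(scope, counts) {
  counts <- as.vector(counts, mode = "integer") |>
    stats::setNames(names(counts))
  n <- sum(counts)
  structure(list(scope = scope, N = n, counts = counts,
                 p = counts / n, I = length(counts)),
            class = "pattern_profile")
}

#' @export
print.pattern_profile <- function(x, ...) {
  cat(sprintf("pattern_profile [%s]: N = %d, I = %d distinct patterns\n",
              paste(x$scope, collapse = "+"), x$N, x$I))
  if (x$N >= 2)
    cat(sprintf("  C = %.4f, D = %.4f, DL = %.4f\n",
                confusion_probability(x), discriminating_power(x),
                dl_limit(x)))
  invisible(x)
}

#' Confusion probability of a pattern profile
#'
#' Probability that two samples drawn at random without replacement share
#' the same banding pattern:
#' \eqn{C_j = \sum_i p_i (N p_i - 1)/(N - 1)}, identically
#' \eqn{\sum_i c_i (c_i - 1) / (N (N-1))}.
#'
#' @param profile a \code{pattern_profile} with \code{N >= 2}
#' @return the confusion probability in [0, 1]
#' @export
confusion_probability <- function(profile) {
  stopifnot(inherits(profile, "pattern_profile"))
  if (profile$N < 2) stop("confusion probability needs N >= 2")
  c_i <- profile$counts
  n <- profile$N
  sum(c_i * (c_i - 1)) / (n * (n - 1))
}

#' Discriminating power of a pattern profile
#'
#' Complement of the confusion probability: the probability that two random
#' samples are distinguished by the locus (or locus set).
#'
#' @inheritParams confusion_probability
#' @return \eqn{D_j = 1 - C_j}
#' @export
discriminating_power <- function(profile) {
  1 - confusion_probability(profile)
}

#' Asymptotic limit of the discriminating power
#'
#' \eqn{DL = 1 - \sum_i p_i^2}, the with-replacement (large-N) limit; the
#' finite-sample value satisfies \eqn{D_j = N \, DL / (N - 1)} exactly.
#'
#' @inheritParams confusion_probability
#' @return the limit value in [0, 1]
#' @export
dl_limit <- function(profile) {
  stopifnot(inherits(profile, "pattern_profile"))
  1 - sum(profile$p^2)
}

#' Finite-sample discriminating power from its asymptotic limit
#'
#' Inverts the identity \eqn{D = N \, DL / (N - 1)}; useful for checking
#' published D columns against published DL columns.
#'
#' @param dl asymptotic limit value(s)
#' @param n number of samples
#' @return discriminating power value(s)
#' @export
d_from_dl <- function(dl, n) {
  stopifnot(n >= 2)
  n * dl / (n - 1)
}

#' Combined pattern profile over a set of loci
#'
#' The pattern of a sample is the tuple of its per-locus patterns. A missing
#' locus contributes a distinct sentinel symbol rather than excluding the
#' sample, so N stays constant across locus subsets and cumulative
#' discriminating powers are comparable.
#'
#' @param x an [ssr_matrix()]
#' @param loci non-empty character vector of locus names
#' @return a \code{pattern_profile} with \code{scope = loci}
#' @export
combined_profile <- function(x, loci) {
  stopifnot(inherits(x, "ssr_matrix"), length(loci) >= 1)
  keys <- vapply(loci, function(ln) {
    sub <- x$calls[, locus_cols(x, ln), drop = FALSE]
    k <- apply(sub, 1L, paste, collapse = "")
    k[rowSums(is.na(sub)) > 0] <- "?"   # missing-locus sentinel
    k
  }, character(nrow(x$calls)))
  if (is.null(dim(keys))) keys <- matrix(keys, nrow = 1L)  # single sample
  combined <- apply(keys, 1L, paste, collapse = "|")
  new_pattern_profile(loci, table(combined))
}

#' Greedy minimal marker-panel selection
#'
#' Builds the cumulative-discrimination ("maximization") curve: the first
#' locus is the one with the highest single-locus discriminating power; each
#' subsequent step tests every remaining locus and retains the one that
#' maximises the combined discriminating power of the panel so far. Ties are
#' broken by input locus order. The plateau index is the first step at which
#' the panel already separates as many distinct multi-locus patterns as the
#' full curve ever attains.
#'
#' @param x an [ssr_matrix()]
#' @param loci candidate loci (default: all loci of \code{x})
#' @return a \code{panel_curve}: data.frame with columns \code{step},
#'   \code{locus}, \code{D} (cumulative discriminating power) and
#'   \code{n_patterns}; attributes \code{plateau_index} and
#'   \code{plateau_D}
#' @export
greedy_panel <- function(x, loci = locus_names(x)) {
  stopifnot(inherits(x, "ssr_matrix"), length(loci) >= 1)
  chosen <- character()
  remaining <- loci
  rows <- vector("list", length(loci))
  for (step in seq_along(loci)) {
    d_cand <- vapply(remaining, function(ln)
      discriminating_power(combined_profile(x, c(chosen, ln))), numeric(1))
    best <- which.max(d_cand)   # first maximum = input-order tie-break
    chosen <- c(chosen, remaining[best])
    prof <- combined_profile(x, chosen)
    rows[[step]] <- data.frame(step = step, locus = remaining[best],
                               D = discriminating_power(prof),
                               n_patterns = prof$I)
    remaining <- remaining[-best]
  }
  out <- do.call(rbind, rows)
  plateau <- which(out$n_patterns == max(out$n_patterns))[1L]
  attr(out, "plateau_index") <- plateau
  attr(out, "plateau_D") <- out$D[plateau]
  class(out) <- c("panel_curve", "data.frame")
  out
}

#' @export
print.panel_curve <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("\nplateau: %d loci reach all %d patterns (D = %.3f)\n",
              attr(x, "plateau_index"), max(x$n_patterns),
              attr(x, "plateau_D")))
  invisible(x)
}

#' Per-locus discrimination table
#'
#' One row per locus in the published layout: number of polymorphic bands,
#' number of distinct patterns I, confusion probability C, discriminating
#' power D and its asymptotic limit DL.
#'
#' @param x an [ssr_matrix()]
#' @return data.frame with columns \code{locus}, \code{NP}, \code{I},
#'   \code{C}, \code{D}, \code{DL}
#' @export
discrimination_table <- function(x) {
  stopifnot(inherits(x, "ssr_matrix"))
  rows <- lapply(locus_names(x), function(ln) {
    prof <- banding_patterns(x, ln)
    sub <- x$calls[, locus_cols(x, ln), drop = FALSE]
    np <- sum(colSums(sub == 1L, na.rm = TRUE) > 0)
    data.frame(locus = ln, NP = np, I = prof$I,
               C = confusion_probability(prof),
               D = discriminating_power(prof),
               DL = dl_limit(prof))
  })
  do.call(rbind, rows)
}
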