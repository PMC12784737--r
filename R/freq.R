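#' Uniform-split allele-frequency estimates
#'
#' For dosage-ambiguous polyploid genotypes, treats every allele observed in
#' a sample's presence set as equally likely to occupy each of the ploidy
#' copies: a sample showing k distinct alleles credits ploidy / k copies to
#' each. This is fast and unbiased for rare alleles but underestimates common
#' ones (a fully homozygous and a balanced genotype contribute identically).
#'
#' @param x an [ssr_matrix()]
#' @param ploidy copies per genotype (defaults to the matrix ploidy)
#' @return an \code{allele_freq_set}: per-locus list with elements \code{p}
#'   (named frequency vector), \code{n} (allele copies underlying the
#'   estimate), \code{defined} (FALSE when every sample is missing);
#'   \code{method = "simple"}.
#' @export
simple_freq <- function(x, ploidy = x$ploidy) {
  stopifnot(inherits(x, "ssr_matrix"))
  loci <- lapply(locus_names(x), function(ln) {
    cols <- locus_cols(x, ln)
    sub <- x$calls[, cols, drop = FALSE]
    scored <- rowSums(is.na(sub)) == 0
    labels <- as.character(x$allele[cols])
    scored <- scored & rowSums(sub == 1L, na.rm = TRUE) > 0
    if (!any(scored))
      return(list(p = NULL, n = 0L, defined = FALSE))
    sub <- sub[scored, , drop = FALSE]
    k <- rowSums(sub)
    credit <- colSums(sub * (ploidy / k))
    names(credit) <- labels
    list(p = credit / sum(credit), n = ploidy * sum(scored), defined = TRUE)
  })
  names(loci) <- locus_names(x)
  structure(list(loci = loci, method = "simple", ploidy = ploidy),
            class = "allele_freq_set")
}

#' @export
print.allele_freq_set <- function(x, ...) {
  nd <- sum(!vapply(x$loci, `[[`, logical(1), "defined"))
  cat(sprintf("allele_freq_set (%s): %d loci%s\n", x$method, length(x$loci),
              if (nd) sprintf(", %d undefined (all samples missing)", nd) else ""))
  if (x$method == "em") {
    conv <- vapply(x$loci, function(l) isTRUE(l$converged), logical(1))
    cat(sprintf("  converged: %d/%d loci\n", sum(conv), length(x$loci)))
  }
  invisible(x)
}

# all ways to allocate m copies over k observed alleles, each allele >= 1 copy
# (k x n matrix of copy counts); tiny for m = 6, k <= 6
compositions_min1 <- function(m, k) {
  if (k == 1L) return(matrix(m, 1L, 1L))
  out <- list()
  for (first in seq_len(m - (k - 1L))) {
    rest <- compositions_min1(m - first, k - 1L)
    out[[first]] <- rbind(first, rest)
  }
  do.call(cbind, out)
}

#' Probability of a dosage genotype under polysomic inheritance with selfing
#'
#' The genotype prior shared by the simulator and the EM estimator: with
#' probability \code{1 - F} the \code{ploidy} allele copies are independent
#' draws from \code{p} (multinomial), with probability \code{F = s/(2 - s)}
#' all copies are identical by descent (a single draw from \code{p}).
#' Probabilities over all dosage multisets of a given size sum to 1.
#'
#' @param multiset vector of allele labels of length \code{ploidy}
#'   (order irrelevant)
#' @param p named allele-frequency vector
#' @param s selfing rate in [0, 1)
#' @param ploidy number of copies; defaults to \code{length(multiset)}
#' @return the genotype probability
#' @export
genotype_probability <- function(multiset, p, s = 0, ploidy = length(multiset)) {
  stopifnot(length(multiset) == ploidy, s >= 0, s < 1,
            all(p >= 0), abs(sum(p) - 1) < 1e-9)
  multiset <- as.character(multiset)
  if (!all(multiset %in% names(p)))
    stop("allele(s) absent from the frequency vector: ",
         paste(setdiff(multiset, names(p)), collapse = ", "))
  cnt <- table(multiset)
  f <- inbreeding_f(s)
  iid <- exp(lfactorial(ploidy) - sum(lfactorial(cnt)) +
               sum(cnt * log(p[names(cnt)])))
  collapsed <- if (length(cnt) == 1L) p[[names(cnt)]] else 0
  (1 - f) * iid + f * collapsed
}

#' EM allele-frequency estimates under polysomic inheritance with selfing
#'
#' Treats each sample-locus presence set as an incomplete observation of a
#' latent dosage genotype. The E-step enumerates every dosage genotype
#' compatible with the presence set (compositions of \code{ploidy} copies
#' over the observed alleles, each observed allele at least once), weights
#' each by [genotype_probability()] at the current frequencies, and
#' accumulates expected allele-draw counts (a collapsed, identical-by-descent
#' genotype contributes a single draw; an independent-copies genotype
#' contributes its copy counts). The M-step renormalises the counts.
#' Initialisation is the [simple_freq()] estimate; iteration stops when the
#' largest frequency change drops below \code{tol}.
#'
#' @param x an [ssr_matrix()]
#' @param ploidy copies per genotype (defaults to the matrix ploidy)
#' @param selfing_rate selfing rate s in [0, 1); default 0.07
#' @param tol L-infinity convergence tolerance on the frequency vector
#' @param max_iter iteration cap; non-convergence is flagged, with a warning
#' @return an \code{allele_freq_set} with \code{method = "em"}; each locus
#'   additionally carries \code{converged}, \code{iterations} and
#'   \code{loglik} (the observed-data log-likelihood trajectory, one value
#'   per iteration — non-decreasing by construction).
#' @export
em_freq <- function(x, ploidy = x$ploidy, selfing_rate = 0.07,
                    tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(x, "ssr_matrix"), selfing_rate >= 0, selfing_rate < 1,
            tol > 0)
  f <- inbreeding_f(selfing_rate)
  init <- simple_freq(x, ploidy)
  loci <- lapply(locus_names(x), function(ln) {
    cols <- locus_cols(x, ln)
    sub <- x$calls[, cols, drop = FALSE]
    scored <- rowSums(is.na(sub)) == 0 & rowSums(sub == 1L, na.rm = TRUE) > 0
    if (!any(scored))
      return(list(p = NULL, n = 0L, defined = FALSE, converged = NA,
                  iterations = 0L, loglik = numeric()))
    sub <- sub[scored, , drop = FALSE]
    labels <- as.character(x$allele[cols])
    # unique phenotypes with multiplicities
    key <- apply(sub, 1L, paste, collapse = "")
    tab <- table(key)
    phen <- lapply(names(tab), function(k)
      which(strsplit(k, "")[[1]] == "1"))
    wts <- as.numeric(tab)
    comps <- lapply(phen, function(a) compositions_min1(ploidy, length(a)))
    lcoef <- lapply(comps, function(cc)
      lfactorial(ploidy) - colSums(lfactorial(cc)))
    p <- init$loci[[ln]]$p
    ll_trace <- numeric()
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      counts <- numeric(length(labels))
      ll <- 0
      for (u in seq_along(phen)) {
        a <- phen[[u]]; cc <- comps[[u]]
        w_iid <- (1 - f) * exp(lcoef[[u]] + colSums(cc * log(p[a])))
        w_self <- if (length(a) == 1L) f * p[a] else 0
        tot <- sum(w_iid) + w_self
        ll <- ll + wts[u] * log(tot)
        post_iid <- w_iid / tot
        counts[a] <- counts[a] +
          wts[u] * (as.numeric(cc %*% post_iid) +
                      if (length(a) == 1L) w_self / tot else 0)
      }
      ll_trace <- c(ll_trace, ll)
      p_new <- counts / sum(counts)
      names(p_new) <- labels
      delta <- max(abs(p_new - p))
      p <- p_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("em_freq: locus ", ln, " did not converge in ", max_iter,
              " iterations", call. = FALSE)
    list(p = p, n = ploidy * sum(scored), defined = TRUE,
         converged = converged, iterations = it, loglik = ll_trace)
  })
  names(loci) <- locus_names(x)
  structure(list(loci = loci, method = "em", ploidy = ploidy,
                 selfing_rate = selfing_rate),
            class = "allele_freq_set")
}

#' Write a per-allele frequency table
#'
#' CSV with one row per (locus, allele): both estimates side by side, the
#' copy count behind them and the EM convergence flag.
#'
#' @param fs_simple \code{allele_freq_set} from [simple_freq()]
#' @param fs_em \code{allele_freq_set} from [em_freq()]
#' @param path output CSV
#' @return invisibly, \code{path}
#' @export
write_freq_table <- function(fs_simple, fs_em, path) {
  stopifnot(identical(names(fs_simple$loci), names(fs_em$loci)))
  rows <- do.call(rbind, lapply(names(fs_simple$loci), function(ln) {
    ls <- fs_simple$loci[[ln]]; le <- fs_em$loci[[ln]]
    if (!ls$defined)
      return(data.frame(locus = ln, allele = NA, p_simple = NA, p_em = NA,
                        n = 0L, converged = NA))
    data.frame(locus = ln, allele = names(ls$p),
               p_simple = unname(ls$p), p_em = unname(le$p[names(ls$p)]),
               n = ls$n, converged = le$converged)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
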