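#' Nei's gene diversity with finite-sample correction
#'
#' Expected heterozygosity \eqn{H = 1 - \sum_i p_i^2}, and its unbiased
#' finite-sample rescaling \eqn{n/(n-1) \, (1 - \sum_i p_i^2)} where n is the
#' number of allele copies behind the frequency estimate.
#'
#' @param p allele-frequency vector (non-negative, sums to 1)
#' @param n allele-copy count used for the correction; must be at least 2
#' @return named numeric vector \code{c(uncorrected, corrected)}
#' @export
nei_diversity <- function(p, n) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9)
  if (n < 2) stop("sample-size correction needs n >= 2")
  h <- 1 - sum(p^2)
  c(uncorrected = h, corrected = n / (n - 1) * h)
}

#' Polymorphism information content
#'
#' Marker informativeness
#' \eqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}: the probability
#' that a marker distinguishes genotypes in a cross, always bounded above by
#' the gene diversity.
#'
#' @param p allele-frequency vector
#' @return the PIC value in [0, 1)
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9)
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Mean number of present alleles per individual at a locus
#'
#' @param x an [ssr_matrix()]
#' @param locus locus name
#' @param group \code{"all"}, \code{"study"} or \code{"reference"}
#' @return mean present-allele count over the group's non-missing samples;
#'   \code{NA} (with a warning) when the group has no scored sample
#' @export
mean_alleles_per_individual <- function(x, locus,
                                        group = c("all", "study", "reference")) {
  stopifnot(inherits(x, "ssr_matrix"))
  group <- match.arg(group)
  sub <- x$calls[, locus_cols(x, locus), drop = FALSE]
  in_group <- if (group == "all") rep(TRUE, nrow(sub)) else
    x$samples$group == group
  sub <- sub[in_group, , drop = FALSE]
  scored <- rowSums(is.na(sub)) == 0
  if (!any(scored)) {
    warning("no scored sample at locus ", locus, " in group ", group)
    return(NA_real_)
  }
  mean(rowSums(sub[scored, , drop = FALSE]))
}

#' Percentage change between uncorrected and corrected estimates
#'
#' Absolute difference divided by the uncorrected value, as a percentage.
#'
#' @param uncorrected,corrected the two estimates
#' @return percentage; \code{NA} with a warning when the uncorrected value
#'   is zero
#' @export
percent_change <- function(uncorrected, corrected) {
  if (any(uncorrected == 0)) {
    warning("percent change undefined for zero uncorrected value")
    return(ifelse(uncorrected == 0, NA_real_,
                  abs(corrected - uncorrected) / uncorrected * 100))
  }
  abs(corrected - uncorrected) / uncorrected * 100
}

#' Pearson correlation with degeneracy checks
#'
#' Thin wrapper over [stats::cor()] that enforces equal lengths of at least
#' 3 and flags zero-variance inputs as undefined instead of propagating
#' \code{NaN} silently.
#'
#' @param x,y numeric vectors
#' @return the sample correlation coefficient, or \code{NA} with a warning
#'   when either input has zero variance
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors of length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("correlation undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Per-locus diversity summary table
#'
#' One row per locus: allele counts and size range, mean allele number per
#' individual (overall and per sample group), Nei's gene diversity with and
#' without the finite-sample correction, and PIC under both frequency
#' estimates, with the correction-induced percentage changes. The n used in
#' the Nei correction is the total number of observed allele presences at
#' the locus. An aggregate of unweighted column means and ranges is attached
#' as attribute \code{"aggregate"}.
#'
#' @param x an [ssr_matrix()]
#' @param fs_simple \code{allele_freq_set} from [simple_freq()] on \code{x}
#' @param fs_em \code{allele_freq_set} from [em_freq()] on \code{x}
#' @return data.frame of class \code{locus_diversity}
#' @export
diversity_table <- function(x, fs_simple = simple_freq(x),
                            fs_em = em_freq(x)) {
  stopifnot(inherits(x, "ssr_matrix"))
  rows <- lapply(locus_names(x), function(ln) {
    cols <- locus_cols(x, ln)
    ls <- fs_simple$loci[[ln]]; le <- fs_em$loci[[ln]]
    sub <- x$calls[, cols, drop = FALSE]
    scored <- rowSums(is.na(sub)) == 0
    n_pres <- sum(sub[scored, , drop = FALSE])
    if (!ls$defined || n_pres < 2)
      return(data.frame(locus = ln, size_min = min(x$allele[cols]),
                        size_max = max(x$allele[cols]),
                        n_alleles = length(cols),
                        mean_alleles_total = NA_real_,
                        mean_alleles_reference = NA_real_,
                        mean_alleles_study = NA_real_,
                        n = n_pres, H_uncorrected = NA_real_,
                        H_corrected = NA_real_, pct_change_H = NA_real_,
                        PIC_simple = NA_real_, PIC_em = NA_real_,
                        pct_change_PIC = NA_real_))
    h <- nei_diversity(ls$p, n_pres)
    pic_s <- pic(ls$p); pic_e <- pic(le$p)
    grp_mean <- function(g) suppressWarnings(
      mean_alleles_per_individual(x, ln, g))
    data.frame(
      locus = ln,
      size_min = min(x$allele[cols]), size_max = max(x$allele[cols]),
      n_alleles = length(cols),
      mean_alleles_total = grp_mean("all"),
      mean_alleles_reference = grp_mean("reference"),
      mean_alleles_study = grp_mean("study"),
      n = n_pres,
      H_uncorrected = unname(h["uncorrected"]),
      H_corrected = unname(h["corrected"]),
      pct_change_H = percent_change(h[["uncorrected"]], h[["corrected"]]),
      PIC_simple = pic_s, PIC_em = pic_e,
      pct_change_PIC = percent_change(pic_s, pic_e))
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  safe_range <- function(f) function(v)
    if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE)
  attr(out, "aggregate") <- list(
    mean = colMeans(out[num], na.rm = TRUE),
    min = vapply(out[num], safe_range(min), numeric(1)),
    max = vapply(out[num], safe_range(max), numeric(1)),
    total_alleles = sum(out$n_alleles))
  class(out) <- c("locus_diversity", "data.frame")
  out
}

#' @export
print.locus_diversity <- function(x, digits = 3, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE)
  ag <- attr(x, "aggregate")
  cat(sprintf("\nTotal alleles: %d; mean alleles/locus %.2f; mean corrected H %.2f; mean PIC (simple) %.2f; mean PIC (EM) %.2f\n",
              ag$total_alleles, ag$mean[["n_alleles"]],
              ag$mean[["H_corrected"]], ag$mean[["PIC_simple"]],
              ag$mean[["PIC_em"]]))
  invisible(x)
}

#' Write the diversity summary table with its aggregate row
#'
#' @param tab a \code{locus_diversity} table
#' @param path output CSV
#' @return invisibly, \code{path}
#' @export
write_diversity_table <- function(tab, path) {
  ag <- attr(tab, "aggregate")
  out <- as.data.frame(tab)
  mean_row <- out[1, ]
  mean_row[] <- NA
  mean_row$locus <- "Mean"
  for (cn in names(ag$mean)) mean_row[[cn]] <- ag$mean[[cn]]
  utils::write.csv(rbind(out, mean_row), path, row.names = FALSE)
  invisible(path)
}
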