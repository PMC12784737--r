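#' Configuration for the hexaploid SSR simulator
#'
#' Defaults mirror a curated sweetpotato fingerprinting panel: 19 loci with
#' 3-12 alleles each (symmetric Dirichlet frequencies, concentration 1, which
#' gives expected gene diversity near 0.8 at 8 alleles), hexaploid genomes,
#' clonally propagated accessions organised as founder genotypes replicated
#' 2-4 times, partial selfing at rate 0.07, and mild scoring noise (allele
#' dropout 0.01, false allele 0.005, whole-locus failure 0.02).
#'
#' @param n_loci number of SSR loci
#' @param alleles_per_locus integer range \code{c(min, max)} for the number
#'   of alleles per locus
#' @param dirichlet_concentration symmetric Dirichlet concentration for the
#'   per-locus allele-frequency vectors
#' @param ploidy ploidy level
#' @param n_founders number of distinct founder genotypes
#' @param clones_per_founder integer range \code{c(min, max)}; each founder
#'   is replicated a uniform draw from this range
#' @param selfing_rate selfing rate s in [0, 1); at equilibrium this induces
#'   inbreeding coefficient F = s / (2 - s)
#' @param dropout_rate per-allele probability a present band is scored absent
#' @param false_allele_rate per-allele probability an absent band is scored
#'   present
#' @param locus_missing_rate probability a sample-locus fails entirely
#' @param seed integer seed; all stochastic steps derive from it
#' @return a validated list of class \code{sim_config}
#' @export
sim_config <- function(n_loci = 19L, alleles_per_locus = c(3L, 12L),
                       dirichlet_concentration = 1,
                       ploidy = 6L, n_founders = 20L,
                       clones_per_founder = c(2L, 4L),
                       selfing_rate = 0.07,
                       dropout_rate = 0.01, false_allele_rate = 0.005,
                       locus_missing_rate = 0.02, seed = 1L) {
  cfg <- list(n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(rep(alleles_per_locus, length.out = 2L)),
              dirichlet_concentration = dirichlet_concentration,
              ploidy = as.integer(ploidy),
              n_founders = as.integer(n_founders),
              clones_per_founder = as.integer(rep(clones_per_founder, length.out = 2L)),
              selfing_rate = selfing_rate,
              dropout_rate = dropout_rate,
              false_allele_rate = false_allele_rate,
              locus_missing_rate = locus_missing_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_loci >= 1L, cfg$n_founders >= 1L, cfg$ploidy >= 1L,
            cfg$alleles_per_locus[1] >= 1L,
            cfg$alleles_per_locus[1] <= cfg$alleles_per_locus[2],
            cfg$clones_per_founder[1] >= 1L,
            cfg$clones_per_founder[1] <= cfg$clones_per_founder[2],
            cfg$dirichlet_concentration > 0,
            cfg$selfing_rate >= 0, cfg$selfing_rate < 1,
            cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            cfg$false_allele_rate >= 0, cfg$false_allele_rate < 1,
            cfg$locus_missing_rate >= 0, cfg$locus_missing_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# equilibrium inbreeding coefficient under partial selfing
inbreeding_f <- function(s) s / (2 - s)

# uniform draw(s) from an integer range, safe against scalar sample()
sample_range <- function(range, n = 1L) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# run expr with a derived RNG seed, restoring the caller's RNG state
with_derived_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw the allele-frequency vector of one simulated locus
#'
#' Frequencies are a symmetric Dirichlet draw; the number of alleles is drawn
#' uniformly from \code{config$alleles_per_locus}. The draw is keyed on
#' \code{(config$seed, locus_index)}, so each locus is reproducible in
#' isolation and the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()]
#' @param locus_index integer locus index (1-based)
#' @return numeric frequency vector summing to 1
#' @export
draw_locus_frequencies <- function(config, locus_index) {
  stopifnot(inherits(config, "sim_config"), locus_index >= 1L)
  with_derived_seed((config$seed * 1009L + locus_index) %% 2147483647L, {
    k <- sample_range(config$alleles_per_locus)
    g <- stats::rgamma(k, shape = config$dirichlet_concentration)
    g / sum(g)
  })
}

#' Simulate one founder genotype at one locus
#'
#' Draws the \code{ploidy} allele copies of a founder under polysomic
#' inheritance with partial selfing: with probability \code{F = s/(2 - s)}
#' all copies collapse to a single draw from \code{freqs} (the fully inbred,
#' identical-by-descent event), otherwise all copies are independent draws.
#' This exchangeable mixture gives pairwise identity-by-descent exactly F and
#' reaches P(all copies identical) = 1 as s tends to 1. Uses the current RNG
#' stream.
#'
#' @param freqs allele-frequency vector (named or unnamed)
#' @param ploidy number of allele copies
#' @param s selfing rate in [0, 1)
#' @return integer vector of \code{ploidy} allele indices (a dosage multiset)
#' @export
simulate_founder_genotype <- function(freqs, ploidy = 6L, s = 0) {
  stopifnot(all(freqs >= 0), abs(sum(freqs) - 1) < 1e-9, s >= 0, s < 1)
  k <- length(freqs)
  if (stats::runif(1) < inbreeding_f(s))
    rep(sample.int(k, 1L, prob = freqs), ploidy)
  else
    sample.int(k, ploidy, replace = TRUE, prob = freqs)
}

#' Collapse a dosage genotype to its presence set
#'
#' Mimics binary gel scoring: dosage information is lost and only the set of
#' distinct alleles remains.
#'
#' @param multiset integer vector of allele copies (length = ploidy)
#' @return sorted integer vector of distinct alleles
#' @export
phenotype_from_genotype <- function(multiset) {
  sort(unique(as.integer(multiset)))
}

#' Corrupt a genotype matrix with scoring noise
#'
#' Applies, in order: per-allele dropout (present scored absent), per-allele
#' false alleles (absent scored present), and whole sample-locus failures
#' (all cells missing). A scored sample-locus is never left with zero present
#' alleles: if dropout empties it, one of the originally present alleles is
#' re-instated (a lane with no band at all would have been scored as failed).
#'
#' @param x an [ssr_matrix()]
#' @param config a [sim_config()] providing the three rates
#' @param seed optional integer; if given the corruption is keyed on it,
#'   otherwise the current RNG stream is used
#' @return the corrupted \code{ssr_matrix}
#' @export
apply_errors <- function(x, config, seed = NULL) {
  stopifnot(inherits(x, "ssr_matrix"), inherits(config, "sim_config"))
  run <- function() {
    calls <- x$calls
    pres <- which(calls == 1L)
    abse <- which(calls == 0L)
    drop <- pres[stats::runif(length(pres)) < config$dropout_rate]
    gain <- abse[stats::runif(length(abse)) < config$false_allele_rate]
    calls[drop] <- 0L
    calls[gain] <- 1L
    loci <- locus_names(x)
    for (ln in loci) {
      cols <- locus_cols(x, ln)
      fail <- stats::runif(nrow(calls)) < config$locus_missing_rate
      was_scored <- rowSums(is.na(x$calls[, cols, drop = FALSE])) == 0
      # false alleles may not push a genotype past ploidy presences; surplus
      # gained bands are removed at random
      over <- was_scored &
        rowSums(calls[, cols, drop = FALSE] == 1L, na.rm = TRUE) > x$ploidy
      for (i in which(over)) {
        gained_i <- cols[x$calls[i, cols] == 0L & calls[i, cols] == 1L]
        excess <- sum(calls[i, cols] == 1L) - x$ploidy
        take <- sample.int(length(gained_i), min(excess, length(gained_i)))
        calls[i, gained_i[take]] <- 0L
      }
      calls[fail, cols] <- NA_integer_
      # re-instate one original allele where dropout emptied a scored locus
      empty <- was_scored & !fail &
        rowSums(calls[, cols, drop = FALSE] == 1L, na.rm = TRUE) == 0
      for (i in which(empty)) {
        orig <- cols[x$calls[i, cols] == 1L]
        if (length(orig))
          calls[i, orig[sample.int(length(orig), 1L)]] <- 1L
      }
    }
    ssr_matrix(calls, locus = x$locus, allele = x$allele,
               samples = x$samples, ploidy = x$ploidy)
  }
  if (is.null(seed)) run() else with_derived_seed(seed, run())
}

#' Simulate a clonally structured hexaploid SSR dataset
#'
#' Generates per-locus allele frequencies, draws founder genotypes under the
#' partial-selfing model, collapses them to binary presence/absence
#' phenotypes, replicates each founder into a clone group (clones share the
#' identical pre-error phenotype, as vegetatively propagated accessions do),
#' and finally applies scoring noise.
#'
#' @param config a [sim_config()]
#' @return list of class \code{ssr_simulation} with elements
#'   \describe{
#'     \item{matrix}{the corrupted [ssr_matrix()]}
#'     \item{clean}{the pre-error matrix}
#'     \item{truth}{list: \code{true_frequencies} (per-locus named vectors),
#'       \code{founder_genotypes} (per founder, per locus, dosage multisets of
#'       allele labels), \code{clone_group} (named vector sample -> founder)}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  freqs <- lapply(seq_len(config$n_loci), function(j) {
    p <- draw_locus_frequencies(config, j)
    names(p) <- as.character(100L + 2L * seq_along(p))  # size labels in bp
    p
  })
  names(freqs) <- loci

  set.seed(config$seed)
  clones <- sample_range(config$clones_per_founder, config$n_founders)
  founders <- sprintf("F%02d", seq_len(config$n_founders))
  geno <- lapply(freqs, function(p) {
    lapply(seq_len(config$n_founders), function(f)
      as.integer(names(p))[simulate_founder_genotype(p, config$ploidy,
                                                     config$selfing_rate)])
  })
  # binary founder phenotypes
  locus_vec <- rep(loci, times = lengths(freqs))
  allele_vec <- unlist(lapply(freqs, function(p) as.integer(names(p))),
                       use.names = FALSE)
  fcalls <- matrix(0L, config$n_founders, length(allele_vec))
  col0 <- c(0L, cumsum(lengths(freqs)))
  for (j in seq_along(loci)) {
    labels <- as.integer(names(freqs[[j]]))
    for (f in seq_len(config$n_founders)) {
      present <- phenotype_from_genotype(geno[[j]][[f]])
      fcalls[f, col0[j] + match(present, labels)] <- 1L
    }
  }
  calls <- fcalls[rep(seq_len(config$n_founders), times = clones), , drop = FALSE]
  sample_ids <- unlist(lapply(seq_len(config$n_founders), function(f)
    sprintf("%s_c%d", founders[f], seq_len(clones[f]))), use.names = FALSE)
  rownames(calls) <- sample_ids
  clone_group <- rep(founders, times = clones)
  names(clone_group) <- sample_ids
  clean <- ssr_matrix(calls, locus = locus_vec, allele = allele_vec,
                      ploidy = config$ploidy)
  corrupted <- apply_errors(clean, config)  # continues the global stream
  founder_geno <- lapply(seq_len(config$n_founders), function(f)
    lapply(stats::setNames(seq_along(loci), loci), function(j) geno[[j]][[f]]))
  names(founder_geno) <- founders
  structure(list(matrix = corrupted, clean = clean,
                 truth = list(true_frequencies = freqs,
                              founder_genotypes = founder_geno,
                              clone_group = clone_group),
                 config = config),
            class = "ssr_simulation")
}

#' @export
print.ssr_simulation <- function(x, ...) {
  cat(sprintf("ssr_simulation: %d founders, %d samples, %d loci (seed %d)\n",
              x$config$n_founders, nrow(x$matrix$calls), x$config$n_loci,
              x$config$seed))
  invisible(x)
}

#' Write the simulation truth sidecar
#'
#' JSON companion to the genotype CSV: true allele frequencies, clone-group
#' labels and the generating configuration.
#'
#' @param sim an \code{ssr_simulation}
#' @param path output JSON file
#' @return invisibly, \code{path}
#' @export
write_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "ssr_simulation"))
  jsonlite::write_json(
    list(true_frequencies = lapply(sim$truth$true_frequencies, as.list),
         clone_group = as.list(sim$truth$clone_group),
         config = unclass(sim$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
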