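#' Published per-locus diversity statistics for the sweetpotato SSR panel
#'
#' Transcription of the published per-locus marker statistics of a 19-locus
#' SSR fingerprinting panel genotyped on 65 hexaploid sweetpotato accessions
#' (37 newly collected samples plus 28 matching genebank accessions): allele
#' counts and size ranges, mean allele number per individual (overall and
#' per sample group), Nei's gene diversity without and with the
#' finite-sample correction, and PIC under uniform-split and EM-corrected
#' allele frequencies. The underlying 65 x 156 genotype matrix is not
#' publicly deposited, so these printed summaries are the reference values
#' against which the package's aggregation and correlation code is checked.
#'
#' @return data.frame, one row per locus
#' @export
published_marker_diversity <- function() {
  utils::read.csv(system.file("extdata", "published_marker_diversity.csv",
                              package = "ssrclone"),
                  stringsAsFactors = FALSE)
}

#' Published per-locus discrimination statistics for the sweetpotato SSR panel
#'
#' Companion table to [published_marker_diversity()]: number of polymorphic
#' bands (NP), number of distinct banding patterns (I), confusion
#' probability (C), discriminating power (D) and its asymptotic limit (DL)
#' for each of the 19 loci over the same 65 accessions.
#'
#' @return data.frame, one row per locus
#' @export
published_marker_discrimination <- function() {
  utils::read.csv(system.file("extdata", "published_marker_discrimination.csv",
                              package = "ssrclone"),
                  stringsAsFactors = FALSE)
}
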