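#' Run the full fingerprinting pipeline
#'
#' Orchestrates the analysis end to end: optional panel merge, allele
#' frequencies by both estimators, the diversity summary table, the
#' discrimination table and greedy panel curve, the Jaccard dissimilarity
#' matrix, the NJ tree with locus-level bootstrap, and threshold duplicate
#' flagging. All artifacts are written under \code{out_dir}:
#' \code{table2.csv} (diversity), \code{table3.csv} (discrimination),
#' \code{frequencies.csv}, \code{panel_curve.csv}, \code{tree.nwk},
#' \code{distances.phy}, \code{distances.csv}, \code{duplicates.csv},
#' \code{duplicates.json} and \code{run_log.json}. Any stage failure aborts
#' with the stage name and cause, and no partial artifact set is left behind
#' (outputs are staged in a temporary directory and moved on success).
#'
#' @param reference an [ssr_matrix()] or path to a genotype CSV
#' @param query optional second panel to merge into the reference
#' @param ploidy ploidy used when reading from file
#' @param selfing_rate selfing rate for the EM estimator (default 0.07)
#' @param threshold strict duplicate-flagging threshold (default 0.05)
#' @param bootstrap bootstrap replicate count (default 1000; 0 skips
#'   bootstrap and reports the plain NJ tree)
#' @param seed integer seed for the bootstrap resampling
#' @param out_dir output directory (created if absent)
#' @param unshared_loci merge policy passed to [merge_panels()]
#' @return invisibly, a list with the in-memory results (\code{matrix},
#'   \code{diversity}, \code{discrimination}, \code{panel}, \code{distances},
#'   \code{tree}, \code{duplicates})
#' @export
run_pipeline <- function(reference, query = NULL, ploidy = 6L,
                         selfing_rate = 0.07, threshold = 0.05,
                         bootstrap = 1000L, seed = 1L, out_dir = ".",
                         unshared_loci = "drop") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tmp <- tempfile("ssrclone_run_")
  dir.create(tmp)
  x <- stage("input", {
    m <- if (inherits(reference, "ssr_matrix")) reference else
      read_genotype_table(reference, ploidy = ploidy)
    if (!is.null(query)) {
      q <- if (inherits(query, "ssr_matrix")) query else
        read_genotype_table(query, ploidy = ploidy)
      m <- merge_panels(m, q, unshared_loci = unshared_loci)
    }
    viol <- validate_ssr_matrix(m)
    if (nrow(viol)) stop("input matrix fails validation (",
                         nrow(viol), " violations)")
    m
  })
  fs <- stage("frequencies", simple_freq(x))
  fe <- stage("frequencies", em_freq(x, selfing_rate = selfing_rate))
  stage("frequencies", write_freq_table(fs, fe, file.path(tmp, "frequencies.csv")))
  div <- stage("diversity", {
    tab <- diversity_table(x, fs, fe)
    write_diversity_table(tab, file.path(tmp, "table2.csv"))
    tab
  })
  disc <- stage("discrimination", {
    tab <- discrimination_table(x)
    utils::write.csv(tab, file.path(tmp, "table3.csv"), row.names = FALSE)
    tab
  })
  panel <- stage("panel", {
    pc <- greedy_panel(x)
    utils::write.csv(as.data.frame(pc), file.path(tmp, "panel_curve.csv"),
                     row.names = FALSE)
    pc
  })
  d <- stage("distances", {
    dm <- jaccard_matrix(x)
    write_phylip(dm, file.path(tmp, "distances.phy"))
    utils::write.csv(as.data.frame(as.matrix(dm)),
                     file.path(tmp, "distances.csv"))
    dm
  })
  tree <- stage("tree", {
    tr <- if (bootstrap > 0)
      bootstrap_support(x, n_reps = bootstrap, seed = seed)
    else {
      d0 <- d
      if (anyNA(d0)) d0[is.na(d0)] <- mean(d0[upper.tri(d0)], na.rm = TRUE)
      nj_tree(d0)
    }
    to_newick(tr, file.path(tmp, "tree.nwk"))
    tr
  })
  dup <- stage("duplicates", {
    rep <- find_duplicates(d, threshold = threshold)
    write_duplicate_report(rep, csv_path = file.path(tmp, "duplicates.csv"),
                           json_path = file.path(tmp, "duplicates.json"),
                           x = x)
    rep
  })
  stage("log", jsonlite::write_json(
    list(package = "ssrclone",
         version = as.character(utils::packageVersion("ssrclone")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = list(ploidy = x$ploidy, selfing_rate = selfing_rate,
                       threshold = threshold, bootstrap = bootstrap,
                       seed = seed),
         n_samples = nrow(x$calls), n_loci = length(locus_names(x))),
    file.path(tmp, "run_log.json"), auto_unbox = TRUE))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(tmp, full.names = TRUE))
    file.copy(f, file.path(out_dir, basename(f)), overwrite = TRUE)
  unlink(tmp, recursive = TRUE)
  invisible(list(matrix = x, diversity = div, discrimination = disc,
                 panel = panel, distances = d, tree = tree,
                 duplicates = dup))
}
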