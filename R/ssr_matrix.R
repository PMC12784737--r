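#' Binary SSR genotype matrix for polyploid samples
#'
#' Container for presence/absence-scored SSR (microsatellite) genotypes.
#' Because allele dosage cannot be read from band intensity in polyploids,
#' each allele is scored 1 (band present), 0 (band absent) or missing; a
#' failed amplification affects a whole locus, so missingness is locus-level:
#' for a given sample, either every allele column of a locus is \code{NA} or
#' none is.
#'
#' @param calls integer matrix, samples x allele columns, values 0/1/\code{NA}.
#'   Row names are sample ids.
#' @param locus character vector, one locus name per allele column.
#' @param allele integer vector of allele size labels (bp), one per column,
#'   sorted ascending within each locus.
#' @param samples optional data.frame with columns \code{sample_id},
#'   \code{group} (\code{"study"} or \code{"reference"}), \code{display_name},
#'   \code{biological_status}. Defaults to all-\code{"study"} records built
#'   from the row names of \code{calls}.
#' @param ploidy integer ploidy level (default 6, hexaploid).
#'
#' @return An object of class \code{ssr_matrix}.
#'
#' @details The constructor enforces structural well-formedness (dimensions,
#' unique ids, value domain, sorted allele labels). Biological invariants
#' (at most \code{ploidy} present alleles per sample-locus, locus-level
#' missingness) are checked by [validate_ssr_matrix()], which reports rather
#' than raises, so that partially invalid matrices can be inspected.
#'
#' @seealso [read_genotype_table()], [validate_ssr_matrix()], [merge_panels()],
#'   [subset_ssr()]
#' @export
ssr_matrix <- function(calls, locus, allele, samples = NULL, ploidy = 6L) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (length(locus) != ncol(calls))
    stop("'locus' must have one entry per allele column")
  if (length(allele) != ncol(calls))
    stop("'allele' must have one entry per allele column")
  locus <- as.character(locus)
  allele <- as.integer(allele)
  bad <- !(calls %in% c(0L, 1L) | is.na(calls))
  if (any(bad)) stop("calls must be 0, 1 or NA")
  # locus blocks must be contiguous and allele labels sorted ascending
  rl <- rle(locus)
  if (anyDuplicated(rl$values))
    stop("allele columns of one locus must be contiguous")
  for (ln in rl$values) {
    a <- allele[locus == ln]
    if (anyDuplicated(a))
      stop("duplicate allele label at locus ", ln)
    if (is.unsorted(a))
      stop("allele labels must be sorted ascending at locus ", ln)
  }
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (anyDuplicated(rownames(calls)))
    stop("sample ids must be unique")
  rid <- rownames(calls)
  if (is.null(rid)) rid <- character(0)
  if (is.null(samples)) {
    samples <- data.frame(
      sample_id = rid,
      group = rep("study", length(rid)),
      display_name = rid,
      biological_status = rep(NA_character_, length(rid)),
      stringsAsFactors = FALSE
    )
  } else {
    samples <- as.data.frame(samples, stringsAsFactors = FALSE)
    ns <- nrow(samples)
    if (is.null(samples$group)) samples$group <- rep("study", ns)
    if (is.null(samples$display_name)) samples$display_name <- samples$sample_id
    if (is.null(samples$biological_status))
      samples$biological_status <- rep(NA_character_, ns)
    if (!setequal(samples$sample_id, rid) ||
        anyDuplicated(samples$sample_id))
      stop("'samples$sample_id' must match the row names of 'calls'")
    samples <- samples[match(rid, samples$sample_id),
                       c("sample_id", "group", "display_name",
                         "biological_status")]
    rownames(samples) <- NULL
  }
  if (!all(samples$group %in% c("study", "reference")))
    stop("sample group must be 'study' or 'reference'")
  colnames(calls) <- paste(locus, allele, sep = ".")
  structure(
    list(calls = calls, locus = locus, allele = allele,
         samples = samples, ploidy = as.integer(ploidy)),
    class = "ssr_matrix"
  )
}

#' @export
print.ssr_matrix <- function(x, ...) {
  cat(sprintf("ssr_matrix: %d samples x %d allele columns in %d loci (ploidy %d)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$locus)), x$ploidy))
  tab <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.ssr_matrix <- function(object, ...) {
  ln <- locus_names(object)
  per <- t(vapply(ln, function(l) {
    cols <- which(object$locus == l)
    sub <- object$calls[, cols, drop = FALSE]
    scored <- rowSums(is.na(sub)) == 0
    c(n_alleles = length(cols),
      n_scored = sum(scored),
      mean_present = if (any(scored))
        mean(rowSums(sub[scored, , drop = FALSE])) else NA_real_)
  }, numeric(3)))
  out <- data.frame(locus = ln, per, row.names = NULL)
  class(out) <- c("summary.ssr_matrix", "data.frame")
  out
}

#' Locus names of an SSR matrix
#' @param x an \code{ssr_matrix}
#' @return character vector of locus names in column order
#' @export
locus_names <- function(x) {
  stopifnot(inherits(x, "ssr_matrix"))
  unique(x$locus)
}

# column indices of one locus
locus_cols <- function(x, locus) {
  idx <- which(x$locus == locus)
  if (!length(idx)) stop("unknown locus: ", locus)
  idx
}

#' Check the biological invariants of an SSR matrix
#'
#' Reports, without raising, every violation of the two data-model rules:
#' at most \code{ploidy} present alleles per sample per locus, and locus-level
#' missingness (a sample may not mix missing and scored cells within one
#' locus).
#'
#' @param x an \code{ssr_matrix}
#' @return data.frame with columns \code{sample_id}, \code{locus},
#'   \code{rule}, \code{detail}; zero rows iff the matrix is valid.
#' @export
validate_ssr_matrix <- function(x) {
  stopifnot(inherits(x, "ssr_matrix"))
  out <- list()
  for (ln in locus_names(x)) {
    sub <- x$calls[, locus_cols(x, ln), drop = FALSE]
    na_n <- rowSums(is.na(sub))
    mixed <- na_n > 0 & na_n < ncol(sub)
    for (i in which(mixed)) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = rownames(x$calls)[i], locus = ln,
        rule = "locus_level_missing",
        detail = sprintf("%d of %d allele cells missing", na_n[i], ncol(sub)),
        stringsAsFactors = FALSE)
    }
    pres <- rowSums(sub == 1L, na.rm = TRUE)
    over <- !mixed & na_n == 0 & pres > x$ploidy
    for (i in which(over)) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = rownames(x$calls)[i], locus = ln,
        rule = "ploidy_exceeded",
        detail = sprintf("%d present alleles > ploidy %d", pres[i], x$ploidy),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), locus = character(),
                      rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Subset an SSR matrix by samples and/or loci
#'
#' Retained samples and loci keep their original matrix order; calls are
#' unchanged.
#'
#' @param x an \code{ssr_matrix}
#' @param sample_ids character vector of sample ids to keep (default all)
#' @param loci character vector of locus names to keep (default all)
#' @return the subsetted \code{ssr_matrix}
#' @export
subset_ssr <- function(x, sample_ids = NULL, loci = NULL) {
  stopifnot(inherits(x, "ssr_matrix"))
  if (is.null(sample_ids)) sample_ids <- rownames(x$calls)
  if (is.null(loci)) loci <- locus_names(x)
  unknown <- setdiff(sample_ids, rownames(x$calls))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(loci, locus_names(x))
  if (length(unknown))
    stop("unknown locus name(s): ", paste(unknown, collapse = ", "))
  keep_r <- rownames(x$calls) %in% sample_ids
  keep_c <- x$locus %in% loci
  ssr_matrix(x$calls[keep_r, keep_c, drop = FALSE],
             locus = x$locus[keep_c], allele = x$allele[keep_c],
             samples = x$samples[keep_r, , drop = FALSE],
             ploidy = x$ploidy)
}

#' Merge a query genotype panel into a reference panel
#'
#' Allele columns are matched within a locus by exact size label and the
#' merged locus carries the union of the two panels' labels. A sample whose
#' source panel never scored an allele column receives 0 (absent) at that
#' column when its locus was scored — presence/absence scoring registers all
#' detected bands, so a size unreported in one panel is an absence — and
#' \code{NA} when the locus is missing for that sample.
#'
#' @param reference,query \code{ssr_matrix} objects of the same ploidy
#' @param unshared_loci policy for loci present in only one panel:
#'   \code{"drop"} removes them, \code{"keep"} retains them with all-missing
#'   calls for the other panel's samples.
#' @return merged \code{ssr_matrix}
#' @export
merge_panels <- function(reference, query,
                         unshared_loci = c("drop", "keep")) {
  stopifnot(inherits(reference, "ssr_matrix"), inherits(query, "ssr_matrix"))
  unshared_loci <- match.arg(unshared_loci)
  if (reference$ploidy != query$ploidy)
    stop("panels have different ploidy")
  dup <- intersect(rownames(reference$calls), rownames(query$calls))
  if (length(dup))
    stop("duplicate sample id(s) across panels: ", paste(dup, collapse = ", "))
  ln_r <- locus_names(reference); ln_q <- locus_names(query)
  loci <- if (unshared_loci == "drop") intersect(ln_r, ln_q) else
    union(ln_r, ln_q)
  if (!length(loci)) stop("no loci in common between panels")
  n_r <- nrow(reference$calls); n_q <- nrow(query$calls)
  blocks <- list(); locus_out <- character(); allele_out <- integer()
  for (ln in loci) {
    a_r <- if (ln %in% ln_r) reference$allele[reference$locus == ln] else integer()
    a_q <- if (ln %in% ln_q) query$allele[query$locus == ln] else integer()
    alle <- sort(union(a_r, a_q))
    block <- matrix(NA_integer_, n_r + n_q, length(alle))
    fill <- function(panel, rows, a_have) {
      if (!length(a_have)) return()  # locus absent from panel: stays NA
      sub <- panel$calls[, locus_cols(panel, ln), drop = FALSE]
      scored <- rowSums(is.na(sub)) == 0
      block[rows[scored], ] <<- 0L
      block[rows, match(a_have, alle)] <<- sub
    }
    fill(reference, seq_len(n_r), a_r)
    fill(query, n_r + seq_len(n_q), a_q)
    blocks[[ln]] <- block
    locus_out <- c(locus_out, rep(ln, length(alle)))
    allele_out <- c(allele_out, alle)
  }
  calls <- do.call(cbind, blocks)
  rownames(calls) <- c(rownames(reference$calls), rownames(query$calls))
  ssr_matrix(calls, locus = locus_out, allele = allele_out,
             samples = rbind(reference$samples, query$samples),
             ploidy = reference$ploidy)
}
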