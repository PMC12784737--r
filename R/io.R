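#' Read a binary SSR genotype table
#'
#' Parses the canonical genotype CSV dialect: row 1 gives the locus name of
#' every allele column (repeated across a locus's alleles), row 2 the allele
#' size label in bp, and each following row one sample —
#' \code{sample_id, group, cell, cell, ...} with cells in \{0, 1, 9\} where 9
#' codes missing data. A 9 must cover every allele cell of the locus for that
#' sample (gel lanes fail per locus, not per band).
#'
#' @param path file to read
#' @param ploidy integer ploidy; samples showing more than \code{ploidy}
#'   present alleles at one locus are rejected.
#' @param missing_code integer code for missing cells (default 9)
#' @return an [ssr_matrix()]
#' @export
read_genotype_table <- function(path, ploidy = 6L, missing_code = 9L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("malformed header: need locus and allele rows (line 1-2)")
  split1 <- strsplit(lines, ",", fixed = TRUE)
  hdr_loc <- split1[[1L]]
  hdr_all <- split1[[2L]]
  if (length(hdr_loc) < 3L || length(hdr_all) != length(hdr_loc))
    stop("malformed header: locus row (line 1) and allele row (line 2) ",
         "must align and carry at least one allele column")
  locus <- trimws(hdr_loc[-(1:2)])
  allele_chr <- trimws(hdr_all[-(1:2)])
  allele <- suppressWarnings(as.integer(allele_chr))
  if (anyNA(allele))
    stop("malformed header: non-integer allele size label on line 2 (",
         paste(allele_chr[is.na(allele)], collapse = ", "), ")")
  body <- split1[-(1:2)]
  body <- body[lengths(body) > 0L & vapply(body, function(f) any(nzchar(f)), logical(1))]
  n <- length(body)
  calls <- matrix(NA_integer_, n, length(locus))
  ids <- character(n); grp <- character(n)
  for (i in seq_len(n)) {
    f <- trimws(body[[i]])
    if (length(f) != length(hdr_loc))
      stop("parse error on line ", i + 2L, ": expected ",
           length(hdr_loc), " fields, found ", length(f))
    ids[i] <- f[1L]; grp[i] <- f[2L]
    v <- suppressWarnings(as.integer(f[-(1:2)]))
    ok <- v %in% c(0L, 1L, missing_code)
    if (anyNA(v) || !all(ok))
      stop("parse error on line ", i + 2L, ": cells must be 0, 1 or ",
           missing_code)
    v[v == missing_code] <- NA_integer_
    calls[i, ] <- v
  }
  if (n > 0) rownames(calls) <- ids
  m <- ssr_matrix(calls, locus = locus, allele = allele,
                  samples = data.frame(sample_id = ids, group = grp,
                                       stringsAsFactors = FALSE),
                  ploidy = ploidy)
  viol <- validate_ssr_matrix(m)
  if (nrow(viol))
    stop("validation error: ",
         paste(sprintf("sample %s, locus %s: %s (%s)", viol$sample_id,
                       viol$locus, viol$rule, viol$detail), collapse = "; "))
  m
}

#' Write a binary SSR genotype table
#'
#' Inverse of [read_genotype_table()]; missing (locus-level \code{NA}) cells
#' are written as the missing code. Round-trips to an identical matrix.
#'
#' @param x an [ssr_matrix()]
#' @param path output file
#' @param missing_code integer code for missing cells (default 9)
#' @return invisibly, \code{path}
#' @export
write_genotype_table <- function(x, path, missing_code = 9L) {
  stopifnot(inherits(x, "ssr_matrix"))
  hdr1 <- paste(c("sample_id", "group", x$locus), collapse = ",")
  hdr2 <- paste(c("", "", x$allele), collapse = ",")
  cells <- x$calls
  cells[is.na(cells)] <- missing_code
  rows <- vapply(seq_len(nrow(cells)), function(i) {
    paste(c(x$samples$sample_id[i], x$samples$group[i], cells[i, ]),
          collapse = ",")
  }, character(1))
  writeLines(c(hdr1, hdr2, rows), path)
  invisible(path)
}
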