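#' Concatenate locus alignments into a partitioned supermatrix
#'
#' The taxon universe is the union over all loci; a taxon absent from a
#' locus receives a gap-only block there. Partition coordinates are
#' 1-based inclusive, in input locus order.
#'
#' @param loci List of [locus_alignment()] objects with unique ids.
#' @return Object of class `supermatrix`: `taxa`, `matrix` (named
#'   character vector of concatenated rows) and `partitions`
#'   (data.frame locus_id, start, end).
#' @export
concatenate <- function(loci) {
  stopifnot(length(loci) >= 1L)
  ids <- vapply(loci, function(a) a$locus_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate locus id ", ids[duplicated(ids)][1L])
  taxa <- sort(unique(unlist(lapply(loci, function(a) names(a$rows)))))
  lens <- vapply(loci, function(a) nchar(a$rows[[1L]]), integer(1L))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rows <- vapply(taxa, function(t) {
    paste(vapply(loci, function(a) {
      if (t %in% names(a$rows)) a$rows[[t]]
      else strrep("-", nchar(a$rows[[1L]]))
    }, character(1L)), collapse = "")
  }, character(1L))
  structure(list(taxa = taxa, matrix = rows,
                 partitions = data.frame(locus_id = ids, start = starts,
                                         end = ends,
                                         stringsAsFactors = FALSE)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$taxa), " taxa x ",
      nchar(x$matrix[[1L]]), " sites in ", nrow(x$partitions),
      " partitions\n", sep = "")
  invisible(x)
}

#' Alignment statistics of a supermatrix
#'
#' Characters are uppercased and `?`, `.` and every ambiguity code are
#' unified with `N` before counting; a site pattern is the full column
#' string over the fixed taxon order, and the gap/undetermined
#' proportion counts cells that are `-` or `N`.
#'
#' @param sm A [concatenate()] result (or a `locus_aln`).
#' @return list with `n_taxa`, `n_sites`, `n_distinct_patterns`,
#'   `prop_gap_undetermined`.
#' @export
matrix_stats <- function(sm) {
  rows <- aln_rows(sm)
  m <- aln_char_matrix(rows)
  n_taxa <- nrow(m); n_sites <- ncol(m)
  patterns <- apply(m, 2L, paste, collapse = "")
  miss <- m == "-" | m == "N"
  list(n_taxa = n_taxa, n_sites = n_sites,
       n_distinct_patterns = length(unique(patterns)),
       prop_gap_undetermined = sum(miss) / (n_taxa * n_sites))
}

#' Slice one partition back out of a supermatrix
#' @param sm A `supermatrix`.
#' @param locus_id Partition to extract.
#' @param drop_absent Drop taxa that are all-gap in the block.
#' @return A [locus_alignment()].
#' @export
extract_partition <- function(sm, locus_id, drop_absent = TRUE) {
  p <- sm$partitions[sm$partitions$locus_id == locus_id, ]
  if (nrow(p) != 1L) stop("unknown locus ", locus_id)
  rows <- substr(sm$matrix, p$start, p$end)
  if (drop_absent)
    rows <- rows[rows != strrep("-", p$end - p$start + 1L)]
  locus_alignment(locus_id, rows)
}

#' Write a RAxML-style partition file
#'
#' One line per partition, `"DNA, locus = start-end"` with 1-based
#' inclusive coordinates.
#'
#' @param sm A `supermatrix`.
#' @param datatype `"DNA"` or `"AA"`.
#' @param path Output path.
#' @export
write_partition_file <- function(sm, datatype = c("DNA", "AA"), path) {
  datatype <- match.arg(datatype)
  p <- sm$partitions
  writeLines(sprintf("%s, %s = %d-%d", datatype, p$locus_id, p$start, p$end),
             path)
  invisible(path)
}
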