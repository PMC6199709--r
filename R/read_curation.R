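#' Deduplication parameters
#'
#' Replicate read pairs (typically PCR duplicates) are recognized by
#' comparing the first `prefix_len` bases of both mates.
#'
#' @param prefix_len Prefix length compared between pairs.
#' @export
dedup_params <- function(prefix_len = 20L) {
  prefix_len <- as.integer(prefix_len)
  if (prefix_len < 1L) stop("prefix_len must be >= 1")
  structure(list(prefix_len = prefix_len), class = "dedup_params")
}

#' Remove replicate read pairs
#'
#' Scanning pairs in input order, a pair is removed iff some earlier
#' *kept* pair has an identical mate-1 prefix AND an identical mate-2
#' prefix of length `prefix_len`. The first occurrence of a prefix class
#' is always kept; pairs with either mate shorter than `prefix_len` are
#' never removed. Comparison is case-insensitive on the raw read text.
#'
#' @param pairs data.frame from [read_pairs()] / [read_fastq_pairs()].
#' @param params A [dedup_params()] object.
#' @return list with data.frames `kept` and `removed`, input order
#'   preserved in both.
#' @export
deduplicate_pairs <- function(pairs, params = dedup_params()) {
  pl <- params$prefix_len
  long_enough <- nchar(pairs$mate1) >= pl & nchar(pairs$mate2) >= pl
  key <- paste(toupper(substr(pairs$mate1, 1L, pl)),
               toupper(substr(pairs$mate2, 1L, pl)), sep = "\r")
  dup <- duplicated(key) & long_enough
  # a short pair must not shadow or be shadowed: drop only pairs whose
  # key repeats among long-enough pairs seen earlier
  if (any(!long_enough)) {
    dup <- rep(FALSE, nrow(pairs))
    seen <- character(0L)
    for (i in seq_len(nrow(pairs))) {
      if (!long_enough[i]) next
      if (key[i] %in% seen) dup[i] <- TRUE else seen <- c(seen, key[i])
    }
  }
  list(kept = pairs[!dup, , drop = FALSE],
       removed = pairs[dup, , drop = FALSE])
}

#' Sort sequences into per-locus gene bins
#'
#' Each read or contig is matched against every bait on both strands by
#' exact k-mer seeding plus ungapped extension; it joins the bin of the
#' locus holding the single highest score at or above `min_score`.
#' Score ties across loci resolve to the lexicographically smallest
#' locus id with a warning; sequences below `min_score` stay unassigned.
#'
#' @param seqs Named character vector of reads or contigs.
#' @param baits Named character vector of bait sequences (names
#'   `locus|start` or plain locus ids), or a prebuilt
#'   [build_bait_index()] object.
#' @param params A [match_params()] object (ignored when a prebuilt
#'   index is given).
#' @return list with `bins` (named list locus -> named character vector
#'   of members), `scores` (data.frame seq_id, locus, score, strand) and
#'   `unassigned` (named character vector).
#' @export
assign_to_bins <- function(seqs, baits, params = match_params()) {
  idx <- if (is.list(baits) && !is.null(baits$index)) baits
         else build_bait_index(baits, params)
  hits <- lapply(names(seqs), function(id)
    best_locus_match(seqs[[id]], idx, query_id = id))
  names(hits) <- names(seqs)
  assigned <- !vapply(hits, is.null, logical(1L))
  scores <- if (any(assigned)) {
    data.frame(seq_id = names(seqs)[assigned],
               locus = vapply(hits[assigned], `[[`, character(1L), "locus"),
               score = vapply(hits[assigned], `[[`, numeric(1L), "score"),
               strand = vapply(hits[assigned], `[[`, character(1L), "strand"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(seq_id = character(0L), locus = character(0L),
               score = numeric(0L), strand = character(0L))
  }
  bins <- lapply(split(scores$seq_id, scores$locus), function(ids) seqs[ids])
  list(bins = bins, scores = scores, unassigned = seqs[!assigned])
}
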