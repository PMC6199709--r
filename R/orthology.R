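translate_frame <- function(chars, offset) {
  n <- length(chars)
  if (offset + 3L > n) return(character(0L))
  starts <- seq(offset + 1L, n - 2L, by = 3L)
  codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Predict the reading frame of a nucleotide sequence
#'
#' All six strand/offset translations under the standard genetic code
#' are compared; the call minimizes the internal stop-codon count, with
#' ties broken by the longest stop-free stretch and then by the fixed
#' order `+0, +1, +2, -0, -1, -2`. The trailing partial codon is
#' dropped, a terminal stop is trimmed, and if internal stops remain the
#' amino-acid sequence is truncated at the first one with a warning.
#'
#' @param nt A nucleotide string (or length-1 named character vector).
#' @return list with `strand` (`"+"`/`"-"`), `offset` (0/1/2), `aa_seq`
#'   and `n_internal_stops_before_trim`.
#' @export
predict_frame <- function(nt) {
  s <- toupper(unname(nt[[1L]]))
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  fwd <- strsplit(s, "", fixed = TRUE)[[1L]]
  rev <- strsplit(revcomp(s), "", fixed = TRUE)[[1L]]
  frames <- list()
  for (strand in c("+", "-")) {
    ch <- if (strand == "+") fwd else rev
    for (off in 0:2) {
      aa <- translate_frame(ch, off)
      if (!length(aa)) next
      is_stop <- aa == "*"
      internal <- if (length(aa) > 1L) is_stop[-length(aa)] else logical(0L)
      runs <- rle(!is_stop)
      longest_free <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
      frames[[length(frames) + 1L]] <- list(
        strand = strand, offset = off, aa = aa,
        n_internal = sum(internal),
        terminal_stop = is_stop[length(aa)],
        longest_free = longest_free)
    }
  }
  n_int <- vapply(frames, `[[`, numeric(1L), "n_internal")
  term <- vapply(frames, `[[`, logical(1L), "terminal_stop")
  lf <- vapply(frames, `[[`, numeric(1L), "longest_free")
  # a clean terminal stop is positive evidence for a frame and outranks
  # the stop-free-stretch tie-break among equally stop-poor frames
  ord <- order(n_int, -term, -lf)  # stable: final ties keep frame order
  best <- frames[[ord[1L]]]
  aa <- best$aa
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    warning("internal stop in chosen frame; truncating", call. = FALSE)
    aa <- aa[seq_len(which(aa == "*")[1L] - 1L)]
  }
  list(strand = best$strand, offset = best$offset,
       aa_seq = paste(aa, collapse = ""),
       n_internal_stops_before_trim = best$n_internal)
}

# Highest-scoring collinear chain of diagonal segments. Segment ends
# may overrun an exon junction by a few chance matches, so bounded
# overlap between consecutive segments is allowed and charged against
# the chain score; the overlapping bases are trimmed at splice time.
chain_segments <- function(segs, max_overlap = 50L) {
  segs <- segs[order(sstart, qstart)]
  n <- nrow(segs)
  best <- segs$score
  prev <- rep(NA_integer_, n)
  if (n > 1L) for (i in 2:n) for (j in 1:(i - 1L)) {
    if (segs$qend[j] >= segs$qend[i] || segs$send[j] >= segs$send[i] ||
        segs$qstart[j] >= segs$qstart[i] || segs$sstart[j] >= segs$sstart[i])
      next
    o <- max(0L, segs$qend[j] - segs$qstart[i] + 1L,
             segs$send[j] - segs$sstart[i] + 1L)
    if (o > max_overlap) next
    cand <- best[j] + segs$score[i] - o
    if (cand > best[i]) { best[i] <- cand; prev[i] <- j }
  }
  end <- which.max(best)
  path <- end
  while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
  list(segments = segs[path], score = best[end])
}

#' Splice intron-bearing contigs down to their exon sequence
#'
#' Seeded matches between the contig and its locus reference are chained
#' collinearly (coordinates strictly increasing on both sequences); the
#' contig segments covered by the chain are concatenated in reference
#' order, removing intron interiors. Both strands are tried.
#'
#' @param contig A nucleotide string (length-1 named character vector or
#'   bare string).
#' @param bait Reference exon sequence for the contig's locus.
#' @param params A [match_params()] object.
#' @return Spliced nucleotide string (named like the contig when named).
#' @export
splice_to_exon <- function(contig, bait, params = match_params()) {
  id <- names(contig)
  query <- toupper(unname(contig[[1L]]))
  idx <- build_bait_index(setNames(unname(bait[[1L]]), "ref"), params)
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    segs <- diagonal_segments(strsplit(q, "", fixed = TRUE)[[1L]],
                              seq_kmers(q, params$seed_k), idx)
    if (is.null(segs) || nrow(segs) == 0L) next
    ch <- chain_segments(segs)
    if (is.null(best) || ch$score > best$score) {
      best <- ch; best$strand <- strand; best$query <- q
    }
  }
  if (is.null(best) || best$score < params$min_score)
    stop("no exon structure found")
  segs <- best$segments[order(sstart)]
  # trim junction overruns so each reference position is used once
  if (nrow(segs) > 1L) for (i in 2:nrow(segs)) {
    o <- max(0L, segs$qend[i - 1L] - segs$qstart[i] + 1L,
             segs$send[i - 1L] - segs$sstart[i] + 1L)
    if (o > 0L) {
      segs$qstart[i] <- segs$qstart[i] + o
      segs$sstart[i] <- segs$sstart[i] + o
    }
  }
  segs <- segs[qstart <= qend]
  out <- paste(substring(best$query, segs$qstart, segs$qend), collapse = "")
  if (!is.null(id)) names(out) <- id
  out
}

#' Reciprocal-best-hit orthology check
#'
#' A binned contig is re-searched against the full bait set; if the
#' locus of its single top score disagrees with its assigned locus the
#' contig is flagged as a potential paralog and excluded downstream.
#'
#' @param contig A nucleotide string (length-1 named character vector).
#' @param assigned_locus Locus the contig was binned to.
#' @param baits Full bait set (named character vector) or a prebuilt
#'   [build_bait_index()].
#' @param params A [match_params()] object.
#' @return list with `contig_id`, `assigned_locus`, `reverse_best_locus`
#'   and `status` (`"ortholog"` or `"paralog_flagged"`).
#' @export
reciprocal_best_hit <- function(contig, assigned_locus, baits,
                                params = match_params()) {
  idx <- if (is.list(baits) && !is.null(baits$index)) baits
         else build_bait_index(baits, params)
  id <- if (!is.null(names(contig))) names(contig) else "contig"
  hit <- best_locus_match(contig[[1L]], idx, query_id = id)
  rev_best <- if (is.null(hit)) NA_character_ else hit$locus
  status <- if (!is.na(rev_best) && rev_best == assigned_locus)
    "ortholog" else "paralog_flagged"
  list(contig_id = id, assigned_locus = assigned_locus,
       reverse_best_locus = rev_best, status = status)
}

#' Run the reciprocal-best-hit screen over a set of binned contigs
#'
#' @param contigs Named character vector of contig sequences.
#' @param assignments Named character vector contig id -> assigned locus.
#' @param baits Full bait set or prebuilt index.
#' @param params A [match_params()] object.
#' @return data.frame with one verdict row per contig.
#' @export
screen_orthology <- function(contigs, assignments, baits,
                             params = match_params()) {
  idx <- if (is.list(baits) && !is.null(baits$index)) baits
         else build_bait_index(baits, params)
  rows <- lapply(names(contigs), function(id) {
    v <- reciprocal_best_hit(contigs[id], assignments[[id]], idx, params)
    data.frame(contig_id = id, assigned_locus = v$assigned_locus,
               reverse_best_locus = v$reverse_best_locus, status = v$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
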