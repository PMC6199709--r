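#' Matching parameters for the seeded ungapped aligner
#'
#' The pipeline replaces an external BLAST dependency with a
#' self-contained matcher: exact k-mer seeds are located on both strands
#' and extended without gaps (match +1, mismatch -1); the score of a
#' hit is the best ungapped segment score on a seeded diagonal.
#'
#' @param seed_k Seed k-mer size.
#' @param min_score Minimum score for an assignment to be accepted.
#' @export
match_params <- function(seed_k = 11L, min_score = 50L) {
  seed_k <- as.integer(seed_k); min_score <- as.integer(min_score)
  if (seed_k < 4L) stop("seed_k must be >= 4")
  if (min_score <= 0L) stop("min_score must be positive")
  structure(list(seed_k = seed_k, min_score = min_score),
            class = "match_params")
}

# locus id of a bait: the part before the first '|' (tiled baits are
# named "locus|start"); a bare name is its own locus.
bait_locus <- function(ids) sub("\\|.*$", "", ids)

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0L))
  substring(s, 1:(n - k + 1L), k:n)
}

#' Build a reusable seed index over a bait set
#'
#' @param baits Named character vector of bait (or reference exon)
#'   sequences; names either `locus|start` or plain locus ids.
#' @param params A [match_params()] object.
#' @return Opaque index object consumed by the matching operations.
#' @export
build_bait_index <- function(baits, params = match_params()) {
  if (length(baits) == 0L) stop("empty bait set")
  up <- toupper(unname(baits))
  k <- params$seed_k
  tabs <- lapply(seq_along(up), function(i) {
    km <- seq_kmers(up[i], k)
    if (!length(km)) return(NULL)
    data.table(kmer = km, bait = i, spos = seq_along(km))
  })
  idx <- data.table::rbindlist(tabs)
  idx <- idx[!grepl("[^ACGT]", kmer)]
  data.table::setkey(idx, kmer)
  list(index = idx, seqs = up,
       chars = strsplit(up, "", fixed = TRUE),
       locus = bait_locus(names(baits)),
       params = params)
}

# Best-scoring contiguous segment of a +1/-1 vector (Kadane), returning
# score and 1-based bounds; all-negative input yields score 0.
best_segment <- function(v) {
  best <- 0; cur <- 0; curi <- 1L; bi <- 0L; bj <- -1L
  for (j in seq_along(v)) {
    if (cur <= 0) { cur <- 0; curi <- j }
    cur <- cur + v[j]
    if (cur > best) { best <- cur; bi <- curi; bj <- j }
  }
  list(score = best, from = bi, to = bj)
}

# All seeded diagonal segments of one query (single strand) against the
# index: data.table(bait, locus, qstart, qend, sstart, send, score).
diagonal_segments <- function(query_chars, query_kmers, idx) {
  if (!length(query_kmers)) return(NULL)
  qdt <- data.table(kmer = query_kmers, qpos = seq_along(query_kmers))
  qdt <- qdt[!grepl("[^ACGT]", kmer)]
  if (nrow(qdt) == 0L) return(NULL)
  hits <- idx$index[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(NULL)
  hits[, diag := qpos - spos]
  diags <- unique(hits[, .(bait, diag)])
  n <- length(query_chars)
  out <- vector("list", nrow(diags))
  for (r in seq_len(nrow(diags))) {
    b <- diags$bait[r]; d <- diags$diag[r]
    sc <- idx$chars[[b]]; m <- length(sc)
    s0 <- max(1L, 1L - d); s1 <- min(m, n - d)
    if (s1 < s0) next
    ss <- s0:s1; qq <- ss + d
    v <- ifelse(query_chars[qq] == sc[ss] & query_chars[qq] %in% c("A", "C", "G", "T"),
                1L, -1L)
    seg <- best_segment(v)
    if (seg$score <= 0) next
    out[[r]] <- data.table(bait = b, locus = idx$locus[b],
                           qstart = qq[seg$from], qend = qq[seg$to],
                           sstart = ss[seg$from], send = ss[seg$to],
                           score = seg$score)
  }
  data.table::rbindlist(out)
}

# Best segments for a query on both strands; strand '-' coordinates are
# on the reverse-complemented query.
query_segments <- function(query, idx) {
  k <- idx$params$seed_k
  up <- toupper(query)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") up else revcomp(up)
    segs <- diagonal_segments(strsplit(s, "", fixed = TRUE)[[1L]],
                              seq_kmers(s, k), idx)
    if (!is.null(segs) && nrow(segs)) {
      segs[, strand := strand]
      res[[strand]] <- segs
    }
  }
  data.table::rbindlist(res)
}

# Best match per locus for one query; returns data.table(locus, score,
# strand) sorted by score desc then locus.
per_locus_scores <- function(query, idx) {
  segs <- query_segments(query, idx)
  if (is.null(segs) || nrow(segs) == 0L)
    return(data.table(locus = character(0L), score = integer(0L),
                      strand = character(0L)))
  best <- segs[order(-score, locus, strand), .SD[1L], by = locus]
  best[order(-score, locus), .(locus, score, strand)]
}

# Single best locus for a query under the tie rule (lexicographically
# smallest locus id); NULL when nothing reaches min_score.
best_locus_match <- function(query, idx, warn_ties = TRUE, query_id = "?") {
  sc <- per_locus_scores(query, idx)
  sc <- sc[score >= idx$params$min_score]
  if (nrow(sc) == 0L) return(NULL)
  top <- sc[score == max(score)]
  if (nrow(top) > 1L && warn_ties)
    warning("tied best score for ", query_id, "; keeping lexicographically ",
            "smallest locus ", sort(top$locus)[1L], call. = FALSE)
  top <- top[order(locus)][1L]
  list(locus = top$locus, score = top$score, strand = top$strand,
       tied = nrow(sc[score == top$score]) > 1L)
}
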