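# Run code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Treelikeness-scoring parameters
#'
#' @param max_quartets Quartet-sample cap; quartets are enumerated
#'   exhaustively when `choose(n, 4)` fits, otherwise sampled uniformly.
#' @param resolution_margin Minimum margin by which the smallest
#'   four-point sum must beat the runner-up for a quartet to count as
#'   resolved.
#' @param rng_seed Seed for quartet sampling (logged for reproducibility).
#' @export
treelikeness_params <- function(max_quartets = 2000L, resolution_margin = 0,
                                rng_seed = 1L) {
  if (max_quartets < 1L) stop("max_quartets >= 1")
  if (resolution_margin < 0) stop("resolution_margin >= 0")
  structure(list(max_quartets = as.integer(max_quartets),
                 resolution_margin = resolution_margin,
                 rng_seed = as.integer(rng_seed)),
            class = "treelikeness_params")
}

# Four-point evaluation of one quartet given a p-distance matrix:
# 1 resolved, 0 unresolved, NA not evaluable. For an additive tree
# metric the smallest pairing sum sits uniquely below the two larger
# sums, which are equal; a quartet is resolved when the winning gap
# (s2 - s1) clears the margin AND is not exceeded by the additivity
# violation (s3 - s2). Noise data, whose three sums are just order
# statistics, fails the second test about half the time, while exact
# ties (no signal at all) fail the first.
quartet_resolved <- function(D, q, margin = 0) {
  d <- c(D[q[1L], q[2L]] + D[q[3L], q[4L]],
         D[q[1L], q[3L]] + D[q[2L], q[4L]],
         D[q[1L], q[4L]] + D[q[2L], q[3L]])
  if (anyNA(d)) return(NA)
  s <- sort(d)
  as.integer(s[2L] - s[1L] > margin && s[3L] - s[2L] <= s[2L] - s[1L])
}

#' Score per-locus treelikeness by quartet mapping
#'
#' For each sampled four-taxon subset the three four-point sums of
#' pairwise p-distances are compared; the quartet is resolved iff the
#' unique minimum beats the runner-up by more than `resolution_margin`.
#' Treelikeness is the resolved fraction over evaluated quartets;
#' quartets involving an undefined distance are skipped.
#'
#' @param aln A [locus_alignment()] with at least four taxa.
#' @param params A [treelikeness_params()] object.
#' @param min_overlap Comparable-site minimum for the distances.
#' @return list (class `locus_score`) with `locus_id`, `n_taxa`,
#'   `treelikeness`, `n_quartets_evaluated`.
#' @export
treelikeness <- function(aln, params = treelikeness_params(),
                         min_overlap = 1L) {
  n <- length(aln$rows)
  if (n < 4L) stop("fewer than 4 taxa in locus ", aln$locus_id)
  D <- pdist_matrix(aln, min_overlap)$d
  total <- choose(n, 4L)
  quartets <- if (total <= params$max_quartets) {
    utils::combn(n, 4L)
  } else {
    with_seed(params$rng_seed, {
      qs <- unique(t(replicate(3L * params$max_quartets,
                               sort(sample.int(n, 4L)))))
      t(qs[seq_len(min(nrow(qs), params$max_quartets)), , drop = FALSE])
    })
  }
  res <- apply(quartets, 2L, quartet_resolved, D = D,
               margin = params$resolution_margin)
  res <- res[!is.na(res)]
  if (!length(res)) stop("fewer than 4 evaluable taxa in locus ", aln$locus_id)
  structure(list(locus_id = aln$locus_id, n_taxa = n,
                 treelikeness = mean(res),
                 n_quartets_evaluated = length(res)),
            class = "locus_score")
}

#' Drop loci represented by too few taxa
#'
#' A row counts toward the taxon total only if it carries at least one
#' determined, non-gap character; all-gap or all-N rows are ghosts left
#' by upstream filtering.
#'
#' @param loci List of [locus_alignment()] objects.
#' @param min_taxa Minimum effective taxa (default 4, the smallest
#'   number that defines an unrooted topology).
#' @return list with `kept` and `excluded` lists of alignments.
#' @export
filter_min_taxa <- function(loci, min_taxa = 4L) {
  eff <- vapply(loci, function(a) {
    m <- aln_char_matrix(a$rows)
    sum(apply(m, 1L, function(r) any(!(r %in% c("-", "N")))))
  }, integer(1L))
  list(kept = loci[eff >= min_taxa], excluded = loci[eff < min_taxa])
}

#' Rank loci by informativeness and take the top set
#'
#' Composite informativeness is treelikeness times taxon-coverage
#' fraction, trading phylogenetic signal against matrix occupancy. Ties
#' resolve by taxon count (descending) then locus id (ascending), so the
#' ranking is deterministic.
#'
#' @param scores List of `locus_score` objects (or the data.frame from
#'   [score_loci()]).
#' @param total_taxa Size of the full taxon universe.
#' @param n_target Number of loci to select.
#' @return data.frame of selected loci in rank order, with the composite
#'   score column.
#' @export
select_informative <- function(scores, total_taxa, n_target) {
  if (n_target <= 0L) stop("n_target must be positive")
  df <- if (is.data.frame(scores)) scores else
    do.call(rbind, lapply(scores, function(s)
      data.frame(locus_id = s$locus_id, n_taxa = s$n_taxa,
                 treelikeness = s$treelikeness, stringsAsFactors = FALSE)))
  if (n_target > nrow(df)) stop("n_target exceeds number of scored loci")
  df$composite <- df$treelikeness * df$n_taxa / total_taxa
  ord <- order(-df$composite, -df$n_taxa, df$locus_id)
  utils::head(df[ord, , drop = FALSE], n_target)
}

#' Score a list of loci
#' @param loci List of [locus_alignment()] objects.
#' @param params A [treelikeness_params()] object.
#' @return data.frame locus_id, n_taxa, treelikeness, n_quartets_evaluated.
#' @export
score_loci <- function(loci, params = treelikeness_params()) {
  do.call(rbind, lapply(loci, function(a) {
    s <- treelikeness(a, params)
    data.frame(locus_id = s$locus_id, n_taxa = s$n_taxa,
               treelikeness = s$treelikeness,
               n_quartets_evaluated = s$n_quartets_evaluated,
               stringsAsFactors = FALSE)
  }))
}
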