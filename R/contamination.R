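#' Cross-contamination screen parameters
#'
#' A locus is flagged for a pair of distantly related taxa when their
#' p-distance is at or below `p_threshold` (default 0.002, i.e. at most
#' one mismatch per 500 comparable sites). Pairs whose flagged-locus
#' percentage reaches `pct_alarm` are reported as suspected
#' contamination; `pct_alarm` has no canonical value and is an artifact
#' choice (a clean dataset sits well below it).
#'
#' @param p_threshold p-distance at or below which a locus is flagged.
#' @param min_overlap Minimum comparable sites for a distance to count.
#' @param pct_alarm Flagged-locus percentage that raises an alarm.
#' @export
screen_params <- function(p_threshold = 0.002, min_overlap = 1L,
                          pct_alarm = 5.0) {
  if (p_threshold < 0 || p_threshold > 1) stop("p_threshold in [0,1]")
  if (min_overlap < 1L) stop("min_overlap >= 1")
  if (pct_alarm <= 0 || pct_alarm > 100) stop("pct_alarm in (0,100]")
  structure(list(p_threshold = p_threshold,
                 min_overlap = as.integer(min_overlap),
                 pct_alarm = pct_alarm), class = "screen_params")
}

#' Uncorrected pairwise distance between two alignment rows
#'
#' Comparable sites are columns where both rows carry an unambiguous
#' nucleotide (`A`, `C`, `G`, `T` after normalization); gaps, `N` and
#' ambiguity codes never count. The distance is mismatches over
#' comparable sites, `NA` when fewer than `min_overlap` sites compare.
#'
#' @param aln A [locus_alignment()].
#' @param a,b Taxon names present in `aln`.
#' @param min_overlap Minimum comparable-site count.
#' @return list with `distance` (or `NA`) and `n_comparable`.
#' @export
p_distance <- function(aln, a, b, min_overlap = 1L) {
  rows <- aln$rows
  for (t in c(a, b)) if (!t %in% names(rows))
    stop("taxon ", t, " absent from locus ", aln$locus_id)
  x <- norm_chars(strsplit(rows[[a]], "", fixed = TRUE)[[1L]])
  y <- norm_chars(strsplit(rows[[b]], "", fixed = TRUE)[[1L]])
  acgt <- c("A", "C", "G", "T")
  comp <- x %in% acgt & y %in% acgt
  n <- sum(comp)
  d <- if (n >= min_overlap) sum(x[comp] != y[comp]) / n else NA_real_
  list(distance = d, n_comparable = n)
}

# All pairwise p-distances of an alignment as matrices (distance and
# comparable-site counts); used by the screen and by treelikeness.
pdist_matrix <- function(aln, min_overlap = 1L) {
  m <- aln_char_matrix(aln$rows)
  comp <- m %in% c("A", "C", "G", "T")
  dim(comp) <- dim(m)
  n <- nrow(m)
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  N <- matrix(0L, n, n, dimnames = dimnames(D))
  diag(D) <- 0
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- comp[i, ] & comp[j, ]
    nn <- sum(ok)
    N[i, j] <- N[j, i] <- nn
    if (nn >= min_overlap)
      D[i, j] <- D[j, i] <- sum(m[i, ok] != m[j, ok]) / nn
  }
  list(d = D, n = N)
}

#' Screen loci for cross-contamination between distant taxa
#'
#' For every inter-group taxon pair, every locus containing both taxa
#' with an evaluable distance contributes to that pair's denominator;
#' the locus is flagged iff the distance is `<= p_threshold`. Pairs
#' whose flagged percentage reaches `pct_alarm` are listed as suspected
#' contamination. Intra-group pairs are skipped unless
#' `within_groups = TRUE` (debugging aid).
#'
#' @param loci List of [locus_alignment()] objects.
#' @param groups A [taxon_groups()] object with at least two groups.
#' @param params A [screen_params()] object.
#' @param within_groups Also test pairs inside a group.
#' @return Object of class `contamination_report`: `per_pair`
#'   (data.frame taxon_a, taxon_b, n_evaluable, n_flagged, percentage,
#'   alarm), `max_percentage`, `flagged_loci` (data.frame locus,
#'   taxon_a, taxon_b, p_distance) and `params`.
#' @export
screen_cross_contamination <- function(loci, groups,
                                       params = screen_params(),
                                       within_groups = FALSE) {
  stopifnot(length(loci) >= 1L)
  g <- groups$assignment
  if (length(unique(g)) < 2L && !within_groups)
    stop("no distant pairs: taxon table declares a single group")
  taxa <- sort(names(g))
  pairs <- utils::combn(taxa, 2L)
  inter <- g[pairs[1L, ]] != g[pairs[2L, ]]
  if (!within_groups) pairs <- pairs[, inter, drop = FALSE]
  n_pairs <- ncol(pairs)
  n_eval <- integer(n_pairs); n_flag <- integer(n_pairs)
  flagged <- list()
  for (loc in loci) {
    pd <- pdist_matrix(loc, params$min_overlap)
    present <- rownames(pd$d)
    for (k in seq_len(n_pairs)) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      if (!(a %in% present && b %in% present)) next
      d <- pd$d[a, b]
      if (is.na(d)) next
      n_eval[k] <- n_eval[k] + 1L
      if (d <= params$p_threshold) {
        n_flag[k] <- n_flag[k] + 1L
        flagged[[length(flagged) + 1L]] <-
          data.frame(locus = loc$locus_id, taxon_a = a, taxon_b = b,
                     p_distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  pct <- ifelse(n_eval > 0L, 100 * n_flag / n_eval, 0)
  per_pair <- data.frame(taxon_a = pairs[1L, ], taxon_b = pairs[2L, ],
                         n_evaluable = n_eval, n_flagged = n_flag,
                         percentage = pct, alarm = pct >= params$pct_alarm,
                         stringsAsFactors = FALSE)
  structure(list(per_pair = per_pair,
                 max_percentage = if (n_pairs) max(pct) else 0,
                 flagged_loci = if (length(flagged)) do.call(rbind, flagged)
                                else data.frame(locus = character(0L),
                                                taxon_a = character(0L),
                                                taxon_b = character(0L),
                                                p_distance = numeric(0L)),
                 params = params),
            class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  cat("<contamination_report> ", nrow(x$per_pair), " distant pairs; max ",
      sprintf("%.2f%%", x$max_percentage), " flagged loci; ",
      sum(x$per_pair$alarm), " pair(s) above alarm\n", sep = "")
  invisible(x)
}
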