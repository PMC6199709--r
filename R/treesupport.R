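split_key <- function(side) paste(side, collapse = "\r")

canon_side <- function(side, universe) {
  side <- sort(side)
  if (min(universe) %in% side) side else sort(setdiff(universe, side))
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' One bipartition per internal branch; trivial splits (a single leaf
#' against the rest) are excluded. Each split is canonically oriented:
#' the returned side contains the lexicographically smallest leaf label.
#'
#' @param tree A `phylo` object.
#' @return Named list (keyed canonically) of sorted character vectors,
#'   with the leaf universe as attribute `universe`. Empty for trees
#'   with fewer than 4 leaves.
#' @export
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  out <- list()
  if (length(tips) >= 4L) {
    tree <- ape::unroot(tree)
    pp <- ape::prop.part(tree)
    labels <- attr(pp, "labels")
    n <- length(labels)
    for (cl in pp) {
      if (length(cl) < 2L || length(cl) > n - 2L) next
      side <- canon_side(labels[cl], tips)
      out[[split_key(side)]] <- side
    }
  }
  attr(out, "universe") <- tips
  out
}

# Restrict a split (side on `universe`) to leaf subset `s`; NULL when
# the restriction is trivial (either side < 2).
restrict_split <- function(side, universe, s) {
  sa <- intersect(side, s)
  sb <- setdiff(s, side)
  if (length(sa) < 2L || length(sb) < 2L) return(NULL)
  canon_side(sa, s)
}

# Two splits over the same universe conflict iff all four pairwise
# side intersections are non-empty (four-intersection test).
splits_conflict <- function(side1, side2, universe) {
  c1 <- setdiff(universe, side1); c2 <- setdiff(universe, side2)
  length(intersect(side1, side2)) > 0L &&
    length(intersect(side1, c2)) > 0L &&
    length(intersect(c1, side2)) > 0L &&
    length(intersect(c1, c2)) > 0L
}

plog <- function(p, base) ifelse(p > 0, p * log(p, base = base), 0)

# IC from the reference frequency and its strongest conflictor.
ic_value <- function(f_b, f_b1) {
  if (is.na(f_b1)) return(if (f_b > 0) 1 else 0)
  if (f_b + f_b1 == 0) return(0)
  p <- f_b / (f_b + f_b1)
  v <- 1 + plog(p, 2) + plog(1 - p, 2)
  if (f_b1 > f_b) -v else v
}

# ICA over the reference split and all conflictors passing the
# relative-frequency threshold.
ica_value <- function(f_b, conf_freqs, threshold = 0.05) {
  if (!length(conf_freqs)) return(if (f_b > 0) 1 else 0)
  f_top <- max(f_b, conf_freqs)
  keep <- conf_freqs[conf_freqs >= threshold * f_top]
  if (!length(keep)) return(ic_value(f_b, max(conf_freqs)))
  fr <- c(f_b, keep)
  q <- fr / sum(fr)
  v <- 1 + sum(plog(q, base = length(fr)))
  if (max(conf_freqs) > f_b) -v else v
}

#' Internode certainty and tree certainty from gene trees
#'
#' For each internal branch of the reference tree, gene trees are
#' reduced to the branch's leaf set; a tree is evaluable when the
#' restricted split is still nontrivial (both sides keep two or more
#' leaves). Support and conflictor frequencies are fractions of
#' evaluable trees; IC scores the entropy between the reference split
#' and its strongest conflictor, ICA generalizes over all conflictors
#' at or above `conflictor_threshold` times the top frequency. The sign
#' is negative when the reference split is not the most frequent — gene
#' trees prefer an alternative resolution. TC is the sum of IC over
#' internal branches; relative TC divides by the branch count.
#'
#' @param reference A `phylo` reference topology (>= 4 leaves).
#' @param gene_trees List of `phylo` gene trees; leaf sets must be
#'   subsets of the reference leaf set (partial trees allowed).
#' @param conflictor_threshold Inclusion threshold for ICA, as a
#'   fraction of the top frequency.
#' @return Object of class `certainty_result`: `per_branch` data.frame
#'   (key, branch, ic, ica, support_freq, top_conflict_freq,
#'   n_evaluable_trees), `tc`, `relative_tc`, `n_internal_branches`.
#' @export
internode_certainty <- function(reference, gene_trees,
                                conflictor_threshold = 0.05) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  stopifnot(length(gene_trees) >= 1L)
  ref_tips <- sort(reference$tip.label)
  for (i in seq_along(gene_trees)) {
    extra <- setdiff(gene_trees[[i]]$tip.label, ref_tips)
    if (length(extra))
      stop("gene tree ", i, " has leaves outside the reference: ",
           paste(extra, collapse = ", "))
  }
  ref_splits <- bipartitions(reference)
  gt <- lapply(gene_trees, function(t)
    list(tips = sort(t$tip.label), splits = bipartitions(t)))
  rows <- lapply(names(ref_splits), function(key) {
    side <- ref_splits[[key]]
    n_eval <- 0L; n_support <- 0L
    conf_counts <- new.env(parent = emptyenv())
    for (g in gt) {
      r <- restrict_split(side, ref_tips, g$tips)
      if (is.null(r)) next
      n_eval <- n_eval + 1L
      rkey <- split_key(r)
      if (!is.null(g$splits[[rkey]])) n_support <- n_support + 1L
      for (skey in names(g$splits)) {
        s <- g$splits[[skey]]
        if (splits_conflict(r, s, g$tips)) {
          full <- paste(split_key(g$tips), skey, sep = "\n")
          assign(full, get0(full, envir = conf_counts, ifnotfound = 0L) + 1L,
                 envir = conf_counts)
        }
      }
    }
    conf <- unlist(as.list(conf_counts))
    f_b <- if (n_eval > 0L) n_support / n_eval else 0
    conf_freqs <- if (n_eval > 0L && length(conf)) sort(conf / n_eval,
                                                        decreasing = TRUE)
                  else numeric(0L)
    ic <- if (length(conf_freqs)) ic_value(f_b, conf_freqs[1L])
          else ic_value(f_b, NA_real_)
    ica <- ica_value(f_b, conf_freqs, conflictor_threshold)
    data.frame(key = key, branch = paste(side, collapse = ","),
               ic = ic, ica = ica, support_freq = f_b,
               top_conflict_freq = if (length(conf_freqs)) conf_freqs[1L]
                                   else 0,
               n_evaluable_trees = n_eval, stringsAsFactors = FALSE)
  })
  per_branch <- do.call(rbind, rows)
  n_internal <- length(ref_splits)
  tc <- sum(per_branch$ic)
  structure(list(per_branch = per_branch, tc = tc,
                 relative_tc = if (n_internal > 0L) tc / n_internal else NA_real_,
                 n_internal_branches = n_internal),
            class = "certainty_result")
}

#' @export
print.certainty_result <- function(x, ...) {
  cat("<certainty_result> ", x$n_internal_branches, " internal branches; TC = ",
      sprintf("%.3f", x$tc), "; relative TC = ",
      sprintf("%.3f", x$relative_tc), "\n", sep = "")
  invisible(x)
}

#' Annotate a reference tree with IC/ICA branch labels
#'
#' @param reference The `phylo` used in [internode_certainty()].
#' @param result The matching `certainty_result`.
#' @param digits Label precision.
#' @return `phylo` with `ic/ica` node labels on matched internal nodes.
#' @export
annotate_ic <- function(reference, result, digits = 3L) {
  tree <- ape::unroot(reference)
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  node_lab <- rep("", tree$Nnode)
  lut <- setNames(sprintf(paste0("%.", digits, "f/%.", digits, "f"),
                          result$per_branch$ic, result$per_branch$ica),
                  result$per_branch$key)
  for (i in seq_along(pp)) {
    cl <- pp[[i]]
    if (length(cl) < 2L || length(cl) > length(labels) - 2L) next
    key <- split_key(canon_side(labels[cl], tips))
    if (!is.na(lut[key])) node_lab[i] <- lut[[key]]
  }
  tree$node.label <- node_lab
  tree
}

#' Neighbor-joining tree from a distance table
#'
#' A thin, validated front on the standard agglomeration; used to build
#' surrogate gene trees from synthetic loci.
#'
#' @param d Symmetric distance matrix (or `dist`) over >= 4 taxa with a
#'   zero diagonal and no undefined entries.
#' @return Unrooted `phylo` with branch lengths.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 4L) stop("neighbor joining needs >= 4 taxa")
  if (anyNA(m)) stop("undefined entry in distance table")
  if (any(abs(m - t(m)) > 1e-9)) stop("distance table not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance table diagonal not zero")
  ape::nj(stats::as.dist(m))
}
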