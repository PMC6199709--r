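# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: plain loops and base R only (plus
# phangorn for split enumeration in the tree-certainty oracle).

# write a named character vector as a temporary FASTA, one line per seq
tmp_fasta <- function(seqs, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# brute-force p-distance by per-character loop
oracle_pdist <- function(sa, sb) {
  a <- toupper(strsplit(sa, "")[[1]]); b <- toupper(strsplit(sb, "")[[1]])
  acgt <- c("A", "C", "G", "T")
  n <- 0L; mm <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% acgt && b[i] %in% acgt) {
      n <- n + 1L
      if (a[i] != b[i]) mm <- mm + 1L
    }
  }
  list(d = if (n > 0) mm / n else NA_real_, n = n)
}

# brute-force distinct column count and gap/undetermined proportion
oracle_matrix_stats <- function(rows) {
  m <- do.call(rbind, strsplit(toupper(unname(rows)), ""))
  m[m %in% c("?", ".")] <- "N"
  m[!(m %in% c("A", "C", "G", "T", "-", "N"))] <- "N"
  cols <- apply(m, 2, paste, collapse = "")
  list(patterns = length(unique(cols)),
       prop = mean(m == "-" | m == "N"))
}

# exhaustive four-point quartet score from a distance matrix
oracle_treelikeness <- function(D, margin = 0) {
  n <- nrow(D)
  res <- c()
  for (q in utils::combn(n, 4, simplify = FALSE)) {
    s <- c(D[q[1], q[2]] + D[q[3], q[4]],
           D[q[1], q[3]] + D[q[2], q[4]],
           D[q[1], q[4]] + D[q[2], q[3]])
    if (anyNA(s)) next
    s <- sort(s)
    res <- c(res, as.integer(s[2] - s[1] > margin && s[3] - s[2] <= s[2] - s[1]))
  }
  if (!length(res)) NA_real_ else mean(res)
}

# best ungapped local alignment score by exhaustive diagonal scan
oracle_ungapped_score <- function(query, subject) {
  best_for <- function(qc, sc) {
    n <- length(qc); m <- length(sc); best <- 0
    for (d in (-(m - 1)):(n - 1)) {
      s0 <- max(1, 1 - d); s1 <- min(m, n - d)
      if (s1 < s0) next
      cur <- 0
      for (s in s0:s1) {
        v <- if (qc[s + d] == sc[s] && qc[s + d] %in% c("A", "C", "G", "T"))
          1 else -1
        cur <- max(0, cur + v)
        best <- max(best, cur)
      }
    }
    best
  }
  qc <- strsplit(toupper(query), "")[[1]]
  sc <- strsplit(toupper(subject), "")[[1]]
  rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(query)))), "")[[1]]
  max(best_for(qc, sc), best_for(rc, sc))
}

# naive bipartition-frequency recount of IC/ICA/TC for complete gene
# trees, using phangorn for split enumeration
oracle_certainty <- function(reference, gene_trees, threshold = 0.05) {
  splits_of <- function(tr) {
    tips <- sort(tr$tip.label)
    sp <- phangorn::as.splits(ape::unroot(tr))
    labs <- attr(sp, "labels")
    out <- character(0)
    for (s in sp) {
      side <- labs[s]
      if (length(side) < 2 || length(side) > length(labs) - 2) next
      if (!(min(tips) %in% side)) side <- setdiff(tips, side)
      out <- c(out, paste(sort(side), collapse = "|"))
    }
    unique(out)
  }
  conflict <- function(k1, k2, tips) {
    a <- strsplit(k1, "|", fixed = TRUE)[[1]]
    b <- strsplit(k2, "|", fixed = TRUE)[[1]]
    ca <- setdiff(tips, a); cb <- setdiff(tips, b)
    length(intersect(a, b)) > 0 && length(intersect(a, cb)) > 0 &&
      length(intersect(ca, b)) > 0 && length(intersect(ca, cb)) > 0
  }
  tips <- sort(reference$tip.label)
  gsplits <- lapply(gene_trees, splits_of)
  n <- length(gene_trees)
  ics <- c()
  for (rk in splits_of(reference)) {
    support <- sum(vapply(gsplits, function(s) rk %in% s, logical(1)))
    conf <- table(unlist(lapply(gsplits, function(s)
      s[vapply(s, conflict, logical(1), k2 = rk, tips = tips)])))
    f_b <- support / n
    if (!length(conf)) {
      ic <- if (f_b > 0) 1 else 0
    } else {
      f1 <- max(conf) / n
      p <- f_b / (f_b + f1)
      h <- function(x) if (x > 0) x * log2(x) else 0
      ic <- (1 + h(p) + h(1 - p)) * (if (f1 > f_b) -1 else 1)
      if (f_b + f1 == 0) ic <- 0
    }
    ics <- c(ics, ic)
  }
  list(ic = ics, tc = sum(ics))
}

# deterministic toy alignment: rows of fixed strings
toy_aln <- function(locus_id, ...) {
  locus_alignment(locus_id, c(...))
}
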