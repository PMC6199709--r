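STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Simulate an intact open reading frame
#'
#' `ATG` followed by codons drawn uniformly from the 61 non-stop codons,
#' so the +0 frame is stop-free by construction.
#'
#' @param n_codons Number of codons including the start.
#' @return Nucleotide string of length `3 * n_codons`.
#' @export
sim_orf <- function(n_codons) {
  stopifnot(n_codons >= 2L)
  bases <- c("A", "C", "G", "T")
  codons <- paste0(sample(bases, n_codons - 1L, TRUE),
                   sample(bases, n_codons - 1L, TRUE),
                   sample(bases, n_codons - 1L, TRUE))
  bad <- codons %in% STOP_CODONS
  while (any(bad)) {
    codons[bad] <- paste0(sample(bases, sum(bad), TRUE),
                          sample(bases, sum(bad), TRUE),
                          sample(bases, sum(bad), TRUE))
    bad <- codons %in% STOP_CODONS
  }
  paste0("ATG", paste(codons, collapse = ""))
}

# Jukes-Cantor-like site substitution: each site changes with
# probability `p` to a uniformly chosen different base. With
# preserve_orf, codons that would become stops revert to the parent
# codon (purifying selection keeps frame-prediction truth well defined).
mutate_chars <- function(parent, p, preserve_orf = FALSE) {
  n <- length(parent)
  child <- parent
  hit <- which(runif(n) < p)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    child[hit] <- vapply(parent[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1L))
  }
  if (preserve_orf && n %% 3L == 0L) {
    starts <- seq(1L, n, by = 3L)
    codons <- paste0(child[starts], child[starts + 1L], child[starts + 2L])
    bad <- which(codons %in% STOP_CODONS)
    for (b in bad) {
      i <- starts[b]
      child[i:(i + 2L)] <- parent[i:(i + 2L)]
    }
  }
  child
}

jc_prob <- function(rate, t) 0.75 * (1 - exp(-4 / 3 * rate * t))

#' Configuration of the synthetic capture dataset
#'
#' Defaults emulate a desk-scale capture experiment: 20 taxa on a
#' pure-birth species tree of unit height, 100 coding loci of 300-900 nt,
#' per-locus substitution rates giving tip-reference divergences of at
#' most ~15% (orthologs stay under the matcher's working range while
#' cross-group p-distances exceed 5%), 20% PCR-duplicate read pairs,
#' introns in 30% of contigs, 10% missing taxa per locus, and planted
#' paralogs three times as divergent as the typical ortholog.
#'
#' @param n_taxa Number of taxa.
#' @param n_loci Number of target loci.
#' @param locus_length_range Locus length bounds, nt (rounded to codons).
#' @param subs_rate_range Per-locus substitution rate bounds (expected
#'   substitutions per site along a unit branch).
#' @param dup_read_fraction Fraction of duplicate read pairs planted.
#' @param paralog_count Number of planted paralog contigs.
#' @param paralog_divergence_mult Paralog divergence as a multiple of
#'   the mean substitution rate.
#' @param contamination_events List of events, each
#'   `list(donor=, recipient=, fraction=, residual_noise=)`; noise must
#'   stay below the screen threshold so the plant is detectable.
#' @param intron_rate Per-contig intron probability.
#' @param intron_length_range Intron length bounds, nt.
#' @param missing_taxon_fraction Per-locus taxon dropout probability.
#' @param read_length Read length for the simulated pairs.
#' @param pairs_per_contig Unique read pairs cut per contig.
#' @param birth_tree_seed Seed of the species tree (defaults to
#'   `rng_seed + 1`).
#' @param rng_seed Master seed; identical seeds give identical outputs.
#' @param make_contigs,make_reads Set `FALSE` to skip the contig / read
#'   layers when only alignments are needed (alignment content is
#'   unaffected).
#' @export
sim_config <- function(n_taxa = 20L, n_loci = 100L,
                       locus_length_range = c(300L, 900L),
                       subs_rate_range = c(0.05, 0.15),
                       dup_read_fraction = 0.2,
                       paralog_count = 5L,
                       paralog_divergence_mult = 3,
                       contamination_events = list(),
                       intron_rate = 0.3,
                       intron_length_range = c(60L, 300L),
                       missing_taxon_fraction = 0.1,
                       read_length = 100L,
                       pairs_per_contig = 3L,
                       birth_tree_seed = NULL,
                       rng_seed = 1L,
                       make_contigs = TRUE,
                       make_reads = TRUE) {
  stopifnot(n_taxa >= 4L, n_loci >= 1L,
            dup_read_fraction >= 0, dup_read_fraction <= 1,
            intron_rate >= 0, intron_rate <= 1,
            missing_taxon_fraction >= 0, missing_taxon_fraction < 1)
  for (ev in contamination_events) {
    stopifnot(all(c("donor", "recipient", "fraction") %in% names(ev)))
    if (ev$donor == ev$recipient)
      stop("contamination donor equals recipient: ", ev$donor)
    if (is.null(ev$residual_noise)) ev$residual_noise <- 0
    if (ev$residual_noise > 0.001)
      stop("residual_noise must be <= 0.001 to stay detectable")
  }
  structure(list(n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci),
                 locus_length_range = as.integer(locus_length_range),
                 subs_rate_range = subs_rate_range,
                 dup_read_fraction = dup_read_fraction,
                 paralog_count = as.integer(paralog_count),
                 paralog_divergence_mult = paralog_divergence_mult,
                 contamination_events = contamination_events,
                 intron_rate = intron_rate,
                 intron_length_range = as.integer(intron_length_range),
                 missing_taxon_fraction = missing_taxon_fraction,
                 read_length = as.integer(read_length),
                 pairs_per_contig = as.integer(pairs_per_contig),
                 birth_tree_seed = if (is.null(birth_tree_seed))
                   as.integer(rng_seed) + 1L else as.integer(birth_tree_seed),
                 rng_seed = as.integer(rng_seed),
                 make_contigs = isTRUE(make_contigs),
                 make_reads = isTRUE(make_reads) && isTRUE(make_contigs)),
            class = "sim_config")
}

sim_species_tree <- function(cfg) {
  tr <- with_seed(cfg$birth_tree_seed,
                  ape::rphylo(cfg$n_taxa, birth = 1, death = 0))
  tr$tip.label <- sprintf("t%02d", seq_len(cfg$n_taxa))
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h
  tr
}

root_groups <- function(tree) {
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  side1 <- if (kids[1L] <= length(tree$tip.label)) tree$tip.label[kids[1L]]
           else ape::extract.clade(tree, kids[1L])$tip.label
  g <- ifelse(tree$tip.label %in% side1, "g1", "g2")
  taxon_groups(setNames(g, tree$tip.label))
}

#' Preview the species tree and taxon groups of a configuration
#'
#' The tree (and hence the group assignment) depends only on
#' `birth_tree_seed`, so the preview matches a later full
#' [simulate_dataset()] run with the same configuration; use it to pick
#' inter-group donor/recipient taxa for contamination events.
#'
#' @param cfg A [sim_config()] object.
#' @return list with `tree` and `groups`.
#' @export
sim_taxon_groups <- function(cfg = sim_config()) {
  tree <- sim_species_tree(cfg)
  list(tree = tree, groups = root_groups(tree))
}

# Evolve one locus along the tree; returns list(ref =, tips = named list
# of char vectors).
evolve_locus <- function(tree, root_chars, rate) {
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root_chars
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    p <- jc_prob(rate, tr$edge.length[e])
    seqs[[child]] <- mutate_chars(seqs[[par]], p, preserve_orf = TRUE)
  }
  setNames(seqs[seq_len(ntip)], tree$tip.label)
}

#' Simulate one locus alignment along a given tree
#'
#' Evolves an intact ORF down an arbitrary `phylo` under the same
#' uniform-replacement process the full generator uses; handy for
#' building loci with controlled branch-length signal.
#'
#' @param tree A `phylo` with branch lengths.
#' @param n_codons ORF length in codons.
#' @param rate Expected substitutions per site per unit branch length.
#' @param rng_seed Seed.
#' @param locus_id Label of the returned alignment.
#' @return A [locus_alignment()] over the tree's tips.
#' @export
sim_locus_on_tree <- function(tree, n_codons, rate, rng_seed = 1L,
                              locus_id = "locus") {
  with_seed(rng_seed, {
    root <- strsplit(sim_orf(n_codons), "", fixed = TRUE)[[1L]]
    tips <- evolve_locus(tree, root, rate)
    locus_alignment(locus_id,
                    vapply(tips, paste, character(1L), collapse = ""))
  })
}

#' Simulate a capture-like dataset with planted artifacts
#'
#' Generates a species tree, per-locus alignments evolved under a
#' uniform-replacement substitution process, contigs with optional
#' introns and random strands, paired reads with planted prefix
#' duplicates, paralog contigs claimed for the wrong locus, and
#' cross-contamination events, together with truth tables for every
#' plant. With `out_dir` set, all artifacts are written to disk
#' (FASTA/FASTQ/TSV/Newick); identical seeds give identical bytes.
#'
#' @param cfg A [sim_config()] object.
#' @param out_dir Optional output directory.
#' @return list with `tree`, `groups`, `refs` (bait/reference exons),
#'   `loci` (list of [locus_alignment()]), `contigs`, `claimed` (contig
#'   -> claimed locus), `pairs` (read-pair data.frame), `truth` (tables
#'   described above), `config`, and `files` when written.
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  tree <- sim_species_tree(cfg)
  with_seed(cfg$rng_seed, {
    groups <- root_groups(tree)
    taxa <- tree$tip.label
    llr <- cfg$locus_length_range
    locus_ids <- sprintf("locus%03d", seq_len(cfg$n_loci))
    codon_choices <- seq(max(2L, llr[1L] %/% 3L), max(2L, llr[2L] %/% 3L))
    n_codons <- codon_choices[sample.int(length(codon_choices), cfg$n_loci,
                                         replace = TRUE)]
    rates <- runif(cfg$n_loci, cfg$subs_rate_range[1L], cfg$subs_rate_range[2L])
    refs <- list(); tipseqs <- list()
    for (i in seq_len(cfg$n_loci)) {
      root_chars <- strsplit(sim_orf(n_codons[i]), "", fixed = TRUE)[[1L]]
      refs[[locus_ids[i]]] <- root_chars
      tipseqs[[locus_ids[i]]] <- evolve_locus(tree, root_chars, rates[i])
    }

    # taxon dropout per locus, keeping at least four taxa
    present <- lapply(locus_ids, function(l) {
      keep <- taxa[runif(length(taxa)) >= cfg$missing_taxon_fraction]
      if (length(keep) < 4L)
        keep <- sort(unique(c(keep, sample(taxa, 4L))))
      keep
    })
    names(present) <- locus_ids

    # contamination: overwrite the recipient's row with the donor's
    contam_truth <- list()
    for (ev in cfg$contamination_events) {
      noise <- if (is.null(ev$residual_noise)) 0 else ev$residual_noise
      n_pick <- round(ev$fraction * cfg$n_loci)
      picked <- sort(sample(locus_ids, n_pick))
      for (l in picked) {
        present[[l]] <- sort(unique(c(present[[l]], ev$donor, ev$recipient)))
        tipseqs[[l]][[ev$recipient]] <-
          mutate_chars(tipseqs[[l]][[ev$donor]], noise)
        contam_truth[[length(contam_truth) + 1L]] <-
          data.frame(locus = l, donor = ev$donor, recipient = ev$recipient,
                     stringsAsFactors = FALSE)
      }
    }

    loci <- lapply(locus_ids, function(l) {
      rows <- vapply(tipseqs[[l]][present[[l]]], paste, character(1L),
                     collapse = "")
      locus_alignment(l, rows)
    })
    names(loci) <- locus_ids

    # planted paralogs: a duplicate locus M of L joins the bait set; the
    # paralog contig is near M but claimed for L
    paralog_truth <- list()
    par_loci <- if (cfg$paralog_count > 0L)
      sample(locus_ids, min(cfg$paralog_count, cfg$n_loci)) else character(0L)
    par_contigs <- list()
    for (L in par_loci) {
      pd <- cfg$paralog_divergence_mult * mean(cfg$subs_rate_range)
      M <- paste0(L, "dup")
      refs[[M]] <- mutate_chars(refs[[L]], jc_prob(pd, 1), preserve_orf = TRUE)
      tx <- sample(taxa, 1L)
      cid <- paste0(tx, "@", L, "#par")
      par_contigs[[cid]] <- paste(
        mutate_chars(refs[[M]], jc_prob(mean(cfg$subs_rate_range), 1),
                     preserve_orf = TRUE), collapse = "")
      paralog_truth[[length(paralog_truth) + 1L]] <-
        data.frame(contig_id = cid, claimed_locus = L, source_locus = M,
                   stringsAsFactors = FALSE)
    }

    # contigs: tip sequence, optional intron, random strand
    contig_rows <- list()
    contigs <- character(0L)
    if (cfg$make_contigs) for (l in locus_ids) {
      for (tx in present[[l]]) {
        chars <- tipseqs[[l]][[tx]]
        n <- length(chars)
        has_intron <- runif(1L) < cfg$intron_rate && n >= 9L
        istart <- NA_integer_; iend <- NA_integer_
        if (has_intron) {
          ilr <- cfg$intron_length_range
          ilen_choices <- seq(ilr[1L], ilr[2L])
          ilen <- max(8L, ilen_choices[sample.int(length(ilen_choices), 1L)])
          pos <- 3L * sample.int(n %/% 3L - 1L, 1L)  # codon boundary, 0-based
          intron <- c("G", "T", rand_dna(ilen - 4L), "A", "G")
          chars <- c(chars[seq_len(pos)], intron, chars[(pos + 1L):n])
          istart <- pos; iend <- pos + ilen
        }
        seq <- paste(chars, collapse = "")
        strand <- if (runif(1L) < 0.5) "+" else "-"
        clen <- nchar(seq)
        if (strand == "-") {
          seq <- revcomp(seq)
          if (has_intron) {
            tmp <- clen - iend; iend <- clen - istart; istart <- tmp
          }
        }
        cid <- paste0(tx, "@", l)
        contigs[[cid]] <- seq
        contig_rows[[length(contig_rows) + 1L]] <-
          data.frame(contig_id = cid, taxon = tx, locus = l, strand = strand,
                     has_intron = has_intron, intron_start = istart,
                     intron_end = iend, stringsAsFactors = FALSE)
      }
    }
    claimed <- if (length(contig_rows))
      setNames(vapply(contig_rows, function(r) r$locus, character(1L)),
               vapply(contig_rows, function(r) r$contig_id, character(1L)))
    else setNames(character(0L), character(0L))
    for (i in seq_along(par_contigs)) {
      cid <- names(par_contigs)[i]
      contigs[[cid]] <- par_contigs[[cid]]
      claimed[[cid]] <- paralog_truth[[i]]$claimed_locus
    }

    # paired reads with planted prefix duplicates
    rl <- cfg$read_length
    p_ids <- character(0L); m1 <- character(0L); m2 <- character(0L)
    # near-identical contigs (sister taxa, contaminants) can yield reads
    # with coinciding prefixes; re-draw such starts so the only prefix
    # duplicates in the output are the planted ones
    seen <- new.env(parent = emptyenv())
    if (cfg$make_reads) for (cid in names(contigs)) {
      s <- contigs[[cid]]
      n <- nchar(s)
      flen <- min(n, max(rl, 250L))
      cand <- if (n > flen) sample.int(n - flen + 1L) else 1L
      made <- 0L
      for (start in cand) {
        if (made >= cfg$pairs_per_contig) break
        frag <- substr(s, start, start + flen - 1L)
        mm1 <- substr(frag, 1L, min(rl, nchar(frag)))
        mm2 <- revcomp(substr(frag, max(1L, nchar(frag) - rl + 1L),
                              nchar(frag)))
        key <- paste(substr(mm1, 1L, 20L), substr(mm2, 1L, 20L))
        if (isTRUE(get0(key, envir = seen, ifnotfound = FALSE))) next
        assign(key, TRUE, envir = seen)
        made <- made + 1L
        p_ids <- c(p_ids, paste0(cid, "/", made))
        m1 <- c(m1, mm1); m2 <- c(m2, mm2)
      }
    }
    n_unique <- length(p_ids)
    n_dup <- round(cfg$dup_read_fraction * n_unique)
    dup_truth <- NULL
    if (n_dup > 0L) {
      src <- sample.int(n_unique, n_dup, replace = TRUE)
      dup_ids <- paste0(p_ids[src], ".dup", seq_len(n_dup))
      dup_truth <- data.frame(id = dup_ids, dup_of = p_ids[src],
                              stringsAsFactors = FALSE)
      # tails beyond the compared prefix may differ; only prefixes repeat
      dm1 <- vapply(m1[src], function(x) {
        if (nchar(x) > 25L) {
          i <- sample(26L:nchar(x), 1L)
          substr(x, i, i) <- sample(c("A", "C", "G", "T"), 1L)
        }
        x
      }, character(1L))
      p_ids <- c(p_ids, dup_ids); m1 <- c(m1, unname(dm1)); m2 <- c(m2, m2[src])
    }
    ord <- sample.int(length(p_ids))
    pairs <- read_pairs(p_ids[ord], m1[ord], m2[ord])
    prefix_key <- paste(substr(pairs$mate1, 1L, 20L),
                        substr(pairs$mate2, 1L, 20L))
    truth <- list(
      contigs = if (length(contig_rows)) do.call(rbind, contig_rows)
                else data.frame(contig_id = character(0L),
                                taxon = character(0L), locus = character(0L),
                                strand = character(0L),
                                has_intron = logical(0L),
                                intron_start = integer(0L),
                                intron_end = integer(0L)),
      paralogs = if (length(paralog_truth)) do.call(rbind, paralog_truth)
                 else data.frame(contig_id = character(0L),
                                 claimed_locus = character(0L),
                                 source_locus = character(0L)),
      contamination = if (length(contam_truth)) do.call(rbind, contam_truth)
                      else data.frame(locus = character(0L),
                                      donor = character(0L),
                                      recipient = character(0L)),
      read_dups = if (is.null(dup_truth))
        data.frame(id = character(0L), dup_of = character(0L)) else dup_truth,
      n_unique_pairs = n_unique,
      expected_kept_pairs = length(unique(prefix_key)),
      rates = setNames(rates, locus_ids),
      present = present)

    refs_str <- vapply(refs, paste, character(1L), collapse = "")
    out <- list(tree = tree, groups = groups, refs = refs_str, loci = loci,
                contigs = contigs, claimed = claimed, pairs = pairs,
                truth = truth, config = cfg, files = NULL)
    if (!is.null(out_dir)) out$files <- write_sim_dataset(out, out_dir)
    out
  })
}

write_sim_dataset <- function(sim, out_dir) {
  dir.create(file.path(out_dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  f <- list()
  f$baits <- file.path(out_dir, "baits.fasta")
  write_fasta(sim$refs, f$baits)
  f$contigs <- file.path(out_dir, "contigs.fasta")
  write_fasta(sim$contigs, f$contigs)
  f$loci <- vapply(sim$loci, function(a) {
    p <- file.path(out_dir, "loci", paste0(a$locus_id, ".fasta"))
    write_fasta(a$rows, p)
    p
  }, character(1L))
  f$groups <- file.path(out_dir, "groups.tsv")
  write_taxon_groups(sim$groups, f$groups)
  f$tree <- file.path(out_dir, "tree.nwk")
  write_newick(sim$tree, f$tree)
  f$r1 <- file.path(out_dir, "reads_1.fastq")
  f$r2 <- file.path(out_dir, "reads_2.fastq")
  write_fastq <- function(ids, seqs, path) {
    qual <- strrep("I", nchar(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  }
  write_fastq(sim$pairs$id, sim$pairs$mate1, f$r1)
  write_fastq(sim$pairs$id, sim$pairs$mate2, f$r2)
  f$bins <- file.path(out_dir, "truth", "claimed_bins.tsv")
  utils::write.table(data.frame(contig_id = names(sim$claimed),
                                locus = unname(sim$claimed)),
                     f$bins, sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("contigs", "paralogs", "contamination", "read_dups")) {
    p <- file.path(out_dir, "truth", paste0(nm, ".tsv"))
    utils::write.table(sim$truth[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f[[paste0("truth_", nm)]] <- p
  }
  f
}
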