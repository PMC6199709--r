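test_that("identical rows give treelikeness zero", {
  rows <- setNames(rep(strrep("ACGT", 25), 6), paste0("t", 1:6))
  sc <- treelikeness(locus_alignment("flat", rows))
  expect_equal(sc$treelikeness, 0)
  expect_equal(sc$n_quartets_evaluated, choose(6, 4))
})

strong_tree <- ape::read.tree(
  text = "((a:0.3,b:0.3):0.25,(c:0.3,d:0.3):0.25,(e:0.5,f:0.5):0.2);")

test_that("on-tree loci score high, randomized columns lower", {
  aln <- sim_locus_on_tree(strong_tree, 500, 0.25, rng_seed = 43)
  on_tree <- treelikeness(aln)$treelikeness
  expect_equal(on_tree, 1.0)

  # shuffle every column independently: destroys covariation
  set.seed(99)
  m <- do.call(rbind, strsplit(unname(aln$rows), ""))
  for (j in seq_len(ncol(m))) m[, j] <- m[sample.int(nrow(m)), j]
  shuf <- locus_alignment("shuf", setNames(apply(m, 1, paste, collapse = ""),
                                           names(aln$rows)))
  expect_lt(treelikeness(shuf)$treelikeness, on_tree)
})

test_that("treelikeness equals the exhaustive quartet oracle", {
  set.seed(47)
  sim <- simulate_dataset(sim_config(n_taxa = 8, n_loci = 3,
                                     missing_taxon_fraction = 0.2,
                                     paralog_count = 0, make_contigs = FALSE,
                                     rng_seed = 53))
  for (aln in sim$loci) {
    D <- capcure:::pdist_matrix(aln)$d
    expect_equal(treelikeness(aln)$treelikeness, oracle_treelikeness(D))
  }
})

test_that("treelikeness is invariant under row reordering", {
  sim <- simulate_dataset(sim_config(n_taxa = 7, n_loci = 1,
                                     missing_taxon_fraction = 0,
                                     paralog_count = 0, make_contigs = FALSE,
                                     rng_seed = 59))
  aln <- sim$loci[[1]]
  perm <- locus_alignment("perm", aln$rows[rev(names(aln$rows))])
  expect_equal(treelikeness(aln)$treelikeness,
               treelikeness(perm)$treelikeness)
  expect_error(treelikeness(toy_aln("s", a = "AC", b = "AC", c = "AC")),
               "fewer than 4")
})

test_that("quartet subsampling is seeded and capped", {
  sim <- simulate_dataset(sim_config(n_taxa = 12, n_loci = 1,
                                     missing_taxon_fraction = 0,
                                     paralog_count = 0, make_contigs = FALSE,
                                     rng_seed = 61))
  aln <- sim$loci[[1]]
  prm <- treelikeness_params(max_quartets = 100, rng_seed = 5)
  s1 <- treelikeness(aln, prm)
  s2 <- treelikeness(aln, prm)
  expect_identical(s1, s2)
  expect_lte(s1$n_quartets_evaluated, 100)
})

test_that("minimum-taxon filter uses effective (non-blank) rows", {
  l3 <- toy_aln("three", a = "ACGT", b = "ACGT", c = "ACGT")
  l4 <- toy_aln("four", a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT")
  l5g <- toy_aln("ghosts", a = "ACGT", b = "ACGT", c = "ACGT",
                 d = "----", e = "NN--")
  out <- filter_min_taxa(list(l3, l4, l5g))
  expect_equal(vapply(out$kept, function(a) a$locus_id, ""), "four")
  expect_setequal(vapply(out$excluded, function(a) a$locus_id, ""),
                  c("three", "ghosts"))
  # idempotence
  again <- filter_min_taxa(out$kept)
  expect_equal(length(again$kept), 1)
  expect_equal(length(again$excluded), 0)
})

test_that("selection ranks by composite score with deterministic ties", {
  scores <- data.frame(
    locus_id = c("lB", "lA", "lC"),
    n_taxa = c(10, 5, 5),
    treelikeness = c(0.9, 0.9, 0.9))
  sel <- select_informative(scores, total_taxa = 10, n_target = 1)
  expect_equal(sel$locus_id, "lB")  # full coverage dominates

  # equal composite: lexicographically smaller id first
  tie <- data.frame(locus_id = c("lZ", "lA"), n_taxa = c(8, 8),
                    treelikeness = c(0.5, 0.5))
  expect_equal(select_informative(tie, 8, 2)$locus_id, c("lA", "lZ"))

  expect_error(select_informative(scores, 10, 0), "positive")
  expect_error(select_informative(scores, 10, 4), "exceeds")
})

test_that("selection prefers on-tree loci over noise loci", {
  sim <- simulate_dataset(sim_config(n_taxa = 8, n_loci = 16,
                                     locus_length_range = c(600, 600),
                                     missing_taxon_fraction = 0,
                                     paralog_count = 0, make_contigs = FALSE,
                                     rng_seed = 67))
  loci <- sim$loci
  set.seed(101)
  noise <- lapply(1:4, function(i) {
    a <- loci[[i]]
    m <- do.call(rbind, strsplit(unname(a$rows), ""))
    for (j in seq_len(ncol(m))) m[, j] <- m[sample.int(nrow(m)), j]
    locus_alignment(paste0("noise", i),
                    setNames(apply(m, 1, paste, collapse = ""),
                             names(a$rows)))
  })
  pool <- c(loci, noise)
  scores <- score_loci(pool)
  sel <- select_informative(scores, 8, 16)
  expect_gte(sum(grepl("^locus", sel$locus_id)), 15)
})
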