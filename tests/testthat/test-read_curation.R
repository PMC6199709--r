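mk_pair <- function(id, m1, m2) read_pairs(id, m1, m2)

test_that("deduplication follows the both-mate prefix rule", {
  pre1 <- strrep("AC", 10); pre2 <- strrep("GT", 10)
  pairs <- mk_pair(c("p1", "p2", "p3"),
                   c(paste0(pre1, "AAAA"), paste0(pre1, "CCCC"),
                     paste0(pre1, "GGGG")),
                   c(paste0(pre2, "TTTT"), paste0(pre2, "AAAA"),
                     paste0(strrep("TT", 10), "AAAA")))
  out <- deduplicate_pairs(pairs)
  # p2 duplicates p1 on both prefixes; p3 differs on mate2
  expect_equal(out$kept$id, c("p1", "p3"))
  expect_equal(out$removed$id, "p2")

  # short mates are never removed
  short <- mk_pair(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"),
                   c("TTTTTTTTTT", "TTTTTTTTTT"))
  expect_equal(nrow(deduplicate_pairs(short)$removed), 0)
})

test_that("dedup matches brute-force prefix comparison on simulated reads", {
  sim <- simulate_dataset(sim_config(n_taxa = 8, n_loci = 6,
                                     dup_read_fraction = 0.2,
                                     paralog_count = 0, rng_seed = 21))
  out <- deduplicate_pairs(sim$pairs)
  # oracle: first-kept scan with quadratic prefix comparison
  kept_oracle <- character(0)
  keys <- character(0)
  for (i in seq_len(nrow(sim$pairs))) {
    k <- paste(substr(sim$pairs$mate1[i], 1, 20),
               substr(sim$pairs$mate2[i], 1, 20))
    if (!k %in% keys) {
      keys <- c(keys, k)
      kept_oracle <- c(kept_oracle, sim$pairs$id[i])
    }
  }
  expect_equal(out$kept$id, kept_oracle)
  expect_equal(nrow(out$kept), sim$truth$expected_kept_pairs)

  # idempotence and order stability
  again <- deduplicate_pairs(out$kept)
  expect_equal(again$kept, out$kept)
  expect_equal(nrow(again$removed), 0)
})

test_that("binning assigns exact substrings with score equal to length", {
  set.seed(5)
  baits <- setNames(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    character(1)), c("locA", "locB", "locC"))
  q <- substr(baits[["locB"]], 50, 149)  # 100 nt exact substring
  out <- assign_to_bins(c(q1 = q), baits, match_params(min_score = 50))
  expect_equal(out$scores$locus, "locB")
  expect_equal(out$scores$score, 100)

  # no seed hit: short alternating sequence absent from random baits
  out2 <- assign_to_bins(c(q2 = strrep("AT", 40)), baits)
  expect_equal(length(out2$unassigned), 1)

  expect_error(assign_to_bins(c(q = "ACGT"), character(0)), "empty bait")
})

test_that("binning is invariant under reverse complement", {
  sim <- simulate_dataset(sim_config(n_taxa = 6, n_loci = 5,
                                     paralog_count = 0, make_reads = FALSE,
                                     rng_seed = 31))
  idx <- build_bait_index(sim$refs, match_params())
  cids <- names(sim$contigs)[1:5]
  for (cid in cids) {
    fwd <- assign_to_bins(sim$contigs[cid], idx)$scores
    rc <- setNames(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sim$contigs[[cid]]))), cid)
    rev <- assign_to_bins(rc, idx)$scores
    expect_equal(fwd$locus, rev$locus)
    expect_equal(fwd$score, rev$score)
  }
})

test_that("synthetic contigs all bin to their source locus", {
  sim <- simulate_dataset(sim_config(n_taxa = 10, n_loci = 20,
                                     paralog_count = 0, make_reads = FALSE,
                                     rng_seed = 41))
  out <- assign_to_bins(sim$contigs, sim$refs)
  expect_equal(length(out$unassigned), 0)
  got <- setNames(out$scores$locus, out$scores$seq_id)
  expect_equal(got[names(sim$claimed)], sim$claimed)

  # matcher agrees with the exhaustive-diagonal oracle on a subsample
  idx <- build_bait_index(sim$refs, match_params())
  for (cid in names(sim$contigs)[seq(1, length(sim$contigs), by = 19)]) {
    sc <- capcure:::per_locus_scores(sim$contigs[[cid]], idx)
    loc <- sc$locus[1]
    expect_equal(sc$score[1],
                 oracle_ungapped_score(sim$contigs[[cid]], sim$refs[[loc]]),
                 info = cid)
  }
})
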