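test_that("p_distance counts comparable sites correctly", {
  aln <- toy_aln("l", a = "ACGT", b = "ACGT", c = "ACGA", d = "AC--",
                 e = "--GT", f = "ACNT")
  expect_equal(p_distance(aln, "a", "b"), list(distance = 0, n_comparable = 4))
  expect_equal(p_distance(aln, "a", "c"),
               list(distance = 0.25, n_comparable = 4))
  expect_equal(p_distance(aln, "d", "e"),
               list(distance = NA_real_, n_comparable = 0))
  # N never counts as comparable
  expect_equal(p_distance(aln, "a", "f")$n_comparable, 3)
  expect_error(p_distance(aln, "a", "zz"), "absent")
})

test_that("p_distance is symmetric and matches the loop oracle", {
  set.seed(23)
  chars <- c("A", "C", "G", "T", "-", "N", "?")
  for (i in 1:20) {
    ra <- paste(sample(chars, 60, TRUE, prob = c(rep(0.2, 4), rep(0.066, 3))),
                collapse = "")
    rb <- paste(sample(chars, 60, TRUE, prob = c(rep(0.2, 4), rep(0.066, 3))),
                collapse = "")
    aln <- toy_aln("l", a = ra, b = rb)
    ab <- p_distance(aln, "a", "b")
    ba <- p_distance(aln, "b", "a")
    orc <- oracle_pdist(ra, rb)
    expect_equal(ab, ba)
    expect_equal(ab$distance, orc$d)
    expect_equal(ab$n_comparable, orc$n)
  }
})

make_screen_fixture <- function(n_loci = 100, n_flagged = 3, seed = 29) {
  # two groups of two; taxa a1/a2 vs b1/b2; b1 carries a1's sequence
  # (contamination) at n_flagged loci
  set.seed(seed)
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    base <- sample(c("A", "C", "G", "T"), 200, TRUE)
    perturb <- function(p) {
      x <- base
      hit <- which(runif(200) < p)
      x[hit] <- vapply(x[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(x, collapse = "")
    }
    rows <- c(a1 = perturb(0.01), a2 = perturb(0.02),
              b1 = perturb(0.10), b2 = perturb(0.12))
    if (i <= n_flagged) rows[["b1"]] <- rows[["a1"]]
    loci[[i]] <- locus_alignment(sprintf("L%03d", i), rows)
  }
  list(loci = loci,
       groups = taxon_groups(c(a1 = "gA", a2 = "gA", b1 = "gB", b2 = "gB")))
}

test_that("the screen reports per-pair percentages as specified", {
  fx <- make_screen_fixture(100, 3)
  rep <- screen_cross_contamination(fx$loci, fx$groups)
  pp <- rep$per_pair
  row <- pp[pp$taxon_a == "a1" & pp$taxon_b == "b1", ]
  expect_equal(row$n_evaluable, 100)
  expect_equal(row$n_flagged, 3)
  expect_equal(row$percentage, 3.0)
  expect_false(row$alarm)  # below the 5% default alarm
  # only inter-group pairs are tested: 2x2 = 4 pairs
  expect_equal(nrow(pp), 4)
  expect_equal(nrow(rep$flagged_loci), 3)

  # brute-force recount of the flagged pair
  n_flag_oracle <- sum(vapply(fx$loci, function(a) {
    o <- oracle_pdist(a$rows[["a1"]], a$rows[["b1"]])
    !is.na(o$d) && o$d <= 0.002
  }, logical(1)))
  expect_equal(row$n_flagged, n_flag_oracle)
})

test_that("clean data yields zero percentages and one group errors", {
  fx <- make_screen_fixture(50, 0)
  rep <- screen_cross_contamination(fx$loci, fx$groups)
  expect_equal(rep$max_percentage, 0)
  expect_equal(nrow(rep$flagged_loci), 0)

  one <- taxon_groups(c(a1 = "g", a2 = "g", b1 = "g", b2 = "g"))
  expect_error(screen_cross_contamination(fx$loci, one), "no distant pairs")
})

test_that("raising the threshold never lowers flag counts", {
  fx <- make_screen_fixture(60, 2, seed = 31)
  flags <- vapply(c(0.001, 0.002, 0.01, 0.05, 0.2), function(th) {
    sum(screen_cross_contamination(fx$loci, fx$groups,
                                   screen_params(p_threshold = th))
        $per_pair$n_flagged)
  }, numeric(1))
  expect_true(all(diff(flags) >= 0))
})

test_that("report is invariant under locus reordering", {
  fx <- make_screen_fixture(40, 2, seed = 37)
  r1 <- screen_cross_contamination(fx$loci, fx$groups)
  r2 <- screen_cross_contamination(rev(fx$loci), fx$groups)
  expect_equal(r1$per_pair, r2$per_pair)
  expect_equal(r1$max_percentage, r2$max_percentage)
})

test_that("planted contamination in the simulator is recovered", {
  cfg0 <- sim_config(n_taxa = 12, n_loci = 50, paralog_count = 0,
                     make_contigs = FALSE, rng_seed = 7)
  g <- sim_taxon_groups(cfg0)$groups$assignment
  donor <- names(g)[g == "g1"][1]; recip <- names(g)[g == "g2"][1]
  cfg <- sim_config(n_taxa = 12, n_loci = 50, paralog_count = 0,
                    make_contigs = FALSE, rng_seed = 7,
                    contamination_events = list(
                      list(donor = donor, recipient = recip,
                           fraction = 0.08, residual_noise = 0)))
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$contamination), 4)  # round(0.08 * 50)
  rep <- screen_cross_contamination(sim$loci, sim$groups)
  pp <- rep$per_pair
  sel <- pp$taxon_a %in% c(donor, recip) & pp$taxon_b %in% c(donor, recip)
  expect_equal(pp$n_flagged[sel], 4)
  expect_true(pp$alarm[sel])
  expect_equal(sum(pp$alarm[!sel]), 0)
})
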