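nwk <- function(s) ape::read.tree(text = s)

splits_plain <- function(tr) {
  b <- bipartitions(tr)
  attributes(b) <- NULL
  b
}

test_that("bipartitions enumerate nontrivial splits canonically", {
  expect_equal(splits_plain(nwk("((a,b),(c,d));")), list(c("a", "b")))
  expect_length(bipartitions(nwk("(((a,b),c),(d,e));")), 2)
  expect_length(bipartitions(nwk("(a,b,c,d,e);")), 0)
  expect_length(bipartitions(nwk("((a,b),c);")), 0)
  # canonical side contains the smallest label
  bp <- bipartitions(nwk("((c,d),(a,b),(e,f));"))
  expect_true(all(vapply(bp, function(s) "a" %in% s, logical(1))))
})

test_that("IC matches its closed forms", {
  ref <- nwk("((a,b),(c,d),e);")
  g_sup <- nwk("((a,b),(c,d),e);")
  g_con <- nwk("((a,c),(b,d),e);")

  # universal support, no conflictor
  res <- internode_certainty(ref, rep(list(g_sup), 100))
  expect_equal(res$per_branch$ic, rep(1, 2))
  expect_equal(res$per_branch$ica, rep(1, 2))

  # 50/50: maximal conflict
  res50 <- internode_certainty(ref, c(rep(list(g_sup), 50),
                                      rep(list(g_con), 50)))
  expect_equal(res50$per_branch$ic, rep(0, 2), tolerance = 1e-12)

  # 70/30 and the sign flip at 30/70
  ic_expected <- 1 + 0.7 * log2(0.7) + 0.3 * log2(0.3)
  res73 <- internode_certainty(ref, c(rep(list(g_sup), 70),
                                      rep(list(g_con), 30)))
  expect_equal(res73$per_branch$ic, rep(ic_expected, 2), tolerance = 1e-12)
  res37 <- internode_certainty(ref, c(rep(list(g_sup), 30),
                                      rep(list(g_con), 70)))
  expect_equal(res37$per_branch$ic, rep(-ic_expected, 2), tolerance = 1e-12)

  # TC is the sum of per-branch IC
  expect_equal(res73$tc, sum(res73$per_branch$ic))
  expect_equal(res73$relative_tc, res73$tc / res73$n_internal_branches)
})

test_that("IC equals ICA when a single conflictor is observed", {
  ref <- nwk("((a,b),(c,d));")
  g_sup <- nwk("((a,b),(c,d));")
  g_con <- nwk("((a,c),(b,d));")
  res <- internode_certainty(ref, c(rep(list(g_sup), 7), rep(list(g_con), 3)))
  expect_equal(res$per_branch$ic, res$per_branch$ica)
})

test_that("partial gene trees use the evaluable-tree adjustment", {
  ref <- nwk("(((a,b),c),(d,e));")
  # this tree lacks 'b': split ab|cde restricts to a|cde -> trivial
  g_partial <- nwk("((a,c),(d,e));")
  g_full <- nwk("(((a,b),c),(d,e));")
  res <- internode_certainty(ref, c(rep(list(g_full), 4),
                                    rep(list(g_partial), 6)))
  pb <- res$per_branch
  ab <- pb[pb$branch == "a,b", ]
  expect_equal(ab$n_evaluable_trees, 4)
  expect_equal(ab$support_freq, 1)
  abc <- pb[pb$branch == "a,b,c", ]
  expect_equal(abc$n_evaluable_trees, 10)

  expect_error(internode_certainty(ref, list(nwk("((a,zz),(c,d));"))),
               "outside the reference: zz")
})

test_that("IC/ICA agree with the naive recount oracle on random sets", {
  skip_if_not_installed("phangorn")
  set.seed(83)
  for (rep_i in 1:25) {
    ref <- ape::rtree(8)
    gts <- lapply(1:8, function(i) ape::rtree(8))
    res <- internode_certainty(ref, gts)
    orc <- oracle_certainty(ref, gts)
    expect_equal(sort(res$per_branch$ic), sort(orc$ic), tolerance = 1e-12)
    expect_equal(res$tc, orc$tc, tolerance = 1e-12)
  }
})

test_that("results are invariant under gene-tree order", {
  set.seed(89)
  ref <- ape::rtree(8)
  gts <- lapply(1:10, function(i) ape::rtree(8))
  r1 <- internode_certainty(ref, gts)
  r2 <- internode_certainty(ref, rev(gts))
  expect_equal(r1$per_branch, r2$per_branch)
})

test_that("annotate_ic places ic/ica labels on matching nodes", {
  ref <- nwk("((a,b),(c,d),e);")
  res <- internode_certainty(ref, rep(list(nwk("((a,b),(c,d),e);")), 5))
  ann <- annotate_ic(ref, res)
  expect_true(any(ann$node.label == "1.000/1.000"))
})

test_that("neighbor joining recovers additive and ultrametric trees", {
  set.seed(97)
  tr <- ape::rtree(5)
  d <- ape::cophenetic.phylo(tr)  # additive by construction
  expect_equal(ape::dist.topo(ape::unroot(tr), nj_tree(d)), 0,
               ignore_attr = TRUE)

  # ultrametric 4-taxon: cherries (a,b) and (c,d)
  dm <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 4,
                 8, 8, 4, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  njt <- nj_tree(dm)
  expect_equal(splits_plain(njt), list(c("a", "b")))

  expect_error(nj_tree(dm[1:3, 1:3]), ">= 4")
  dm_na <- dm; dm_na[1, 2] <- dm_na[2, 1] <- NA
  expect_error(nj_tree(dm_na), "undefined")
})
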