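test_that("pairwise distances match closed forms", {
  a <- paste(rep("A", 100), collapse = "")
  expect_equal(pairwise_distance(a, a, "p"), 0)
  expect_equal(pairwise_distance(a, a, "poisson"), 0)
  expect_equal(pairwise_distance(a, a, "gamma", alpha = 0.5), 0)

  b <- paste0(paste(rep("C", 10), collapse = ""),
              paste(rep("A", 90), collapse = ""))
  expect_equal(pairwise_distance(a, b, "p"), 0.1)
  expect_equal(pairwise_distance(a, b, "poisson"), -log(0.9))
  expect_equal(pairwise_distance(a, b, "gamma", alpha = 1), 1 / 0.9 - 1)
})

test_that("gap and unknown columns are excluded pairwise", {
  # 2 of 10 columns unusable; 1 mismatch over 8 usable
  a <- "AC-DEFGHXK"
  b <- "ACMDEFGHIK"
  a2 <- "ACWDEFGHIK"
  expect_equal(pairwise_distance(a, b, "p"), 0)
  expect_equal(pairwise_distance(a2, b, "p"), 1 / 10)
  expect_error(pairwise_distance("--", "AA", "p"), "usable")
})

test_that("saturated distances error under corrected models", {
  a <- "AAAA"; b <- "CCCC"
  expect_equal(pairwise_distance(a, b, "p"), 1)
  expect_error(pairwise_distance(a, b, "poisson"), "saturated")
  expect_error(pairwise_distance(a, b, "gamma"), "saturated")
})

test_that("corrections order as p <= poisson <= divergent gamma, and gamma -> poisson", {
  withr::with_seed(11, {
    for (k in 1:20) {
      a <- random_seq(200); b <- random_seq(200)
      p <- pairwise_distance(a, b, "p")
      if (p >= 1) next
      pois <- pairwise_distance(a, b, "poisson")
      gam <- pairwise_distance(a, b, "gamma", alpha = 0.8)
      expect_gte(pois, p)
      expect_gte(gam, pois)  # smaller alpha inflates the correction
    }
    # gamma -> poisson as alpha -> infinity; the residual term is
    # ln^2(1-p)/(2 alpha), so check at moderate divergence
    for (k in 1:10) {
      a <- random_seq(300)
      b <- a
      for (i in sample(300, 60)) substr(b, i, i) <- "W"
      pois <- pairwise_distance(a, b, "poisson")
      expect_lt(abs(pairwise_distance(a, b, "gamma", alpha = 1e6) - pois),
                1e-6)
    }
  })
})

test_that("neighbor joining validates input and recovers 3-taxon closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D)
  # three-point formulas: la = (dab + dac - dbc)/2, etc.
  pat <- ape::cophenetic.phylo(tr)
  expect_equal(pat[letters[1:3], letters[1:3]], D)
  tip_len <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(tip_len[1], (3 + 4 - 5) / 2)
  expect_equal(tip_len[2], (3 + 5 - 4) / 2)
  expect_equal(tip_len[3], (4 + 5 - 3) / 2)

  expect_error(neighbor_joining(D[1:2, 1:2]), "3 taxa")
  Dg <- D; Dg[1, 2] <- 99
  expect_error(neighbor_joining(Dg), "symmetric")
})

test_that("NJ reproduces random additive trees exactly", {
  withr::with_seed(13, {
    for (k in 1:50) {
      tr <- random_branch_tree(sample(6:10, 1))
      D <- ape::cophenetic.phylo(tr)
      rec <- neighbor_joining(D)
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
                   ignore_attr = TRUE)
      expect_equal(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)], D,
                   tolerance = 1e-8)
    }
  })
})

test_that("midpoint rooting of an ultrametric matrix is clocklike", {
  tr <- two_clade_tree(100)
  D <- ape::cophenetic.phylo(tr)
  rec <- neighbor_joining(D)
  rooted <- root_by_outgroup(rec, paste0("A", 1:4))
  depth <- ape::node.depth.edgelength(rooted)[1:8]
  expect_equal(unname(depth), rep(100, 8), tolerance = 1e-8)
})

test_that("bootstrap supports are deterministic and saturate on clean clades", {
  # two clearly distinct clades: identical within, very different between
  blockA <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  blockB <- paste(rep("MNPQRSTVWY", 10), collapse = "")
  aln <- c(a1 = blockA, a2 = blockA, b1 = blockB, b2 = blockB)
  # perturb one residue per taxon so distances are not all exactly equal
  substr(aln[["a2"]], 1, 1) <- "C"; substr(aln[["b2"]], 1, 1) <- "N"
  tr <- bootstrap_support(aln, model = "p", B = 50, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  tr1 <- bootstrap_support(aln, model = "p", B = 1, seed = 9)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  again <- bootstrap_support(aln, model = "p", B = 50, seed = 3)
  expect_identical(tr$node.label, again$node.label)
})

test_that("bootstrap supports survive taxon-order permutation", {
  aln <- evolve_alignment(two_clade_tree(400), rate = 8e-4, sites = 300,
                          seed = 21)$alignment
  t1 <- bootstrap_support(aln, B = 30, seed = 5)
  t2 <- bootstrap_support(aln[c(5:8, 1:4)], B = 30, seed = 5)
  # same seed, same column-resample mapping: supports of the shared
  # bipartitions agree
  key <- function(tr) {
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    sets <- vapply(parts, function(p)
      paste(sort(labs[p]), collapse = "|"), character(1))
    setNames(tr$node.label, sets)
  }
  k1 <- key(t1); k2 <- key(t2)
  shared <- intersect(names(k1), names(k2))
  expect_gt(length(shared), 0)
  expect_identical(k1[shared], k2[shared])
})

test_that("outgroup rooting preserves patristic distances and checks monophyly", {
  tr <- ape::unroot(ape::read.tree(
    text = "((A:1,B:2):0.5,(C:1.5,D:0.5):1,E:3);"))
  rooted <- root_by_outgroup(tr, c("C", "D"))
  expect_true(ape::is.rooted(rooted))
  expect_equal(ape::cophenetic.phylo(rooted)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-10)
  # single-tip outgroup: rooted on its pendant branch
  r1 <- root_by_outgroup(tr, "E")
  expect_true(ape::is.rooted(r1))
  expect_error(root_by_outgroup(tr, c("A", "C")), "not monophyletic")
  expect_error(root_by_outgroup(tr, c("A", "Z")), "not in tree")
})
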