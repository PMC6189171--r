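test_that("scan_sequence finds constructed minimal and Moesin-like matches", {
  h <- scan_sequence("YAALGGGGGGYAAI")
  expect_equal(h$start, 1L)
  expect_equal(h$spacer, 6L)
  expect_equal(h$end, 14L)
  expect_equal(h$matched_seq, "YAALGGGGGGYAAI")

  # two-tyrosine arrangement at residues 191/205 in a 210-mer: one hit,
  # 10-residue spacer
  s <- paste(rep("A", 210), collapse = "")
  substr(s, 191, 191) <- "Y"; substr(s, 194, 194) <- "L"
  substr(s, 205, 205) <- "Y"; substr(s, 208, 208) <- "I"
  h <- scan_sequence(s)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 191L)
  expect_equal(h$spacer, 10L)
  expect_equal(h$end, 208L)
})

test_that("unknown symbols may fill spacers but never anchors or tails", {
  expect_equal(nrow(scan_sequence("YAALXXXXXXYAAI")), 1L)  # X in spacer ok
  expect_equal(nrow(scan_sequence("XAALGGGGGGYAAI")), 0L)  # anchor1
  expect_equal(nrow(scan_sequence("YAAXGGGGGGYAAI")), 0L)  # tail1
  expect_equal(nrow(scan_sequence("YAALGGGGGGXAAI")), 0L)  # anchor2
  expect_equal(nrow(scan_sequence("YAALGGGGGGYAAX")), 0L)  # tail2
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  withr::with_seed(41, {
    for (k in 1:200) {
      s <- random_seq(300)
      got <- scan_sequence(s)[, c("start", "spacer")]
      want <- brute_force_scan(s)
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
    }
  })
})

test_that("match geometry invariants hold on random hits", {
  withr::with_seed(42, {
    hits <- do.call(rbind, lapply(1:100, function(i) {
      s <- random_seq(250)
      h <- scan_sequence(s)
      if (nrow(h) == 0L) NULL else cbind(h, len = nchar(s))
    }))
  })
  expect_gt(nrow(hits), 0)
  span <- hits$end - hits$start + 1L
  expect_true(all(span >= 14L & span <= 20L))
  expect_true(all(hits$end <= hits$len))
  expect_true(all(substr(hits$matched_seq, 1, 1) == "Y"))
})

test_that("decoy hit rate matches the analytic per-start probability", {
  # per (start, spacer): (1/20)(2/20)(1/20)(2/20); 7 spacers per start
  p_combo <- (1 / 20) * (2 / 20) * (1 / 20) * (2 / 20)
  n_seq <- 700L; len <- 1500L
  withr::with_seed(43, {
    n_hits <- sum(vapply(seq_len(n_seq),
                         function(i) nrow(scan_sequence(random_seq(len))),
                         numeric(1)))
  })
  n_combos <- n_seq * sum(pmax(0L, len - (7L + 6:12)))
  expect_gt(n_seq * len, 1e6)
  expected <- n_combos * p_combo
  se <- sqrt(n_combos * p_combo * (1 - p_combo))
  expect_lt(abs(n_hits - expected), 3 * se)
})

test_that("scan_proteome deduplicates to one row per protein", {
  # the two planted blocks sit 15 residues apart so no cross-block spacer
  # can reach from one half-site to the other
  prot <- c(one = "YAALGGGGGGYAAIAAAAAAAAAAAAAAAYAALGGGGGGYAAI",
            two = paste(rep("A", 40), collapse = ""),
            three = "AAAYAALGGGGGGYAAIAAA")
  tab <- scan_proteome(prot)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$hit_count[tab$protein_id == "one"], 2L)
  expect_equal(tab$hit_count[tab$protein_id == "three"], 1L)
  expect_error(scan_proteome(c(a = "AAAA", a = "CCCC")), "duplicate")
})

test_that("planted-motif proteomes are recovered exactly", {
  gp <- gen_proteome(n_planted = 20L, n_decoys = 120L, seed = 5L)
  tab <- scan_proteome(gp$sequences)
  planted <- grep("^PLT", names(gp$sequences), value = TRUE)
  expect_setequal(tab$protein_id, planted)        # sensitivity 1, no decoys
  expect_true(all(tab$hit_count == 1L))
  first <- tab[match(planted, tab$protein_id), ]
  expect_equal(first$first_start, gp$truth$params$start)
  expect_equal(first$first_spacer, gp$truth$params$spacer)
  # oracle confirms decoys are motif-free
  decoy_hits <- vapply(gp$sequences[grep("^DCY", names(gp$sequences))],
                       function(s) nrow(vector_scan(s)), numeric(1))
  expect_true(all(decoy_hits == 0))
})

test_that("rank_candidates aggregates percentile ranks as specified", {
  tab <- data.frame(protein_id = letters[1:4], gene = letters[1:4],
                    hit_count = 1L)
  up <- data.frame(gene = letters[1:4], abundance = c(1, 2, 3, 4))
  down <- data.frame(gene = letters[1:4], abundance = c(4, 3, 2, 1))

  one <- rank_candidates(tab, list(up), n_top = 2L)
  expect_equal(one$gene, c("d", "c", "b", "a"))   # abundance order
  expect_equal(one$top, c(TRUE, TRUE, FALSE, FALSE))

  # exactly reversed datasets: all aggregate scores equal, lexicographic
  both <- rank_candidates(tab, list(up, down))
  expect_true(all(both$score == both$score[1]))
  expect_equal(both$gene, letters[1:4])

  # hand-computed mean percentile ranks
  expect_equal(both$score[1], mean(c(1 / 4, 4 / 4)))

  # missing gene contributes rank 0
  partial <- data.frame(gene = c("a", "b"), abundance = c(5, 1))
  r <- rank_candidates(tab, list(partial))
  expect_equal(r$score[r$gene == "c"], 0)
  expect_equal(r$score[r$gene == "a"], 1)

  expect_error(rank_candidates(tab, list()), "non-empty")
})

test_that("ranking is invariant to row order and monotone rescaling", {
  withr::with_seed(7, {
    tab <- data.frame(protein_id = paste0("p", 1:12),
                      gene = paste0("g", sample(12)), hit_count = 1L)
    ds1 <- data.frame(gene = tab$gene, abundance = rexp(12))
    ds2 <- data.frame(gene = tab$gene, abundance = rexp(12))
  })
  base <- rank_candidates(tab, list(ds1, ds2), n_top = 5L)
  shuffled <- rank_candidates(tab[sample(12), ], list(ds1, ds2), n_top = 5L)
  expect_equal(shuffled$gene, base$gene)
  expect_equal(shuffled$score, base$score)
  ds1_scaled <- transform(ds1, abundance = abundance^3 * 100)
  rescaled <- rank_candidates(tab, list(ds1_scaled, ds2), n_top = 5L)
  expect_equal(rescaled$score, base$score)
})

test_that("exclusions keep the single highest-precedence reason", {
  tab <- data.frame(protein_id = letters[1:3], gene = letters[1:3],
                    hit_count = 1L)
  ann <- data.frame(gene = letters[1:3],
                    secreted = c(TRUE, FALSE, FALSE),
                    nuclear_only = c(TRUE, TRUE, FALSE))
  out <- apply_exclusions(tab, ann)
  expect_equal(out$reason, c("secreted", "nuclear_only", NA))
  # reversed precedence flips the doubly-failing row's reason
  out2 <- apply_exclusions(tab, ann, rules = c("nuclear_only", "secreted"))
  expect_equal(out2$reason, c("nuclear_only", "nuclear_only", NA))
  expect_equal(nrow(shortlist(out)), 1L)

  none <- apply_exclusions(tab, data.frame(gene = letters[1:3],
                                           secreted = FALSE))
  expect_equal(shortlist(none)$gene, tab$gene)    # identity when all pass
  expect_error(apply_exclusions(tab, ann, rules = "unheard_of"),
               "unknown exclusion rule")
})
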