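test_that("pairwise differences rescale to the locus under missing data", {
  a <- aln_from_strings(c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(pairwise_differences(a)[1, 2], 0)
  b <- aln_from_strings(c("ACGTACGTAC", "ACGTACGTTT"))
  expect_equal(pairwise_differences(b)[1, 2], 2)
  # 2 differences over 8 comparable sites of L = 10 -> 2.5
  c3 <- aln_from_strings(c("ACGTACGTNN", "ACGTACAAAC"))
  expect_equal(pairwise_differences(c3)[1, 2], 2 / 8 * 10)
})

test_that("AMOVA reproduces the brute-force decomposition and the
           boundary cases", {
  # all identical -> no variance, Phi undefined
  same <- aln_from_strings(rep("ACGTACGT", 6))
  d0 <- pairwise_differences(same)
  a0 <- amova(d0, rep(c("p1", "p2"), each = 3), n_perm = 10, seed = 1)
  expect_true(is.na(a0$phi["phi_st"]))

  # two populations each fixed for a distinct haplotype -> Phi_ST = 1
  fix <- aln_from_strings(c(rep("AAAAAAAA", 4), rep("TTTTAAAA", 4)))
  d1 <- pairwise_differences(fix)
  a1 <- amova(d1, rep(c("p1", "p2"), each = 4), n_perm = 99, seed = 2)
  expect_equal(unname(a1$phi["phi_st"]), 1)
  expect_lt(a1$p["phi_st"], 0.05)

  # toy two-population set against the explicit-formula oracle
  toy <- aln_from_strings(c("AAAA", "AAAT", "TTTA", "TTTT"))
  pops <- c("P1", "P1", "P2", "P2")
  d <- pairwise_differences(toy)
  am <- amova(d, pops, n_perm = 10, seed = 3)
  br <- brute_amova_1(d, pops)
  expect_equal(unname(am$ss["among_populations"]), br$ss_among)
  expect_equal(unname(am$ss["within_populations"]), br$ss_within)
  expect_equal(unname(am$sigma2["among_populations"]), br$sigma_a)
  expect_equal(unname(am$sigma2["within_populations"]), br$sigma_w)
  expect_equal(unname(am$phi["phi_st"]), br$phi_st)
})

test_that("AMOVA sums of squares are additive and match vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(19)
  for (rep in 1:5) {
    aln <- random_alignment(12, 30)
    pops <- sample(c("a", "b", "c"), 12, replace = TRUE)
    if (length(unique(pops)) < 2 || min(table(pops)) < 2) next
    d <- pairwise_differences(aln)
    am <- amova(d, pops, n_perm = 5, seed = rep)
    expect_equal(unname(am$ss["among_populations"] +
                          am$ss["within_populations"]),
                 unname(am$ss["total"]), tolerance = 1e-9)
    expect_equal(sum(am$df[c("among_populations", "within_populations")]),
                 nrow(d) - 1L)
    # adonis2 on sqrt(d) partitions the same squared distances
    ad <- vegan::adonis2(stats::as.dist(sqrt(d)) ~ pop,
                         data = data.frame(pop = pops), permutations = 2)
    expect_equal(unname(am$ss["among_populations"]), ad$SumOfSqs[1],
                 tolerance = 1e-8)
    expect_equal(unname(am$ss["within_populations"]), ad$SumOfSqs[2],
                 tolerance = 1e-8)
  }
})

test_that("hierarchical AMOVA decomposes three levels coherently", {
  set.seed(23)
  aln <- random_alignment(24, 40)
  pops <- rep(c("p1", "p2", "p3", "p4"), each = 6)
  groups <- c(p1 = "g1", p2 = "g1", p3 = "g2", p4 = "g2")
  d <- pairwise_differences(aln)
  am <- amova(d, pops, groups = groups, n_perm = 49, seed = 4)
  expect_equal(unname(am$ss["among_groups"] + am$ss["among_populations"] +
                        am$ss["within_populations"]),
               unname(am$ss["total"]), tolerance = 1e-9)
  expect_equal(unname(sum(am$df[c("among_groups", "among_populations",
                                  "within_populations")])), 23L)
  expect_named(am$phi, c("phi_ct", "phi_sc", "phi_st"))
  expect_true(all(am$p > 0 & am$p <= 1, na.rm = TRUE))
  # deterministic under the seed
  am2 <- amova(d, pops, groups = groups, n_perm = 49, seed = 4)
  expect_identical(am$p, am2$p)
})

test_that("the diversity permutation test is symmetric, add-one
           corrected, and detects an extreme contrast", {
  # A and B copies of the same multiset -> observed 0, p = 1
  aln <- aln_from_strings(c("ACGT", "ACGA", "ACGT", "ACGA"))
  r <- diversity_permutation_test(aln, c("s1", "s2"), c("s3", "s4"),
                                  n_perm = 200, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p, 1)

  # label-swap invariance
  set.seed(31)
  aln2 <- random_alignment(10, 25)
  ra <- diversity_permutation_test(aln2, paste0("s", 1:5), paste0("s", 6:10),
                                   n_perm = 500, seed = 9)
  rb <- diversity_permutation_test(aln2, paste0("s", 6:10), paste0("s", 1:5),
                                   n_perm = 500, seed = 9)
  expect_equal(ra$p, rb$p)
  expect_equal(ra$observed, rb$observed)

  # monomorphic vs maximally diverse toy set -> small p
  mono <- rep("AAAAAAAAAAAAAAAAAAAA", 4)
  div <- c("TTTTTAAAAAAAAAAAAAAA", "AAAAATTTTTAAAAAAAAAA",
           "AAAAAAAAAATTTTTAAAAA", "AAAAAAAAAAAAAAATTTTT")
  aln3 <- aln_from_strings(c(mono, div))
  r3 <- diversity_permutation_test(aln3, paste0("s", 1:4), paste0("s", 5:8),
                                   n_perm = 10000, seed = 2)
  expect_lte(r3$p, 0.05)

  expect_error(diversity_permutation_test(aln, c("s1", "s2"),
                                          c("s2", "s3"), seed = 1),
               "disjoint")
})

test_that("Fisher's exact test matches enumeration and base R", {
  expect_equal(fisher_exact(rbind(c(1, 1), c(1, 1)))$p, 1)
  expect_equal(fisher_exact(rbind(c(3, 0), c(0, 3)))$p, 0.1)
  set.seed(5)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)$p
    expect_equal(p, brute_fisher_2x2(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # Monte Carlo 2 x k tracks the exact criterion
  tab3 <- rbind(c(8, 2, 5), c(3, 7, 4))
  pmc <- fisher_exact(tab3, mc_draws = 2e5, seed = 11)$p
  expect_equal(pmc, stats::fisher.test(tab3)$p.value, tolerance = 0.02)
  expect_warning(fisher_exact(rbind(c(2, 0), c(3, 0))), "all-zero")
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), "row sums")
})

test_that("the bootstrap clade test is reproducible and directionally
           sound", {
  ids <- paste0("x", 1:40)
  clades <- stats::setNames(rep(c("I", "II"), 20), ids)
  era <- stats::setNames(rep(c("modern", "ancient"), c(32, 8)), ids)

  r1 <- clade_abundance_test(clades, era, n_boot = 50, seed = 7)
  r2 <- clade_abundance_test(clades, era, n_boot = 50, seed = 7)
  expect_identical(r1$p_values, r2$p_values)
  expect_equal(r1$subsample_size, 8L)

  # single clade -> every bootstrap table degenerate -> p = 1
  one <- clade_abundance_test(stats::setNames(rep("I", 40), ids), era,
                              n_boot = 20, seed = 1)
  expect_true(all(one$p_values == 1))

  # complete era/clade separation -> small p throughout
  sep <- stats::setNames(rep(c("I", "II"), c(32, 8)), ids)
  r3 <- clade_abundance_test(sep, era, n_boot = 100, seed = 3)
  expect_lte(r3$p_mean, 0.05)
})
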