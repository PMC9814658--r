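test_that("neighbor joining recovers additive and ultrametric trees", {
  # additive matrix constructed from a known 5-taxon tree
  true <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:0.5):2,e:3);")
  d <- ape::cophenetic.phylo(true)
  nj <- build_nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(true)), 0,
               ignore_attr = TRUE)
  # clear ultrametric pairs joined together
  d4 <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 2,
                 8, 8, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  nj4 <- build_nj_tree(d4)
  pairs <- ape::prop.part(nj4)
  expect_true(any(vapply(pairs, function(p)
    setequal(nj4$tip.label[p], c("a", "b")) ||
    setequal(nj4$tip.label[p], c("c", "d")), logical(1))))
  expect_warning(build_nj_tree(matrix(0, 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("a", "b")))),
                 "fewer than 3")
})

test_that("Fitch reconstruction matches hand examples and the exhaustive
           oracle", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  prof <- matrix(c("T", "T", "C", "C"), 4, 1,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(fitch_reconstruct(tr, prof)$score, 1L)

  same <- matrix("A", 4, 3, dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(fitch_reconstruct(tr, same)$score, 0L)

  expect_error(fitch_reconstruct(tr, prof[1:3, , drop = FALSE]),
               "no sequence for tip")

  set.seed(41)
  for (rep in 1:15) {
    ntip <- sample(4:6, 1)
    tree <- ape::rtree(ntip)
    L <- sample(2:5, 1)
    prof <- matrix(sample(c("A", "C", "G", "T", "N"), ntip * L,
                          replace = TRUE, prob = c(rep(0.23, 4), 0.08)),
                   ntip, L, dimnames = list(tree$tip.label, NULL))
    expect_equal(fitch_reconstruct(tree, prof)$score,
                 brute_fitch_score(tree, prof))
  }
})

test_that("Fitch scores agree with phangorn's parsimony", {
  skip_if_not_installed("phangorn")
  set.seed(43)
  for (rep in 1:10) {
    ntip <- sample(5:10, 1)
    tree <- ape::rtree(ntip)
    L <- 12
    prof <- matrix(sample(c("A", "C", "G", "T"), ntip * L, replace = TRUE),
                   ntip, L, dimnames = list(tree$tip.label, NULL))
    pd <- phangorn::phyDat(prof, type = "DNA")
    expect_equal(fitch_reconstruct(tree, prof)$score,
                 phangorn::parsimony(tree, pd, method = "fitch"))
  }
})

test_that("the genealogy graph expands mutations into unit edges", {
  # two haplotypes (counts 2,2) differing at 3 sites: path of 3 edges
  aln <- aln_from_strings(c("AAATTT", "AAATTT", "AAAGGG", "AAAGGG"))
  tr <- ape::read.tree(text = "((s1,s2),(s3,s4));")
  gen <- build_haplotype_genealogy(tr, aln)
  g <- gen$graph
  types <- igraph::V(g)$type
  expect_equal(sum(types == "haplotype"), 2L)
  expect_equal(sum(types == "intermediate"), 2L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(gen$score, 3L)
  mult <- igraph::V(g)$multiplicity[types == "haplotype"]
  expect_equal(sort(mult), c(2L, 2L))

  # single haplotype: one node, no edges
  g1 <- build_haplotype_genealogy(tr, aln_from_strings(rep("ACGT", 4)))
  expect_equal(igraph::vcount(g1$graph), 1L)
  expect_equal(igraph::ecount(g1$graph), 0L)

  # star: three haplotypes one change each from a shared unsampled state
  star <- aln_from_strings(c("TAAA", "ATAA", "AATA"))
  gst <- build_haplotype_genealogy(ape::read.tree(text = "((s1,s2),s3);"),
                                   star)
  degs <- igraph::degree(gst$graph)
  expect_equal(gst$score, 3L)
  expect_equal(sum(igraph::V(gst$graph)$type == "haplotype"), 3L)
  expect_equal(max(degs), 3L)                 # the inferred hub
})

test_that("edge count always equals the parsimony score", {
  set.seed(47)
  for (rep in 1:8) {
    cfg <- sim_config(n_modern = 12, n_ancient = 0, L = 300,
                      N0_f = 3e4, growth_rate = 0,
                      split_time_years = 1e5, n_locations = 2)
    ds <- simulate_dataset(cfg, seed = 100 + rep)
    tr <- build_nj_tree(pairwise_differences(ds$alignment))
    gen <- build_haplotype_genealogy(tr, ds$alignment)
    expect_equal(igraph::ecount(gen$graph), gen$score)
  }
})

test_that("parsimony score and clade partition are invariant to
           re-rooting of the input tree", {
  set.seed(53)
  aln <- random_alignment(7, 20)
  tr <- ape::rtree(7, tip.label = aln$ids)
  gen1 <- build_haplotype_genealogy(tr, aln)
  cl1 <- assign_clades(gen1)
  part1 <- split(names(cl1$clades), cl1$clades[names(cl1$clades)])
  for (og in c(2, 5)) {
    gen2 <- build_haplotype_genealogy(ape::root(ape::unroot(tr), og,
                                                resolve.root = TRUE), aln)
    expect_equal(gen2$score, gen1$score)
    expect_equal(igraph::ecount(gen2$graph), igraph::ecount(gen1$graph))
    cl2 <- assign_clades(gen2)
    part2 <- split(names(cl2$clades), cl2$clades[names(cl2$clades)])
    expect_setequal(unname(lapply(part1, sort)),
                    unname(lapply(part2, sort)))
  }
})

test_that("clade assignment cuts long paths and is monotone in the
           threshold", {
  # two tight clusters joined by a 5-change path
  aln <- aln_from_strings(c("AAAAAAAA", "AAAAAAAT",
                            "TTTTTAAA", "TTTTTAAT"))
  tr <- ape::read.tree(text = "((s1,s2),(s3,s4));")
  gen <- build_haplotype_genealogy(tr, aln)

  auto <- assign_clades(gen)                   # longest path (5) is cut
  expect_equal(auto$n_clades, 2L)
  expect_equal(auto$threshold, 5L)
  expect_equal(unname(auto$clades[c("s1", "s2")]),
               rep(auto$clades[["s1"]], 2))
  expect_false(auto$clades[["s1"]] == auto$clades[["s3"]])

  one <- assign_clades(gen, 1)                 # every haplotype its own
  expect_equal(one$n_clades, gen$ht$Nh)

  n_prev <- Inf
  for (thr in 1:6) {
    n_now <- assign_clades(gen, thr)$n_clades
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
  expect_message(assign_clades(gen, 50), "single clade")
})

test_that("genealogy export writes GraphML and DOT", {
  aln <- aln_from_strings(c("AAATTT", "AAATTT", "AAAGGG", "AAAGGG"))
  tr <- ape::read.tree(text = "((s1,s2),(s3,s4));")
  gen <- build_haplotype_genealogy(tr, aln)
  gml <- tempfile(fileext = ".graphml")
  dot <- tempfile(fileext = ".dot")
  write_genealogy(gen, gml, dot)
  expect_true(file.exists(gml) && file.size(gml) > 0)
  expect_true(file.exists(dot) && file.size(dot) > 0)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(gen$graph))
})
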