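test_that("simulation configs validate their parameters", {
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_modern + cfg$n_ancient, 376L)
  expect_equal(cfg$L, 16724L)
  expect_error(sim_config(clade_mix = 1.5))
  expect_error(sim_config(n_modern = 1, n_ancient = 0))
  expect_error(sim_config(cr_interval = c(0, 10)))
  expect_error(sim_config(n_ancient = 3, ancient_ages = c(100, 200)))
})

test_that("pair coalescence times have the analytic mean", {
  cfg <- sim_config(n_modern = 2, n_ancient = 0, L = 100, N0_f = 1000,
                    growth_rate = 0, split_time_years = NA,
                    clade_mix = 1, n_locations = 1)
  set.seed(61)
  tm <- replicate(3000, {
    sim <- simulate_genealogy(cfg, tip_ages = c(0, 0))
    max(sim$node_ages)
  })
  # haploid pair coalescence at rate 1/(N0 gen): mean N0 * gen years
  expect_equal(mean(tm), 1000, tolerance = 0.05)
})

test_that("tips in different clades never coalesce before the split", {
  cfg <- sim_config(n_modern = 2, n_ancient = 0, L = 100, N0_f = 500,
                    growth_rate = 0, split_time_years = 5000,
                    n_locations = 1)
  set.seed(67)
  for (rep in 1:25) {
    sim <- simulate_genealogy(cfg, tip_ages = c(0, 0),
                              tip_clades = c(1L, 2L))
    expect_gte(max(sim$node_ages), 5000)
  }
})

test_that("serial tips attach at their ages", {
  cfg <- sim_config(n_modern = 3, n_ancient = 2, L = 50, N0_f = 2000,
                    growth_rate = 0, split_time_years = NA, clade_mix = 1,
                    n_locations = 1)
  set.seed(71)
  sim <- simulate_genealogy(cfg, tip_ages = c(0, 0, 0, 400, 700))
  expect_equal(unname(sim$node_ages[as.character(1:5)]),
               c(0, 0, 0, 400, 700))
  # every internal node is older than its children
  tr <- sim$tree
  ages <- sim$node_ages[as.character(tr$edge[, 1])] -
    sim$node_ages[as.character(tr$edge[, 2])]
  expect_true(all(ages >= -1e-9))
  expect_equal(unname(ages), tr$edge.length, tolerance = 1e-12)
})

test_that("mutation counts follow the two-rate Poisson model", {
  # zero-length tree -> identical sequences
  cfg0 <- sim_config(n_modern = 4, n_ancient = 0, L = 200, N0_f = 100,
                     growth_rate = 0, split_time_years = NA, clade_mix = 1,
                     n_locations = 1)
  tr0 <- ape::read.tree(text = "((t1:0,t2:0):0,(t3:0,t4:0):0);")
  aln0 <- sprinkle_mutations(tr0, cfg0, seed = 3)
  expect_equal(collapse_haplotypes(aln0)$Nh, 1L)

  # two-tip tree of fixed duration: E[diffs] = 2 t mu_locus (small rates,
  # so repeat hits are negligible)
  cfg <- sim_config(n_modern = 2, n_ancient = 0, L = 1000,
                    cr_interval = c(901, 1000), N0_f = 100,
                    growth_rate = 0, split_time_years = NA, clade_mix = 1,
                    n_locations = 1)
  mu_loc <- cfg$mu_body * 900 + cfg$mu_cr * 100
  t_half <- 2e5
  tr <- ape::read.tree(text = sprintf("(t1:%d,t2:%d);", t_half, t_half))
  set.seed(73)
  diffs <- replicate(400, {
    a <- sprinkle_mutations(tr, cfg)
    sum(a$states[1, ] != a$states[2, ])
  })
  expect_equal(mean(diffs), 2 * t_half * mu_loc, tolerance = 0.05)

  # control-region density exceeds body density by roughly mu_cr/mu_body
  set.seed(79)
  cr_hits <- 0; body_hits <- 0
  for (rep in 1:60) {
    a <- sprinkle_mutations(tr, cfg)
    dif <- which(a$states[1, ] != a$states[2, ])
    cr_hits <- cr_hits + sum(dif > 900)
    body_hits <- body_hits + sum(dif <= 900)
  }
  ratio <- (cr_hits / 100) / (body_hits / 900)
  expect_equal(ratio, cfg$mu_cr / cfg$mu_body, tolerance = 0.25)
})

test_that("datasets are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_modern = 15, n_ancient = 4, L = 400, N0_f = 2e4,
                    growth_rate = 0, split_time_years = 1e5,
                    n_locations = 3)
  d1 <- simulate_dataset(cfg, seed = 99)
  d2 <- simulate_dataset(cfg, seed = 99)
  expect_identical(d1$alignment$states, d2$alignment$states)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$truth, d2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_alignment(d1$alignment, f1)
  write_alignment(d2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed, different data
  d3 <- simulate_dataset(cfg, seed = 100)
  expect_false(identical(d1$alignment$states, d3$alignment$states))
})

test_that("dataset assembly respects the configured design", {
  cfg <- sim_config(n_modern = 20, n_ancient = 5, L = 300, N0_f = 2e4,
                    growth_rate = 0, split_time_years = 1e5,
                    n_locations = 4)
  ds <- simulate_dataset(cfg, seed = 17)
  expect_equal(ds$alignment$N, 25L)
  expect_equal(ds$alignment$L, 300L)
  expect_equal(sum(ds$metadata$era == "ancient"), 5L)
  anc_ages <- ds$metadata$age_years[ds$metadata$era == "ancient"]
  expect_true(all(anc_ages >= 200 & anc_ages <= 750))
  expect_true(all(ds$metadata$age_years[ds$metadata$era == "modern"] == 0))
  expect_setequal(unique(ds$truth$clade), c("clade_1", "clade_2"))
})

test_that("analytic expectations apply only to constant-size single-clade
           configs and scale linearly", {
  cfg <- sim_config(n_modern = 20, n_ancient = 0, L = 1000, N0_f = 5e3,
                    growth_rate = 0, split_time_years = NA, clade_mix = 1,
                    n_locations = 1)
  e <- expected_summaries(cfg)
  expect_equal(e$theta, 2 * 5e3 * mitotempo:::mu_locus(cfg))
  expect_equal(e$E_S, e$theta * sum(1 / (1:19)))
  e2 <- expected_summaries(sim_config(n_modern = 20, n_ancient = 0,
                                      L = 1000, N0_f = 1e4,
                                      growth_rate = 0,
                                      split_time_years = NA,
                                      clade_mix = 1, n_locations = 1))
  expect_equal(e2$E_pi_site, 2 * e$E_pi_site)
  expect_error(expected_summaries(sim_config()), "constant-size")
})
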