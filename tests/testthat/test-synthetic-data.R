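test_that("sim_config validates its domain", {
  expect_error(sim_config(n_samples = 1), "n_samples")
  expect_error(sim_config(mu = 0), "mu")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("genealogies are rooted, ultrametric-aged and seeded", {
  gen <- simulate_genealogy(sim_config(n_samples = 10, seed = 5))
  phy <- gen$phy
  expect_true(ape::is.rooted(phy))
  expect_equal(ape::Ntip(phy), 10)
  # parent strictly older than child along every edge; tip ages 0
  expect_true(all(gen$ages[phy$edge[, 1]] > gen$ages[phy$edge[, 2]] - 1e-9))
  expect_true(all(gen$ages[seq_len(10)] == 0))
  # seeded determinism
  gen2 <- simulate_genealogy(sim_config(n_samples = 10, seed = 5))
  expect_identical(ape::write.tree(phy), ape::write.tree(gen2$phy))
  gen3 <- simulate_genealogy(sim_config(n_samples = 10, seed = 6))
  expect_false(identical(ape::write.tree(phy), ape::write.tree(gen3$phy)))
})

test_that("tmrca_target rescales the root age exactly", {
  gen <- simulate_genealogy(sim_config(n_samples = 2, seed = 1,
                                       tmrca_target = 54000))
  expect_equal(max(gen$ages), 54000)
  gen20 <- simulate_genealogy(sim_config(n_samples = 20, seed = 3,
                                         tmrca_target = 50000))
  expect_equal(max(gen20$ages), 50000)
})

test_that("mean TMRCA matches the Kingman expectation 2N(1 - 1/n)", {
  n <- 10; Ne <- 200; reps <- 200
  tm <- vapply(seq_len(reps), function(r) {
    max(simulate_genealogy(sim_config(n_samples = n, Ne = Ne,
                                      generation_time = 1, seed = r))$ages)
  }, numeric(1))
  expected <- 2 * Ne * (1 - 1 / n)  # 360 generations
  # sd(TMRCA) = Ne * sqrt(sum 1/C(k,2)^2) ~ 1.077 Ne; allow 4 standard errors
  tol <- 4 * 1.08 * Ne / sqrt(reps)
  expect_lt(abs(mean(tm) - expected), tol)
})

test_that("segregating sites match Watterson's expectation under constant Ne", {
  n <- 10; Ne <- 200; reps <- 120
  cfgs <- lapply(seq_len(reps), function(r)
    sim_config(n_samples = n, Ne = Ne, generation_time = 1, seed = 1000 + r))
  S <- vapply(cfgs, function(cfg) {
    ncol(drop_mutations(simulate_genealogy(cfg))$geno)
  }, numeric(1))
  expected <- cfgs[[1]]$mu * cfgs[[1]]$L * 2 * Ne * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - expected), 4 * stats::sd(S) / sqrt(reps))
})

test_that("mutation counts follow the Poisson infinite-sites model", {
  # two tips at TMRCA 54 ky: E[pairwise diffs] = 2 mu L T ~ 845.3
  reps <- 40
  d <- vapply(seq_len(reps), function(r) {
    m <- drop_mutations(simulate_genealogy(
      sim_config(n_samples = 2, seed = 200 + r, tmrca_target = 54000)))
    ncol(m$geno)
  }, numeric(1))
  expected <- 2 * 0.76e-9 * 10.3e6 * 54000
  expect_lt(abs(mean(d) - expected), 4 * sqrt(expected / reps))

  # zero-length edge carries zero mutations
  gen <- simulate_genealogy(sim_config(n_samples = 5, seed = 2))
  gen$phy$edge.length[1] <- 0
  m <- drop_mutations(gen)
  expect_length(attr(m, "edge_sites")[[1]], 0)

  # infinite-sites violation is an error
  gen2 <- simulate_genealogy(sim_config(n_samples = 5, seed = 2, L = 10))
  expect_error(drop_mutations(gen2, mu = 1, L = 10), "infinite-sites")
})

test_that("simulated matrices always pass the four-gamete test", {
  for (s in 1:5) {
    m <- drop_mutations(simulate_genealogy(sim_config(n_samples = 12,
                                                      seed = 300 + s)))
    expect_identical(nrow(four_gamete_scan(m)), 0L)
  }
})

test_that("artifact injection round-trips under no noise", {
  cfg <- sim_config(n_samples = 8, seed = 4, missing_rate = 0,
                    allele_error_rate = 0, indel_rate = 0,
                    depth_mean = 60, depth_sd = 1)
  m <- drop_mutations(simulate_genealogy(cfg))
  calls <- inject_artifacts(m, cfg)
  res <- filter_calls(calls)
  expect_identical(res$matrix$geno, m$geno)
  expect_identical(res$matrix$pos, m$pos)
  expect_equal(res$matrix$L_effective, m$L_effective)
})

test_that("artifact truth masks reflect the planted corruption", {
  # allele_error_rate 1 on one sample corrupts that sample everywhere
  cfg <- sim_config(n_samples = 4, seed = 8, missing_rate = 0,
                    allele_error_rate = c(1, 0, 0, 0), indel_rate = 0)
  m <- drop_mutations(simulate_genealogy(cfg))
  calls <- inject_artifacts(m, cfg)
  truth <- attr(calls, "truth")
  expect_true(all(truth$corrupt[1, ]))
  expect_false(any(truth$corrupt[-1, ]))
  # corrupted fraction ~ Binomial(n*p, rate)
  cfg2 <- sim_config(n_samples = 10, seed = 9, allele_error_rate = 0.1,
                     indel_rate = 0)
  m2 <- drop_mutations(simulate_genealogy(cfg2))
  truth2 <- attr(inject_artifacts(m2, cfg2), "truth")
  ntot <- length(truth2$corrupt)
  phat <- mean(truth2$corrupt)
  expect_lt(abs(phat - 0.1), 4 * sqrt(0.1 * 0.9 / ntot))
  # every corrupted genotype is removable by the allele-balance rule
  calls2 <- inject_artifacts(m2, cfg2)
  snv <- attr(calls2, "truth")$snv_cols
  frac <- calls2$ad_called[, snv] / (calls2$ad_called[, snv] +
                                       calls2$ad_other[, snv])
  expect_true(all(frac[truth2$corrupt] < 0.85))
})

test_that("planted markers are nested and identify the true clade", {
  gen <- simulate_genealogy(sim_config(n_samples = 15, seed = 11))
  ms <- plant_markers(gen, "auto", n_per_clade = 1)
  # nesting: carriers of a child clade's marker are derived at its parent's
  hgs <- ms$haplogroups
  for (k in seq_len(nrow(hgs))) {
    par <- hgs$parent[k]
    if (par == "Y") next
    child_mk <- ms$markers$name[ms$markers$haplogroup == hgs$haplogroup[k]]
    par_mk <- ms$markers$name[ms$markers$haplogroup == par]
    carriers <- ms$genotypes[, child_mk[1]] == 1
    expect_true(all(ms$genotypes[carriers, par_mk[1]] == 1))
  }
  # most terminal derived marker = smallest named enclosing clade (oracle:
  # direct tree lookup stored in ms$truth)
  for (i in seq_len(15)) {
    derived_hgs <- ms$markers$haplogroup[ms$genotypes[i, ] == 1]
    sizes <- vapply(derived_hgs, function(h)
      sum(ms$genotypes[, ms$markers$name[ms$markers$haplogroup == h][1]]),
      numeric(1))
    smallest <- if (length(derived_hgs)) derived_hgs[which.min(sizes)] else "Y"
    expect_identical(smallest, ms$truth$clade[i])
  }
  expect_error(plant_markers(gen, c(BAD = 1L)), "internal")
})

test_that("population assignment is seeded and handles one population", {
  gen <- simulate_genealogy(sim_config(n_samples = 10, seed = 12))
  p1 <- simulate_populations(gen, n_pops = 4)
  p2 <- simulate_populations(gen, n_pops = 4)
  expect_identical(p1, p2)
  single <- simulate_populations(gen, n_pops = 1)
  expect_identical(unique(single$population), "P01")
  expect_identical(nrow(dplyr::distinct(single[, c("lat", "lon")])), 1L)
})
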