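test_that("pairwise divergence counts differences over comparable sites", {
  g <- rbind(a = c(1L, 1L, 1L, 1L), b = c(0L, 1L, 1L, NA))
  m <- hap_matrix(g, 1:4, 10)
  # 2 differences among jointly called sites, 1 site missing in one sample:
  # denominator 10 - 1 = 9 comparable sites
  g2 <- rbind(a = c(1L, 1L, 0L, 1L), b = c(0L, 1L, 1L, NA))
  m2 <- hap_matrix(g2, 1:4, 10)
  expect_equal(pairwise_divergence(m2, "a", "b"), 2 / 9)
  expect_equal(pairwise_divergence(m, "a", "b"), 1 / 9)
  expect_error(pairwise_divergence(m, "a", "a"), "differ")
  # identical samples diverge by zero
  g3 <- rbind(a = c(1L, 0L), b = c(1L, 0L), c = c(0L, 1L))
  expect_equal(pairwise_divergence(hap_matrix(g3, 1:2, 10), "a", "b"), 0)
})

test_that("pairwise divergence equals a brute-force site loop", {
  brute <- function(m, i, j) {
    num <- 0; miss <- 0
    for (s in seq_along(m$pos)) {
      gi <- m$geno[i, s]; gj <- m$geno[j, s]
      if (is.na(gi) || is.na(gj)) { miss <- miss + 1; next }
      if (gi != gj) num <- num + 1
    }
    num / (m$L_effective - miss)
  }
  for (s in 1:8) {
    set.seed(500 + s)
    g <- matrix(sample(c(0L, 1L, NA), 5 * 12, TRUE, prob = c(.5, .4, .1)),
                5, 12, dimnames = list(letters[1:5], NULL))
    g[1, ] <- 1L
    m <- hap_matrix(g, seq_len(12), 40)
    for (pair in list(c(1, 2), c(2, 5), c(3, 4)))
      expect_equal(pairwise_divergence(m, pair[1], pair[2]),
                   brute(m, pair[1], pair[2]))
  }
})

test_that("clade divergence averages cross-clade pairs", {
  # children of sizes 2 and 3: mean of the 6 enumerated pair values
  phy <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1,e:1):1);")
  set.seed(1)
  g <- matrix(sample(c(0L, 1L), 5 * 10, TRUE), 5, 10,
              dimnames = list(letters[1:5], NULL))
  g[1, ] <- 1L
  m <- hap_matrix(g, 1:10, 30)
  got <- clade_divergence(phy, 6, m)
  pairs <- expand.grid(A = c("a", "b"), B = c("c", "d", "e"))
  manual <- mean(mapply(function(i, j) pairwise_divergence(m, i, j),
                        as.character(pairs$A), as.character(pairs$B)))
  expect_equal(got$divergence, manual)
  expect_identical(got$n_pairs, 6L)
  # both children singletons: equals the single pairwise divergence
  phy2 <- ape::read.tree(text = "(a:1,b:1);")
  got2 <- clade_divergence(phy2, 3, m)
  expect_equal(got2$divergence, pairwise_divergence(m, "a", "b"))
})

test_that("clades above 100 samples are subsampled to a reproducible third", {
  tips <- sprintf("t%03d", 1:150)
  txt <- sprintf("(B:1,(%s):1);", paste0(tips, ":1", collapse = ","))
  phy <- ape::read.tree(text = txt)
  g <- matrix(0L, 151, 2, dimnames = list(c("B", tips), NULL))
  g["B", 1] <- 1L; g[tips, 2] <- 1L
  m <- hap_matrix(g, 1:2, 100)
  got <- clade_divergence(phy, 152, m, dating_config(seed = 7))
  expect_identical(got$n_pairs, 50L)  # ceiling(150/3) x 1
  again <- clade_divergence(phy, 152, m, dating_config(seed = 7))
  expect_identical(got, again)
})

test_that("date_node implements the analytic conversion and round-trip", {
  expect_equal(date_node(0)$age, 0)
  expect_equal(date_node(0)$ci_low, 0)
  d <- 8.2e-5
  out <- date_node(d)
  expect_equal(out$age, d / (2 * 0.76e-9))       # 53947.4 y
  expect_equal(out$ci_low, d / (2 * 0.86e-9))    # 47674.4 y
  expect_equal(out$ci_high, d / (2 * 0.67e-9))   # 61194.0 y
  expect_equal(round(out$age), 53947)
  expect_equal(round(out$ci_low), 47674)
  expect_equal(round(out$ci_high), 61194)
  # algebraic round-trip and linearity
  cfg <- dating_config()
  expect_equal(out$age * 2 * cfg$mu, d)
  expect_equal(date_node(2 * d)$age, 2 * out$age)
  expect_equal(date_node(2 * d)$ci_high - date_node(2 * d)$ci_low,
               2 * (out$ci_high - out$ci_low))
})

test_that("two-tip trees date the root at k/(2 mu L)", {
  g <- rbind(a = c(1L, 1L, 0L), b = c(0L, 0L, 1L))
  m <- hap_matrix(g, 1:3, 1000)
  tr <- build_tree(m)
  dt <- date_tree(tr, m)
  cfg <- dating_config()
  expect_equal(dt$nodes$age, 3 / (2 * cfg$mu * 1000))
  expect_equal(glance(dt)$root_age, dt$nodes$age)
  expect_identical(tidy(dt), dt$nodes)
})

test_that("dating is invariant to sample order", {
  rep <- sim_replicate(601, n = 12)
  tr <- build_tree(rep$matrix)
  dt1 <- date_tree(tr, rep$matrix, dating_config(seed = 3))
  perm <- sample(nrow(rep$matrix$geno))
  m2 <- hap_matrix(rep$matrix$geno[perm, , drop = FALSE], rep$matrix$pos,
                   rep$matrix$L_effective)
  dt2 <- date_tree(tr, m2, dating_config(seed = 3))
  expect_equal(dt1$nodes, dt2$nodes)
})

test_that("lineage counts match fixtures and the closed-form oracle", {
  # fixture with splits at 60k / 54k / 50k
  phy <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  ages <- c(0, 0, 0, 0, 60000, 54000, 50000)
  dt <- list(phy = phy, ages = ages)
  expect_identical(lineages_through_time(dt, 52000), 3L)
  expect_identical(lineages_through_time(dt, 0), 4L)
  expect_identical(lineages_through_time(dt, 59999), 2L)
  expect_identical(lineages_through_time(dt, 70000), 1L)  # stem convention
  # clade restriction: subtree (A,B,C) at 52k has 2 lineages
  expect_identical(lineages_through_time(dt, 52000, clade = 6L), 2L)

  # closed form on binary coalescent trees: n - #{internal nodes <= t}
  for (s in 1:5) {
    gen <- simulate_genealogy(sim_config(n_samples = 12, seed = 700 + s))
    internal_ages <- gen$ages[13:23]
    for (t in runif(20, 0, max(gen$ages) * 1.05)) {
      expected <- if (t >= max(gen$ages)) 1L
                  else 12L - sum(internal_ages <= t)
      expect_identical(lineages_through_time(gen, t), expected)
    }
  }
  # non-increasing in t
  gen <- simulate_genealogy(sim_config(n_samples = 15, seed = 99))
  ts <- sort(runif(30, 0, max(gen$ages)))
  counts <- vapply(ts, function(t) lineages_through_time(gen, t), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rho dating recovers simulated root ages on clean data", {
  errs <- vapply(1:8, function(s) {
    rep <- sim_replicate(800 + s, n = 12, tmrca = 55000)
    tr <- build_tree(rep$matrix)
    dt <- date_tree(tr, rep$matrix, dating_config(seed = s))
    root <- dt$nodes[dt$nodes$node == 13L, ]
    (root$age - 55000) / 55000
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
})
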