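# coalescent genealogies, mutations, geography, STRs, degraded samples

test_that("coalescent simulator is deterministic and validates input", {
  d <- demography_model(2000)
  t1 <- simulate_genealogy(15, d, seed = 7)
  t2 <- simulate_genealogy(15, d, seed = 7)
  expect_identical(t1$edge, t2$edge)
  expect_identical(t1$edge.length, t2$edge.length)
  t3 <- simulate_genealogy(15, d, seed = 8)
  expect_false(identical(t1$edge.length, t3$edge.length))
  expect_error(demography_model(-5), "positive")
  expect_error(demography_model(c(1000, 2000), times = c(0, 0)),
               "strictly increas")
  one <- simulate_genealogy(1, d, seed = 1)
  expect_equal(length(one$tip.label), 1L)
  expect_equal(one$Nnode, 0L)
})

test_that("two-tip TMRCA matches the analytic coalescent expectation", {
  Ne <- 1000; g <- 31
  d <- demography_model(Ne, generation_time = g)
  tm <- vapply(seq_len(10000), function(i)
    max(node_ages(simulate_genealogy(2, d, seed = i))), numeric(1))
  expected <- 2 * Ne * g
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - expected), 3 * se)
})

test_that("total tree length matches the closed-form harmonic expectation", {
  Ne <- 1500; g <- 31; n <- 10
  d <- demography_model(Ne, generation_time = g)
  len <- vapply(seq_len(2000), function(i)
    sum(simulate_genealogy(n, d, seed = 5000 + i)$edge.length), numeric(1))
  # standard result: E[L] = 2 * H(n-1) on the 2*Ne*g year time scale
  expected <- 2 * (2 * Ne * g) * sum(1 / seq_len(n - 1))
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - expected), 3 * se)
})

test_that("piecewise epochs change the coalescent rate at the boundary", {
  # no coalescence possible before 1000 BP, then Ne = 10
  d <- demography_model(c(1e9, 10), times = c(0, 1000))
  tm <- vapply(seq_len(2000), function(i)
    max(node_ages(simulate_genealogy(2, d, seed = i))), numeric(1))
  expect_true(all(tm > 1000))
  expected <- 1000 + 2 * 10 * 31
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - expected), 3 * se)
})

test_that("mutation counts are Poisson with the configured intensity", {
  tr <- simulate_genealogy(8, demography_model(2000), seed = 3)
  mu <- 5e-9; L <- 1e6
  expect_error(drop_mutations(tr, -1, L), "mu")
  empty <- drop_mutations(tr, 0, L, seed = 1)
  expect_equal(nrow(empty$matrix$geno), 0L)
  tot <- vapply(seq_len(1000), function(i)
    nrow(drop_mutations(tr, mu, L, seed = i)$matrix$geno), numeric(1))
  expected <- mu * L * sum(tr$edge.length)
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("simulated sites form a perfect phylogeny on the truth tree", {
  tr <- simulate_genealogy(12, demography_model(3000), seed = 9)
  sim <- drop_mutations(tr, 7e-10, 5e6, seed = 10)
  tu <- tips_under(tr)
  for (i in seq_len(nrow(sim$matrix$geno))) {
    carriers <- which(sim$matrix$geno[i, ] == 1L)
    expect_identical(carriers, tu[[sim$truth$branch[i]]],
                     ignore_attr = TRUE)
  }
  expect_identical(fitch_changes(tr, sim$matrix$geno),
                   rep(1L, nrow(sim$matrix$geno)))
})

test_that("Brownian dispersal has the exact mean-squared displacement", {
  tr <- two_tip_tree(4000)
  sigma <- 0.4
  fix <- simulate_brownian_locations(tr, c(35, 45), 0, seed = 1)
  expect_true(all(abs(fix$lat - 35) < 1e-12) && all(abs(fix$lon - 45) < 1e-12))
  d2 <- t(vapply(seq_len(3000), function(i) {
    loc <- simulate_brownian_locations(tr, c(35, 45), sigma, seed = i)
    c((loc$x[1] - loc$x[3])^2 + (loc$y[1] - loc$y[3])^2,
      (loc$x[1] + loc$x[2]) / 2)           # midpoint x of the two tips
  }, numeric(2)))
  expected <- 2 * sigma^2 * 4000
  se <- sd(d2[, 1]) / sqrt(nrow(d2))
  expect_lt(abs(mean(d2[, 1]) - expected), 3 * se)
  # tip midpoint is an unbiased root estimator (root x = 0 in the plane)
  se_mid <- sd(d2[, 2]) / sqrt(nrow(d2))
  expect_lt(abs(mean(d2[, 2])), 4 * se_mid)
})

test_that("STR haplotypes follow the stepwise model with a floor", {
  tr <- simulate_genealogy(10, demography_model(5000), seed = 4)
  frozen <- simulate_str_haplotypes(tr, str_rate = 0, seed = 1)
  expect_true(all(frozen$repeats == 14L))
  expect_identical(colnames(frozen$repeats), YSTR_LOCI)
  nm <- vapply(seq_len(400), function(i)
    sum(simulate_str_haplotypes(tr, str_rate = 0.01, seed = i)$n_mutations),
    numeric(1))
  expected <- 8 * 0.01 * sum(tr$edge.length) / 31
  se <- sd(nm) / sqrt(length(nm))
  expect_lt(abs(mean(nm) - expected), 3 * se)
  hot <- simulate_str_haplotypes(tr, str_rate = 0.5, seed = 2,
                                 root_haplotype = rep(2L, 8))
  expect_true(all(hot$repeats >= 1L))
})

test_that("sample degradation matches its binomial rates", {
  gen <- rep(c(0L, 1L), length.out = 4292)
  all_miss <- degrade_sample(gen, 1, 0, seed = 1)
  expect_true(all(is.na(all_miss$state)))
  ident <- degrade_sample(gen, 0, 0, seed = 1)
  expect_identical(ident$state, gen)
  dg <- degrade_sample(gen, 0.3, 0, seed = 5)
  p <- mean(is.na(dg$state))
  se <- sqrt(0.3 * 0.7 / 4292)
  expect_lt(abs(p - 0.3), 3 * se)
  expect_error(degrade_sample(gen, 1.5, 0), "rates")
})
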