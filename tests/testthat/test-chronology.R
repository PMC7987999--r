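# HPD, ESS, chain combining, dating MCMC behaviour

test_that("hpd_interval is the shortest leftmost window", {
  expect_equal(hpd_interval(rep(3.5, 10)), c(3.5, 3.5))
  expect_equal(hpd_interval(1:100, 0.95), c(1, 95))
  set.seed(2)
  z <- rnorm(100000)
  h <- hpd_interval(z, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  expect_error(hpd_interval(numeric(0)), "empty")
  # exhaustive window-search oracle on small samples
  set.seed(3)
  for (r in 1:20) {
    x <- sort(rnorm(40))
    m <- ceiling(0.8 * 40)
    widths <- vapply(seq_len(40 - m + 1),
                     function(i) x[i + m - 1] - x[i], numeric(1))
    i <- which.min(widths)
    expect_equal(hpd_interval(x, 0.8), c(x[i], x[i + m - 1]))
  }
})

test_that("combine_chains drops burn-in and concatenates", {
  tr1 <- data.frame(state = 1:1000, mu = rnorm(1000))
  tr2 <- data.frame(state = 1:1000, mu = rnorm(1000, 5))
  one <- combine_chains(list(tr1))
  expect_equal(nrow(one), 900)
  both <- combine_chains(list(tr1, tr2))
  expect_equal(nrow(both), 1800)
  expect_equal(mean(both$mu),
               mean(c(tr1$mu[101:1000], tr2$mu[101:1000])))
  expect_error(combine_chains(list(tr1, data.frame(a = 1:10))),
               "mismatch")
})

test_that("ess matches i.i.d., AR(1) and degenerate-series expectations", {
  set.seed(4)
  white <- rnorm(10000)
  expect_lt(abs(ess(white) - 10000) / 10000, 0.10)
  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), 20000))
  expected <- 20000 * (1 - rho) / (1 + rho)
  expect_lt(abs(ess(ar) - expected) / expected, 0.20)
  const <- ess(rep(1, 100))
  expect_equal(as.numeric(const), 0)
  expect_equal(attr(const, "flag"), "constant series")
  alt <- rep(c(-1, 1), 500) + rnorm(1000, sd = 1e-6)
  expect_lte(ess(alt), 1000)             # anti-correlation clipped at n
  expect_error(ess(1:5), "at least 10")
})

test_that("prior-only sampling reproduces the normal node calibration", {
  tr <- simulate_genealogy(12, demography_model(4000), seed = 51)
  cal <- list(node = 13L, mean = 18741, sd = 1874)
  tra <- run_dating_mcmc(tr, rep(0, nrow(tr$edge)), L = 9.4e6,
                         calibration = cal, tree_prior = "flat",
                         chains = 2, n_sweeps = 2500, thin = 2, seed = 52)
  x <- combine_chains(tra)$age_13
  expect_lt(abs(mean(x) - 18741) / 18741, 0.02)
  expect_lt(abs(sd(x) - 1874) / 1874, 0.10)
  expect_error(run_dating_mcmc(tr, rep(0, nrow(tr$edge)), 9.4e6,
                               calibration = list(node = 99L, mean = 1,
                                                  sd = 1)), "absent")
})

test_that("single-branch rate posterior matches the Gamma-Poisson oracle", {
  tr <- two_tip_tree(10000)
  tra <- run_dating_mcmc(tr, c(7, 7), L = 1e6,
                         calibration = list(node = 3L, mean = 10000, sd = 1),
                         tree_prior = "flat", chains = 2,
                         n_sweeps = 6000, thin = 2, seed = 53)
  mu <- combine_chains(tra)$mu
  # p(mu) ~ 1/mu, n = 14 events at exposure 2*L*10000 -> Gamma(14, 2e10)
  oracle_mean <- 14 / 2e10
  mc_se <- sd(mu) / sqrt(ess(mu))
  expect_lt(abs(mean(mu) - oracle_mean), 4 * mc_se + 0.02 * oracle_mean)
})

test_that("chain-seed exchange leaves summaries within MC error", {
  tr <- simulate_genealogy(10, demography_model(3000), seed = 55)
  sim <- drop_mutations(tr, 7e-10, 9.4e6, seed = 56)
  nb <- tabulate(sim$truth$branch, nbins = 19)[tr$edge[, 2]]
  cal <- list(node = 11L, mean = max(node_ages(tr)),
              sd = 0.1 * max(node_ages(tr)))
  run1 <- combine_chains(run_dating_mcmc(tr, nb, 9.4e6, cal,
    tree_prior = "flat", chains = 2, n_sweeps = 2000, seed = 57))
  run2 <- combine_chains(run_dating_mcmc(tr, nb, 9.4e6, cal,
    tree_prior = "flat", chains = 2, n_sweeps = 2000, seed = 58))
  for (v in c("age_11", "mu")) {
    se <- sd(run1[[v]]) / sqrt(ess(run1[[v]])) +
      sd(run2[[v]]) / sqrt(ess(run2[[v]]))
    expect_lt(abs(median(run1[[v]]) - median(run2[[v]])), 5 * se)
  }
})

test_that("relaxed clock on strict-clock data concentrates CoV near zero", {
  tr <- simulate_genealogy(10, demography_model(3000), seed = 61)
  sim <- drop_mutations(tr, 7e-10, 9.4e6, seed = 62)
  nb <- tabulate(sim$truth$branch, nbins = 19)[tr$edge[, 2]]
  cal <- list(node = 11L, mean = max(node_ages(tr)),
              sd = 0.1 * max(node_ages(tr)))
  tra <- run_dating_mcmc(tr, nb, 9.4e6, cal, clock = "relaxed",
                         tree_prior = "flat", chains = 2,
                         n_sweeps = 1500, thin = 2, seed = 63)
  cmb <- combine_chains(tra)
  expect_lt(median(cmb$cov), 0.15)
})

test_that("node-age summaries respect the per-sample ordering constraint", {
  tr <- simulate_genealogy(15, demography_model(4000), seed = 65)
  sim <- drop_mutations(tr, 7e-10, 9.4e6, seed = 66)
  nb <- tabulate(sim$truth$branch, nbins = 29)[tr$edge[, 2]]
  cal <- list(node = 16L, mean = max(node_ages(tr)),
              sd = 0.1 * max(node_ages(tr)))
  cmb <- combine_chains(run_dating_mcmc(tr, nb, 9.4e6, cal,
    tree_prior = "skyline", chains = 2, n_sweeps = 1200, seed = 67))
  # every sampled state satisfies parent > child
  pv <- ychron:::parent_vec(tr)
  for (v in 17:29) {
    p <- pv[v]
    expect_true(all(cmb[[paste0("age_", p)]] > cmb[[paste0("age_", v)]]))
  }
  tab <- summarize_node_ages(cmb, tr)
  expect_true(all(tab$hpd_lo <= tab$median_age &
                    tab$median_age <= tab$hpd_hi))
  # medians monotone along root-to-tip paths
  med <- setNames(tab$median_age, tab$node)
  for (v in 17:29)
    expect_gte(med[as.character(pv[v])], med[as.character(v)])
})

test_that("skyline trajectories honour their envelope invariants", {
  tr <- simulate_genealogy(40, demography_model(5000), seed = 71)
  sim <- drop_mutations(tr, 7e-10, 9.4e6, seed = 72)
  nb <- tabulate(sim$truth$branch, nbins = 79)[tr$edge[, 2]]
  cal <- list(node = 41L, mean = max(node_ages(tr)),
              sd = 0.1 * max(node_ages(tr)))
  expect_error(run_dating_mcmc(tr, nb, 9.4e6, cal, tree_prior = "skyline",
                               skyline_groups = 40), "exceeds")
  cmb <- combine_chains(run_dating_mcmc(tr, nb, 9.4e6, cal,
    tree_prior = "skyline", skyline_groups = 5, chains = 2,
    n_sweeps = 1200, seed = 73))
  sk <- skyline_from_trace(cmb)
  ok <- !is.na(sk$median)
  expect_true(all(sk$lo[ok] <= sk$median[ok] & sk$median[ok] <= sk$hi[ok]))
  # group counts 3 and 8 give mutually compatible median curves
  cmb3 <- combine_chains(run_dating_mcmc(tr, nb, 9.4e6, cal,
    tree_prior = "skyline", skyline_groups = 3, chains = 2,
    n_sweeps = 1200, seed = 74))
  sk3 <- skyline_from_trace(cmb3, grid = sk$time)
  both <- ok & !is.na(sk3$median)
  expect_gt(mean(sk3$median[both] >= sk$lo[both] &
                   sk3$median[both] <= sk$hi[both]), 0.9)
  expect_gt(mean(sk$median[both] >= sk3$lo[both] &
                   sk$median[both] <= sk3$hi[both]), 0.9)
})
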