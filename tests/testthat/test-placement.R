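# informative panels, allele observation, branch affiliation

mk_panel_fixture <- function(seed = 81, n = 30) {
  tr <- simulate_genealogy(n, demography_model(4000), seed = seed)
  sim <- drop_mutations(tr, 7e-10, 9.4e6, seed = seed + 1)
  bt <- build_parsimony_tree(sim$matrix)
  asn <- map_sites_to_branches(bt, sim$matrix)
  list(tree = bt, sim = sim, asn = asn,
       panel = informative_site_panel(bt, asn))
}

test_that("the panel carries single-origin sites only and round-trips", {
  fx <- mk_panel_fixture()
  expect_equal(nrow(fx$panel), sum(!fx$asn$recurrent))
  inj <- inject_qc_artifacts(fx$sim$matrix, fx$tree,
                             spec = list(recurrent_sites = 2), seed = 83)
  asn2 <- map_sites_to_branches(fx$tree, inj$matrix)
  p2 <- informative_site_panel(fx$tree, asn2)
  rec_pos <- vapply(inj$truth$recurrent_sites, `[[`, numeric(1), "pos")
  expect_true(all(!rec_pos %in% p2$pos))
  f <- tempfile(fileext = ".tsv")
  write_tsv(fx$panel, f)
  back <- read_tsv(f)
  expect_equal(back$pos, fx$panel$pos)
  expect_equal(back$branch, fx$panel$branch)
  expect_error(informative_site_panel(fx$tree, NULL), "assignments")
})

test_that("allele observation applies depth, matching and error rules", {
  fx <- mk_panel_fixture()
  empty <- observe_alleles(data.frame(pos = numeric(0),
                                      allele = character(0),
                                      depth = numeric(0)), fx$panel)
  expect_true(all(is.na(empty$state)))
  tab <- data.frame(pos = fx$panel$pos[1:3],
                    allele = c("G", "A", "G"), depth = c(3, 2, 1))
  obs <- observe_alleles(tab, fx$panel, min_depth = 2)
  expect_identical(obs$state[1:3], c(1L, 0L, NA))
  expect_warning(
    mm <- observe_alleles(data.frame(pos = fx$panel$pos[1],
                                     allele = "T", depth = 5), fx$panel),
    "neither panel allele")
  expect_equal(mm$n_mismatch, 1L)
  expect_true(is.na(mm$state[1]))
  expect_error(observe_alleles(data.frame(pos = c(1, NA),
                                          allele = c("A", "G"),
                                          depth = c(1, 1)), fx$panel),
               "malformed")
})

test_that("path support assigns, degrades at sister conflicts, or abstains", {
  fx <- mk_panel_fixture()
  tr <- fx$tree; panel <- fx$panel
  tipname <- tr$tip.label[1]
  tipidx <- 1L
  gcol <- fx$sim$matrix$geno[match(panel$pos, fx$sim$matrix$pos),
                            match(tipname, fx$sim$matrix$samples)]
  obs <- structure(list(state = as.integer(gcol), pos = panel$pos),
                   class = "ancient_observation")
  aff <- place_sample(obs, tr, panel)
  expect_equal(aff$status, "assigned")
  expect_equal(aff$branch, tipidx)
  # no contradicted branch may sit on the assigned path
  sup <- aff$support
  expect_true(all(sup$derived >= sup$ancestral))

  blank <- structure(list(state = rep(NA_integer_, nrow(panel)),
                          pos = panel$pos), class = "ancient_observation")
  expect_equal(place_sample(blank, tr, panel)$status, "unassigned")

  # inject a derived call at a sister-defining site: degrade to parent
  pv <- ychron:::parent_vec(tr)
  sis <- setdiff(ychron:::children_list(tr)[[pv[tipidx]]], tipidx)
  sis_sites <- which(panel$branch %in% sis)
  if (length(sis_sites)) {
    st2 <- as.integer(gcol)
    st2[sis_sites[1]] <- 1L
    obs2 <- structure(list(state = st2, pos = panel$pos),
                      class = "ancient_observation")
    aff2 <- place_sample(obs2, tr, panel)
    expect_equal(aff2$status, "degraded_to_parent")
    expect_equal(aff2$branch, pv[tipidx])
  }
})

test_that("heavier missingness never deepens an assignment", {
  fx <- mk_panel_fixture(seed = 91)
  tr <- fx$tree; panel <- fx$panel
  depth_of <- function(node) length(ychron:::root_path(tr, node))
  set.seed(5)
  for (r in 1:10) {
    tipname <- sample(tr$tip.label, 1)
    gcol <- as.integer(
      fx$sim$matrix$geno[match(panel$pos, fx$sim$matrix$pos),
                         match(tipname, fx$sim$matrix$samples)])
    miss_order <- sample(length(gcol))
    last_depth <- Inf
    for (frac in c(0, 0.5, 0.9, 0.99)) {
      st <- gcol
      st[miss_order[seq_len(floor(frac * length(st)))]] <- NA
      aff <- place_sample(structure(list(state = st, pos = panel$pos),
                                    class = "ancient_observation"),
                          tr, panel)
      d <- if (is.na(aff$branch)) 0 else depth_of(aff$branch)
      expect_lte(d, last_depth)
      last_depth <- d
    }
  }
})

test_that("degraded cohorts land on the truth branch or an ancestor", {
  fx <- mk_panel_fixture(seed = 95, n = 40)
  tr <- fx$tree; panel <- fx$panel
  ok <- 0; off <- 0
  for (r in 1:60) {
    tipname <- sample(tr$tip.label, 1)
    tipidx <- match(tipname, tr$tip.label)
    gcol <- as.integer(
      fx$sim$matrix$geno[match(panel$pos, fx$sim$matrix$pos),
                         match(tipname, fx$sim$matrix$samples)])
    dg <- degrade_sample(gcol, 0.8, 0.005, seed = 7000 + r)
    aff <- place_sample(structure(list(state = dg$state, pos = panel$pos),
                                  class = "ancient_observation"), tr, panel)
    if (is.na(aff$branch)) next
    if (aff$branch %in% ychron:::root_path(tr, tipidx)) ok <- ok + 1
    else off <- off + 1
  }
  expect_equal(off, 0)
  expect_gte(ok, 55)
})
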