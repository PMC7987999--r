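# region-based QC rules and mask arithmetic

mk_gm <- function(geno, pos, mask = NULL, platform = NULL) {
  geno_matrix(geno, pos, platform = platform, mask = mask)
}

test_that("region mask keeps exactly in-mask sites (coordinate conventions)", {
  g <- matrix(1L, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  gm <- mk_gm(g, c(100, 101))
  out <- apply_region_mask(gm, region_mask(0, 100))
  expect_identical(out$pos, 100)          # [0,100) covers POS 1..100
  empty <- apply_region_mask(gm, region_mask())
  expect_length(empty$pos, 0L)
  expect_equal(callable_length(empty$mask), 0)
  expect_error(region_mask(c(0, 50), c(100, 150)), "non-overlapping")
  expect_error(region_mask(10, 10), "start < end")
})

test_that("mask membership equals the per-base oracle on random masks", {
  set.seed(7)
  for (r in 1:10) {
    starts <- sort(sample(0:180, 6)) * 10
    ends <- starts + sample(1:9, 6) * 10
    keep <- !c(FALSE, starts[-1] < ends[-6])
    m <- region_mask(starts[keep], ends[keep])
    base <- logical(2000)
    for (i in seq_along(m$start)) base[(m$start[i] + 1):m$end[i]] <- TRUE
    pos <- sample(1:2000, 300)
    expect_identical(pos_in_mask(pos, m), base[pos])
    expect_equal(callable_length(m), sum(base))
  }
})

test_that("same-carrier singleton runs are excised with their flanks", {
  g <- matrix(0L, 3, 4, dimnames = list(NULL, letters[1:4]))
  g[1, 1] <- 1L; g[2, 1] <- 1L; g[3, ] <- c(1L, 1L, 0L, 0L)
  gm <- mk_gm(g, c(100, 140, 500), mask = region_mask(0, 1000))
  out <- filter_singleton_clusters(gm)
  expect_identical(out$matrix$pos, 500)
  expect_equal(unname(out$excluded$start), 49)
  expect_equal(unname(out$excluded$end), 190)
  # gap > 50: both singletons kept
  gm2 <- mk_gm(g, c(100, 200, 500), mask = region_mask(0, 1000))
  expect_length(filter_singleton_clusters(gm2)$excluded$start, 0L)
  # different carriers: kept
  g3 <- g; g3[2, ] <- c(0L, 1L, 0L, 0L)
  gm3 <- mk_gm(g3, c(100, 140, 500), mask = region_mask(0, 1000))
  expect_length(filter_singleton_clusters(gm3)$excluded$start, 0L)
})

test_that("replicate groups keep the least-missing column and excise discordant intervals", {
  set.seed(1)
  g <- matrix(0L, 30, 4, dimnames = list(NULL, c("dupA", "dupB", "x", "y")))
  g[1:20, "x"] <- 1L
  g[sample(30, 10), "dupA"] <- NA                   # 10 no-calls
  g[sample(30, 3), "dupB"] <- NA                    # 3 no-calls
  gm <- mk_gm(g, seq(10, 300, by = 10), mask = tiled_mask(1000, 100))
  out <- filter_replicate_discordance(gm, list(c("dupA", "dupB")))
  expect_identical(unname(out$kept), "dupB")
  expect_false("dupA" %in% out$matrix$samples)
  expect_length(out$excluded$start, 0L)
  expect_error(filter_replicate_discordance(gm, list(c("dupA", "nope"))),
               "unknown sample")

  # one discordant site inside [1000, 2000) condemns that whole interval
  g2 <- matrix(0L, 3, 3, dimnames = list(NULL, c("r1", "r2", "z")))
  g2[1, ] <- c(0L, 1L, 0L)                          # discordant at 1500
  g2[2, ] <- c(1L, 1L, 0L)
  g2[3, 3] <- 1L
  gm2 <- mk_gm(g2, c(1500, 1600, 2500), mask = tiled_mask(3000, 1000))
  out2 <- filter_replicate_discordance(gm2, list(c("r1", "r2")))
  expect_equal(unname(out2$excluded$start), 1000)
  expect_equal(unname(out2$excluded$end), 2000)
  expect_identical(out2$matrix$pos, 2500)

  # three discordances in distinct intervals -> three excluded regions
  g3 <- matrix(0L, 4, 2, dimnames = list(NULL, c("r1", "r2")))
  g3[1:3, 2] <- 1L
  g3[4, ] <- 1L
  gm3 <- mk_gm(g3, c(150, 1150, 2150, 2950), mask = tiled_mask(3000, 1000))
  out3 <- filter_replicate_discordance(gm3, list(c("r1", "r2")))
  expect_length(out3$excluded$start, 3L)
})

test_that("recurrence threshold: 1 change kept, 2 flagged, >= 3 excised", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  g <- rbind(c(1, 1, 0, 0, 0, 0, 0, 0),       # clean clade {a,b}
             c(1, 0, 1, 0, 0, 0, 0, 0),       # 2 origins
             c(1, 0, 1, 0, 1, 0, 0, 0))       # 3 origins
  storage.mode(g) <- "integer"
  colnames(g) <- letters[1:8]
  gm <- mk_gm(g, c(500, 1500, 2500), mask = tiled_mask(3000, 1000))
  out <- filter_recurrent_site_regions(gm, tr)
  expect_identical(out$matrix$pos, c(500, 1500))
  expect_identical(out$flagged_pos, 1500)
  expect_equal(unname(out$excluded$start), 2000)
  expect_error(filter_recurrent_site_regions(
    mk_gm(g[, 1:7], c(1, 2, 3)), ape::drop.tip(tr, "a")), "span")
})

test_that("recurrence is judged within platform subsets", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  # 3 origins overall, but each platform subset sees <= 1 change
  g <- matrix(c(1, 0, 1, 0, 1, 0, 0, 0), 1, 8,
              dimnames = list(NULL, letters[1:8]))
  storage.mode(g) <- "integer"
  pf <- setNames(c("P1", "P2", "P1", "P2", "P1", "P2", "P2", "P2"),
                 letters[1:8])
  gm <- mk_gm(g, 500, mask = tiled_mask(1000, 1000), platform = pf)
  out <- filter_recurrent_site_regions(gm, tr)
  expect_identical(out$matrix$pos, 500)    # P1 sees {a,c,e} = 1 change
})

test_that("missingness rule is strict and bridges barren gaps", {
  g <- matrix(0L, 3, 100, dimnames = list(NULL, sprintf("s%03d", 1:100)))
  g[1, 1:11] <- NA; g[2, 1:10] <- NA
  g[1, 50] <- 1L; g[2, 50] <- 1L; g[3, 50] <- 1L
  gm <- mk_gm(g, c(1000, 2000, 3000), mask = region_mask(0, 4000))
  out <- filter_missingness(gm)
  expect_identical(out$matrix$pos, c(2000, 3000))  # 10/100 kept, 11/100 dropped
  clean <- mk_gm(g[3, , drop = FALSE], 3000, mask = region_mask(0, 4000))
  expect_length(filter_missingness(clean)$excluded$start, 0L)

  # two marked sites 400 bp apart, no variant between -> gap excised
  g2 <- matrix(0L, 2, 100, dimnames = list(NULL, sprintf("s%03d", 1:100)))
  g2[1, 1:15] <- NA; g2[2, 1:15] <- NA
  gm2 <- mk_gm(g2, c(1000, 1400), mask = region_mask(0, 4000))
  out2 <- filter_missingness(gm2)
  expect_true(any(out2$excluded$start <= 999 & out2$excluded$end >= 1400))
  # with a clean variant between, only the marked bases go
  g3 <- matrix(0L, 3, 100, dimnames = list(NULL, sprintf("s%03d", 1:100)))
  g3[1, 1:15] <- NA; g3[3, 1:15] <- NA; g3[2, 1] <- 1L
  gm3 <- mk_gm(g3, c(1000, 1200, 1400), mask = region_mask(0, 4000))
  out3 <- filter_missingness(gm3)
  expect_identical(out3$matrix$pos, 1200)
  expect_equal(sum(out3$excluded$end - out3$excluded$start), 2)
})

test_that("callable_length sums interval widths", {
  expect_equal(callable_length(region_mask(c(0, 20), c(10, 25))), 15)
  expect_equal(callable_length(region_mask()), 0)
})

test_that("full pipeline: artifact exclusion is exact at region granularity", {
  fx <- qc_fixture(n_samples = 25, L = 4e6, seed = 31,
                   spec = list(singleton_clusters = 3,
                               replicate_discordances = 1,
                               recurrent_sites = 2, missing_blocks = 1))
  qc <- run_qc(fx$inj$matrix, replicate_groups = fx$groups)
  bad <- artifact_positions(fx$inj$truth)
  expect_true(all(!bad %in% qc$matrix$pos))
  # every excised region overlaps a labelled artifact (precision)
  reg <- artifact_regions(fx$inj$truth)
  for (m in qc$report$excluded_regions) {
    for (i in seq_along(m$start)) {
      expect_true(any(pmax(reg[, 1], m$start[i]) <
                        pmin(reg[, 2], m$end[i])),
                  label = sprintf("region [%d,%d) labelled", m$start[i],
                                  m$end[i]))
    }
  }
  # pipeline idempotence and mask monotonicity
  qc2 <- run_qc(qc$matrix, mask = qc$mask, replicate_groups = list())
  expect_identical(qc2$matrix$geno, qc$matrix$geno)
  expect_identical(qc2$mask, qc$mask)
  expect_lte(callable_length(qc$mask), callable_length(fx$inj$matrix$mask))
  # site accounting is exact
  expect_equal(qc$report$input_sites - sum(qc$report$excluded),
               qc$report$surviving_sites)
})

test_that("two alternative alleles at one position are independent sites", {
  g <- matrix(c(1L, 0L, 0L,
                0L, 1L, 0L), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  gm <- mk_gm(g, c(700, 700), mask = region_mask(0, 1000))
  out <- apply_region_mask(gm, gm$mask)
  expect_equal(nrow(out$geno), 2L)
  expect_identical(out$pos, c(700, 700))
})
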