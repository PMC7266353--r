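# Multi-locus statistics on recorded genealogies.

test_that("lineage traces start at the sample size and end at coalescence", {
  g <- simulate_genealogy(quick_config("dtwf", n = 7, N = 25, seed = 2))
  tr <- lineage_counts(g)
  expect_equal(tr$lineages[1], 7)
  expect_equal(tr$generation[1], 0)
  expect_equal(tr$lineages[nrow(tr)], 0)
  expect_true(all(tr$lineages <= 2 * 25))
})

test_that("IBD extraction matches hand-built cases", {
  # two samples in N = 1 coalesce in one generation over a whole chromosome
  g <- simulate_genealogy(quick_config("dtwf", n = 2, N = 1,
                                       map = genetic_map(1), seed = 14,
                                       stop_time = 1))
  # force coalescence at generation 1 by retrying seeds (probability 1/2)
  seed <- 14
  while (!g$fully_coalesced) {
    seed <- seed + 1
    g <- simulate_genealogy(quick_config("dtwf", n = 2, N = 1,
                                         map = genetic_map(1), seed = seed,
                                         stop_time = 1))
  }
  ibd <- extract_ibd(g, max_gen = 5, min_cm = 0)
  expect_equal(nrow(ibd), 1)
  expect_equal(ibd$length_cm, 100)
  expect_equal(ibd$tmrca, 1)
  # a segment shorter than min_cm is discarded
  expect_equal(nrow(extract_ibd(g, max_gen = 5, min_cm = 150)), 0)
  expect_error(extract_ibd(g, max_gen = 0), "max_gen")
})

test_that("extract_ibd equals the brute-force grid MRCA scan", {
  # the acceptance-level oracle check at unit-test scale
  set.seed(8)
  for (rep in 1:6) {
    model <- sample(c("dtwf", "hudson"), 1)
    g <- simulate_genealogy(quick_config(model, n = sample(3:6, 1),
                                         N = sample(5:15, 1),
                                         map = tiny_map(sample(1:2, 1), 0.05),
                                         seed = 400 + rep))
    maxg <- sample(2:6, 1)
    scan <- ibd_grid_scan(g, max_gen = maxg, step = 0.001)
    seg <- ibd_segments_on_grid(extract_ibd(g, max_gen = maxg, min_cm = 0),
                                g, step = 0.001)
    scan <- dplyr::arrange(scan, .data$position, .data$sample_a, .data$sample_b)
    expect_equal(nrow(seg), nrow(scan))
    expect_identical(seg$mrca, scan$mrca)
    expect_identical(seg$tmrca, scan$tmrca)
  }
})

test_that("IBD output is symmetric and bounded", {
  g <- simulate_genealogy(quick_config("dtwf", n = 10, N = 10,
                                       map = tiny_map(2, 0.4), seed = 17))
  ibd <- extract_ibd(g, max_gen = 4, min_cm = 0)
  expect_true(all(ibd$sample_a < ibd$sample_b))
  expect_true(all(ibd$tmrca > 0 & ibd$tmrca <= 4))
  expect_true(all(ibd$length_cm > 0))
  pairs <- ibd_pair_summary(ibd)
  expect_true(all(pairs$total_cm <= 100 * g$map$L + 1e-9))
  expect_equal(sum(pairs$n_segments), nrow(ibd))
})

test_that("ancestry fractions hit the degenerate pulse limits", {
  for (f in c(0, 1)) {
    cfg <- admixture_config("dtwf", samples = 10, N = 10, g = 2, f = f,
                            map = genetic_map(c(0.5, 0.5), 0.5), seed = 5 + f)
    fr <- ancestry_fractions(simulate_genealogy(cfg))
    expect_equal(fr$fraction, rep(f, 10))
    expect_equal(ancestry_variance(fr), 0)
  }
  # fractions always lie in [0, 1]; cohort mean is close to f
  cfg <- admixture_config("dtwf", samples = 40, N = 40, g = 3, f = 0.3,
                          map = human22_map(), seed = 77)
  fr <- ancestry_fractions(simulate_genealogy(cfg))
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
  expect_equal(mean(fr$fraction), 0.3, tolerance = 0.25)
  # missing census is a clear error
  g2 <- simulate_genealogy(quick_config("dtwf", n = 4, N = 10, seed = 3))
  expect_error(ancestry_fractions(g2, census_generation = 2), "pulse")
})

test_that("cohort mean ancestry is an unbiased estimator of f", {
  means <- vapply(1:25, function(i) {
    cfg <- admixture_config("dtwf", samples = 20, N = 20, g = 2, f = 0.3,
                            map = genetic_map(rep(1, 4), 0.5), seed = 500 + i)
    mean(ancestry_fractions(simulate_genealogy(cfg))$fraction)
  }, 0)
  expect_lt(abs(mean(means) - 0.3), 2.5 * stats::sd(means) / 5)
})

test_that("mutations are Poisson on branches and sites know their carriers", {
  g <- simulate_genealogy(quick_config("dtwf", n = 6, N = 20,
                                       map = tiny_map(1, 0.5), seed = 23))
  expect_equal(nrow(drop_mutations(g, 0)), 0)
  set.seed(1)
  sites <- drop_mutations(g, mu = 50)
  expect_true(all(sites$count >= 1 & sites$count <= 5))
  expect_true(all(lengths(sites$carriers) == sites$count))
  expect_true(all(sites$chrom == 1))
  # expected number of polymorphic sites = mu * branch-span measure
  bl <- sfs_branch(g, mu = 50)
  expect_equal(nrow(sites), sum(bl$expected_sites), tolerance = 0.35)
})

test_that("mean pairwise diversity matches 4 N mu span for n = 2", {
  N <- 30
  mu <- 2
  span <- 0.01
  pis <- vapply(1:300, function(i) {
    g <- simulate_genealogy(quick_config("dtwf", n = 2, N = N,
                                         map = genetic_map(span),
                                         seed = 3000 + i))
    nrow(drop_mutations(g, mu))
  }, 0)
  expect_equal(mean(pis), 4 * N * mu * span, tolerance = 0.15)
})

test_that("sfs tabulates carrier counts; n = 2 gives only singletons", {
  g <- simulate_genealogy(quick_config("dtwf", n = 2, N = 10,
                                       map = tiny_map(), seed = 2))
  set.seed(4)
  sites <- drop_mutations(g, mu = 100)
  s <- sfs(sites, 2)
  expect_equal(nrow(s), 1)
  expect_equal(s$sites, nrow(sites))
  empty <- sfs(drop_mutations(g, 0), 5)
  expect_equal(empty$sites, rep(0L, 4))
  # branch and site modes agree in expectation
  sb <- sfs_branch(g, mu = 100)
  expect_equal(nrow(sb), 1)
})

test_that("r2 is 1 for a site with itself and ~1/n for independent sites", {
  # construct pseudo-sites directly: two independent fair coins
  set.seed(6)
  n <- 40
  fake <- function(pos, chrom) {
    carriers <- which(stats::runif(n) < 0.5) - 1L
    tibble::tibble(position = pos, chrom = chrom, node = 0L,
                   count = length(carriers), carriers = list(carriers))
  }
  map <- genetic_map(c(1, 1), spacer = 0.5)
  sites <- dplyr::bind_rows(lapply(1:200, function(i) {
    fake(stats::runif(1, 0, 1), 1L)
  }))
  # self-pair: duplicate a site at the same position
  dup <- dplyr::bind_rows(sites[1, ], sites[1, ])
  r <- pairwise_r2(dup, map, n, breaks = c(0, Inf))
  expect_equal(r$mean_r2, 1)
  r2 <- pairwise_r2(sites, map, n, breaks = c(0, Inf))
  expect_equal(sum(r2$n_pairs), choose(200, 2))
  expect_equal(weighted.mean(r2$mean_r2, r2$n_pairs), 1 / n, tolerance = 0.15)
  # monomorphic input -> empty result
  mono <- sites[0, ]
  expect_equal(nrow(pairwise_r2(mono, map, n)), 0)
})

test_that("cross-chromosome r2 is higher under DTWF than Hudson at small N", {
  # genuinely unlinked chromosomes (10-Morgan spacer) so the coalescent arm
  # builds their genealogies independently
  r2_unlinked <- function(model, seeds) {
    vals <- vapply(seeds, function(s) {
      g <- simulate_genealogy(quick_config(model, n = 50, N = 100,
                                           map = genetic_map(c(0.05, 0.05), 10),
                                           seed = s))
      set.seed(s)
      sites <- drop_mutations(g, mu = 40)
      r <- pairwise_r2(sites, g$map, 50, min_count = 5)
      v <- r$mean_r2[r$bin == "unlinked"]
      if (length(v)) v else NA_real_
    }, 0)
    vals[!is.na(vals)]
  }
  d <- r2_unlinked("dtwf", 1:30)
  h <- r2_unlinked("hudson", 101:130)
  tt <- stats::t.test(d, h, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
})
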