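# Closed-form expectations and the forward gene-dropping oracle.

test_that("expected_ibd behaves at threshold limits and is monotone in m", {
  map <- human22_map()
  far <- expected_ibd(4, 2, map, min_len = 50)
  expect_equal(far$expected_n, 0, tolerance = 1e-6)
  expect_equal(far$expected_total_cm, 0, tolerance = 1e-4)
  e <- expected_ibd(c(2, 4, 6, 8, 10), 1, map, min_len = 0.01)
  expect_true(all(diff(e$expected_n) < 0))
  expect_true(all(diff(e$expected_total_cm) < 0))
  expect_error(expected_ibd(1, 1, map), "at least 2")
  # long-chromosome limit recovers the classic a 2^(1-m) (mL + C) count
  longmap <- genetic_map(rep(50, 4))
  e2 <- expected_ibd(6, 1, longmap, min_len = 0)
  expect_equal(e2$expected_n, 2^(1 - 6) * (6 * 200 + 4), tolerance = 1e-3)
})

test_that("expected_ibd falls inside the forward oracle's confidence bands", {
  set.seed(19)
  map <- human22_map()
  for (cls in list(c(2, 1), c(4, 2), c(6, 1))) {
    reps <- t(replicate(70, unlist(relative_pair_ibd(map, cls[1], cls[2],
                                                     min_len = 0.01))))
    th <- expected_ibd(cls[1], cls[2], map, min_len = 0.01)
    ci_n <- mean(reps[, 1]) + c(-1, 1) * 3 * stats::sd(reps[, 1]) / sqrt(70)
    ci_l <- mean(reps[, 2]) + c(-1, 1) * 3 * stats::sd(reps[, 2]) / sqrt(70)
    expect_gt(th$expected_n, ci_n[1])
    expect_lt(th$expected_n, ci_n[2])
    expect_gt(th$expected_total_cm, ci_l[1])
    expect_lt(th$expected_total_cm, ci_l[2])
  }
})

test_that("cousin containment is monotone and hits the degenerate cases", {
  set.seed(3)
  expect_equal(cousin_containment(1, 100, 1, replicates = 3)$probability, 0)
  expect_error(cousin_containment(200, 100, 1), "exceed")
  cc <- cousin_containment(80, 400, c(1, 2, 3), replicates = 8)
  expect_true(all(diff(cc$probability) >= 0))  # more distant cousins commoner
  ccK <- vapply(c(40, 120, 300), function(K) {
    cousin_containment(K, 400, 1, replicates = 8)$probability
  }, 0)
  expect_true(all(diff(ccK) > 0))
  # closed form of the cited calculation
  cf <- cousin_containment(2000, 10000, c(1, 2), method = "closed_form")
  expect_equal(cf$probability[1], 0.55, tolerance = 0.01)
  expect_equal(cf$probability[2], 0.96, tolerance = 0.01)
})

test_that("ancestry variance expectations reduce to the genealogical term", {
  map <- human22_map()
  z <- expected_ancestry_variance(0, 1:5, map)
  expect_equal(z$variance, rep(0, 5))
  v <- expected_ancestry_variance(0.3, 1, map)
  expect_equal(v$genealogical, 0.3 * 0.7 / 2, tolerance = 0.01)
  expect_gt(v$variance, v$genealogical)  # recombination term adds on top
  # genealogical part decays 2^-g; recombination decays ~1/g and eventually
  # dominates (the crossover near g ~ 10)
  curve <- expected_ancestry_variance(0.3, 1:20, map)
  ratio <- curve$recombination / curve$genealogical
  expect_lt(ratio[1], 0.1)
  expect_gt(ratio[20], 1)
})

test_that("the ancestry-variance curve tracks the forward pedigree oracle", {
  set.seed(23)
  map <- human22_map()
  N <- 80
  f <- 0.3
  for (g in c(2, 8)) {
    vars <- vapply(1:22, function(i) {
      o <- forward_pedigree_oracle(N, g, map)
      stats::var(pedigree_ancestry_fractions(o, f)$fraction)
    }, 0)
    th <- expected_ancestry_variance(f, g, map, N = N)$variance
    ci <- mean(vars) + c(-1, 1) * 3 * stats::sd(vars) / sqrt(22)
    expect_gt(th, ci[1])
    expect_lt(th, ci[2])
  }
})

test_that("gene dropping conserves the genome and mixes exactly two parents", {
  set.seed(9)
  map <- genetic_map(c(1, 0.8), spacer = 0.5)
  o <- forward_pedigree_oracle(6, 1, map)
  per_hap <- o$genomes |>
    dplyr::group_by(.data$individual, .data$haplotype) |>
    dplyr::summarise(tot = sum(.data$right - .data$left), .groups = "drop")
  expect_equal(per_hap$tot, rep(map$axis_length, 12))
  # each haplotype of a child is a mosaic of exactly one parent's two labels
  for (i in 1:6) {
    labs1 <- unique(o$genomes$founder_hap[o$genomes$individual == i &
                                            o$genomes$haplotype == 1])
    f <- o$pedigree[[1]][i, 1]
    expect_true(all(labs1 %in% c(2 * f - 1, 2 * f)))
  }
})

test_that("full siblings share about half their genome", {
  set.seed(31)
  map <- human22_map()
  shares <- vapply(1:60, function(i) {
    r <- relative_pair_ibd(map, m = 2, a = 2, min_len = 0)
    r$total_cm / (2 * 100 * map$L)  # two haplotype channels
  }, 0)
  expect_equal(mean(shares), 0.5, tolerance = 0.03)
})

test_that("oracle and closed form are independent routes that agree for cousins", {
  set.seed(41)
  map <- human22_map()
  reps <- t(replicate(100, unlist(relative_pair_ibd(map, 4, 2, min_len = 0.01))))
  th <- expected_ibd(4, 2, map, 0.01)
  expect_equal(mean(reps[, 1]), th$expected_n, tolerance = 0.1)
  expect_equal(mean(reps[, 2]), th$expected_total_cm, tolerance = 0.1)
})
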