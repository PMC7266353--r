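test_that("sample lineages start as whole-axis segments with sample nodes", {
  st <- new_sample_lineages(c(2, 0), genetic_map(1))
  expect_length(st$lineages, 2)
  expect_equal(st$lineages[[1]]$left, 0)
  expect_equal(st$lineages[[1]]$right, 1)
  expect_equal(st$nodes$time, c(0, 0))
  expect_equal(st$nodes$flags, c(1L, 1L))
  expect_error(new_sample_lineages(0, genetic_map(1)), "at least one")
  st2 <- new_sample_lineages(5000, genetic_map(1))
  expect_equal(sum(st2$nodes$flags == 1L), 5000)
})

test_that("total recombination mass uses the span convention", {
  one <- new_lineage(0, 1, 0L)
  expect_equal(total_recomb_mass(list(one)), 1.0)
  gapped <- new_lineage(c(0, 0.8), c(0.2, 1), c(0L, 0L))
  expect_equal(total_recomb_mass(list(gapped)), 1.0)  # trapped gap counts
  expect_equal(total_recomb_mass(list()), 0.0)
})

test_that("recombination splits conserve material and respect the span", {
  lin <- new_lineage(c(0, 0.8), c(0.2, 1), c(3L, 3L))
  sp <- apply_recombination(lin, 0.5)  # breakpoint in the trapped gap
  expect_equal(nrow(sp$left), 1)
  expect_equal(nrow(sp$right), 1)
  expect_equal(sp$left$right, 0.2)
  expect_equal(sp$right$left, 0.8)
  sp2 <- apply_recombination(new_lineage(0, 1, 0L), 0.5)
  expect_equal(sp2$left$right, 0.5)
  expect_equal(sp2$right$left, 0.5)
  expect_error(apply_recombination(lin, 1.5), "span")
  expect_error(apply_recombination(lin, 0), "span")
  # conservation
  tot <- sum(sp$left$right - sp$left$left) + sum(sp$right$right - sp$right$left)
  expect_equal(tot, sum(lin$right - lin$left))
})

test_that("merging records one node per event and prunes at full coalescence", {
  st <- new_sample_lineages(2, genetic_map(1))
  a <- st$lineages[[1]]
  b <- st$lineages[[2]]
  st <- merge_lineages(a, b, time = 5, st)
  expect_equal(nrow(st$merged), 0)          # grand MRCA everywhere
  expect_equal(nrow(st$nodes), 3)           # one new ancestor node
  expect_equal(nrow(st$edges), 2)           # one edge per child
  expect_setequal(st$edges$child, c(0L, 1L))
  expect_true(all(st$counter$count %in% 0L))

  # disjoint segments pass through without creating a node (the two halves
  # carry the same child node, so the reunited lineage squashes to one row)
  st2 <- new_sample_lineages(3, genetic_map(1))
  a2 <- apply_recombination(st2$lineages[[1]], 0.5)
  st2 <- merge_lineages(a2$left, structure(a2$right, population = 1L),
                        time = 1, st2)
  expect_equal(sum(st2$merged$right - st2$merged$left), 1)
  expect_equal(nrow(st2$nodes), 3)          # unchanged
  expect_equal(nrow(st2$edges), 0)
  # genuinely disjoint material from different samples stays two segments
  st3 <- new_sample_lineages(3, genetic_map(1))
  b1 <- apply_recombination(st3$lineages[[1]], 0.5)$left
  b2 <- apply_recombination(st3$lineages[[2]], 0.5)$right
  st3 <- merge_lineages(b1, b2, time = 1, st3)
  expect_equal(nrow(st3$merged), 2)
  expect_equal(nrow(st3$edges), 0)
})

test_that("merging refuses lineages from different populations", {
  st <- new_sample_lineages(c(1, 1), genetic_map(1))
  expect_error(merge_lineages(st$lineages[[1]], st$lineages[[2]], 1, st),
               "population")
})

test_that("overlap bookkeeping matches a brute-force per-point count", {
  # random 5-lineage, 3-interval states, merged pairwise: the reference
  # counter must always equal the number of lineages covering each point
  set.seed(42)
  for (rep in 1:10) {
    st <- new_sample_lineages(5, genetic_map(1))
    # fragment some lineages to create interval structure
    for (i in 1:3) {
      sp <- apply_recombination(st$lineages[[i]], runif(1, 0.2, 0.8))
      st$lineages[[i]] <- sp$left
      st$lineages[[length(st$lineages) + 1]] <- sp$right
    }
    ij <- sample(length(st$lineages), 2)
    a <- st$lineages[[ij[1]]]
    b <- st$lineages[[ij[2]]]
    st2 <- merge_lineages(a, b, 1, st)
    lins <- c(st$lineages[-ij], list(st2$merged))
    grid <- seq(0.005, 0.995, by = 0.01)
    brute <- vapply(grid, function(x) {
      sum(vapply(lins, function(l) any(l$left <= x & x < l$right), TRUE))
    }, 0)
    fromcounter <- vapply(grid, function(x) {
      st2$counter$count[st2$counter$left <= x & x < st2$counter$right][1]
    }, 0L)
    # pruned intervals read 0 in the counter and are covered by no lineage
    expect_equal(brute, as.numeric(fromcounter))
  }
})

test_that("is_fully_coalesced reflects remaining ancestral material", {
  st <- new_sample_lineages(2, genetic_map(1))
  expect_false(is_fully_coalesced(st))
  st2 <- merge_lineages(st$lineages[[1]], st$lineages[[2]], 1, st)
  st2$lineages <- list(st2$merged)
  expect_true(is_fully_coalesced(st2))
})

test_that("engine edge tables are grouped by parent in time order and squashed", {
  g <- simulate_genealogy(quick_config("dtwf", n = 8, N = 20,
                                       map = tiny_map(2, 0.5), seed = 7))
  ed <- g$edges
  nd <- g$nodes
  ptime <- nd$time[match(ed$parent, nd$id)]
  expect_true(all(diff(ptime) >= 0))
  # squashed: no two adjacent rows with identical (parent, child) and
  # touching intervals
  same <- ed$parent[-1] == ed$parent[-nrow(ed)] &
    ed$child[-1] == ed$child[-nrow(ed)] &
    ed$left[-1] == ed$right[-nrow(ed)]
  expect_false(any(same))
  # every edge satisfies parent.time > child.time
  expect_true(all(ptime > nd$time[match(ed$child, nd$id)]))
})

test_that("engine genealogies are complete: every point finds one grand MRCA", {
  for (model in c("hudson", "dtwf")) {
    g <- simulate_genealogy(quick_config(model, n = 6, N = 15,
                                         map = tiny_map(1, 0.4), seed = 3))
    expect_true(g$fully_coalesced)
    for (x in c(0.05, 0.21, 0.39)) {
      roots <- coverage_at(g$edges, g$nodes, x)
      expect_length(unique(roots), 1)  # single root at every position
    }
  }
})
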