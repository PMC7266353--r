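# Naive R implementation of Hudson's algorithm on the exported lineage
# algebra. Quadratic and slow -- used only at tiny scale as an independent
# oracle for the compiled engine.

naive_hudson <- function(n, map, N, max_events = 10000) {
  st <- new_sample_lineages(n, map)
  t <- 0
  counts <- c(recomb = 0, ca = 0)
  for (ev in seq_len(max_events)) {
    live <- st$lineages[vapply(st$lineages, nrow, 0L) > 0]
    k <- length(live)
    if (k == 0) break
    mass <- total_recomb_mass(live)
    rate_ca <- k * (k - 1) / (4 * N)
    t_rec <- if (mass > 0) stats::rexp(1, mass) else Inf
    t_ca <- if (k >= 2) stats::rexp(1, rate_ca) else Inf
    if (!is.finite(t_rec) && !is.finite(t_ca)) break
    if (t_rec < t_ca) {
      t <- t + t_rec
      counts["recomb"] <- counts["recomb"] + 1
      w <- vapply(live, function(l) max(l$right) - min(l$left), 0)
      i <- sample.int(k, 1, prob = w)
      span <- c(min(live[[i]]$left), max(live[[i]]$right))
      bp <- stats::runif(1, span[1], span[2])
      sp <- apply_recombination(live[[i]], bp)
      live[[i]] <- sp$left
      live[[k + 1]] <- sp$right
    } else {
      t <- t + t_ca
      counts["ca"] <- counts["ca"] + 1
      ij <- sample.int(k, 2)
      st$lineages <- live
      st <- merge_lineages(live[[ij[1]]], live[[ij[2]]], t, st)
      live <- c(live[-ij], list(st$merged))
    }
    st$lineages <- live
  }
  st$time <- t
  st$event_counts <- counts
  st
}
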