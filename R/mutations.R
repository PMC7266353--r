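#' Drop infinite-sites mutations onto a genealogy
#'
#' Mutations are placed on each edge as a Poisson process with mean
#' `mu * (genetic span of the edge, excluding spacers) * (branch length)`,
#' at positions uniform over the edge's non-spacer span. Every mutation
#' creates a unique site; its derived allele is carried by all samples below
#' the edge's child at that position.
#'
#' @param sim a `genealogy` with recorded tables.
#' @param mu mutation rate per Morgan per generation. With the package's
#'   default physical scale of 1 cM/Mb, `mu = 1` corresponds to 1e-8 per bp
#'   per generation.
#' @return A site tibble: `position` (Morgans on the axis), `chrom`, `node`
#'   (the edge child below which the derived allele falls), `count` (number
#'   of carrier samples) and `carriers` (list column of sample node ids).
#'   Only polymorphic sites (1 to n-1 carriers) are returned.
#' @export
drop_mutations <- function(sim, mu) {
  stopifnot(inherits(sim, "genealogy"), mu >= 0)
  n <- sum(sim$nodes$is_sample)
  empty <- tibble::tibble(position = numeric(), chrom = integer(),
                          node = integer(), count = integer(),
                          carriers = list())
  if (mu == 0 || nrow(sim$edges) == 0) return(empty)
  ed <- sim$edges
  span <- map_glen(sim$map, ed$left, ed$right)
  blen <- sim$nodes$time[ed$parent + 1L] - sim$nodes$time[ed$child + 1L]
  k <- stats::rpois(nrow(ed), mu * span * blen)
  idx <- rep.int(seq_len(nrow(ed)), k)
  if (length(idx) == 0) return(empty)
  pos <- unlist(lapply(which(k > 0), function(e) {
    map_runif_positions(sim$map, ed$left[e], ed$right[e], k[e])
  }))
  node <- ed$child[idx]
  dup <- duplicated(pos)
  pos <- pos[!dup]
  node <- node[!dup]
  carriers <- cpp_site_carriers(
    sim$nodes$time, sim$nodes$flags,
    ed$left, ed$right, ed$parent, ed$child,
    pos, node
  )
  out <- tibble::tibble(
    position = pos,
    chrom = map_chrom_of(sim$map, pos),
    node = node,
    count = lengths(carriers),
    carriers = carriers
  ) |>
    dplyr::filter(.data$count >= 1, .data$count <= n - 1) |>
    dplyr::arrange(.data$position)
  out
}

#' Site frequency spectrum
#'
#' Counts of polymorphic sites by number of derived-allele carriers
#' (singletons, doubletons, ...). Simultaneous multi-way coalescences in the
#' Wright-Fisher model produce more singletons and fewer doubletons than the
#' coalescent predicts; this spectrum is how that contrast is measured.
#'
#' @param sites a site table from [drop_mutations()].
#' @param n haploid sample size.
#' @return A tibble with `carriers` (1 to n-1) and `sites`.
#' @export
sfs <- function(sites, n) {
  stopifnot(n >= 2)
  counts <- tabulate(sites$count, nbins = n - 1)
  tibble::tibble(carriers = seq_len(n - 1), sites = counts)
}

#' Branch-mode (expected) site frequency spectrum
#'
#' Instead of Poisson-sampling mutations, accumulates for every allele-count
#' class the total genetic span times branch length subtending exactly that
#' many samples. Multiplied by a mutation rate this is the expected
#' infinite-sites SFS conditional on the genealogy -- the same quantity as
#' [sfs()] with the mutational noise integrated out, which makes
#' model-contrast tests far more powerful at equal simulation effort.
#'
#' @param sim a `genealogy` with recorded tables.
#' @param mu mutation rate per Morgan per generation (scales the spectrum).
#' @return A tibble with `carriers` (1 to n-1) and `expected_sites`.
#' @export
sfs_branch <- function(sim, mu = 1) {
  stopifnot(inherits(sim, "genealogy"))
  n <- sum(sim$nodes$is_sample)
  v <- cpp_branch_sfs(sim$nodes$time, sim$nodes$flags,
                      sim$edges$left, sim$edges$right,
                      sim$edges$parent, sim$edges$child,
                      sim$map$chrom_start, sim$map$chrom_end)
  tibble::tibble(carriers = seq_len(n - 1),
                 expected_sites = mu * v[seq_len(n - 1)])
}

#' Linkage disequilibrium (r-squared) by genetic distance
#'
#' Computes squared correlations of 0/1 haplotype indicators between pairs
#' of polymorphic sites and averages them within genetic-distance bins.
#' Pairs on different chromosomes go into an `"unlinked"` bin: under diploid
#' inheritance even unlinked loci show excess LD in small populations
#' (driving LD-based effective-size estimators), which Hudson's coalescent
#' cannot reproduce because it builds unlinked gene genealogies
#' independently.
#'
#' @param sites a site table from [drop_mutations()].
#' @param map the [genetic_map()] the sites were simulated on.
#' @param n haploid sample size.
#' @param breaks genetic-distance bin breaks in Morgans for same-chromosome
#'   pairs.
#' @param min_count optional minor-allele-count filter (default none).
#' @return A tibble with `bin` (a factor; last level `"unlinked"`),
#'   `mean_r2` and `n_pairs`. Monomorphic input gives zero rows.
#' @export
pairwise_r2 <- function(sites, map, n,
                        breaks = c(0, 0.01, 0.05, 0.1, 0.5, Inf),
                        min_count = 0) {
  sites <- dplyr::filter(sites, .data$count >= min_count,
                         .data$count <= n - min_count)
  if (nrow(sites) < 2) {
    return(tibble::tibble(bin = character(), mean_r2 = numeric(),
                          n_pairs = integer()))
  }
  X <- matrix(0L, n, nrow(sites))
  for (j in seq_len(nrow(sites))) X[sites$carriers[[j]] + 1L, j] <- 1L
  r2 <- suppressWarnings(stats::cor(X))^2
  # genetic position = within-chromosome offset + cumulative map length
  cum <- cumsum(c(0, map$lengths))[sites$chrom]
  gpos <- cum + (sites$position - map$chrom_start[sites$chrom])
  same <- outer(sites$chrom, sites$chrom, "==")
  d <- abs(outer(gpos, gpos, "-"))
  ut <- upper.tri(r2)
  ok <- ut & is.finite(r2)
  labs <- c(paste0("[", utils::head(breaks, -1), ",", utils::tail(breaks, -1), ")"),
            "unlinked")
  bin <- ifelse(same[ok], labs[findInterval(d[ok], breaks)],
                "unlinked")
  tibble::tibble(bin = factor(bin, levels = labs), r2 = r2[ok]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                     .groups = "drop")
}
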