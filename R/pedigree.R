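#' Forward-time pedigree with gene dropping (oracle)
#'
#' An independent check on the backward engines and the closed-form
#' expectations: simulates an explicit random-mating pedigree forward in
#' time, then drops uniquely-labelled founder haplotypes down through it
#' with the same meiosis model the DTWF engine uses (Poisson crossovers,
#' independent chromosome assortment). Every present-day haplotype is then a
#' mosaic of founder haplotypes, from which true IBD and true ancestry can
#' be read off directly.
#'
#' @param N diploid individuals per generation (rounded up to even when
#'   `monogamous`).
#' @param G pedigree depth in generations; founders live at generation `G`.
#' @param map a [genetic_map()].
#' @param monogamous if `TRUE`, each generation forms `N/2` random couples
#'   and children draw a parent couple (no half siblings); if `FALSE`, each
#'   child draws its two parents independently and uniformly, matching the
#'   engines' non-monogamous model.
#' @return A `pedigree_oracle`: the pedigree (list of `n x 2` father/mother
#'   index matrices, one per generation below the founders) and `genomes`, a
#'   tibble of generation-0 haplotype mosaics (`individual`, `haplotype`,
#'   `left`, `right`, `founder_hap`; founder `i` carries haplotypes
#'   `2i - 1` and `2i`).
#' @export
forward_pedigree_oracle <- function(N, G, map, monogamous = FALSE) {
  stopifnot(N >= 1, G >= 1, inherits(map, "genetic_map"))
  if (monogamous) N <- as.integer(2 * ceiling(N / 2))
  pedigree <- vector("list", G)
  for (t in seq_len(G)) {
    if (monogamous) {
      perm <- sample.int(N)
      cpl <- sample.int(N %/% 2L, N, replace = TRUE)
      pedigree[[t]] <- cbind(father = perm[2L * cpl - 1L],
                             mother = perm[2L * cpl])
    } else {
      pedigree[[t]] <- cbind(father = sample.int(N, N, replace = TRUE),
                             mother = sample.int(N, N, replace = TRUE))
    }
  }
  genomes <- tibble::as_tibble(
    cpp_gene_drop(map$chrom_start, map$chrom_end, pedigree, N)
  )
  structure(list(pedigree = pedigree, genomes = genomes, N = N, G = G,
                 map = map, monogamous = monogamous),
            class = "pedigree_oracle")
}

#' @export
print.pedigree_oracle <- function(x, ...) {
  cat(sprintf("<pedigree_oracle> N = %d diploids, %d generations, %s mating\n",
              x$N, x$G, if (x$monogamous) "monogamous" else "random"))
  invisible(x)
}

#' True haploid ancestry fractions from a pedigree oracle
#'
#' Labels each founder haplotype as migrant independently with probability
#' `f` (the pulse acts on haploid lineages) and returns, for every
#' present-day haplotype, the fraction of its map length inherited from
#' migrant founder haplotypes.
#'
#' @param oracle a [forward_pedigree_oracle()].
#' @param f migrant fraction in `[0, 1]`.
#' @return A tibble: `individual`, `haplotype`, `fraction`.
#' @export
pedigree_ancestry_fractions <- function(oracle, f) {
  stopifnot(inherits(oracle, "pedigree_oracle"), f >= 0, f <= 1)
  migrant <- stats::runif(2 * oracle$N) < f
  oracle$genomes |>
    dplyr::mutate(
      glen = map_glen(oracle$map, .data$left, .data$right),
      mig = migrant[.data$founder_hap]
    ) |>
    dplyr::group_by(.data$individual, .data$haplotype) |>
    dplyr::summarise(fraction = sum(.data$glen * .data$mig) / oracle$map$L,
                     .groups = "drop")
}

#' True IBD segments between two pedigree individuals
#'
#' Intervals over which any haplotype of `i` and any haplotype of `j` carry
#' the same founder haplotype, optionally restricted to a set of founder
#' haplotype labels (e.g. those of a known shared ancestor).
#'
#' @param oracle a [forward_pedigree_oracle()].
#' @param i,j generation-0 individual indices.
#' @param labels founder haplotype labels to consider (default: all).
#' @return A tibble of matched intervals: `hap_i`, `hap_j`, `left`, `right`,
#'   `founder_hap`, `length_cm` (spacer gaps excluded).
#' @export
pedigree_ibd_pairs <- function(oracle, i, j, labels = NULL) {
  g <- oracle$genomes
  gi <- g[g$individual == i, ]
  gj <- g[g$individual == j, ]
  if (!is.null(labels)) {
    gi <- gi[gi$founder_hap %in% labels, ]
    gj <- gj[gj$founder_hap %in% labels, ]
  }
  out <- dplyr::inner_join(gi, gj, by = "founder_hap",
                           relationship = "many-to-many",
                           suffix = c("_i", "_j")) |>
    dplyr::mutate(left = pmax(.data$left_i, .data$left_j),
                  right = pmin(.data$right_i, .data$right_j)) |>
    dplyr::filter(.data$right > .data$left) |>
    dplyr::transmute(
      hap_i = .data$haplotype_i, hap_j = .data$haplotype_j,
      left = .data$left, right = .data$right,
      founder_hap = .data$founder_hap
    )
  # segments are per chromosome: clip matched intervals to chromosomes so a
  # run carried across a boundary by the assortment coin counts once per side
  map <- oracle$map
  pieces <- lapply(seq_along(map$lengths), function(k) {
    p <- out |>
      dplyr::mutate(left = pmax(.data$left, map$chrom_start[k]),
                    right = pmin(.data$right, map$chrom_end[k]),
                    chrom = k)
    p[p$right > p$left, ]
  })
  dplyr::bind_rows(pieces) |>
    dplyr::mutate(length_cm = 100 * (.data$right - .data$left)) |>
    dplyr::filter(.data$length_cm > 0)
}

# squash adjacent intervals with the same (hap pair, founder label), so a
# segment is not double-counted when a crossover boundary splits the mosaic
# rows but not the identity
squash_ibd <- function(segs) {
  if (nrow(segs) == 0) return(segs)
  segs <- dplyr::arrange(segs, .data$hap_i, .data$hap_j, .data$founder_hap,
                         .data$chrom, .data$left)
  n <- nrow(segs)
  new_run <- c(TRUE, segs$left[-1] > segs$right[-n] |
                 segs$hap_i[-1] != segs$hap_i[-n] |
                 segs$hap_j[-1] != segs$hap_j[-n] |
                 segs$chrom[-1] != segs$chrom[-n] |
                 segs$founder_hap[-1] != segs$founder_hap[-n])
  segs |>
    dplyr::mutate(run = cumsum(new_run)) |>
    dplyr::group_by(.data$run, .data$hap_i, .data$hap_j, .data$chrom,
                    .data$founder_hap) |>
    dplyr::summarise(left = min(.data$left), right = max(.data$right),
                     length_cm = sum(.data$length_cm), .groups = "drop") |>
    dplyr::select(-"run")
}

#' Forward transmission oracle for a relative pair
#'
#' Builds the minimal pedigree of a relationship (a shared ancestors, `m`
#' meioses in total, spouses drawn as unrelated founders), gene-drops
#' through it, and returns the IBD segments the pair inherited from the
#' shared ancestor(s). Replicated, this gives Monte-Carlo confidence
#' intervals against which [expected_ibd()] is validated.
#'
#' @param map a [genetic_map()].
#' @param m total meioses separating the pair (even, >= 2: the pair sits
#'   `m/2` generations below the shared ancestor(s)).
#' @param a 1 (shared single ancestor, half relationships) or 2 (shared
#'   couple, full relationships).
#' @param min_len detection threshold in Morgans.
#' @return A one-row tibble: `n_segments` and `total_cm` for this replicate.
#' @export
relative_pair_ibd <- function(map, m, a, min_len = 0) {
  stopifnot(m >= 2, m %% 2 == 0, a %in% c(1, 2))
  depth <- m / 2  # generations from the pair up to the shared ancestor(s)
  pedigree <- build_pair_pedigree(depth, a)
  g <- cpp_gene_drop(map$chrom_start, map$chrom_end,
                     pedigree$generations, pedigree$n_founders)
  oracle <- structure(list(genomes = tibble::as_tibble(g), map = map),
                      class = "pedigree_oracle")
  shared_labels <- pedigree$shared_labels
  segs <- pedigree_ibd_pairs(oracle, 1, 2, labels = shared_labels) |>
    squash_ibd() |>
    dplyr::filter(.data$length_cm >= 100 * min_len)
  tibble::tibble(n_segments = nrow(segs), total_cm = sum(segs$length_cm))
}

# Minimal pedigree for a pair separated by m = 2 * depth meioses through
# `a` shared ancestors. Generation-0 rows: 1 = A, 2 = B. Founders: shared
# ancestor(s) first (labels 1:2 / 1:4), then unrelated spouse founders.
# Spouses below the top level are children of the spouses above them: only
# the shared ancestors' labels are ever scored, so spouse relatedness among
# themselves is irrelevant.
build_pair_pedigree <- function(depth, a) {
  shared <- seq_len(2L * a)
  if (depth == 1) {
    gens <- list(if (a == 2) cbind(c(1L, 1L), c(2L, 2L)) else
      cbind(c(1L, 1L), c(2L, 3L)))
    return(list(generations = gens, n_founders = if (a == 2) 2L else 3L,
                shared_labels = shared))
  }
  # layout at every level below the founders: rows 1:2 = chain members,
  # rows 3:4 = their spouses
  top_chain <- if (a == 2) cbind(c(1L, 1L), c(2L, 2L)) else
    cbind(c(1L, 1L), c(2L, 3L))
  top_spouse <- if (a == 2) cbind(c(3L, 3L), c(4L, 4L)) else
    cbind(c(4L, 4L), c(5L, 5L))
  gens <- vector("list", depth)
  gens[[depth]] <- rbind(top_chain, top_spouse)
  mid <- rbind(cbind(c(1L, 2L), c(3L, 4L)),   # chains marry the spouses
               cbind(c(3L, 4L), c(4L, 3L)))   # next spouses: unrelated stock
  if (depth > 2) for (t in seq(depth - 1, 2)) gens[[t]] <- mid
  gens[[1]] <- cbind(c(1L, 2L), c(3L, 4L))
  list(generations = gens, n_founders = if (a == 2) 4L else 5L,
       shared_labels = shared)
}
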