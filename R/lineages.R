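#' Lineage and segment algebra (reference implementation)
#'
#' These functions expose, in plain R on small tibbles, the exact bookkeeping
#' the compiled engines perform on ancestral segments: they are the
#' package's reference semantics for recombination splits and
#' common-ancestor merges, and the property tests cross-validate the
#' compiled engines against them. A lineage is a tibble of half-open
#' segments `[left, right)` sorted by `left`, pairwise disjoint, each tagged
#' with the genealogy `node` whose ancestry it carries, plus a `population`
#' attribute.
#'
#' @name lineage-algebra
NULL

new_lineage <- function(left, right, node, population = 1L) {
  stopifnot(all(left < right), !is.unsorted(left),
            all(utils::head(right, -1) <= utils::tail(left, -1)))
  structure(tibble::tibble(left = left, right = right, node = as.integer(node)),
            population = as.integer(population))
}

#' Initial sample lineages
#'
#' One lineage per haploid sample, each a single segment spanning the whole
#' map axis, with a fresh sample node at time 0.
#'
#' @param counts per-population haploid sample counts.
#' @param map a [genetic_map()].
#' @return A `sim_state`: extant lineages, node/edge tables, the per-point
#'   overlap counter (number of extant lineages ancestral to each genomic
#'   interval) and the current time.
#' @export
new_sample_lineages <- function(counts, map) {
  stopifnot(inherits(map, "genetic_map"))
  counts <- as.integer(counts)
  if (sum(counts) < 1) stop("at least one sample is required", call. = FALSE)
  n <- sum(counts)
  pops <- rep(seq_along(counts), counts)
  lineages <- lapply(seq_len(n), function(i) {
    new_lineage(0, map$axis_length, i - 1L, pops[i])
  })
  state <- list(
    lineages = lineages,
    nodes = tibble::tibble(id = seq_len(n) - 1L, time = 0, population = pops,
                           flags = 1L),
    edges = tibble::tibble(left = numeric(), right = numeric(),
                           parent = integer(), child = integer()),
    counter = tibble::tibble(left = 0, right = map$axis_length, count = n),
    time = 0,
    map = map
  )
  structure(state, class = "sim_state")
}

#' Total recombination mass of a set of lineages
#'
#' The Hudson engine's recombination rate: the sum over lineages of the map
#' distance between the leftmost and rightmost ancestral material, which
#' includes trapped non-ancestral gaps.
#'
#' @param lineages a list of lineages (or a `sim_state`).
#' @return Total mass in Morgans.
#' @export
total_recomb_mass <- function(lineages) {
  if (inherits(lineages, "sim_state")) lineages <- lineages$lineages
  sum(vapply(lineages, function(l) {
    if (nrow(l) == 0) 0 else max(l$right) - min(l$left)
  }, 0))
}

#' Split a lineage at a recombination breakpoint
#'
#' Material left of the breakpoint goes to one lineage, material right of it
#' to a new independent lineage; both inherit the population. Total
#' ancestral length is conserved.
#'
#' @param lineage a lineage tibble.
#' @param breakpoint position in Morgans, strictly inside the lineage span.
#' @return A list with elements `left` and `right`.
#' @export
apply_recombination <- function(lineage, breakpoint) {
  span <- c(min(lineage$left), max(lineage$right))
  if (breakpoint <= span[1] || breakpoint >= span[2]) {
    stop("breakpoint must fall strictly inside the lineage span",
         call. = FALSE)
  }
  pop <- attr(lineage, "population")
  l <- dplyr::filter(lineage, .data$left < breakpoint)
  r <- dplyr::filter(lineage, .data$right > breakpoint)
  l$right <- pmin(l$right, breakpoint)
  r$left <- pmax(r$left, breakpoint)
  list(left = structure(l, population = pop),
       right = structure(r, population = pop))
}

# split the counter at a set of positions
counter_split <- function(counter, at) {
  for (x in at) {
    i <- which(counter$left < x & x < counter$right)
    if (length(i) == 1) {
      counter <- dplyr::bind_rows(
        counter[seq_len(i - 1), ],
        tibble::tibble(left = counter$left[i], right = x,
                       count = counter$count[i]),
        tibble::tibble(left = x, right = counter$right[i],
                       count = counter$count[i]),
        counter[-seq_len(i), ]
      )
    }
  }
  counter
}

#' Merge two lineages at a common-ancestor event
#'
#' Where segments of `a` and `b` overlap a single new ancestor node is
#' created (one node per event, even when several disjoint intervals
#' overlap) and edges are recorded for both children over each overlapping
#' interval. Non-overlapping segments pass through unchanged. Intervals
#' whose overlap counter reaches 1 have found the most recent common
#' ancestor of the entire sample and are pruned from the returned lineage.
#'
#' @param a,b lineages in the same population.
#' @param time event time in generations (after all child node times).
#' @param state the `sim_state` carrying the node/edge tables and counter.
#' @return The updated `sim_state`, with `state$merged` holding the merged
#'   lineage (possibly with zero rows).
#' @export
merge_lineages <- function(a, b, time, state) {
  if (!identical(attr(a, "population"), attr(b, "population"))) {
    stop("lineages must be in the same population to coalesce; ",
         "engines must migrate first", call. = FALSE)
  }
  pop <- attr(a, "population")
  bounds <- sort(unique(c(a$left, a$right, b$left, b$right)))
  pieces <- tibble::tibble(left = utils::head(bounds, -1),
                           right = utils::tail(bounds, -1))
  in_a <- vapply(pieces$left, function(x) any(a$left <= x & x < a$right), TRUE)
  in_b <- vapply(pieces$left, function(x) any(b$left <= x & x < b$right), TRUE)
  node_of <- function(lin, x) lin$node[lin$left <= x & x < lin$right][1]
  anc <- NA_integer_
  out <- list()
  for (i in seq_len(nrow(pieces))) {
    l <- pieces$left[i]; r <- pieces$right[i]
    if (in_a[i] && in_b[i]) {
      if (is.na(anc)) {
        anc <- max(state$nodes$id) + 1L
        state$nodes <- dplyr::bind_rows(
          state$nodes,
          tibble::tibble(id = anc, time = time, population = pop, flags = 0L))
      }
      state$edges <- dplyr::bind_rows(
        state$edges,
        tibble::tibble(left = l, right = r, parent = anc,
                       child = c(node_of(a, l), node_of(b, l))))
      state$counter <- counter_split(state$counter, c(l, r))
      sel <- state$counter$left >= l & state$counter$right <= r
      newc <- state$counter$count[sel] - 1L
      keep <- newc > 1
      state$counter$count[sel] <- ifelse(keep, newc, 0L)
      kept <- state$counter[sel, ][keep, ]
      if (nrow(kept)) {
        out[[length(out) + 1]] <-
          tibble::tibble(left = kept$left, right = kept$right, node = anc)
      }
    } else if (in_a[i] || in_b[i]) {
      src <- if (in_a[i]) a else b
      out[[length(out) + 1]] <-
        tibble::tibble(left = l, right = r, node = node_of(src, l))
    }
  }
  merged <- dplyr::bind_rows(out)
  if (nrow(merged)) {
    merged <- dplyr::arrange(merged, .data$left)
    # squash touching pieces carrying the same node
    grp <- cumsum(c(TRUE, merged$left[-1] != merged$right[-nrow(merged)] |
                            merged$node[-1] != merged$node[-nrow(merged)]))
    merged <- merged |>
      dplyr::mutate(grp = grp) |>
      dplyr::group_by(.data$grp, .data$node) |>
      dplyr::summarise(left = min(.data$left), right = max(.data$right),
                       .groups = "drop") |>
      dplyr::arrange(.data$left) |>
      dplyr::select("left", "right", "node")
  }
  state$merged <- structure(merged, population = pop)
  state$time <- time
  state
}

#' Has every genomic position reached its grand MRCA?
#'
#' @param state a `sim_state`.
#' @return `TRUE` iff no extant lineage carries ancestral material.
#' @export
is_fully_coalesced <- function(state) {
  all(vapply(state$lineages, nrow, 0L) == 0)
}
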