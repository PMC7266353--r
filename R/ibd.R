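#' Extract identity-by-descent segments from a recorded genealogy
#'
#' IBD is defined genealogically: for each pair of samples, the maximal
#' genomic intervals over which the pair's most recent common ancestor node
#' is constant and no older than `max_gen` generations. Adjacent intervals
#' with the same MRCA are merged even when they were recorded by different
#' edges; segment lengths in centimorgans exclude inter-chromosome spacer
#' gaps; records shorter than `min_cm` are discarded.
#'
#' @param sim a `genealogy` with recorded tables.
#' @param max_gen only report sharing through common ancestors up to this
#'   many generations in the past (the cohort-relative notion of "recent"
#'   relatives; 5 in the whole-genome comparisons this package reproduces).
#' @param min_cm minimum reported segment length in centimorgans; short
#'   segments are undetectable in real data, so 5 cM mimics empirical IBD
#'   calls and 1 cM is used for closer agreement with theory.
#' @return A tibble with one row per segment: `sample_a`, `sample_b` (node
#'   ids, `a < b`), `left`, `right` (Morgans on the axis), `mrca` (node id),
#'   `tmrca` (generations) and `length_cm`.
#' @seealso [ibd_pair_summary()] for per-pair aggregation.
#' @export
extract_ibd <- function(sim, max_gen = 5, min_cm = 5) {
  stopifnot(inherits(sim, "genealogy"))
  if (max_gen <= 0) stop("`max_gen` must be positive", call. = FALSE)
  if (nrow(sim$edges) == 0 && sum(sim$nodes$is_sample) > 1) {
    stop("genealogy has no recorded edges; simulate with ",
         "`record_tables = TRUE`", call. = FALSE)
  }
  res <- cpp_ibd_segments(
    sim$nodes$time, sim$nodes$flags,
    sim$edges$left, sim$edges$right, sim$edges$parent, sim$edges$child,
    max_gen, min_cm, sim$map$chrom_start, sim$map$chrom_end
  )
  tibble::as_tibble(res) |>
    dplyr::arrange(.data$sample_a, .data$sample_b, .data$left)
}

#' Per-pair IBD summaries
#'
#' @param segments output of [extract_ibd()].
#' @return A tibble with one row per sample pair: `n_segments`, `total_cm`
#'   and `min_tmrca`. This is the (count, total length) plane used to
#'   classify relative pairs.
#' @export
ibd_pair_summary <- function(segments) {
  segments |>
    dplyr::group_by(.data$sample_a, .data$sample_b) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      total_cm = sum(.data$length_cm),
      min_tmrca = min(.data$tmrca),
      .groups = "drop"
    )
}

#' Brute-force MRCA scan (oracle)
#'
#' Independent check of [extract_ibd()]: walks a fine grid of positions and,
#' at each, climbs the marginal tree from every sample to find each pair's
#' MRCA directly. Quadratic and only meant for small simulations.
#'
#' @param sim a `genealogy`.
#' @param max_gen as in [extract_ibd()].
#' @param step grid resolution in Morgans.
#' @return A tibble: `position`, `sample_a`, `sample_b`, `mrca`, `tmrca`
#'   for every grid point at which the pair has an MRCA within `max_gen`.
#' @export
ibd_grid_scan <- function(sim, max_gen = 5, step = 0.001) {
  nodes <- sim$nodes
  edges <- sim$edges
  samples <- nodes$id[nodes$is_sample]
  grid <- seq(0, sim$map$axis_length - step / 2, by = step)
  # drop grid points inside spacer gaps: they carry no map distance
  grid <- grid[!is.na(map_chrom_of(sim$map, grid))]
  out <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    x <- grid[gi]
    ed <- edges[edges$left <= x & x < edges$right, ]
    parent_of <- stats::setNames(ed$parent, ed$child)
    anc_list <- lapply(samples, function(s) {
      path <- s
      while (as.character(path[length(path)]) %in% names(parent_of)) {
        path <- c(path, parent_of[[as.character(path[length(path)])]])
      }
      path
    })
    rows <- list()
    for (i in seq_along(samples)) {
      for (j in seq_len(i - 1)) {
        common <- intersect(anc_list[[j]], anc_list[[i]])
        common <- common[nodes$time[match(common, nodes$id)] <= max_gen &
                           nodes$time[match(common, nodes$id)] > 0]
        if (length(common) == 0) next
        tt <- nodes$time[match(common, nodes$id)]
        m <- common[which.min(tt)]
        rows[[length(rows) + 1]] <- tibble::tibble(
          position = x, sample_a = samples[j], sample_b = samples[i],
          mrca = m, tmrca = min(tt)
        )
      }
    }
    out[[gi]] <- dplyr::bind_rows(rows)
  }
  proto <- tibble::tibble(position = numeric(), sample_a = integer(),
                          sample_b = integer(), mrca = integer(),
                          tmrca = numeric())
  dplyr::bind_rows(proto, out)
}

#' Expand IBD segments onto a grid for comparison with [ibd_grid_scan()]
#'
#' @param segments output of [extract_ibd()] (use `min_cm = 0`).
#' @param sim the `genealogy` the segments came from.
#' @param step grid resolution in Morgans.
#' @return A tibble in the same shape as [ibd_grid_scan()].
#' @export
ibd_segments_on_grid <- function(segments, sim, step = 0.001) {
  grid <- seq(0, sim$map$axis_length - step / 2, by = step)
  grid <- grid[!is.na(map_chrom_of(sim$map, grid))]
  out <- lapply(seq_len(nrow(segments)), function(i) {
    g <- grid[segments$left[i] <= grid & grid < segments$right[i]]
    if (length(g) == 0) return(NULL)
    tibble::tibble(position = g, sample_a = segments$sample_a[i],
                   sample_b = segments$sample_b[i], mrca = segments$mrca[i],
                   tmrca = segments$tmrca[i])
  })
  proto <- tibble::tibble(position = numeric(), sample_a = integer(),
                          sample_b = integer(), mrca = integer(),
                          tmrca = numeric())
  dplyr::bind_rows(proto, out) |>
    dplyr::arrange(.data$position, .data$sample_a, .data$sample_b)
}
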