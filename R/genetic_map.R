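#' Build a genetic map on a single concatenated coordinate axis
#'
#' Coordinates throughout the package are genetic (Morgans). Chromosomes are
#' laid end to end on one axis; an optional inter-chromosome `spacer` (in
#' Morgans) separates consecutive chromosomes. The spacer is recombining
#' distance for the Hudson engine -- its linear-rate model cannot represent
#' true independent assortment, so a gap of `spacer` Morgans stands in for it
#' -- whereas the Wright-Fisher meiosis model ignores spacers entirely and
#' flips an independent-assortment coin at every chromosome boundary, so
#' DTWF results do not depend on the spacer value.
#'
#' @param lengths_morgans positive per-chromosome genetic lengths, in Morgans.
#' @param spacer inter-chromosome gap in Morgans (Hudson engine only).
#' @param bp_per_morgan linear scale used when physical (bp) coordinates are
#'   needed, e.g. when writing VCF. Default 1e8 (1 cM/Mb).
#' @return A `genetic_map` object: chromosome intervals on the axis, total
#'   genetic length `L` (excluding spacers) and the axis length.
#' @examples
#' m <- genetic_map(c(1, 0.8), spacer = 0.5)
#' m$L          # 1.8 Morgans of map
#' m$axis_length # 2.3: includes the spacer gap
#' @export
genetic_map <- function(lengths_morgans, spacer = 0, bp_per_morgan = 1e8) {
  if (length(lengths_morgans) < 1 || any(!is.finite(lengths_morgans)) ||
      any(lengths_morgans <= 0)) {
    stop("all chromosome lengths must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(spacer) || spacer < 0) {
    stop("`spacer` must be a non-negative number of Morgans", call. = FALSE)
  }
  n <- length(lengths_morgans)
  start <- cumsum(c(0, lengths_morgans[-n] + spacer))
  structure(
    list(
      lengths = as.numeric(lengths_morgans),
      spacer = spacer,
      bp_per_morgan = bp_per_morgan,
      chrom_start = start,
      chrom_end = start + lengths_morgans,
      L = sum(lengths_morgans),
      axis_length = start[n] + lengths_morgans[n]
    ),
    class = "genetic_map"
  )
}

#' Human-like 22-autosome genetic map
#'
#' A fixture map with realistic sex-averaged genetic lengths for 22
#' autosomes, totalling about 36 Morgans. Lengths are shipped as a versioned
#' TSV fixture (`extdata/human22_genetic_map.tsv`); downstream expectations
#' always use the map's actual lengths, never a hard-coded total.
#'
#' @inheritParams genetic_map
#' @return A [genetic_map()] with 22 chromosomes.
#' @examples
#' m <- human22_map()
#' length(m$lengths) # 22
#' @export
human22_map <- function(spacer = 0.5, bp_per_morgan = 1e8) {
  path <- system.file("extdata", "human22_genetic_map.tsv",
                      package = "wfcoal", mustWork = TRUE)
  tab <- utils::read.delim(path)
  genetic_map(tab$genetic_length_morgans, spacer = spacer,
              bp_per_morgan = bp_per_morgan)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(
    "<genetic_map> %d chromosome(s), L = %.4g Morgans, axis = %.4g (spacer %.3g)\n",
    length(x$lengths), x$L, x$axis_length, x$spacer
  ))
  invisible(x)
}

#' @export
as.data.frame.genetic_map <- function(x, ...) {
  data.frame(
    chromosome = seq_along(x$lengths),
    start = x$chrom_start,
    end = x$chrom_end,
    genetic_length_morgans = x$lengths
  )
}

#' Per-chromosome table of a genetic map
#'
#' @param x a [genetic_map()].
#' @param ... unused.
#' @return A tibble with one row per chromosome: axis start/end and length.
#' @method tidy genetic_map
#' @export
tidy.genetic_map <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

# non-spacer genetic length within [l, r) -- R mirror of the C++ helper
map_glen <- function(map, l, r) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(l) == 0) return(numeric(0))
  gl <- function(a, b) {
    sum(pmax(0, pmin(b, map$chrom_end) - pmax(a, map$chrom_start)))
  }
  mapply(gl, l, r)
}

# chromosome index of axis positions (NA inside a spacer gap)
map_chrom_of <- function(map, x) {
  idx <- findInterval(x, map$chrom_start)
  idx[idx < 1 | x >= map$chrom_end[pmax(idx, 1)]] <- NA_integer_
  idx
}

# axis -> physical bp position (within-chromosome offset scaled linearly)
map_bp_of <- function(map, x) {
  chrom <- map_chrom_of(map, x)
  offset <- x - map$chrom_start[chrom]
  list(chrom = chrom, pos = round(offset * map$bp_per_morgan) + 1)
}

# uniform positions within the non-spacer part of [l, r)
map_runif_positions <- function(map, l, r, k) {
  if (k == 0) return(numeric(0))
  a <- pmax(l, map$chrom_start)
  b <- pmin(r, map$chrom_end)
  w <- pmax(0, b - a)
  tot <- sum(w)
  stopifnot(tot > 0)
  u <- stats::runif(k, 0, tot)
  cw <- cumsum(c(0, w))
  i <- findInterval(u, cw, rightmost.closed = TRUE)
  a[i] + (u - cw[i])
}
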