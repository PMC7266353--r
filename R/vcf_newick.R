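#' Write simulated variants to VCF 4.2
#'
#' Haploid sample columns; `CHROM` is the chromosome index on the map, `POS`
#' the within-chromosome genetic offset scaled by `bp_per_morgan`. Position
#' collisions after rounding are resolved by shifting the later site one bp
#' to the right (with a warning), keeping positions unique as the
#' infinite-sites model requires.
#'
#' @param sim a `genealogy`.
#' @param sites a site table from [drop_mutations()].
#' @param path output file.
#' @param bp_per_morgan physical scale; defaults to the map's.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sim, sites, path, bp_per_morgan = NULL) {
  stopifnot(inherits(sim, "genealogy"))
  map <- sim$map
  if (!is.null(bp_per_morgan)) map$bp_per_morgan <- bp_per_morgan
  if (map$bp_per_morgan <= 0) stop("`bp_per_morgan` must be positive",
                                   call. = FALSE)
  samples <- sim$nodes$id[sim$nodes$is_sample]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=wfcoal",
    sprintf("##contig=<ID=%d,length=%d>", seq_along(map$lengths),
            ceiling(map$lengths * map$bp_per_morgan) + 1),
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("hap", samples)), collapse = "\t")
  )
  lines <- hdr
  if (nrow(sites)) {
    sites <- dplyr::arrange(sites, .data$position)
    bp <- map_bp_of(map, sites$position)
    chrom <- bp$chrom
    pos <- bp$pos
    shifted <- FALSE
    for (i in seq_len(length(pos))[-1]) {
      if (chrom[i] == chrom[i - 1] && pos[i] <= pos[i - 1]) {
        pos[i] <- pos[i - 1] + 1
        shifted <- TRUE
      }
    }
    if (shifted) {
      warning("position collisions after bp rounding were shifted by +1",
              call. = FALSE)
    }
    gt <- vapply(seq_len(nrow(sites)), function(i) {
      g <- integer(length(samples))
      g[match(sites$carriers[[i]], samples)] <- 1L
      paste(g, collapse = "\t")
    }, "")
    lines <- c(lines, sprintf("%d\t%d\t.\tA\tT\t.\tPASS\tAC=%d\tGT\t%s",
                              chrom, pos, sites$count, gt))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Newick string of the marginal tree at a position
#'
#' @param sim a `genealogy`, fully coalesced at `position`.
#' @param position map-axis position in Morgans.
#' @param digits branch-length precision.
#' @return A newick string with branch lengths in generations; sample nodes
#'   are labelled `hap<id>`, internal nodes are unlabelled.
#' @export
write_newick <- function(sim, position, digits = 10) {
  stopifnot(inherits(sim, "genealogy"))
  if (position < 0 || position >= sim$map$axis_length) {
    stop("`position` must lie on the map axis", call. = FALSE)
  }
  ed <- sim$edges[sim$edges$left <= position & position < sim$edges$right, ]
  nodes <- sim$nodes
  kids <- split(ed$child, ed$parent)
  has_parent <- unique(ed$child)
  in_tree <- union(ed$child, ed$parent)
  samples <- nodes$id[nodes$is_sample]
  roots <- setdiff(in_tree, has_parent)
  # samples with no parent edge at this position are unreached roots
  roots <- union(roots, setdiff(samples, has_parent))
  if (length(roots) != 1) {
    stop("position is not fully coalesced: ", length(roots),
         " roots at x = ", position, call. = FALSE)
  }
  tm <- stats::setNames(nodes$time, nodes$id)
  # splice through unary (census) chains: branch lengths span them
  resolve <- function(v) {
    ch <- kids[[as.character(v)]]
    while (!is.null(ch) && length(ch) == 1) {
      v <- ch
      ch <- kids[[as.character(v)]]
    }
    v
  }
  rec <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(sprintf("hap%d", v))
    paste0("(", paste(vapply(ch, function(c) {
      c <- resolve(c)
      paste0(rec(c), ":",
             format(tm[[as.character(v)]] - tm[[as.character(c)]],
                    digits = digits))
    }, ""), collapse = ","), ")")
  }
  paste0(rec(resolve(roots)), ";")
}
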