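#' Write / read genealogy tables
#'
#' Writes `nodes.tsv` and `edges.tsv` (tab-separated, header line, a
#' `#wfcoal-tables v1` version comment, deterministic ordering, full double
#' precision) plus the run configuration, so a simulation round-trips
#' losslessly through disk.
#'
#' @param sim a `genealogy`.
#' @param dir output directory (created if needed).
#' @return `write_tables` returns `dir` invisibly; `read_tables` returns the
#'   `genealogy`.
#' @export
write_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "genealogy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  }
  wr <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#wfcoal-tables v1", con)
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df)) {
      body <- do.call(paste, c(lapply(df, fmt), sep = "\t"))
      writeLines(body, con)
    }
  }
  wr(sim$nodes[c("id", "flags", "time", "population")],
     file.path(dir, "nodes.tsv"))
  wr(sim$edges[c("left", "right", "parent", "child")],
     file.path(dir, "edges.tsv"))
  wr(sim$trace, file.path(dir, "lineages.tsv"))
  write_config(sim$config, file.path(dir, "config.txt"))
  meta <- c(sprintf("fully_coalesced = %s", sim$fully_coalesced),
            sprintf("end_time = %.17g", sim$end_time),
            sprintf("n_extant = %.17g", sim$n_extant))
  writeLines(meta, file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname write_tables
#' @export
read_tables <- function(dir) {
  rd <- function(path, types) {
    head <- readLines(path, n = 1)
    if (!startsWith(head, "#wfcoal-tables")) {
      stop("not a wfcoal table file (missing version header): ", path,
           call. = FALSE)
    }
    df <- utils::read.delim(path, skip = 1, colClasses = types)
    tibble::as_tibble(df)
  }
  nodes <- rd(file.path(dir, "nodes.tsv"),
              c("integer", "integer", "numeric", "integer"))
  edges <- rd(file.path(dir, "edges.tsv"),
              c("numeric", "numeric", "integer", "integer"))
  trace <- rd(file.path(dir, "lineages.tsv"), c("numeric", "numeric"))
  config <- read_config(file.path(dir, "config.txt"))
  meta <- readLines(file.path(dir, "meta.txt"))
  val <- function(key) sub(paste0(key, " = "), "", grep(key, meta, value = TRUE))
  res <- list(
    node_time = nodes$time, node_population = nodes$population - 1L,
    node_flags = nodes$flags,
    edge_left = edges$left, edge_right = edges$right,
    edge_parent = edges$parent, edge_child = edges$child,
    trace_gen = trace$generation, trace_count = trace$lineages,
    fully_coalesced = as.logical(val("fully_coalesced")),
    end_time = as.numeric(val("end_time")),
    n_extant = as.numeric(val("n_extant"))
  )
  new_genealogy(res, config)
}

#' Write IBD / statistics tables
#'
#' Plain TSV writers with a version header, matching [write_tables()].
#'
#' @param x a tibble (IBD segments, pair summaries, lineage counts, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stat_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#wfcoal-tables v1", con)
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.list),
                                      ~ vapply(.x, paste, "", collapse = ",")))
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x)) {
    body <- do.call(paste, c(lapply(x, function(col) {
      if (is.double(col)) sprintf("%.10g", col) else as.character(col)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
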