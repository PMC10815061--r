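# Interval algebra helpers. All pedmapr interval tibbles are 0-based
# half-open [start, end) with a `chrom` column; IRanges (1-based closed)
# does the set operations behind the scenes.

as_iranges0 <- function(tbl) {
  IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
}

iranges_to_tbl0 <- function(ir, chrom) {
  tibble(chrom = chrom,
         start = as.integer(IRanges::start(ir) - 1L),
         end = as.integer(IRanges::end(ir)))
}

#' Union (reduce) of an interval tibble
#'
#' Collapses overlapping or adjacent intervals per chromosome.
#'
#' @param tbl Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Sorted, disjoint interval tibble.
#' @export
reduce_intervals <- function(tbl) {
  if (nrow(tbl) == 0L) return(tibble(chrom = character(), start = integer(),
                                     end = integer()))
  tbl %>%
    dplyr::group_split(.data$chrom) %>%
    purrr::map(function(g) {
      iranges_to_tbl0(IRanges::reduce(as_iranges0(g)), g$chrom[1])
    }) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$start)
}

#' Intersection of a list of interval tibbles
#'
#' Per chromosome, intersects the (reduced) interval sets; chromosomes
#' absent from any one set contribute nothing. An empty input list or any
#' empty member yields an empty result.
#'
#' @param tbls List of interval tibbles (`chrom`, `start`, `end`).
#' @return Sorted, disjoint interval tibble covering the common ground.
#' @export
intersect_interval_sets <- function(tbls) {
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  if (length(tbls) == 0L || any(purrr::map_int(tbls, nrow) == 0L)) return(empty)
  chroms <- Reduce(intersect, purrr::map(tbls, ~ unique(.x$chrom)))
  if (length(chroms) == 0L) return(empty)
  purrr::map(sort(chroms), function(ch) {
    irs <- purrr::map(tbls, function(t) {
      IRanges::reduce(as_iranges0(t[t$chrom == ch, , drop = FALSE]))
    })
    iranges_to_tbl0(Reduce(IRanges::intersect, irs), ch)
  }) %>%
    bind_rows() %>%
    filter(.data$end > .data$start)
}

#' Overlap test of query intervals against subject intervals
#'
#' @param query,subject Interval tibbles (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return Logical vector along `query`: overlaps at least one subject
#'   interval by >= 1 bp.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  out <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sj <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sj) == 0L) next
    hits <- IRanges::overlapsAny(as_iranges0(query[qi, , drop = FALSE]),
                                 as_iranges0(sj))
    out[qi] <- hits
  }
  out
}

#' Jaccard index between two interval sets
#'
#' Base-pair Jaccard similarity: intersection length over union length.
#' Used to score recovery of planted truth regions in simulations.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @return A single number in \[0, 1\]; 1 when both sets are empty.
#' @export
interval_jaccard <- function(a, b) {
  a <- reduce_intervals(a); b <- reduce_intervals(b)
  len <- function(x) sum(as.numeric(x$end - x$start))
  inter <- len(intersect_interval_sets(list(a, b)))
  union <- len(a) + len(b) - inter
  if (union == 0) return(1)
  inter / union
}

#' Read a BED file of intervals
#'
#' Minimal BED3+ reader: chrom, start (0-based), end, optional name.
#'
#' @param path BED file path.
#' @return Interval tibble with `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  f <- stringr::str_split_fixed(lines, "\t", 4)
  out <- tibble(chrom = f[, 1],
                start = as.integer(f[, 2]),
                end = as.integer(f[, 3]))
  if (any(nzchar(f[, 4]))) out$name <- f[, 4]
  out
}

#' Write an interval tibble as BED
#'
#' @param tbl Interval tibble (`chrom`, `start`, `end`, optional `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tbl, path) {
  cols <- list(tbl$chrom, tbl$start, tbl$end)
  if ("name" %in% names(tbl)) cols <- c(cols, list(tbl$name))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}
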