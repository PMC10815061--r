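#' Load a gene prioritization score table
#'
#' Reads an Exomiser-style TSV of gene-level prioritization scores. The
#' scoring tool itself is external; this package only consumes its output
#' and combines it with the IBD shared regions.
#'
#' @param path TSV path (or character vector of lines).
#' @param gene_col,score_col Column names holding the gene symbol and the
#'   score (several tools emit different headers, so both are
#'   configurable). Defaults `"gene"` and `"score"`.
#' @param variants_col Optional column of comma-separated contributing
#'   variant ids.
#' @return Tibble with `gene`, `score` (numeric in \[0, 1\]) and
#'   `variant_ids` (list column, possibly empty). Rows with unparseable
#'   scores are dropped with a message; the count is in the
#'   `n_skipped` attribute.
#' @export
load_gene_scores <- function(path, gene_col = "gene", score_col = "score",
                             variants_col = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("empty gene-score table")
  tab <- utils::read.delim(text = lines, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(gene_col, score_col)) {
    if (!col %in% names(tab)) {
      abort(sprintf("gene-score table lacks required column '%s'", col))
    }
  }
  score <- suppressWarnings(as.numeric(tab[[score_col]]))
  bad <- is.na(score)
  if (any(bad)) {
    inform(sprintf("load_gene_scores: skipped %d row(s) with unparseable scores",
                   sum(bad)))
  }
  out <- tibble(
    gene = as.character(tab[[gene_col]])[!bad],
    score = score[!bad],
    variant_ids = if (!is.null(variants_col) && variants_col %in% names(tab)) {
      strsplit(as.character(tab[[variants_col]])[!bad], ",", fixed = TRUE)
    } else {
      rep(list(character(0)), sum(!bad))
    }
  )
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Apply the prioritization score cutoff
#'
#' Discards genes scoring strictly less than the cutoff (default 0.5) and
#' sorts the survivors by descending score for reporting.
#'
#' @param scores Gene-score tibble ([load_gene_scores()]).
#' @param cutoff Minimum retained score; genes with `score >= cutoff` pass.
#' @return Filtered tibble sorted by descending score.
#' @export
filter_by_score <- function(scores, cutoff = 0.5) {
  scores %>%
    filter(.data$score >= cutoff) %>%
    arrange(dplyr::desc(.data$score))
}

#' Restrict scored genes to the IBD shared regions
#'
#' Keeps genes whose interval overlaps at least one base pair of any shared
#' region. Genes without a mapped interval cannot be placed and are dropped
#' with a message.
#'
#' @param scores Gene-score tibble.
#' @param regions Shared-region tibble (`chrom`, `start`, `end`).
#' @param gene_intervals Interval tibble (`chrom`, `start`, `end`, `name`)
#'   mapping gene symbols (matched against `name`) to coordinates.
#' @return The subset of `scores` for genes overlapping a region.
#' @export
genes_in_regions <- function(scores, regions, gene_intervals) {
  if (!"name" %in% names(gene_intervals)) {
    abort("gene_intervals needs a 'name' column of gene symbols")
  }
  unmapped <- setdiff(scores$gene, gene_intervals$name)
  if (length(unmapped)) {
    inform(sprintf("genes_in_regions: %d scored gene(s) have no interval and are dropped",
                   length(unmapped)))
  }
  if (nrow(regions) == 0L) return(scores[0, , drop = FALSE])
  hit <- overlaps_any(gene_intervals, regions)
  in_region <- unique(gene_intervals$name[hit])
  scores %>% filter(.data$gene %in% in_region)
}

#' Prioritize candidate genes within IBD shared regions
#'
#' Convenience composition of [genes_in_regions()] then
#' [filter_by_score()]: the externally scored gene list is restricted to
#' the regions shared identical-by-descent by all affected relatives, and
#' genes below the score cutoff are discarded.
#'
#' @inheritParams genes_in_regions
#' @inheritParams filter_by_score
#' @return Candidate gene tibble sorted by descending score.
#' @export
prioritize_candidates <- function(scores, regions, gene_intervals,
                                  cutoff = 0.5) {
  scores %>%
    genes_in_regions(regions, gene_intervals) %>%
    filter_by_score(cutoff = cutoff)
}
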