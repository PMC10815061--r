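#' Run the full family-mapping pipeline
#'
#' Orchestrates the stages: read (or accept) filtered genotype calls,
#' pairwise IBD segmentation, intersection into shared regions, candidate
#' gene prioritization, multi-caller SV consensus with dominant-model and
#' phenotype filtering, and reporter-assay statistics. Every threshold used
#' and the count surviving each filter step are recorded in the report, so
#' the whole funnel from raw sites to candidates is auditable.
#'
#' All inputs are tibbles (or paths): the pipeline is a pure function of
#' its inputs and parameters, so a rerun on the same inputs reproduces the
#' same report.
#'
#' @param vcf Path to a multi-sample VCF, or a calls tibble from
#'   [read_vcf_genotypes()] / [simulate_family()].
#' @param ped Path to a PED file, or a pedigree tibble.
#' @param gene_scores Optional gene-score tibble or TSV path
#'   ([load_gene_scores()]).
#' @param gene_intervals Optional gene interval tibble or BED path.
#' @param sv_callsets Optional SV call tibble (with `caller` column), list
#'   of tibbles, or named list of VCF paths.
#' @param phenotype_genes Optional character vector of phenotype-related
#'   genes for SV filtering; defaults to all scored genes passing the
#'   cutoff.
#' @param assay Optional measurement tibble or CSV path
#'   ([analyze_reporter_assay()]).
#' @param thresholds Named list overriding filter thresholds: `min_dp`,
#'   `min_gq`, `require_alt_support`.
#' @param seg_params A [segmentation_params()] list.
#' @param sv_params A [merge_params()] list.
#' @param score_cutoff Gene-score cutoff (default 0.5).
#' @param exclude_unaffected_id Optional sample id of an unaffected member
#'   whose shared ground is subtracted from the regions.
#' @param assay_alternative Alternative hypothesis for the assay test.
#' @return A list of class `pedmapr_report`: `counts` (named funnel
#'   vector), `params`, `regions`, `segments`, `candidates`, `svs`,
#'   `assay`, `summary` (one-row region summary tibble).
#' @export
run_pipeline <- function(vcf, ped,
                         gene_scores = NULL, gene_intervals = NULL,
                         sv_callsets = NULL, phenotype_genes = NULL,
                         assay = NULL,
                         thresholds = list(),
                         seg_params = segmentation_params(),
                         sv_params = merge_params(),
                         score_cutoff = 0.5,
                         exclude_unaffected_id = NULL,
                         assay_alternative = "two.sided") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  thr <- utils::modifyList(
    list(min_dp = 14L, min_gq = 30L, require_alt_support = TRUE), thresholds)

  ped <- stage("pedigree", {
    if (is.character(ped)) read_pedigree(ped) else ped
  })
  calls <- stage("vcf", {
    if (is.character(vcf)) {
      if (!file.exists(vcf)) abort(sprintf("VCF not found: %s", vcf))
      read_vcf_genotypes(vcf)
    } else vcf
  })
  n_sites_in <- dplyr::n_distinct(paste(calls$chrom, calls$pos))

  filtered <- stage("filter", {
    filter_sites(calls, ped, min_dp = thr$min_dp, min_gq = thr$min_gq,
                 require_alt_support = thr$require_alt_support)
  })
  funnel <- attr(filtered, "filter_funnel")

  segments <- stage("ibd", ibd_segments_all(filtered, ped, seg_params))
  regions <- stage("ibd", shared_regions(segments, ped))
  if (!is.null(exclude_unaffected_id)) {
    regions <- stage("ibd", exclude_unaffected(
      regions, filtered, ped, exclude_unaffected_id, seg_params))
  }

  gene_intervals <- stage("annotation", {
    if (is.character(gene_intervals)) read_bed(gene_intervals)
    else gene_intervals
  })
  gene_scores <- stage("prioritize", {
    if (is.character(gene_scores)) load_gene_scores(gene_scores)
    else gene_scores
  })
  candidates <- NULL
  if (!is.null(gene_scores) && !is.null(gene_intervals)) {
    candidates <- stage("prioritize", prioritize_candidates(
      gene_scores, regions, gene_intervals, cutoff = score_cutoff))
  }

  svs <- NULL
  if (!is.null(sv_callsets)) {
    svs <- stage("svmerge", {
      callsets <- if (is.character(sv_callsets)) {
        purrr::imap(sv_callsets, ~ read_sv_vcf(.x, .y))
      } else sv_callsets
      merged <- merge_callsets(callsets, sv_params)
      merged <- dominant_model_filter(merged, ped)
      if (is.null(phenotype_genes) && !is.null(candidates)) {
        phenotype_genes <- candidates$gene
      }
      if (!is.null(phenotype_genes) && !is.null(gene_intervals)) {
        merged <- annotate_and_filter_svs(
          merged, gene_intervals, phenotype_genes, ibd_regions = regions)
      }
      merged
    })
  }

  assay_res <- NULL
  if (!is.null(assay)) {
    assay_res <- stage("assay", {
      if (is.character(assay)) assay <- as_tibble(utils::read.csv(assay))
      analyze_reporter_assay(assay, alternative = assay_alternative)
    })
  }

  summ <- summarize_regions(regions, gene_intervals)
  counts <- c(
    sites_read = n_sites_in,
    sites_pass_call_qc = unname(funnel["pass_call_qc"]),
    sites_pass_mendelian = unname(funnel["pass_mendelian"]),
    n_segments = nrow(segments),
    n_shared_regions = nrow(regions),
    shared_bp = summ$total_bp,
    n_genes_in_regions = summ$n_genes,
    n_candidate_genes = if (is.null(candidates)) NA_integer_ else nrow(candidates),
    n_candidate_svs = if (is.null(svs)) NA_integer_ else nrow(svs)
  )
  structure(list(
    counts = counts,
    params = list(thresholds = thr, seg_params = seg_params,
                  sv_params = sv_params, score_cutoff = score_cutoff),
    segments = segments, regions = regions, candidates = candidates,
    svs = svs, assay = assay_res, summary = summ
  ), class = "pedmapr_report")
}

#' @export
print.pedmapr_report <- function(x, ...) {
  cat("pedmapr pipeline report\n")
  cat("  filter funnel:\n")
  for (nm in names(x$counts)) {
    if (!is.na(x$counts[[nm]])) {
      cat(sprintf("    %-22s %s\n", nm, format(x$counts[[nm]], big.mark = ",")))
    }
  }
  if (!is.null(x$candidates) && nrow(x$candidates)) {
    cat("  top candidates:",
        paste(utils::head(x$candidates$gene, 5), collapse = ", "), "\n")
  }
  if (!is.null(x$assay)) {
    cat(sprintf("  assay: p = %.4g, r = %.3f (%s)\n",
                x$assay$test$p_value, x$assay$test$effect_size_r,
                x$assay$test$method))
  }
  invisible(x)
}
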