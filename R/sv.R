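#' Merge parameters for multi-caller SV consensus
#'
#' Two calls are considered the same event when they lie on the same
#' chromosome, (optionally) have the same SV type, overlap reciprocally by
#' at least `min_reciprocal_overlap`, and their matched breakends are at
#' most `max_breakend_distance_bp` apart. The defaults (50% reciprocal
#' overlap, 1000 bp) are the thresholds used for consensus merging of
#' Manta/Lumpy/CNVnator-style call sets.
#'
#' @param min_reciprocal_overlap Minimum reciprocal overlap in \[0, 1\].
#' @param max_breakend_distance_bp Maximum distance between matched
#'   breakends, in bp.
#' @param require_same_type Only merge calls of the same SVTYPE.
#' @param both_breakends If `TRUE` (default) both the start-start and the
#'   end-end distances must satisfy the threshold; if `FALSE`, either.
#' @return A named list of class `merge_params`.
#' @export
merge_params <- function(min_reciprocal_overlap = 0.5,
                         max_breakend_distance_bp = 1000L,
                         require_same_type = TRUE,
                         both_breakends = TRUE) {
  stopifnot(min_reciprocal_overlap >= 0, min_reciprocal_overlap <= 1,
            max_breakend_distance_bp >= 0)
  structure(list(min_reciprocal_overlap = min_reciprocal_overlap,
                 max_breakend_distance_bp = as.numeric(max_breakend_distance_bp),
                 require_same_type = isTRUE(require_same_type),
                 both_breakends = isTRUE(both_breakends)),
            class = "merge_params")
}

#' Reciprocal overlap of two intervals
#'
#' `min(overlap/len(a), overlap/len(b))`; 0 when disjoint or on different
#' chromosomes. Vectorized.
#'
#' @param start1,end1,start2,end2 0-based half-open interval coordinates.
#' @param chrom1,chrom2 Optional chromosome labels; a mismatch gives 0.
#' @return Numeric in \[0, 1\].
#' @examples
#' reciprocal_overlap(1000, 2000, 1400, 2400)  # 0.6
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2,
                               chrom1 = NULL, chrom2 = NULL) {
  if (any(end1 <= start1) || any(end2 <= start2)) {
    abort("reciprocal_overlap requires positive-length intervals")
  }
  ov <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  ro <- pmin(ov / (end1 - start1), ov / (end2 - start2))
  if (!is.null(chrom1) && !is.null(chrom2)) {
    ro[chrom1 != chrom2] <- 0
  }
  ro
}

#' Distances between matched breakends of two intervals
#'
#' @inheritParams reciprocal_overlap
#' @return Tibble with columns `start_dist` and `end_dist`.
#' @examples
#' breakend_distances(1000, 2000, 1400, 2400)  # 400, 400
#' @export
breakend_distances <- function(start1, end1, start2, end2,
                               chrom1 = NULL, chrom2 = NULL) {
  if (!is.null(chrom1) && !is.null(chrom2) && any(chrom1 != chrom2)) {
    abort("breakend distances are undefined across chromosomes")
  }
  tibble(start_dist = abs(start1 - start2), end_dist = abs(end1 - end2))
}

#' Are two SV calls mergeable?
#'
#' Applies the consensus rule of [merge_params()]. For insertions and
#' breakend (`INS`/`BND`) records, whose interval length is not meaningful,
#' only the breakend-distance condition applies.
#'
#' @param a,b SV call tibbles (equal length or length 1, recycled) with
#'   columns `chrom`, `start`, `end`, `svtype`.
#' @param params A [merge_params()] list.
#' @return Logical vector; symmetric in `a` and `b`.
#' @export
sv_mergeable <- function(a, b, params = merge_params()) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L) b <- b[rep(1L, n), ]
  ok <- a$chrom == b$chrom
  if (params$require_same_type) ok <- ok & (a$svtype == b$svtype)
  d <- tibble(start_dist = abs(a$start - b$start),
              end_dist = abs(a$end - b$end))
  dist_ok <- if (params$both_breakends) {
    d$start_dist <= params$max_breakend_distance_bp &
      d$end_dist <= params$max_breakend_distance_bp
  } else {
    d$start_dist <= params$max_breakend_distance_bp |
      d$end_dist <= params$max_breakend_distance_bp
  }
  breakend_only <- a$svtype %in% c("INS", "BND") | b$svtype %in% c("INS", "BND")
  ro <- reciprocal_overlap(a$start, a$end, b$start, b$end)
  ro_ok <- breakend_only | ro >= params$min_reciprocal_overlap
  ok & dist_ok & ro_ok
}

#' Per-caller hard filtering of SV calls
#'
#' Each SV caller publishes its own recommended hard filters; they are
#' expressed here as configuration, not code. The shipped default requires
#' the `PASS` filter flag where a flag is present.
#'
#' @param calls SV call tibble with at least `caller`, `filter`, `quality`.
#' @param config Named list: caller name -> list with optional elements
#'   `require_pass` (logical) and `min_quality` (numeric). Callers without
#'   an entry pass through with a warning.
#' @return The retained calls.
#' @export
caller_hard_filter <- function(calls,
                               config = list()) {
  unknown <- setdiff(unique(calls$caller), names(config))
  if (length(unknown)) {
    warn(sprintf("no hard-filter config for caller(s) %s; passing through",
                 paste(unknown, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(calls))
  for (cl in intersect(names(config), unique(calls$caller))) {
    idx <- calls$caller == cl
    cfg <- config[[cl]]
    if (isTRUE(cfg$require_pass)) {
      flag <- calls$filter[idx]
      keep[idx] <- keep[idx] & (is.na(flag) | flag %in% c("PASS", "."))
    }
    if (!is.null(cfg$min_quality)) {
      q <- calls$quality[idx]
      keep[idx] <- keep[idx] & (is.na(q) | q >= cfg$min_quality)
    }
  }
  calls[keep, , drop = FALSE]
}

#' Merge multi-caller SV call sets into consensus events
#'
#' Single-linkage clustering under [sv_mergeable()] within chromosome (and
#' SV type, when required): two calls end up in the same consensus event
#' when they are connected by a chain of pairwise-mergeable calls. The
#' consensus interval is the per-coordinate median of the members; the
#' per-sample consensus genotype is the most severe non-missing member
#' genotype (`hom` > `het` > `ref`).
#'
#' @param callsets One SV call tibble with a `caller` column, or a list of
#'   per-caller tibbles. Expected columns: `chrom`, `start`, `end`,
#'   `svtype`, `caller`, optional `quality`, `filter`, and a `genotypes`
#'   list column of named vectors with values
#'   `"ref"`/`"het"`/`"hom"`/`"missing"`.
#' @param params A [merge_params()] list.
#' @param min_callers Keep only consensus events supported by at least this
#'   many distinct callers (default 1: single-caller events are retained).
#' @return Tibble of merged SVs sorted by consensus start: `chrom`,
#'   `start`, `end`, `svtype`, `n_callers`, `callers`, `n_members`,
#'   `genotypes` (list), `members` (list of member-call tibbles).
#' @export
merge_callsets <- function(callsets, params = merge_params(),
                           min_callers = 1L) {
  calls <- if (is.data.frame(callsets)) callsets else bind_rows(callsets)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  svtype = character(), n_callers = integer(),
                  callers = character(), n_members = integer(),
                  genotypes = list(), members = list())
  if (nrow(calls) == 0L) return(empty)
  if (!"genotypes" %in% names(calls)) {
    calls$genotypes <- rep(list(character(0)), nrow(calls))
  }
  grp_key <- if (params$require_same_type) {
    paste(calls$chrom, calls$svtype)
  } else {
    calls$chrom
  }
  clusters <- purrr::map(split(seq_len(nrow(calls)), grp_key), function(idx) {
    g <- calls[idx, , drop = FALSE]
    n <- nrow(g)
    if (n == 1L) return(list(idx))
    cmb <- combn(n, 2)
    merge_ok <- sv_mergeable(g[cmb[1, ], ], g[cmb[2, ], ], params)
    el <- cbind(cmb[1, merge_ok], cmb[2, merge_ok])
    gr <- igraph::graph_from_edgelist(el, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership
    purrr::map(seq_len(max(comp)), ~ idx[comp == .x])
  }) %>% purrr::flatten()

  merged <- purrr::map(clusters, function(idx) {
    m <- calls[idx, , drop = FALSE]
    tibble(
      chrom = m$chrom[1],
      start = as.integer(round(median(m$start))),
      end = as.integer(round(median(m$end))),
      svtype = m$svtype[1],
      n_callers = dplyr::n_distinct(m$caller),
      callers = paste(sort(unique(m$caller)), collapse = ","),
      n_members = nrow(m),
      genotypes = list(consensus_genotypes(m$genotypes)),
      members = list(m)
    )
  }) %>% bind_rows()
  merged %>%
    filter(.data$n_callers >= min_callers) %>%
    arrange(.data$chrom, .data$start, .data$svtype)
}

consensus_genotypes <- function(gt_list) {
  samples <- unique(unlist(purrr::map(gt_list, names)))
  if (length(samples) == 0L) return(character(0))
  severity <- c(missing = 0, ref = 1, het = 2, hom = 3)
  out <- purrr::map_chr(samples, function(s) {
    vals <- purrr::map_chr(gt_list, ~ .x[s] %||% "missing")
    vals[is.na(vals)] <- "missing"
    vals_known <- vals[vals != "missing"]
    if (length(vals_known) == 0L) return("missing")
    names(which.max(severity[vals_known]))
  })
  setNames(out, samples)
}

#' Dominant-model inheritance filter for merged SVs
#'
#' Retains consensus events carried (het or hom) by every affected
#' sequenced member and absent (ref) from every unaffected sequenced
#' member. A missing genotype is non-informative and never rejects on its
#' own — callers without genotyping (e.g. read-depth CNV callers) must not
#' veto an otherwise segregating event.
#'
#' @param merged Merged SV tibble from [merge_callsets()].
#' @param ped Pedigree tibble.
#' @return The subset of `merged` compatible with dominant segregation.
#' @export
dominant_model_filter <- function(merged, ped) {
  if (nrow(merged) == 0L) return(merged)
  aff <- ped$id[!is.na(ped$affected) & ped$affected]
  unaff <- ped$id[!is.na(ped$affected) & !ped$affected]
  keep <- purrr::map_lgl(merged$genotypes, function(g) {
    ga <- g[intersect(names(g), aff)]
    gu <- g[intersect(names(g), unaff)]
    !any(ga == "ref") && !any(gu %in% c("het", "hom"))
  })
  merged[keep, , drop = FALSE]
}

#' Annotate merged SVs and apply the phenotype/IBD rejection rules
#'
#' Annotates each consensus event with overlapping genes, regulatory
#' elements, the maximum overlapping population frequency, and whether it
#' falls inside an IBD shared region; then rejects events that do not
#' overlap at least one phenotype-related gene and (when IBD regions are
#' supplied) events outside the shared regions.
#'
#' @param merged Merged SV tibble.
#' @param gene_intervals Gene interval tibble (`chrom`, `start`, `end`,
#'   `name`).
#' @param phenotype_genes Character vector of phenotype-related gene
#'   symbols (e.g. from an external phenotype-prioritization tool).
#' @param regulatory_intervals Optional regulatory-element intervals.
#' @param freq_table Optional population-frequency intervals with a `freq`
#'   column.
#' @param ibd_regions Optional shared-region tibble; when given, events
#'   outside every region are rejected.
#' @return Annotated, filtered tibble with added columns `genes`,
#'   `regulatory`, `max_freq`, `phenotype_genes`, `in_ibd_region`.
#' @export
annotate_and_filter_svs <- function(merged, gene_intervals,
                                    phenotype_genes,
                                    regulatory_intervals = NULL,
                                    freq_table = NULL,
                                    ibd_regions = NULL) {
  if (nrow(merged) == 0L) return(merged)
  iv <- merged %>% select("chrom", "start", "end")
  overlap_names <- function(track) {
    if (is.null(track) || nrow(track) == 0L) {
      return(rep(list(character(0)), nrow(merged)))
    }
    purrr::map(seq_len(nrow(merged)), function(i) {
      hit <- overlaps_any(track, iv[i, , drop = FALSE])
      unique(track$name[hit])
    })
  }
  merged$genes <- overlap_names(gene_intervals)
  merged$regulatory <- overlap_names(regulatory_intervals)
  merged$max_freq <- if (is.null(freq_table) || nrow(freq_table) == 0L) {
    NA_real_
  } else {
    purrr::map_dbl(seq_len(nrow(merged)), function(i) {
      hit <- overlaps_any(freq_table, iv[i, , drop = FALSE])
      if (any(hit)) max(freq_table$freq[hit]) else 0
    })
  }
  if (length(phenotype_genes) == 0L) {
    warn("empty phenotype gene list: every SV will be rejected")
  }
  merged$phenotype_genes <- purrr::map(merged$genes,
                                       ~ intersect(.x, phenotype_genes))
  merged$in_ibd_region <- if (is.null(ibd_regions)) {
    NA
  } else {
    overlaps_any(iv, ibd_regions)
  }
  keep <- lengths(merged$phenotype_genes) > 0L
  if (!is.null(ibd_regions)) keep <- keep & merged$in_ibd_region
  merged[keep, , drop = FALSE]
}

#' Read a structural-variant VCF into a call tibble
#'
#' Parses symbolic-ALT SV records (SVTYPE/END INFO keys) from one caller.
#' Genotypes are collapsed to carrier states: `ref`, `het`, `hom`, or
#' `missing` (also used for callers that do not genotype).
#'
#' @param path VCF path.
#' @param caller Caller name recorded in the `caller` column.
#' @return SV call tibble compatible with [merge_callsets()].
#' @export
read_sv_vcf <- function(path, caller) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  svtype = character(), caller = character(),
                  quality = double(), filter = character(),
                  genotypes = list()))
  }
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svend <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  pos <- as.integer(fix$POS)
  start <- pos
  end <- ifelse(is.na(svend), start + 1L, svend)
  end <- ifelse(svtype %in% c("INS", "BND"), start + 1L, end)

  gts <- rep(list(character(0)), nrow(fix))
  if (!is.null(v@gt) && ncol(v@gt) > 1L) {
    gt_raw <- vcfR::extract.gt(v, element = "GT")
    samples <- colnames(gt_raw)
    gts <- purrr::map(seq_len(nrow(fix)), function(i) {
      al <- parse_gt(gt_raw[i, ])
      state <- ifelse(is.na(al[, 1]) | is.na(al[, 2]), "missing",
               ifelse(al[, 1] > 0 & al[, 2] > 0, "hom",
               ifelse(al[, 1] > 0 | al[, 2] > 0, "het", "ref")))
      setNames(state, samples)
    })
  }
  tibble(
    chrom = fix$CHROM, start = start, end = as.integer(end),
    svtype = as.character(svtype), caller = caller,
    quality = suppressWarnings(as.numeric(fix$QUAL)),
    filter = fix$FILTER, genotypes = gts
  )
}
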