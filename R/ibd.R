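#' Allelic ratio and pairwise allelic-ratio difference
#'
#' The allelic ratio of a call is the fraction of reads supporting the
#' alternate allele, `ad_alt / dp`. The pairwise statistic underlying the
#' IBD analysis is the absolute difference between the two patients'
#' allelic ratios at a site: near 0 when the two carry the same alleles in
#' the same dose, near 1 for opposite homozygotes.
#'
#' @param ad_alt Alternate-allele read count(s).
#' @param dp Total read depth(s); must be positive.
#' @return `allelic_ratio()`: numeric in \[0, 1\]. `ratio_diff()`: numeric
#'   in \[0, 1\], symmetric in its two calls.
#' @examples
#' allelic_ratio(10, 20)            # 0.5
#' ratio_diff(15, 20, 5, 20)        # |0.75 - 0.25| = 0.5
#' @export
allelic_ratio <- function(ad_alt, dp) {
  if (any(is.na(dp)) || any(dp <= 0)) {
    abort("allelic_ratio requires dp > 0")
  }
  if (any(is.na(ad_alt))) abort("allelic_ratio requires AD")
  ad_alt / dp
}

#' @rdname allelic_ratio
#' @param ad_alt1,dp1,ad_alt2,dp2 AD and DP for the two calls of the pair.
#' @export
ratio_diff <- function(ad_alt1, dp1, ad_alt2, dp2) {
  abs(allelic_ratio(ad_alt1, dp1) - allelic_ratio(ad_alt2, dp2))
}

#' Number of alleles shared between two diploid genotypes
#'
#' Size of the maximum matching between the two allele multisets: 0 for
#' opposite homozygotes, 1 for e.g. 0/0 vs 0/1, 2 for identical unordered
#' genotypes. This is the per-site IBD state upper bound (IBD0/1/2).
#'
#' @param gt1,gt2 Genotypes as `"a/b"` strings (vectorized) or length-2
#'   integer vectors. Missing genotypes are an error.
#' @return Integer vector with values in 0:2.
#' @examples
#' shared_allele_count("0/0", "0/1")  # 1
#' shared_allele_count("0/1", "1/0")  # 2 (unordered)
#' @export
shared_allele_count <- function(gt1, gt2) {
  g1 <- gt_alleles(gt1); g2 <- gt_alleles(gt2)
  if (nrow(g1) == 1L && nrow(g2) > 1L) g1 <- g1[rep(1L, nrow(g2)), , drop = FALSE]
  if (nrow(g2) == 1L && nrow(g1) > 1L) g2 <- g2[rep(1L, nrow(g1)), , drop = FALSE]
  if (anyNA(g1) || anyNA(g2)) abort("shared_allele_count requires non-missing genotypes")
  shared_count_int(g1[, 1], g1[, 2], g2[, 1], g2[, 2])
}

# multiset-intersection size for allele-index columns (no NA)
shared_count_int <- function(a1, a2, b1, b2) {
  a_hom <- a1 == a2
  b_hom <- b1 == b2
  out <- ifelse(a_hom & b_hom, 2L * (a1 == b1),
         ifelse(a_hom, (a1 == b1) + (a1 == b2),
         ifelse(b_hom, (b1 == a1) + (b1 == a2),
                ((a1 == b1) | (a1 == b2)) + ((a2 == b1) | (a2 == b2)))))
  as.integer(unname(out))
}

#' Is a site informative for a pair?
#'
#' Pairs with identical (unordered) genotypes carry no information about
#' which parental haplotype was transmitted and are filtered out as
#' non-informative; so are sites where either genotype is missing.
#'
#' @inheritParams shared_allele_count
#' @return Logical vector.
#' @export
pair_site_informative <- function(gt1, gt2) {
  g1 <- gt_alleles(gt1); g2 <- gt_alleles(gt2)
  if (nrow(g1) == 1L && nrow(g2) > 1L) g1 <- g1[rep(1L, nrow(g2)), , drop = FALSE]
  if (nrow(g2) == 1L && nrow(g1) > 1L) g2 <- g2[rep(1L, nrow(g1)), , drop = FALSE]
  miss <- is.na(g1[, 1]) | is.na(g1[, 2]) | is.na(g2[, 1]) | is.na(g2[, 2])
  same <- (pmin(g1[, 1], g1[, 2]) == pmin(g2[, 1], g2[, 2])) &
    (pmax(g1[, 1], g1[, 2]) == pmax(g2[, 1], g2[, 2]))
  !miss & !same
}

#' Segmentation parameters for pairwise IBD detection
#'
#' The run-based segmentation classifies each informative site of a pair as
#' concordant (sharing at least one allele and allelic-ratio difference at
#' most `max_ratio_diff`) or discordant, and emits maximal runs of
#' concordant sites tolerating up to `max_discordant_run` consecutive
#' discordant sites. Identical-genotype sites are concordant context: they
#' never break a run but do not count towards `min_sites`.
#'
#' Defaults are tuned for ~30x short-read data: `max_ratio_diff = 0.8`
#' sits between the expected difference at sites sharing one allele
#' (about 0.5 plus binomial noise) and at opposite homozygotes (about
#' 0.96); `max_discordant_run = 1` requires two consecutive discordant
#' sites to end a segment, so isolated genotyping errors are tolerated
#' while true non-IBD ground (where nearly one site in ten is an
#' opposite-homozygote) terminates segments within a few markers.
#' `min_sites` counts *supporting* sites — concordant informative plus
#' identical-genotype context — because a region where the pair shares both
#' alleles (IBD2) consists almost entirely of identical genotypes and has
#' few or no informative sites, yet is genuinely shared.
#' `max_discordant_frac` rejects segments whose overall discordant-site
#' fraction betrays non-IBD ground that merely lacked two adjacent
#' discordant markers.
#'
#' @param max_ratio_diff Discordance threshold on the allelic-ratio
#'   difference, in (0, 1).
#' @param max_discordant_run Longest run of consecutive discordant sites
#'   tolerated inside a segment.
#' @param min_sites Minimum supporting (non-discordant, non-missing) sites
#'   a segment must contain.
#' @param min_span_bp Minimum segment span in base pairs.
#' @param max_discordant_frac Maximum fraction of discordant sites within a
#'   segment.
#' @param end_trim_frac Segment ends are trimmed back over any terminal
#'   stretch whose discordant-site fraction reaches this value (with at
#'   least two discordant sites): the local discordance density at a
#'   segment boundary distinguishes residual non-IBD ground from the
#'   near-zero discordance inside true segments.
#' @param window_sites,window_max_disc Sliding-window separator: any window
#'   of `window_sites` consecutive sites containing more than
#'   `window_max_disc` discordant sites also separates segments. This
#'   catches short non-IBD gaps whose discordant sites happen never to be
#'   adjacent, which the run rule alone would bridge.
#' @return A named list of class `segmentation_params`.
#' @export
segmentation_params <- function(max_ratio_diff = 0.8, max_discordant_run = 1L,
                                min_sites = 25L, min_span_bp = 500000L,
                                max_discordant_frac = 0.03,
                                end_trim_frac = 0.04,
                                window_sites = 30L, window_max_disc = 2L) {
  stopifnot(max_ratio_diff > 0, max_ratio_diff < 1,
            max_discordant_run >= 0, min_sites >= 0, min_span_bp >= 0,
            max_discordant_frac >= 0, max_discordant_frac <= 1,
            end_trim_frac > 0, end_trim_frac <= 1,
            window_sites >= 2, window_max_disc >= max_discordant_run)
  structure(list(max_ratio_diff = max_ratio_diff,
                 max_discordant_run = as.integer(max_discordant_run),
                 min_sites = as.integer(min_sites),
                 min_span_bp = as.integer(min_span_bp),
                 max_discordant_frac = max_discordant_frac,
                 end_trim_frac = end_trim_frac,
                 window_sites = as.integer(window_sites),
                 window_max_disc = as.integer(window_max_disc)),
            class = "segmentation_params")
}

#' Pairwise IBD segments from filtered genotype calls
#'
#' Runs the allele-balance segmentation for one pair of samples over a
#' filtered calls tibble (see [filter_sites()]). Sites must be sorted by
#' position within chromosome.
#'
#' @param calls Filtered genotype tibble (long, one row per site x sample).
#' @param id1,id2 The two sample ids of the pair.
#' @param params A [segmentation_params()] list.
#' @return Tibble of segments: `chrom`, `start`, `end` (0-based half-open,
#'   trimmed to the outermost concordant sites), `id1`, `id2`, `pair`,
#'   `n_informative_sites`, `n_supporting_sites`, `discordant_frac`,
#'   `mean_ratio_diff`, `min_shared_alleles` (2 for pure identical-genotype
#'   IBD2 segments, otherwise the minimum over informative sites).
#' @export
ibd_segments <- function(calls, id1, id2, params = segmentation_params()) {
  ids <- sort(c(id1, id2))
  wide <- pair_table(calls, ids[1], ids[2])
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  id1 = character(), id2 = character(), pair = character(),
                  n_informative_sites = integer(),
                  n_supporting_sites = integer(), discordant_frac = double(),
                  mean_ratio_diff = double(), min_shared_alleles = integer())
  if (nrow(wide) == 0L) return(empty)
  out <- wide %>%
    dplyr::group_split(.data$chrom) %>%
    purrr::map(~ segment_one_chrom(.x, params)) %>%
    bind_rows()
  if (nrow(out) == 0L) return(empty)
  out %>%
    mutate(id1 = ids[1], id2 = ids[2], pair = paste(ids[1], ids[2], sep = "|")) %>%
    select("chrom", "start", "end", "id1", "id2", "pair",
           "n_informative_sites", "n_supporting_sites", "discordant_frac",
           "mean_ratio_diff", "min_shared_alleles") %>%
    arrange(.data$chrom, .data$start)
}

pair_table <- function(calls, id1, id2) {
  c1 <- calls %>% filter(.data$sample == id1)
  c2 <- calls %>% filter(.data$sample == id2)
  dplyr::inner_join(
    c1 %>% select("chrom", "pos", a1_1 = "a1", a2_1 = "a2",
                  ad_alt1 = "ad_alt", dp1 = "dp"),
    c2 %>% select("chrom", "pos", a1_2 = "a1", a2_2 = "a2",
                  ad_alt2 = "ad_alt", dp2 = "dp"),
    by = c("chrom", "pos")
  )
}

segment_one_chrom <- function(w, params) {
  if (is.unsorted(w$pos)) abort("sites must be sorted by position within chromosome")
  w <- w %>% filter(!is.na(.data$a1_1), !is.na(.data$a2_1),
                    !is.na(.data$a1_2), !is.na(.data$a2_2),
                    .data$dp1 > 0, .data$dp2 > 0)
  if (nrow(w) == 0L) return(NULL)
  identical_gt <- (pmin(w$a1_1, w$a2_1) == pmin(w$a1_2, w$a2_2)) &
    (pmax(w$a1_1, w$a2_1) == pmax(w$a1_2, w$a2_2))
  shared <- shared_count_int(w$a1_1, w$a2_1, w$a1_2, w$a2_2)
  rd <- ratio_diff(w$ad_alt1, w$dp1, w$ad_alt2, w$dp2)
  cls <- ifelse(identical_gt, "ctx",
                ifelse(shared == 0L | rd > params$max_ratio_diff,
                       "disc", "info"))

  # blocks are separated by (a) runs of > max_discordant_run consecutive
  # discordant sites and (b) windows of window_sites sites holding more
  # than window_max_disc discordant sites; separator sites are in no block
  d <- cls == "disc"
  n <- length(d)
  r <- rle(d)
  sep <- rep(r$values & r$lengths > params$max_discordant_run, r$lengths)
  w_len <- params$window_sites
  if (n >= w_len) {
    cs <- c(0L, cumsum(d))
    cnt <- cs[(w_len + 1L):(n + 1L)] - cs[1:(n - w_len + 1L)]
    flagged <- logical(n)
    for (i in which(cnt > params$window_max_disc)) {
      flagged[i:(i + w_len - 1L)] <- TRUE
    }
    # discordant sites inside dense windows separate; the short concordant
    # stretches between them fall below min_sites/min_span and drop out
    sep <- sep | (d & flagged)
  }
  rs <- rle(sep)
  block_of_run <- cumsum(rs$values)
  block <- rep(ifelse(rs$values, NA_integer_, block_of_run), rs$lengths)

  segs <- tibble(pos = w$pos, cls = cls, shared = shared, rd = rd,
                 block = block) %>%
    filter(!is.na(.data$block)) %>%
    dplyr::group_split(.data$block) %>%
    purrr::map(~ finalize_block(.x, params, w$chrom[1])) %>%
    bind_rows()
  if (nrow(segs) == 0L) return(NULL)
  segs
}

# turn one candidate block (sites between discordant separator runs) into a
# segment row, or NULL if it fails the support filters
finalize_block <- function(b, params, chrom) {
  trim_conc <- function(b) {
    conc <- which(b$cls != "disc")
    if (length(conc) == 0L) return(NULL)
    b[min(conc):max(conc), , drop = FALSE]
  }
  # sites to cut from the tail: the longest terminal stretch whose
  # discordance density reaches end_trim_frac (>= 2 discordant sites)
  tail_cut <- function(d) {
    cd <- cumsum(rev(d))
    k <- seq_along(d)
    cand <- which(cd >= 2L & cd / k >= params$end_trim_frac)
    if (length(cand)) max(cand) else 0L
  }
  b <- trim_conc(b)
  if (is.null(b)) return(NULL)
  cut_end <- tail_cut(b$cls == "disc")
  if (cut_end >= nrow(b)) return(NULL)
  if (cut_end > 0L) b <- b[seq_len(nrow(b) - cut_end), , drop = FALSE]
  cut_start <- tail_cut(rev(b$cls == "disc"))
  if (cut_start >= nrow(b)) return(NULL)
  if (cut_start > 0L) b <- b[(cut_start + 1L):nrow(b), , drop = FALSE]
  b <- trim_conc(b)
  if (is.null(b)) return(NULL)

  n_info <- sum(b$cls == "info")
  n_supp <- sum(b$cls != "disc")
  n_disc <- sum(b$cls == "disc")
  start <- b$pos[1] - 1L
  end <- b$pos[nrow(b)]
  disc_frac <- n_disc / nrow(b)
  if (n_supp < params$min_sites || end - start < params$min_span_bp ||
      disc_frac > params$max_discordant_frac) {
    return(NULL)
  }
  tibble(chrom = chrom, start = start, end = end,
         n_informative_sites = n_info, n_supporting_sites = n_supp,
         discordant_frac = disc_frac,
         mean_ratio_diff = if (n_info > 0L) mean(b$rd[b$cls == "info"])
                           else NA_real_,
         min_shared_alleles = if (n_info > 0L)
           as.integer(min(b$shared[b$cls == "info"])) else 2L)
}

#' IBD segments for every affected pair
#'
#' @inheritParams ibd_segments
#' @param ped Pedigree tibble; pairs come from [affected_pairs()] restricted
#'   to samples present in `calls`.
#' @return One segments tibble covering all pairs (column `pair`).
#' @export
ibd_segments_all <- function(calls, ped, params = segmentation_params()) {
  pairs <- affected_pairs(ped, sample_ids = unique(calls$sample))
  purrr::map2(pairs$id1, pairs$id2,
              ~ ibd_segments(calls, .x, .y, params)) %>%
    bind_rows()
}

#' Regions shared by every affected pair
#'
#' Under the dominant model a causal region must be identical by descent,
#' with at least one allele, within every pair of affected relatives:
#' regions not shared by all pairs are rejected. This intersects, per
#' chromosome, the union of each affected pair's segments. A pair with no
#' segments (including a pair absent from the table) contributes an empty
#' set, so the result is empty.
#'
#' @param segments Segments tibble from [ibd_segments_all()].
#' @param ped Pedigree tibble, used to enumerate the affected pairs that
#'   must all support a region.
#' @param sample_ids Samples with genotype data; default: ids appearing in
#'   `segments`, plus all affected members of `ped`.
#' @return Tibble of shared regions: `chrom`, `start`, `end`,
#'   `supporting_pairs` (comma-separated), `n_pairs`.
#' @export
shared_regions <- function(segments, ped, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- union(unique(c(segments$id1, segments$id2)),
                        ped$id[!is.na(ped$affected) & ped$affected])
  }
  pairs <- affected_pairs(ped, sample_ids = sample_ids)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  supporting_pairs = character(), n_pairs = integer())
  if (nrow(pairs) == 0L) return(empty)
  per_pair <- purrr::map(pairs$pair, function(p) {
    segments %>% filter(.data$pair == p) %>% select("chrom", "start", "end")
  })
  inter <- intersect_interval_sets(per_pair)
  if (nrow(inter) == 0L) return(empty)
  inter %>%
    mutate(supporting_pairs = paste(pairs$pair, collapse = ","),
           n_pairs = nrow(pairs))
}

#' Subtract segments shared with an unaffected member
#'
#' Optional exclusion mode: removes from the shared regions any ground that
#' the unaffected member also shares (with at least one allele) with every
#' affected member — under full penetrance the causal haplotype must be
#' absent from healthy relatives.
#'
#' @param regions Shared-region tibble from [shared_regions()].
#' @param calls Filtered genotype tibble.
#' @param ped Pedigree tibble.
#' @param unaffected_id Sample id of the unaffected member to subtract.
#' @param params Segmentation parameters.
#' @return Region tibble with the unaffected-shared ground removed.
#' @export
exclude_unaffected <- function(regions, calls, ped, unaffected_id,
                               params = segmentation_params()) {
  aff <- intersect(ped$id[!is.na(ped$affected) & ped$affected],
                   unique(calls$sample))
  if (length(aff) == 0L || nrow(regions) == 0L) return(regions)
  unaff_sets <- purrr::map(aff, function(a) {
    ibd_segments(calls, unaffected_id, a, params) %>%
      select("chrom", "start", "end")
  })
  shared_with_unaff <- intersect_interval_sets(unaff_sets)
  if (nrow(shared_with_unaff) == 0L) return(regions)
  out <- purrr::map(unique(regions$chrom), function(ch) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    s <- shared_with_unaff[shared_with_unaff$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) return(r %>% select("chrom", "start", "end"))
    iranges_to_tbl0(IRanges::setdiff(as_iranges0(r), as_iranges0(s)), ch)
  }) %>% bind_rows()
  if (nrow(out) == 0L) {
    return(regions[0, , drop = FALSE])
  }
  out %>%
    mutate(supporting_pairs = regions$supporting_pairs[1],
           n_pairs = regions$n_pairs[1]) %>%
    arrange(.data$chrom, .data$start)
}

#' Summarize shared regions against a gene track
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param gene_intervals Gene interval tibble (`chrom`, `start`, `end`,
#'   `name`); a `name` column is required to count distinct genes.
#' @return One-row tibble: `n_regions`, `total_bp`, `n_genes` (distinct
#'   genes overlapping any region by >= 1 bp).
#' @export
summarize_regions <- function(regions, gene_intervals = NULL) {
  n_genes <- 0L
  if (!is.null(gene_intervals) && nrow(regions) > 0L &&
      nrow(gene_intervals) > 0L) {
    hit <- overlaps_any(gene_intervals, regions)
    nm <- if ("name" %in% names(gene_intervals)) gene_intervals$name
          else as.character(seq_len(nrow(gene_intervals)))
    n_genes <- dplyr::n_distinct(nm[hit])
  }
  tibble(n_regions = nrow(regions),
         total_bp = sum(as.numeric(regions$end - regions$start)),
         n_genes = n_genes)
}
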