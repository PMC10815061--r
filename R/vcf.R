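#' Read per-sample genotype calls from a multi-sample VCF
#'
#' Reads a VCF (via `vcfR`) and returns one row per site x sample with the
#' fields the allele-balance IBD analysis needs: genotype allele indices,
#' per-allele read counts (AD), total depth (DP) and genotype quality (GQ).
#' Only biallelic autosomal SNVs are retained by default; skipped records
#' are counted and reported.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param samples Character vector of sample ids to extract; default all.
#'   A requested sample missing from the header is an error.
#' @param autosomes_only Keep only chromosomes 1-22 (`chr` prefix
#'   tolerated). Default `TRUE`.
#' @param multiallelic `"skip"` (default) drops records with more than one
#'   ALT allele; `"split"` decomposes them into one biallelic record per
#'   ALT allele (genotype alleles recoded to 0/1 against that ALT, AD taken
#'   from the REF and that ALT column).
#'
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `sample`, `gt` (e.g. `"0/1"`, `NA` when missing), `a1`, `a2` (integer
#'   allele indices), `ad_ref`, `ad_alt`, `dp`, `gq`. The attribute
#'   `skip_counts` records how many records were dropped and why; rows where
#'   `ad_ref + ad_alt > dp` are flagged in the logical column `ad_exceeds_dp`
#'   rather than rejected.
#' @export
read_vcf_genotypes <- function(path, samples = NULL, autosomes_only = TRUE,
                               multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  have <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- have
  missing_s <- setdiff(samples, have)
  if (length(missing_s)) {
    abort(sprintf("sample(s) not in VCF header: %s",
                  paste(missing_s, collapse = ", ")))
  }

  n <- nrow(fix)
  skip <- c(non_autosome = 0L, multiallelic = 0L, indel = 0L, malformed = 0L)
  keep <- rep(TRUE, n)
  if (autosomes_only) {
    auto <- is_autosome(fix$CHROM)
    skip[["non_autosome"]] <- sum(!auto)
    keep <- keep & auto
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  indel <- !multi & (nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L |
                       fix$ALT %in% c(".", "*"))
  skip[["indel"]] <- sum(indel & keep)
  keep <- keep & !indel

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  dp_raw <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq_raw <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)

  rows <- list()
  site_tbl <- function(idx, alt_k = 1L, n_alt = 1L) {
    # one biallelic (or decomposed) record across the requested samples
    gt <- gt_raw[idx, samples]
    al <- parse_gt(gt)
    ad <- stringr::str_split_fixed(ad_raw[idx, samples], ",", n_alt + 1L)
    ad_ref <- suppressWarnings(as.integer(ad[, 1]))
    ad_alt <- suppressWarnings(as.integer(ad[, alt_k + 1L]))
    a1 <- al[, 1]; a2 <- al[, 2]
    if (n_alt > 1L) {
      # recode against this ALT and canonicalize allele order
      r1 <- ifelse(is.na(a1), NA_integer_, as.integer(a1 == alt_k))
      r2 <- ifelse(is.na(a2), NA_integer_, as.integer(a2 == alt_k))
      a1 <- pmin(r1, r2)
      a2 <- pmax(r1, r2)
    }
    tibble(
      chrom = fix$CHROM[idx], pos = as.integer(fix$POS[idx]),
      ref = fix$REF[idx],
      alt = strsplit(fix$ALT[idx], ",", fixed = TRUE)[[1]][alt_k],
      sample = samples,
      gt = ifelse(is.na(a1) | is.na(a2), NA_character_,
                  paste0(a1, "/", a2)),
      a1 = a1, a2 = a2, ad_ref = ad_ref, ad_alt = ad_alt,
      dp = as.integer(dp_raw[idx, samples]),
      gq = as.integer(gq_raw[idx, samples])
    )
  }

  for (i in which(keep)) {
    if (multi[i]) {
      if (multiallelic == "skip") {
        skip[["multiallelic"]] <- skip[["multiallelic"]] + 1L
        next
      }
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      snv_alts <- which(nchar(alts) == 1L & nchar(fix$REF[i]) == 1L)
      for (k in snv_alts) rows[[length(rows) + 1L]] <- site_tbl(i, k, length(alts))
    } else {
      rows[[length(rows) + 1L]] <- site_tbl(i)
    }
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), sample = character(), gt = character(),
    a1 = integer(), a2 = integer(), ad_ref = integer(),
    ad_alt = integer(), dp = integer(), gq = integer()
  )
  out <- out %>%
    mutate(ad_exceeds_dp = !is.na(.data$ad_ref) & !is.na(.data$ad_alt) &
             !is.na(.data$dp) & (.data$ad_ref + .data$ad_alt > .data$dp))
  if (any(skip > 0)) {
    inform(sprintf("read_vcf_genotypes: skipped %s",
                   paste(sprintf("%d %s", skip[skip > 0],
                                 names(skip)[skip > 0]), collapse = ", ")))
  }
  attr(out, "skip_counts") <- skip
  out
}

is_autosome <- function(chrom) {
  core <- sub("^[Cc]hr", "", chrom)
  !is.na(suppressWarnings(as.integer(core))) &
    suppressWarnings(as.integer(core)) >= 1L &
    suppressWarnings(as.integer(core)) <= 22L
}

#' Per-call hard filter on depth, quality and alternate-allele support
#'
#' A genotype call passes when its depth and genotype quality strictly
#' exceed the thresholds (defaults DP > 14, GQ > 30) and, when
#' `require_alt_support` is set, any call carrying an alternate allele is
#' backed by at least one alternate-supporting read — the per-call reading
#' of an "allelic ratio difference of > 0". Missing DP or GQ fails.
#'
#' @param calls Genotype tibble from [read_vcf_genotypes()] (or any tibble
#'   with `dp`, `gq`, `a1`, `a2`, `ad_alt`).
#' @param min_dp,min_gq Exclusive lower thresholds.
#' @param require_alt_support Require `ad_alt > 0` for non-reference calls.
#' @return Logical vector along the rows of `calls`.
#' @export
call_passes <- function(calls, min_dp = 14L, min_gq = 30L,
                        require_alt_support = TRUE) {
  ok <- !is.na(calls$dp) & !is.na(calls$gq) &
    calls$dp > min_dp & calls$gq > min_gq
  if (require_alt_support) {
    carries_alt <- !is.na(calls$a1) & !is.na(calls$a2) &
      (calls$a1 > 0L | calls$a2 > 0L)
    ok <- ok & (!carries_alt | (!is.na(calls$ad_alt) & calls$ad_alt > 0L))
  }
  ok
}

#' Site-level hard filtering for pedigree IBD analysis
#'
#' Retains only sites where every listed sample's call passes
#' [call_passes()] and every child-parent trio among the listed samples is
#' Mendelian-consistent ([mendelian_consistent()]; sites with missing
#' genotypes in a trio are not testable and are retained).
#'
#' @inheritParams call_passes
#' @param ped Pedigree tibble ([read_pedigree()]); trios are formed from
#'   members whose parent ids are also present among the samples.
#' @param samples Samples that must pass; default all samples in `calls`.
#' @return The filtered calls tibble, with a `filter_funnel` attribute
#'   recording site counts at each stage
#'   (`input`, `pass_call_qc`, `pass_mendelian`).
#' @export
filter_sites <- function(calls, ped, samples = NULL,
                         min_dp = 14L, min_gq = 30L,
                         require_alt_support = TRUE) {
  if (is.null(samples)) samples <- unique(calls$sample)
  calls <- calls %>% filter(.data$sample %in% samples)
  calls <- calls %>% mutate(.site = site_key(calls))
  n_in <- dplyr::n_distinct(calls$.site)

  calls <- calls %>%
    mutate(.pass = call_passes(calls, min_dp, min_gq, require_alt_support)) %>%
    group_by(.data$.site) %>%
    mutate(.site_qc = all(.data$.pass) & dplyr::n() == length(samples)) %>%
    ungroup()
  qc <- calls %>% filter(.data$.site_qc)
  n_qc <- dplyr::n_distinct(qc$.site)

  # Mendelian test on every trio-local transmission available in the data
  trios <- ped %>%
    filter(.data$id %in% samples,
           (.data$father_id %in% samples) | (.data$mother_id %in% samples))
  bad_sites <- character(0)
  if (nrow(trios)) {
    wide_a1 <- tidyr::pivot_wider(qc, id_cols = ".site",
                                  names_from = "sample", values_from = "a1")
    wide_a2 <- tidyr::pivot_wider(qc, id_cols = ".site",
                                  names_from = "sample", values_from = "a2")
    consistent <- rep(TRUE, nrow(wide_a1))
    na_col <- rep(NA_integer_, nrow(wide_a1))
    col <- function(w, id) if (!is.null(id) && !is.na(id) && id %in% names(w)) w[[id]] else na_col
    for (i in seq_len(nrow(trios))) {
      kid <- trios$id[i]; fa <- trios$father_id[i]; mo <- trios$mother_id[i]
      consistent <- consistent & mendel_ok(
        col(wide_a1, kid), col(wide_a2, kid),
        col(wide_a1, fa), col(wide_a2, fa),
        col(wide_a1, mo), col(wide_a2, mo))
    }
    bad_sites <- wide_a1$.site[!consistent]
  }
  out <- qc %>%
    filter(!(.data$.site %in% bad_sites)) %>%
    select(-".pass", -".site_qc", -".site")
  attr(out, "filter_funnel") <- c(
    input = n_in, pass_call_qc = n_qc,
    pass_mendelian = n_qc - length(bad_sites)
  )
  out
}

site_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Write genotype calls back out as a minimal VCF
#'
#' Serializes a calls tibble (as produced by [read_vcf_genotypes()] or
#' [simulate_family()]) to a VCF 4.2 file with `GT:AD:DP:GQ` FORMAT
#' fields, suitable for round-tripping through any VCF reader.
#'
#' @param calls Genotype tibble.
#' @param path Output file path.
#' @param samples Sample column order; default sorted unique samples.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(calls, path, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  fmt <- calls %>%
    mutate(
      .site = site_key(calls),
      cell = sprintf("%s:%s,%s:%s:%s",
                     ifelse(is.na(.data$gt), "./.", .data$gt),
                     .data$ad_ref, .data$ad_alt, .data$dp, .data$gq)
    )
  wide <- tidyr::pivot_wider(fmt, id_cols = c(".site", "chrom", "pos", "ref", "alt"),
                             names_from = "sample", values_from = "cell")
  wide <- wide %>% arrange(.data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(wide$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP:GQ\t%s",
                  wide$chrom, wide$pos, wide$ref, wide$alt,
                  do.call(paste, c(lapply(samples, function(s) wide[[s]]),
                                   sep = "\t")))
  writeLines(c(header, body), path)
  invisible(path)
}
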