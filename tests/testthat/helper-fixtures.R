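# Shared fixture builders and independent oracles used across test files.

# compact builder for a long calls tibble from per-sample genotype strings;
# gts: named list sample -> character vector of "g|ad_ref,ad_alt|dp|gq"
# or plain genotypes like "0/1" (AD/DP/GQ then derived noise-free at dp)
make_calls <- function(positions, gts, chrom = "chr1", dp_default = 30L,
                       gq_default = 80L) {
  purrr::imap(gts, function(v, sample) {
    stopifnot(length(v) == length(positions))
    full <- grepl("|", v, fixed = TRUE)
    parts <- stringr::str_split_fixed(v, stringr::fixed("|"), 4)
    gt <- ifelse(full, parts[, 1], v)
    a <- stringr::str_split_fixed(gt, "/", 2)
    a1 <- suppressWarnings(as.integer(a[, 1]))
    a2 <- suppressWarnings(as.integer(a[, 2]))
    n_alt <- (a1 > 0) + (a2 > 0)
    dp <- ifelse(full, suppressWarnings(as.integer(parts[, 3])), dp_default)
    ad_alt_def <- as.integer(round(dp * c(0.0, 0.5, 1.0)[n_alt + 1L]))
    ad <- stringr::str_split_fixed(parts[, 2], ",", 2)
    ad_ref <- ifelse(full, suppressWarnings(as.integer(ad[, 1])),
                     dp - ad_alt_def)
    ad_alt <- ifelse(full, suppressWarnings(as.integer(ad[, 2])), ad_alt_def)
    gq <- ifelse(full, suppressWarnings(as.integer(parts[, 4])), gq_default)
    tibble::tibble(
      chrom = chrom, pos = as.integer(positions), ref = "A", alt = "G",
      sample = sample,
      gt = ifelse(is.na(a1), NA_character_, gt),
      a1 = a1, a2 = a2,
      ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, gq = gq
    )
  }) |> dplyr::bind_rows()
}

# write a small VCF file from header metadata + body lines
write_toy_vcf <- function(body, samples, path = tempfile(fileext = ".vcf"),
                          contigs = c("chr1", "chr2", "chrX")) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

# exhaustive transmission oracle for one biallelic trio
mendel_oracle <- function(child, father, mother) {
  al <- function(g) as.integer(strsplit(g, "/")[[1]])
  c_al <- sort(al(child))
  f_al <- al(father); m_al <- al(mother)
  for (i in 1:2) for (j in 1:2) {
    if (identical(sort(c(f_al[i], m_al[j])), c_al)) return(TRUE)
  }
  FALSE
}

# per-base mask intersection oracle for interval sets on one chromosome
mask_intersect_oracle <- function(tbls, max_bp) {
  masks <- lapply(tbls, function(t) {
    m <- logical(max_bp)
    for (i in seq_len(nrow(t))) {
      if (t$start[i] < max_bp) {
        m[(t$start[i] + 1):min(t$end[i], max_bp)] <- TRUE
      }
    }
    m
  })
  common <- Reduce(`&`, masks)
  r <- rle(common)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  tibble::tibble(chrom = if (nrow(tbls[[1]])) tbls[[1]]$chrom[1] else character(0),
                 start = starts[r$values] - 1L, end = ends[r$values])[r$values[0:sum(r$values)] | TRUE, ][seq_len(sum(r$values)), ]
}

# transitive-closure clustering oracle over a pairwise mergeable predicate
cluster_oracle <- function(calls, params) {
  n <- nrow(calls)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (sv_mergeable(calls[i, ], calls[j, ], params) &&
          comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}
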