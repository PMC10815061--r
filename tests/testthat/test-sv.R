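sv_row <- function(start, end, svtype = "DEL", caller = "manta",
                   chrom = "chr1", quality = 40, filter = "PASS",
                   genotypes = list(character(0))) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), svtype = svtype, caller = caller,
                 quality = quality, filter = filter, genotypes = genotypes)
}

test_that("reciprocal overlap and breakend distances follow their definitions", {
  expect_equal(reciprocal_overlap(1000, 2000, 1000, 2000), 1)
  expect_equal(reciprocal_overlap(0, 100, 500, 600), 0)
  expect_equal(reciprocal_overlap(1000, 2000, 1400, 2400), 0.6)
  # overlap 6000 over lengths 10000 and 16000: the smaller fraction wins
  expect_equal(reciprocal_overlap(0, 10000, 4000, 20000), 0.375)
  expect_equal(reciprocal_overlap(0, 100, 0, 100, "chr1", "chr2"), 0)
  # symmetry, bounded by 1
  set.seed(3)
  for (i in 1:20) {
    a <- sort(sample(0:5000, 2)); b <- sort(sample(0:5000, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    ro1 <- reciprocal_overlap(a[1], a[2], b[1], b[2])
    expect_equal(ro1, reciprocal_overlap(b[1], b[2], a[1], a[2]))
    expect_lte(ro1, 1)
  }
  d <- breakend_distances(1000, 2000, 1400, 2400)
  expect_equal(c(d$start_dist, d$end_dist), c(400, 400))
  d2 <- breakend_distances(0, 5000, 3000, 5000)
  expect_equal(c(d2$start_dist, d2$end_dist), c(3000, 0))
  expect_equal(unlist(breakend_distances(10, 20, 10, 20)), c(start_dist = 0, end_dist = 0))
  expect_error(breakend_distances(0, 1, 0, 1, "chr1", "chr2"), "chromosome")
})

test_that("the consensus merge rule combines overlap, distance and type", {
  p <- merge_params()
  expect_true(sv_mergeable(sv_row(1000, 2000), sv_row(1400, 2400), p))
  expect_false(sv_mergeable(sv_row(0, 10000), sv_row(4000, 20000), p))
  expect_false(sv_mergeable(sv_row(1000, 2000),
                            sv_row(1000, 2000, svtype = "DUP"), p))
  expect_true(sv_mergeable(sv_row(1000, 2000),
                           sv_row(1000, 2000, svtype = "DUP"),
                           merge_params(require_same_type = FALSE)))
  expect_false(sv_mergeable(sv_row(1000, 2000),
                            sv_row(1000, 2000, chrom = "chr2"), p))
  # symmetric
  expect_equal(sv_mergeable(sv_row(1000, 2000), sv_row(1400, 2400), p),
               sv_mergeable(sv_row(1400, 2400), sv_row(1000, 2000), p))
  # insertions merge on breakend distance alone
  expect_true(sv_mergeable(sv_row(5000, 5001, svtype = "INS"),
                           sv_row(5400, 5401, svtype = "INS"), p))
  expect_false(sv_mergeable(sv_row(5000, 5001, svtype = "INS"),
                            sv_row(7000, 7001, svtype = "INS"), p))
  # large intervals with good overlap but distant ends need both breakends
  expect_false(sv_mergeable(sv_row(0, 100000), sv_row(2000, 102000), p))
})

test_that("per-caller hard filters are configuration driven", {
  calls <- dplyr::bind_rows(
    sv_row(0, 1000, filter = "PASS"),
    sv_row(5000, 6000, filter = "LowQual"),
    sv_row(9000, 9500, caller = "lumpy", quality = 3),
    sv_row(12000, 12800, caller = "mystery")
  )
  cfg <- list(manta = list(require_pass = TRUE),
              lumpy = list(min_quality = 20))
  expect_warning(out <- caller_hard_filter(calls, cfg), "mystery")
  expect_equal(out$start, c(0L, 12000L))
})

test_that("merging clusters multi-caller call sets with conserved members", {
  p <- merge_params()
  base <- lapply(c("manta", "lumpy", "cnvnator"), function(cl) {
    dplyr::bind_rows(lapply(0:9, function(i) {
      sv_row(i * 100000, i * 100000 + 10000, caller = cl)
    }))
  })
  merged <- merge_callsets(base, p)
  expect_equal(nrow(merged), 10)
  expect_equal(unique(merged$n_callers), 3)
  expect_equal(sum(merged$n_members), 30)

  # one call set alone passes through
  single <- merge_callsets(base[[1]], p)
  expect_equal(nrow(single), 10)
  expect_equal(unique(single$n_callers), 1)

  # strictest thresholds merge only exact duplicates
  jit <- base
  jit[[2]]$start <- jit[[2]]$start + 5L
  strict <- merge_callsets(jit, merge_params(1, 0))
  expect_equal(nrow(strict), 20)
  # fully relaxed thresholds merge all overlapping same-type calls
  loose <- merge_callsets(jit, merge_params(1e-9, 10^9))
  expect_equal(nrow(loose), 10)

  # consensus coordinates are per-coordinate medians
  tri <- merge_callsets(dplyr::bind_rows(
    sv_row(1000, 2000, caller = "a"),
    sv_row(1100, 2100, caller = "b"),
    sv_row(1300, 2050, caller = "c")
  ), p)
  expect_equal(tri$start, 1100L)
  expect_equal(tri$end, 2050L)
})

test_that("clusters equal connected components of the mergeable graph", {
  set.seed(19)
  p <- merge_params()
  for (rep in 1:5) {
    n <- 40
    s <- sample(0:200000, n)
    calls <- tibble::tibble(
      chrom = "chr1", start = s,
      end = s + sample(c(5000L, 8000L, 12000L), n, replace = TRUE),
      svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
      caller = sample(c("a", "b", "c"), n, replace = TRUE),
      quality = 40, filter = "PASS",
      genotypes = rep(list(character(0)), n)
    )
    merged <- merge_callsets(calls, p)
    comp <- cluster_oracle(calls, p)
    expect_equal(nrow(merged), dplyr::n_distinct(comp))
    expect_equal(sum(merged$n_members), n)
  }
})

test_that("dominant-model filter requires carriers in all affected only", {
  ped <- example_pedigree(sequenced_only = TRUE)
  aff <- c("II.8", "II.9", "III.3", "III.7")
  gt <- function(affected_state, unaffected_state) {
    list(setNames(c(rep(affected_state, 4), unaffected_state),
                  c(aff, "II.10")))
  }
  merged <- dplyr::bind_rows(
    sv_row(0, 1000, genotypes = gt("het", "ref")),        # keep
    sv_row(2000, 3000, genotypes = gt("het", "het")),     # unaffected carrier
    sv_row(4000, 5000, genotypes = list(
      setNames(c("het", "het", "het", "ref", "ref"), c(aff, "II.10")))),
    sv_row(6000, 7000, genotypes = gt("missing", "ref")), # uninformative
    sv_row(8000, 9000, genotypes = gt("hom", "ref"))      # keep
  )
  out <- dominant_model_filter(merged, ped)
  expect_equal(out$start, c(0L, 6000L, 8000L))
})

test_that("annotation rejects SVs without phenotype genes or outside IBD regions", {
  genes <- tibble::tibble(chrom = "chr1",
                          start = c(500L, 90000L), end = c(1500L, 91000L),
                          name = c("pheno1", "other"))
  merged <- dplyr::bind_rows(
    sv_row(0, 1000), sv_row(89000, 92000), sv_row(200000, 201000)
  )
  out <- annotate_and_filter_svs(merged, genes, phenotype_genes = "pheno1")
  expect_equal(out$start, 0L)
  expect_equal(out$genes[[1]], "pheno1")

  ibd <- tibble::tibble(chrom = "chr1", start = 80000L, end = 100000L)
  out2 <- annotate_and_filter_svs(merged, genes,
                                  phenotype_genes = c("pheno1", "other"),
                                  ibd_regions = ibd)
  expect_equal(out2$start, 89000L)
  expect_true(out2$in_ibd_region)

  expect_warning(
    none <- annotate_and_filter_svs(merged, genes, phenotype_genes = character(0)),
    "rejected")
  expect_equal(nrow(none), 0)
})

test_that("SV VCFs parse symbolic ALT records with carrier genotypes", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    "chr1\t10000\tsv1\tN\t<DEL>\t55\tPASS\tSVTYPE=DEL;END=22000\tGT\t0/1\t0/0",
    "chr1\t50000\tsv2\tN\t<INS>\t12\tPASS\tSVTYPE=INS;END=50000\tGT\t1/1\t./."
  ), path)
  calls <- read_sv_vcf(path, caller = "manta")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$svtype, c("DEL", "INS"))
  expect_equal(calls$end[1], 22000L)
  expect_equal(calls$end[2], calls$start[2] + 1L)
  expect_equal(calls$genotypes[[1]][["s1"]], "het")
  expect_equal(calls$genotypes[[1]][["s2"]], "ref")
  expect_equal(calls$genotypes[[2]][["s1"]], "hom")
  expect_equal(calls$genotypes[[2]][["s2"]], "missing")
})
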