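test_that("allelic ratio and ratio difference follow the AD/DP definition", {
  expect_equal(allelic_ratio(10, 20), 0.5)
  expect_equal(allelic_ratio(0, 20), 0)
  expect_equal(allelic_ratio(18, 18), 1)
  expect_error(allelic_ratio(5, 0), "dp > 0")
  expect_equal(ratio_diff(15, 20, 5, 20), 0.5)
  expect_equal(ratio_diff(10, 20, 10, 20), 0)
  # symmetry over random calls
  set.seed(1)
  for (i in 1:20) {
    dp1 <- sample(10:60, 1); dp2 <- sample(10:60, 1)
    a1 <- sample(0:dp1, 1); a2 <- sample(0:dp2, 1)
    expect_equal(ratio_diff(a1, dp1, a2, dp2), ratio_diff(a2, dp2, a1, dp1))
    expect_gte(ratio_diff(a1, dp1, a2, dp2), 0)
    expect_lte(ratio_diff(a1, dp1, a2, dp2), 1)
  }
})

test_that("shared allele count is the multiset matching size", {
  expect_equal(shared_allele_count("0/0", "1/1"), 0L)
  expect_equal(shared_allele_count("0/0", "0/1"), 1L)
  expect_equal(shared_allele_count("0/1", "0/1"), 2L)
  expect_equal(shared_allele_count("1/0", "0/1"), 2L)
  # against a brute-force multiset matcher for all 9 genotype pairs
  brute <- function(g1, g2) {
    a <- as.integer(strsplit(g1, "/")[[1]])
    b <- as.integer(strsplit(g2, "/")[[1]])
    best <- 0
    for (perm in list(b, rev(b))) {
      best <- max(best, sum(a == perm))
    }
    best
  }
  gts <- c("0/0", "0/1", "1/1")
  for (g1 in gts) for (g2 in gts) {
    expect_equal(shared_allele_count(g1, g2), brute(g1, g2),
                 info = paste(g1, g2))
  }
  expect_error(shared_allele_count("./.", "0/1"), "non-missing")
})

test_that("identical or missing genotype pairs are non-informative", {
  expect_false(pair_site_informative("0/1", "0/1"))
  expect_false(pair_site_informative("1/0", "0/1"))
  expect_true(pair_site_informative("0/0", "0/1"))
  expect_false(pair_site_informative("./.", "0/1"))
})

# builds a two-sample calls tibble from a class string:
# i = concordant informative (0/0 vs 0/1), c = identical context (0/1 both),
# d = discordant (0/0 vs 1/1)
pair_calls_from_classes <- function(classes, spacing_bp = 20000) {
  cls <- strsplit(classes, "")[[1]]
  g1 <- c(i = "0/1", c = "0/1", d = "0/0")[cls]
  g2 <- c(i = "0/0", c = "0/1", d = "1/1")[cls]
  make_calls(positions = seq_along(cls) * spacing_bp,
             gts = list(s1 = unname(g1), s2 = unname(g2)))
}

test_that("segmentation emits runs and tolerates short discordant stretches", {
  p <- segmentation_params(min_sites = 25, min_span_bp = 500000)
  # 100 concordant informative sites over 2 Mb: one segment holding all
  seg <- ibd_segments(pair_calls_from_classes(strrep("i", 100)),
                      "s1", "s2", p)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_informative_sites, 100)
  expect_equal(seg$start, 20000 - 1)
  expect_equal(seg$end, 100 * 20000)

  # a single discordant site does not break the run
  one_disc <- paste0(strrep("i", 50), "d", strrep("i", 50))
  seg1 <- ibd_segments(pair_calls_from_classes(one_disc), "s1", "s2", p)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$n_informative_sites, 100)

  # three consecutive discordant sites force a split into two segments
  split <- paste0(strrep("i", 50), "ddd", strrep("i", 50))
  seg2 <- ibd_segments(pair_calls_from_classes(split), "s1", "s2", p)
  expect_equal(nrow(seg2), 2)
  expect_equal(seg2$n_informative_sites, c(50, 50))

  # identical-genotype context sites support segments but stay uninformative
  ctx <- paste0(strrep("i", 20), strrep("c", 60), strrep("i", 20))
  seg3 <- ibd_segments(pair_calls_from_classes(ctx), "s1", "s2", p)
  expect_equal(nrow(seg3), 1)
  expect_equal(seg3$n_informative_sites, 40)
  expect_equal(seg3$n_supporting_sites, 100)

  # a pure identical-genotype stretch is an IBD2 segment
  seg4 <- ibd_segments(pair_calls_from_classes(strrep("c", 100)),
                       "s1", "s2", p)
  expect_equal(nrow(seg4), 1)
  expect_equal(seg4$min_shared_alleles, 2L)
  expect_equal(seg4$n_informative_sites, 0L)
})

test_that("segment support filters drop weak segments and unsorted input errors", {
  p_strict <- segmentation_params(min_sites = 25, min_span_bp = 500000)
  p_loose <- segmentation_params(min_sites = 5, min_span_bp = 10000)
  short <- pair_calls_from_classes(strrep("i", 10), spacing_bp = 2000)
  expect_equal(nrow(ibd_segments(short, "s1", "s2", p_strict)), 0)
  expect_equal(nrow(ibd_segments(short, "s1", "s2", p_loose)), 1)

  bad <- pair_calls_from_classes(strrep("i", 10))
  bad$pos <- rev(bad$pos)
  expect_error(ibd_segments(bad, "s1", "s2", p_loose), "sorted")
})

test_that("tightening support thresholds never increases total shared span", {
  sim <- simulate_family(sim_config(seed = 9, chrom_length_bp = 4000000L))
  f <- suppressMessages(filter_sites(sim$calls, sim$ped))
  span <- function(min_sites, min_span_bp) {
    p <- segmentation_params(min_sites = min_sites, min_span_bp = min_span_bp)
    segs <- ibd_segments_all(f, sim$ped, p)
    sum(as.numeric(segs$end - segs$start))
  }
  expect_gte(span(10, 100000), span(25, 100000))
  expect_gte(span(25, 100000), span(60, 100000))
  expect_gte(span(25, 100000), span(25, 500000))
  expect_gte(span(25, 500000), span(25, 1500000))
})

test_that("interval intersection matches arithmetic and a per-base oracle", {
  a <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  b <- tibble::tibble(chrom = "chr1", start = 5L, end = 15L)
  out <- intersect_interval_sets(list(a, b))
  expect_equal(out$start, 5L)
  expect_equal(out$end, 10L)
  # idempotence
  expect_equal(intersect_interval_sets(list(a, a, a)), a)
  # any empty set annihilates
  empty <- a[0, ]
  expect_equal(nrow(intersect_interval_sets(list(a, empty))), 0)

  set.seed(7)
  for (rep in 1:10) {
    sets <- lapply(1:3, function(i) {
      s <- sort(sample(0:1900, 8))
      tibble::tibble(chrom = "chr1", start = s,
                     end = s + sample(10:120, 8, replace = TRUE))
    })
    got <- intersect_interval_sets(sets)
    want <- mask_intersect_oracle(sets, 2100)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("shared regions are supported by every affected pair", {
  ped <- example_pedigree(sequenced_only = TRUE)
  pairs <- affected_pairs(ped)$pair
  seg_for <- function(pair, start, end) {
    ids <- strsplit(pair, "|", fixed = TRUE)[[1]]
    tibble::tibble(chrom = "chr1", start = start, end = end,
                   id1 = ids[1], id2 = ids[2], pair = pair)
  }
  # all six pairs share [2 Mb, 8 Mb); one pair is narrower
  segs <- dplyr::bind_rows(
    lapply(pairs[-1], function(p) seg_for(p, 0L, 10000000L)),
    seg_for(pairs[1], 2000000L, 8000000L)
  )
  reg <- shared_regions(segs, ped)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 2000000L)
  expect_equal(reg$end, 8000000L)
  expect_equal(reg$n_pairs, 6)
  # containment invariant: region lies inside a segment of every pair
  for (p in pairs) {
    ps <- segs[segs$pair == p, ]
    expect_true(any(ps$start <= reg$start & ps$end >= reg$end))
  }
  # a pair with no segments kills every region
  reg0 <- shared_regions(segs[segs$pair != pairs[2], ], ped)
  expect_equal(nrow(reg0), 0)
  # identical segment lists: intersection equals that list
  same <- dplyr::bind_rows(lapply(pairs, function(p) seg_for(p, 1e6, 4e6)))
  regs <- shared_regions(same, ped)
  expect_equal(regs$start, 1e6)
  expect_equal(regs$end, 4e6)
})

test_that("region summaries count overlapping genes by >= 1 bp", {
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  genes <- tibble::tibble(chrom = "chr1",
                          start = c(100L, 5000L), end = c(200L, 6000L),
                          name = c("g1", "g2"))
  s <- summarize_regions(regions, genes)
  expect_equal(s$n_regions, 1)
  expect_equal(s$total_bp, 1000)
  expect_equal(s$n_genes, 1)
  expect_equal(summarize_regions(regions[0, ], genes),
               tibble::tibble(n_regions = 0L, total_bp = 0, n_genes = 0L))

  # brute-force overlap oracle on a random planted instance
  set.seed(11)
  gs <- sort(sample(0:90000, 50))
  genes2 <- tibble::tibble(chrom = "chr1", start = gs, end = gs + 800L,
                           name = sprintf("g%02d", 1:50))
  regions2 <- tibble::tibble(chrom = "chr1", start = c(10000L, 60000L),
                             end = c(30000L, 70000L))
  brute <- sum(sapply(seq_len(50), function(i) {
    any(genes2$start[i] < regions2$end & genes2$end[i] > regions2$start)
  }))
  expect_equal(summarize_regions(regions2, genes2)$n_genes, brute)
})

test_that("unaffected-sharing exclusion subtracts covered ground", {
  sim <- simulate_family(sim_config(seed = 3, chrom_length_bp = 6000000L))
  f <- suppressMessages(filter_sites(sim$calls, sim$ped))
  segs <- ibd_segments_all(f, sim$ped)
  reg <- shared_regions(segs, sim$ped)
  excl <- exclude_unaffected(reg, f, sim$ped, "II.10")
  expect_lte(sum(excl$end - excl$start), sum(reg$end - reg$start))
})
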