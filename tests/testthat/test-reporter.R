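test_that("luciferase normalization divides by the control reading", {
  m <- tibble::tibble(construct = "wt", reporter = "TOP",
                      firefly = c(1000, 50, 80),
                      renilla = c(100, 50, 100),
                      bgal = c(10, 10, 10))
  out <- normalize_luciferase(m)
  expect_equal(out$activity, c(10, 1, 0.8))
  alt <- normalize_luciferase(m, normalizer = "bgal")
  expect_equal(alt$activity, c(100, 5, 8))
  expect_error(normalize_luciferase(dplyr::mutate(m, renilla = 0)),
               "positive")
  expect_error(normalize_luciferase(dplyr::mutate(m, firefly = -1)),
               "positive")
  expect_error(normalize_luciferase(m, normalizer = "nope"), "not found")
})

test_that("TOP/FOP ratio is the ratio of group means", {
  expect_equal(top_fop_ratio(c(10, 10, 10), c(2, 2, 2)), 5)
  expect_equal(top_fop_ratio(c(3, 5), c(3, 5)), 1)
  expect_equal(top_fop_ratio(8, 4), 2)
  expect_error(top_fop_ratio(numeric(0), 1), "non-empty")
})

test_that("fully separated triplicates give exact one-sided p 0.05 and r ~ 0.8", {
  res <- mann_whitney(c(5.2, 6.1, 5.7), c(1.1, 2.0, 1.4),
                      alternative = "greater")
  expect_equal(res$method, "exact")
  expect_equal(res$u_statistic, 9)
  expect_equal(res$p_value, 1 / 20)
  # z = (9 - 4.5) / sqrt(9 * 7 / 12), r = z / sqrt(6)
  expect_equal(res$z_value, 4.5 / sqrt(5.25))
  expect_equal(res$effect_size_r, (4.5 / sqrt(5.25)) / sqrt(6))
  expect_equal(round(res$effect_size_r, 1), 0.8)
  # two-sided doubles the tail here
  res2 <- mann_whitney(c(5.2, 6.1, 5.7), c(1.1, 2.0, 1.4))
  expect_equal(res2$p_value, 2 / 20)
})

test_that("tied and identical samples behave under the midrank convention", {
  res <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$u_statistic, 9 / 2)
  expect_equal(res$p_value, 1)
  expect_equal(res$z_value, 0)
  # ties convention: one-sided p-values overlap at equality
  x <- c(1, 2, 2, 4); y <- c(2, 3, 5)
  pg <- mann_whitney(x, y, alternative = "greater")$p_value
  pl <- mann_whitney(x, y, alternative = "less")$p_value
  expect_gte(pg + pl, 1)
  # swapping the groups swaps the one-sided tails
  expect_equal(mann_whitney(y, x, alternative = "less")$p_value, pg)
  expect_equal(mann_whitney(y, x, alternative = "greater")$p_value, pl)
})

test_that("exact p matches the rank-sum oracle on tie-free draws", {
  set.seed(99)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    repeat {
      x <- round(rnorm(n1, sd = 5), 3)
      y <- round(rnorm(n2, sd = 5), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    for (alt in c("two.sided", "greater", "less")) {
      ours <- mann_whitney(x, y, alternative = alt)
      oracle <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = alt, exact = TRUE,
                           correct = FALSE))
      expect_equal(ours$p_value, unname(oracle$p.value),
                   tolerance = 1e-12,
                   info = sprintf("alt=%s n1=%d n2=%d", alt, n1, n2))
      expect_equal(ours$u_statistic, unname(oracle$statistic))
    }
  }
})

test_that("effect size is invariant under monotone transforms", {
  set.seed(5)
  x <- rlnorm(5); y <- rlnorm(7, meanlog = 0.8)
  base <- mann_whitney(x, y)
  for (f in list(log, sqrt, function(v) 3 * v + 2, function(v) v^3)) {
    tr <- mann_whitney(f(x), f(y))
    expect_equal(tr$effect_size_r, base$effect_size_r)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(8)
  x <- rnorm(15); y <- rnorm(15, mean = 1)
  res <- mann_whitney(x, y)
  expect_equal(res$method, "normal-approximation")
  oracle <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(res$p_value, unname(oracle$p.value), tolerance = 1e-10)
})

test_that("tidy and glance return one-row summaries", {
  res <- mann_whitney(c(5, 6, 7), c(1, 2, 3), alternative = "greater")
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_named(td, c("u_statistic", "z_value", "p_value", "effect_size_r",
                     "n1", "n2", "alternative", "method"))
  gl <- glance(res)
  expect_equal(gl$p_value, 0.05)
})

test_that("the full assay analysis reproduces ratios and the rank test", {
  cfg <- sim_config(seed = 2, assay_sdlog = 0)
  m <- simulate_assay(cfg)
  res <- analyze_reporter_assay(m, alternative = "greater")
  expect_equal(res$top_fop$top_fop[res$top_fop$construct == "wt"], 10 / 2)
  expect_equal(res$top_fop$top_fop[res$top_fop$construct == "variant"], 6 / 2)
  expect_equal(res$test$p_value, 0.05)
  # with measurement noise the groups stay separated but untied, giving
  # the canonical z-based effect size for separated triplicates
  noisy <- analyze_reporter_assay(
    simulate_assay(sim_config(seed = 2, assay_sdlog = 0.05)),
    alternative = "greater")
  expect_equal(noisy$test$p_value, 0.05)
  expect_equal(round(noisy$test$effect_size_r, 1), 0.8)
  # no effect and no noise: everything ties, p = 1
  flat <- simulate_assay(sim_config(seed = 2, assay_sdlog = 0,
                                    assay_variant_top = 10))
  res_flat <- analyze_reporter_assay(flat)
  expect_equal(res_flat$test$p_value, 1)
})
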