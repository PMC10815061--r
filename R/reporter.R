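#' Normalize dual-luciferase readings
#'
#' Divides each well's firefly reading by its co-transfected control
#' reading. The standard control is renilla luciferase (transfection
#' efficiency); a different control column (e.g. beta-galactosidase) can be
#' named instead.
#'
#' @param measurements Tibble with one row per well, containing at least
#'   `firefly` and the normalizer column.
#' @param normalizer Name of the divisor column (default `"renilla"`).
#' @return The input tibble with an added `activity` column
#'   (`firefly / normalizer`).
#' @export
normalize_luciferase <- function(measurements, normalizer = "renilla") {
  if (!normalizer %in% names(measurements)) {
    abort(sprintf("normalizer column '%s' not found", normalizer))
  }
  div <- measurements[[normalizer]]
  if (any(is.na(div)) || any(div <= 0)) {
    abort("normalizer readings must be positive")
  }
  if (any(is.na(measurements$firefly)) || any(measurements$firefly <= 0)) {
    abort("firefly readings must be positive")
  }
  measurements %>% mutate(activity = .data$firefly / div)
}

#' TOP/FOP activity ratio
#'
#' Ratio of mean normalized activity of the functional (TOP) reporter to
#' the mutated-binding-site (FOP) control: the readout of canonical Wnt
#' transcriptional activity.
#'
#' @param top_values,fop_values Normalized activities of the two reporter
#'   groups; both non-empty.
#' @return `mean(top) / mean(fop)`.
#' @export
top_fop_ratio <- function(top_values, fop_values) {
  if (length(top_values) == 0L || length(fop_values) == 0L) {
    abort("both reporter groups must be non-empty")
  }
  mean(top_values) / mean(fop_values)
}

#' Exact Mann-Whitney U test with Z-based effect size
#'
#' Rank-sum test of two independent samples. For small samples
#' (`n1 + n2 <= 20`) the p-value is exact: every `choose(n1+n2, n1)`
#' relabeling of the pooled data is enumerated (midranks are used
#' throughout, so tied data are handled by the same enumeration). Larger
#' samples use the normal approximation with tie correction. The reported
#' `z_value` always comes from the normal form without continuity
#' correction, and the effect size is `r = |z| / sqrt(n1 + n2)`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param exact_max Largest pooled size for which the exact enumeration is
#'   used (default 20).
#' @return An object of class `mwu_test`: a list with `u_statistic` (U for
#'   `x`), `z_value`, `p_value`, `effect_size_r`, `n1`, `n2`,
#'   `alternative`, `method` (`"exact"` or `"normal-approximation"`).
#'   [tidy()] and [glance()] methods return one-row tibbles.
#' @examples
#' # two triplicate groups, fully separated
#' res <- mann_whitney(c(5.1, 5.4, 5.2), c(3.1, 3.3, 3.0),
#'                     alternative = "greater")
#' res$p_value        # 1/20 = 0.05
#' res$effect_size_r  # ~0.80
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact_max = 20L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks for ties
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  # normal form with tie correction, no continuity correction
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  z <- if (sigma > 0) (u_obs - mu) / sigma else 0

  if (n <= exact_max) {
    method <- "exact"
    u_all <- u_enumeration(rk, n1)
    eps <- 1e-9
    p <- switch(alternative,
      greater = mean(u_all >= u_obs - eps),
      less = mean(u_all <= u_obs + eps),
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
    )
  } else {
    method <- "normal-approximation"
    p <- switch(alternative,
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z),
      two.sided = 2 * pnorm(-abs(z))
    )
    p <- min(1, p)
  }
  structure(list(
    u_statistic = u_obs, z_value = z, p_value = p,
    effect_size_r = abs(z) / sqrt(n),
    n1 = n1, n2 = n2, alternative = alternative, method = method
  ), class = "mwu_test")
}

# U statistic for every labeling of the pooled midranks
u_enumeration <- function(rk, n1) {
  idx <- combn(length(rk), n1)
  colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U test (%s, %s)\n  U = %.4g, z = %.4g, p = %.4g\n  effect size r = %.4g  (n1 = %d, n2 = %d)\n",
    x$method, x$alternative, x$u_statistic, x$z_value, x$p_value,
    x$effect_size_r, x$n1, x$n2))
  invisible(x)
}

#' @rdname mann_whitney
#' @param x An `mwu_test` object.
#' @param ... Unused.
#' @method tidy mwu_test
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble(u_statistic = x$u_statistic, z_value = x$z_value,
         p_value = x$p_value, effect_size_r = x$effect_size_r,
         n1 = x$n1, n2 = x$n2, alternative = x$alternative,
         method = x$method)
}

#' @rdname mann_whitney
#' @method glance mwu_test
#' @export
glance.mwu_test <- function(x, ...) {
  tibble(p_value = x$p_value, effect_size_r = x$effect_size_r,
         method = x$method)
}

#' Full reporter-assay analysis
#'
#' Normalizes a measurement table, computes per-construct TOP/FOP ratios
#' and compares the wild-type and variant constructs' normalized TOP
#' activities with the exact Mann-Whitney test.
#'
#' @param measurements Tibble with columns `construct` (`"wt"`,
#'   `"variant"`, optionally others), `reporter` (`"TOP"`/`"FOP"`),
#'   `firefly`, and the normalizer column.
#' @inheritParams normalize_luciferase
#' @inheritParams mann_whitney
#' @param compare Length-2 character: constructs compared as (x, y) in the
#'   test; default `c("wt", "variant")`, so `alternative = "greater"` asks
#'   whether the wild type activates the reporter more strongly.
#' @return A list of class `reporter_analysis`: `data` (normalized table),
#'   `top_fop` (per-construct T/F ratio tibble), `test` (`mwu_test`).
#' @export
analyze_reporter_assay <- function(measurements, normalizer = "renilla",
                                   alternative = "two.sided",
                                   compare = c("wt", "variant")) {
  d <- normalize_luciferase(measurements, normalizer)
  tf <- d %>%
    group_by(.data$construct) %>%
    summarise(top_fop = top_fop_ratio(
      .data$activity[.data$reporter == "TOP"],
      .data$activity[.data$reporter == "FOP"]), .groups = "drop")
  top <- d %>% filter(.data$reporter == "TOP")
  test <- mann_whitney(
    top$activity[top$construct == compare[1]],
    top$activity[top$construct == compare[2]],
    alternative = alternative
  )
  structure(list(data = d, top_fop = tf, test = test),
            class = "reporter_analysis")
}

#' @export
print.reporter_analysis <- function(x, ...) {
  cat("Reporter assay analysis\nTOP/FOP ratios:\n")
  print(as.data.frame(x$top_fop), row.names = FALSE)
  print(x$test)
  invisible(x)
}
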