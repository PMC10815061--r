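#' Plot pairwise IBD segments and shared regions
#'
#' One horizontal track per affected pair with its IBD segments; shared
#' regions (if supplied) are shaded across all tracks.
#'
#' @param segments Segments tibble from [ibd_segments_all()].
#' @param regions Optional shared-region tibble from [shared_regions()].
#' @param chrom Optional single chromosome to display.
#' @return A ggplot object.
#' @export
plot_ibd_segments <- function(segments, regions = NULL, chrom = NULL) {
  if (!is.null(chrom)) {
    segments <- segments %>% filter(.data$chrom == !!chrom)
    if (!is.null(regions)) regions <- regions %>% filter(.data$chrom == !!chrom)
  }
  p <- ggplot2::ggplot(segments)
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      fill = "tomato", alpha = 0.2)
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$pair, yend = .data$pair),
      linewidth = 3, colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = "Pairwise IBD segments",
                  subtitle = if (!is.null(regions))
                    "shading: regions shared by all affected pairs" else NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-site allelic-ratio difference for one pair
#'
#' The site-level signal the segmentation consumes: allelic-ratio
#' differences along the chromosome, coloured by concordance class.
#'
#' @param calls Filtered genotype tibble.
#' @param id1,id2 Sample pair.
#' @param params Segmentation parameters (threshold drawn as a line).
#' @return A ggplot object.
#' @export
plot_ratio_diff <- function(calls, id1, id2,
                            params = segmentation_params()) {
  w <- pair_table(calls, id1, id2) %>%
    filter(!is.na(.data$a1_1), !is.na(.data$a2_1),
           !is.na(.data$a1_2), !is.na(.data$a2_2),
           .data$dp1 > 0, .data$dp2 > 0)
  w <- w %>% mutate(
    rd = ratio_diff(.data$ad_alt1, .data$dp1, .data$ad_alt2, .data$dp2),
    shared = shared_count_int(.data$a1_1, .data$a2_1, .data$a1_2, .data$a2_2),
    class = dplyr::case_when(
      pmin(.data$a1_1, .data$a2_1) == pmin(.data$a1_2, .data$a2_2) &
        pmax(.data$a1_1, .data$a2_1) == pmax(.data$a1_2, .data$a2_2) ~
        "identical (non-informative)",
      .data$shared == 0 | .data$rd > params$max_ratio_diff ~ "discordant",
      TRUE ~ "concordant"
    ))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$pos / 1e6, y = .data$rd,
                                  colour = .data$class)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = params$max_ratio_diff,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "allelic ratio difference",
                  colour = NULL,
                  title = sprintf("%s vs %s", id1, id2)) +
    ggplot2::theme_minimal()
}

#' Boxplot of normalized reporter activity
#'
#' @param measurements Measurement tibble (see
#'   [analyze_reporter_assay()]), or a `reporter_analysis` object.
#' @param normalizer Divisor column, when raw measurements are given.
#' @return A ggplot object.
#' @export
plot_reporter_assay <- function(measurements, normalizer = "renilla") {
  d <- if (inherits(measurements, "reporter_analysis")) {
    measurements$data
  } else {
    normalize_luciferase(measurements, normalizer)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$construct, y = .data$activity,
                                  fill = .data$construct)) +
    ggplot2::geom_boxplot(outliers = FALSE, alpha = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1),
                        size = 1.5) +
    ggplot2::facet_wrap(~reporter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "normalized activity (RLU ratio)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
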