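#' Simulation configuration
#'
#' Parameters of the seeded gene-dropping simulator. Defaults emulate the
#' study design: a ~30x short-read experiment over a 20 Mb chromosome with
#' one biallelic SNV per ~1.5 kb, founder alternate-allele frequency 0.3,
#' and a human-scale recombination rate of 1e-8 crossovers per bp per
#' meiosis.
#'
#' @param seed Integer seed fixing every draw.
#' @param chrom Chromosome label used in all outputs.
#' @param chrom_length_bp Simulated chromosome length.
#' @param snv_density_per_bp Expected SNVs per bp.
#' @param mean_depth Mean sequencing depth (Poisson).
#' @param recombination_rate Crossovers per bp per meiosis.
#' @param genotype_error_rate Probability a sample's genotype at a site is
#'   replaced by a uniformly different genotype before depths are drawn.
#' @param founder_alt_freq Bernoulli alternate-allele frequency of founder
#'   haplotypes.
#' @param risk_locus_bp Position of the planted risk locus; the designated
#'   risk haplotype is transmitted to every affected member at this locus.
#' @param truth_sv_count,sv_size_bp,sv_jitter_sd_bp,sv_fp_rate Structural
#'   variant truth-set size, event size, per-caller breakpoint jitter SD,
#'   and false-positive rate (expected FPs per caller as a fraction of the
#'   truth count).
#' @param assay_wt_top,assay_variant_top,assay_fop Median normalized
#'   activities used by the assay simulator (wild-type TOP, variant TOP,
#'   and FOP for both constructs).
#' @param assay_sdlog Log-scale SD of the simulated readings.
#' @param n_replicates Assay replicates per construct x reporter.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom = "chr11",
                       chrom_length_bp = 20000000L,
                       snv_density_per_bp = 1 / 1500,
                       mean_depth = 30,
                       recombination_rate = 1e-8,
                       genotype_error_rate = 0,
                       founder_alt_freq = 0.3,
                       risk_locus_bp = NULL,
                       truth_sv_count = 10L,
                       sv_size_bp = 10000L,
                       sv_jitter_sd_bp = 100,
                       sv_fp_rate = 0.2,
                       assay_wt_top = 10,
                       assay_variant_top = 6,
                       assay_fop = 2,
                       assay_sdlog = 0.15,
                       n_replicates = 3L) {
  if (is.null(risk_locus_bp)) risk_locus_bp <- chrom_length_bp %/% 2L
  cfg <- list(seed = as.integer(seed), chrom = chrom,
              chrom_length_bp = as.integer(chrom_length_bp),
              snv_density_per_bp = snv_density_per_bp,
              mean_depth = mean_depth,
              recombination_rate = recombination_rate,
              genotype_error_rate = genotype_error_rate,
              founder_alt_freq = founder_alt_freq,
              risk_locus_bp = as.integer(risk_locus_bp),
              truth_sv_count = as.integer(truth_sv_count),
              sv_size_bp = as.integer(sv_size_bp),
              sv_jitter_sd_bp = sv_jitter_sd_bp,
              sv_fp_rate = sv_fp_rate,
              assay_wt_top = assay_wt_top,
              assay_variant_top = assay_variant_top,
              assay_fop = assay_fop,
              assay_sdlog = assay_sdlog,
              n_replicates = as.integer(n_replicates))
  stopifnot(cfg$chrom_length_bp > 0, cfg$snv_density_per_bp > 0,
            cfg$mean_depth > 0, cfg$genotype_error_rate >= 0,
            cfg$genotype_error_rate < 1, cfg$founder_alt_freq > 0,
            cfg$founder_alt_freq < 1)
  structure(cfg, class = "sim_config")
}

#' Simulate pedigree genotypes by gene dropping
#'
#' Drops founder haplotypes down the pedigree with Poisson-process
#' crossovers, forcing a designated risk haplotype (one haplotype of the
#' first founder ancestral to the affected members) to be transmitted to
#' every affected member at the risk locus. Per-site read depths are
#' Poisson, alternate-allele depths binomial with allele fractions
#' 0.02/0.5/0.98 for ref/het/hom genotypes (allowing sequencing error),
#' and GQ is a phred-scaled likelihood margin capped at 99. Truth IBD
#' segments are recorded from the realized haplotype ancestries.
#'
#' @param config A [sim_config()].
#' @param ped Pedigree tibble; default [example_pedigree()]. Members with
#'   unknown phenotype (`affected` is `NA`) are treated as un-genotyped
#'   ancestors and excluded from the output calls.
#' @return A list of class `family_sim`: `calls` (long genotype tibble as
#'   from [read_vcf_genotypes()]), `truth` (list with `pair_segments`,
#'   `shared_regions` — the intersection across all affected pairs —
#'   `risk_locus_bp`, `positions`), `config`, `ped`.
#' @export
simulate_family <- function(config = sim_config(), ped = example_pedigree()) {
  set.seed(config$seed)
  L <- config$chrom_length_bp
  n_sites <- as.integer(round(L * config$snv_density_per_bp))
  positions <- sort(sample.int(L - 1L, n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))

  founders <- ped$id[is.na(ped$father_id) & is.na(ped$mother_id)]
  if (length(founders) == 0L) abort("pedigree has no founders")
  risk_idx <- which.min(abs(positions - config$risk_locus_bp))

  # identify the founder whose haplotype will be the risk haplotype: the
  # first founder that is an ancestor of every affected member
  aff_ids <- ped$id[!is.na(ped$affected) & ped$affected]
  anc_of <- function(id) {
    out <- character(0); queue <- id
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      row <- ped[ped$id == cur, ]
      ps <- stats::na.omit(c(row$father_id, row$mother_id))
      out <- union(out, ps); queue <- c(queue, ps)
    }
    out
  }
  common_anc <- Reduce(intersect, purrr::map(aff_ids, ~ c(.x, anc_of(.x))))
  risk_founder <- intersect(founders, common_anc)[1]
  if (is.na(risk_founder)) {
    abort("no founder is ancestral to every affected member")
  }
  risk_label <- paste0(risk_founder, ".h1")

  hap <- list()  # per member: list(alleles = n x 2, anc = n x 2)
  gamete <- function(parent_id, force_risk) {
    p <- hap[[parent_id]]
    k <- rpois(1, config$recombination_rate * L)
    bp <- sort(runif(k, 0, L))
    seg <- findInterval(positions, bp)
    s <- sample(1:2, 1)
    h <- 1L + (s - 1L + seg) %% 2L
    if (force_risk) {
      carrier_hap <- which(p$anc[risk_idx, ] == risk_label)
      if (length(carrier_hap) != 1L) {
        abort("parent does not carry the risk haplotype exactly once")
      }
      if (h[risk_idx] != carrier_hap) h <- 3L - h
    }
    list(alleles = p$alleles[cbind(seq_len(n_sites), h)],
         anc = p$anc[cbind(seq_len(n_sites), h)])
  }

  for (i in seq_len(nrow(ped))) {
    m <- ped[i, ]
    if (is.na(m$father_id) && is.na(m$mother_id)) {
      al <- matrix(rbinom(2L * n_sites, 1L, config$founder_alt_freq),
                   ncol = 2)
      an <- matrix(paste0(m$id, ".h", rep(1:2, each = n_sites)), ncol = 2)
      hap[[m$id]] <- list(alleles = al, anc = an)
    } else {
      if (is.na(m$father_id) || is.na(m$mother_id)) {
        abort(sprintf("member %s has only one declared parent; cannot gene-drop", m$id))
      }
      is_aff <- !is.na(m$affected) && m$affected
      force_f <- is_aff && risk_label %in% hap[[m$father_id]]$anc[risk_idx, ]
      force_m <- is_aff && !force_f &&
        risk_label %in% hap[[m$mother_id]]$anc[risk_idx, ]
      g_f <- gamete(m$father_id, force_f)
      g_m <- gamete(m$mother_id, force_m)
      hap[[m$id]] <- list(alleles = cbind(g_f$alleles, g_m$alleles),
                          anc = cbind(g_f$anc, g_m$anc))
    }
  }

  sequenced <- ped$id[!is.na(ped$affected)]
  calls <- purrr::map(sequenced, function(id) {
    g <- hap[[id]]$alleles[, 1] + hap[[id]]$alleles[, 2]
    if (config$genotype_error_rate > 0) {
      err <- runif(n_sites) < config$genotype_error_rate
      if (any(err)) {
        g[err] <- (g[err] + sample(1:2, sum(err), replace = TRUE)) %% 3L
      }
    }
    dp <- rpois(n_sites, config$mean_depth)
    p_alt <- c(0.02, 0.5, 0.98)[g + 1L]
    ad_alt <- rbinom(n_sites, dp, p_alt)
    ad_ref <- dp - ad_alt
    gq <- genotype_quality(ad_alt, dp)
    tibble(chrom = config$chrom, pos = positions, ref = ref, alt = alt,
           sample = id,
           gt = c("0/0", "0/1", "1/1")[g + 1L],
           a1 = as.integer(g >= 1L) * ifelse(g == 1L, 0L, 1L),
           a2 = as.integer(g >= 1L),
           ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, gq = gq)
  }) %>% bind_rows()

  pairs <- affected_pairs(ped, sample_ids = sequenced)
  pair_segments <- purrr::map2(pairs$id1, pairs$id2, function(i1, i2) {
    a <- hap[[i1]]$anc; b <- hap[[i2]]$anc
    share <- (a[, 1] == b[, 1]) | (a[, 1] == b[, 2]) |
      (a[, 2] == b[, 1]) | (a[, 2] == b[, 2])
    runs_to_intervals(share, positions, config$chrom) %>%
      mutate(id1 = i1, id2 = i2, pair = paste(i1, i2, sep = "|"))
  }) %>% bind_rows()
  truth_shared <- intersect_interval_sets(
    purrr::map(pairs$pair,
               ~ pair_segments %>% filter(.data$pair == .x) %>%
                 select("chrom", "start", "end")))

  structure(list(
    calls = calls,
    truth = list(pair_segments = pair_segments,
                 shared_regions = truth_shared,
                 risk_locus_bp = config$risk_locus_bp,
                 risk_founder = risk_founder,
                 positions = positions),
    config = config, ped = ped
  ), class = "family_sim")
}

# phred-scaled margin between best and second-best genotype likelihood
genotype_quality <- function(ad_alt, dp) {
  p_models <- c(0.02, 0.5, 0.98)
  ll <- vapply(p_models, function(p) dbinom(ad_alt, dp, p, log = TRUE),
               numeric(length(dp)))
  if (length(dp) == 1L) ll <- matrix(ll, nrow = 1)
  ord <- t(apply(ll, 1, sort, decreasing = TRUE))
  gq <- round(10 / log(10) * (ord[, 1] - ord[, 2]))
  gq[dp == 0L] <- 0L
  as.integer(pmin(gq, 99L))
}

# TRUE-runs of a site-level logical -> interval tibble spanning the run's
# outermost sites
runs_to_intervals <- function(flag, positions, chrom) {
  if (!any(flag)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(chrom = chrom,
         start = positions[starts[keep]] - 1L,
         end = positions[ends[keep]])
}

#' Simulate multi-caller SV call sets over a known truth set
#'
#' Places `truth_sv_count` non-overlapping events of `sv_size_bp` uniformly
#' along the chromosome; each of three pseudo-callers reports every truth
#' event with breakpoints jittered Normal(0, `sv_jitter_sd_bp`) plus
#' Poisson(`sv_fp_rate` x truth count) private false positives. One
#' designated truth event segregates with the phenotype (het in every
#' affected, ref in the unaffected); the rest receive random carrier sets.
#' The read-depth caller (`cnvnator`) reports no genotypes.
#'
#' @param config A [sim_config()].
#' @param ped Pedigree tibble (carrier assignment).
#' @return List: `callsets` (one tibble, `caller` column, see
#'   [merge_callsets()]), `truth` (tibble with `sv_id`, coordinates,
#'   `svtype`, `segregating`, `carriers`).
#' @export
simulate_sv_callsets <- function(config = sim_config(),
                                 ped = example_pedigree()) {
  set.seed(config$seed + 1L)
  n <- config$truth_sv_count
  sequenced <- ped$id[!is.na(ped$affected)]
  aff <- ped$id[!is.na(ped$affected) & ped$affected]
  empty_calls <- tibble(chrom = character(), start = integer(),
                        end = integer(), svtype = character(),
                        caller = character(), quality = double(),
                        filter = character(), genotypes = list())
  if (n == 0L) {
    return(list(callsets = empty_calls,
                truth = tibble(sv_id = character(), chrom = character(),
                               start = integer(), end = integer(),
                               svtype = character(), segregating = logical(),
                               carriers = list())))
  }
  # one event per equal-width bin keeps the truth set non-overlapping
  bin <- config$chrom_length_bp %/% n
  offset_max <- max(1L, bin - config$sv_size_bp - 2000L)
  starts <- (seq_len(n) - 1L) * bin + sample.int(offset_max, n, replace = TRUE)
  svtype <- sample(c("DEL", "DUP"), n, replace = TRUE)
  seg_idx <- sample.int(n, 1)
  carriers <- purrr::map(seq_len(n), function(i) {
    if (i == seg_idx) aff
    else {
      k <- sample(0:length(sequenced), 1)
      sort(sample(sequenced, k))
    }
  })
  truth <- tibble(sv_id = sprintf("truthSV%02d", seq_len(n)),
                  chrom = config$chrom, start = starts,
                  end = starts + config$sv_size_bp, svtype = svtype,
                  segregating = seq_len(n) == seg_idx,
                  carriers = carriers)

  gt_for <- function(carr) {
    setNames(ifelse(sequenced %in% carr, "het", "ref"), sequenced)
  }
  callers <- c("manta", "lumpy", "cnvnator")
  callsets <- purrr::map(callers, function(cl) {
    jitter_s <- as.integer(round(rnorm(n, 0, config$sv_jitter_sd_bp)))
    jitter_e <- as.integer(round(rnorm(n, 0, config$sv_jitter_sd_bp)))
    tp <- tibble(
      chrom = config$chrom,
      start = pmax(0L, truth$start + jitter_s),
      end = truth$end + jitter_e,
      svtype = truth$svtype,
      caller = cl,
      quality = round(runif(n, 20, 60), 1),
      filter = "PASS",
      genotypes = if (cl == "cnvnator") {
        rep(list(setNames(rep("missing", length(sequenced)), sequenced)), n)
      } else {
        purrr::map(truth$carriers, gt_for)
      }
    )
    n_fp <- rpois(1, config$sv_fp_rate * n)
    if (n_fp > 0L) {
      fp_start <- sample.int(config$chrom_length_bp - 2L * config$sv_size_bp,
                             n_fp)
      fp <- tibble(
        chrom = config$chrom, start = fp_start,
        end = fp_start + as.integer(round(runif(n_fp, 0.3, 1.5) *
                                            config$sv_size_bp)),
        svtype = sample(c("DEL", "DUP"), n_fp, replace = TRUE),
        caller = cl, quality = round(runif(n_fp, 20, 60), 1),
        filter = "PASS",
        genotypes = purrr::map(seq_len(n_fp), function(i) {
          gt_for(sample(sequenced, sample(1:2, 1)))
        })
      )
      tp <- bind_rows(tp, fp)
    }
    tp
  }) %>% bind_rows()
  list(callsets = callsets, truth = truth)
}

#' Simulate a dual-luciferase measurement table
#'
#' Log-normal firefly and renilla readings for wild-type and variant
#' constructs under TOP and FOP reporters, with the configured median
#' normalized activities ([sim_config()]). With `assay_sdlog = 0` the
#' readings are deterministic and the wild-type/variant TOP groups are
#' completely separated.
#'
#' @param config A [sim_config()].
#' @return Measurement tibble: `construct`, `reporter`, `replicate`,
#'   `experiment`, `firefly`, `renilla`.
#' @export
simulate_assay <- function(config = sim_config()) {
  set.seed(config$seed + 2L)
  design <- tidyr::expand_grid(
    construct = c("wt", "variant"),
    reporter = c("TOP", "FOP"),
    replicate = seq_len(config$n_replicates)
  )
  median_act <- dplyr::case_when(
    design$reporter == "FOP" ~ config$assay_fop,
    design$construct == "wt" ~ config$assay_wt_top,
    TRUE ~ config$assay_variant_top
  )
  renilla <- rlnorm(nrow(design), log(100), config$assay_sdlog / 2)
  firefly <- renilla * rlnorm(nrow(design), log(median_act), config$assay_sdlog)
  design %>%
    mutate(experiment = "E1", firefly = firefly, renilla = renilla) %>%
    select("construct", "reporter", "replicate", "experiment",
           "firefly", "renilla")
}

#' Simulate a gene track with prioritization scores
#'
#' Lays out non-overlapping genes along the simulated chromosome, places
#' one gene over the planted risk locus, and draws phenotype-prioritization
#' scores: high for the risk gene, sub-threshold for the rest.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes to place.
#' @param gene_size_bp Gene length.
#' @return List: `genes` (interval tibble with `name`), `scores`
#'   (gene-score tibble), `risk_gene` (name of the gene over the risk
#'   locus).
#' @export
simulate_gene_track <- function(config = sim_config(), n_genes = 50L,
                                gene_size_bp = 20000L) {
  set.seed(config$seed + 3L)
  bin <- config$chrom_length_bp %/% n_genes
  offset_max <- max(1L, bin - gene_size_bp)
  starts <- (seq_len(n_genes) - 1L) * bin +
    sample.int(offset_max, n_genes, replace = TRUE)
  genes <- tibble(chrom = config$chrom, start = starts,
                  end = starts + gene_size_bp,
                  name = sprintf("GENE%03d", seq_len(n_genes)))
  # drop whichever gene owns the risk bin and replace it with one centred
  # on the risk locus, so exactly one gene covers the planted locus
  risk_i <- findInterval(config$risk_locus_bp, starts)
  risk_i <- max(1L, risk_i)
  genes$start[risk_i] <- config$risk_locus_bp - gene_size_bp %/% 2L
  genes$end[risk_i] <- genes$start[risk_i] + gene_size_bp
  risk_gene <- genes$name[risk_i]
  scores <- tibble(
    gene = genes$name,
    score = round(runif(n_genes, 0.01, 0.45), 3),
    variant_ids = rep(list(character(0)), n_genes)
  )
  scores$score[genes$name == risk_gene] <- 0.95
  list(genes = genes, scores = scores, risk_gene = risk_gene)
}
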