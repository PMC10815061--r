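---
title: "Allele-balance IBD mapping in small pedigrees: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-balance IBD mapping in small pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(pedmapr)
```

This vignette is the package's own account of its methods: the models and
their assumptions, every tunable parameter with its default and rationale,
what the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## 1. The mapping model

The setting is a small family segregating an apparently autosomal-dominant
phenotype — in the motivating design, four affected relatives spanning two
generations (two sibs, plus two children of one of them) and one unaffected
spouse, all whole-genome sequenced at about 30×. Under a dominant model
with a single causal locus, the causal allele lies on one ancestral
haplotype, and every *pair* of affected relatives must share that haplotype
region identical by descent with at least one allele (IBD1 or IBD2). The
mapping statistic therefore needs only pairwise sharing, intersected across
all affected pairs; it does not need phasing, population allele
frequencies, or an HMM.

Sharing is read from allele balance rather than from hard genotype calls
alone. For patients 1 and 2 of a pair at site $A$:

$$\mathrm{Ratio\,diff}_A \;=\; \left|\;\frac{AD_{A1}}{DP_{A1}} - \frac{AD_{A2}}{DP_{A2}}\;\right|$$

with $AD$ the alternate-allele read count and $DP$ the total depth. At 30×,
two individuals with the same genotype have a ratio difference near 0,
het-vs-hom pairs sit near 0.5, and opposite homozygotes near 1. Using the
read-level ratio instead of the called genotype keeps the statistic
informative when a genotype is miscalled but the reads tell the truth.

### Per-sample hard filters

Before pairing, every site must pass, in every sequenced sample:

* `DP > 14` and `GQ > 30` — strict inequalities, exactly as printed in the
  filter specification the package implements;
* Mendelian consistency for every trio whose parents are among the
  sequenced samples (`mendelian_consistent()`); a site with any missing
  genotype in a trio is *not testable* and is retained, because an error
  cannot be asserted on missing data;
* alternate-allele support: any non-reference call must be backed by at
  least one alternate read (`require_alt_support`, the per-site reading of
  an "allelic ratio difference of > 0"). The flag can be disabled; whether
  that condition was meant per-site or post-pairing is ambiguous in the
  source description, so both behaviours are reachable.

Members with genotypes but un-genotyped parents are treated as founders
for the Mendelian check: the check applies only where data exist. Only
trio-local constraints are tested; no grandparental inference is done.

### Site classification and segmentation

For one affected pair, each biallelic autosomal SNV that passed filtering
is classified:

* **context** — identical unordered genotypes. These carry no information
  about *which* haplotype was transmitted (they are filtered from the
  ratio-difference analysis as non-informative) but they are fully
  compatible with sharing, and a long stretch of them is exactly what an
  IBD2 region looks like. They support segments without counting as
  informative.
* **concordant informative** — sharing ≥ 1 allele and
  $\mathrm{Ratio\,diff} \le$ `max_ratio_diff`.
* **discordant** — sharing 0 alleles (opposite homozygotes) or an extreme
  ratio difference.

Segments are maximal runs of non-discordant sites. Three rules end or
reject a segment, each with a parameter in `segmentation_params()`:

| parameter | default | role |
|---|---|---|
| `max_ratio_diff` | 0.8 | discordance threshold on the ratio difference |
| `max_discordant_run` | 1 | longest tolerated run of consecutive discordant sites |
| `window_sites` / `window_max_disc` | 30 / 2 | a 30-site window holding > 2 discordant sites separates segments |
| `min_sites` | 25 | minimum supporting (non-discordant) sites |
| `min_span_bp` | 500 kb | minimum segment span |
| `max_discordant_frac` | 0.03 | maximum overall discordant fraction in a segment |
| `end_trim_frac` | 0.04 | trim terminal stretches whose discordance density reaches this |

Why these defaults, at 30× with binomial read sampling:

* **`max_ratio_diff = 0.8`.** The informative genotype configurations
  compatible with IBD1 are het-vs-hom, with expected ratio difference
  ≈ 0.48 and standard deviation ≈ 0.095 at DP 30 (+3σ ≈ 0.76). Opposite
  homozygotes sit at ≈ 0.96 ± 0.04 (−3σ ≈ 0.85). The threshold 0.8 sits in
  the gap: it never rejects genuine one-allele sharing, while a genotype
  whose reads contradict its call (e.g. a "het" with 28 of 30 reference
  reads facing a hom-alt partner) is caught as discordant even though the
  called genotypes share an allele. A lower threshold (e.g. 0.45, which
  separates het-vs-het from het-vs-hom) would misclassify *every*
  het-vs-hom site — i.e. essentially all informative sites inside true
  IBD1 — as discordant, making IBD1 undetectable; only a threshold between
  the het-vs-hom and opposite-hom bands is coherent with the IBD1-or-IBD2
  sharing model.
* **`max_discordant_run = 1`.** One isolated discordant site is the
  signature of a single genotyping error and is tolerated; two adjacent
  discordant sites essentially never occur inside true IBD ground
  (error² ≈ 10⁻⁵ per site) but occur every ~10–15 informative sites in
  non-IBD ground, terminating segments within tens of kilobases of the
  true boundary.
* **Windowed separator.** Discordant sites in non-IBD ground are frequent
  (~9% of sites at founder allele frequency 0.3) but not always adjacent;
  a short non-IBD gap between two true segments can fail to produce two
  adjacent discordant sites. Any 30-site window holding 3+ discordant
  sites is far outside what genotyping error can produce (p ≈ 10⁻⁴ over a
  whole chromosome at 0.5% genotype error), so its discordant sites also
  act as separators; the short concordant scraps between them fall below
  `min_sites`/`min_span_bp` and drop out.
* **Support counting includes context sites.** A region where a pair
  shares *both* alleles (IBD2 — e.g. long stretches between crossovers in
  a sib pair) consists almost entirely of identical genotypes and can
  contain literally zero informative sites. Counting only informative
  sites would make IBD2 invisible and collapse the all-pairs intersection;
  since the dominant model accepts IBD1 *or* IBD2, segments are supported
  by all non-discordant sites. A segment with no informative site is
  labelled `min_shared_alleles = 2` (pure IBD2); otherwise the label is
  the minimum shared-allele count over informative sites.
* **`max_discordant_frac` and `end_trim_frac`.** Segment-level and
  boundary-level purity guards. Non-IBD ground that survives the run rules
  still carries ~9% discordance overall (vs ≲ 0.5% inside true segments
  even with 0.5% genotype error), so segments above 3% are rejected, and
  terminal stretches whose local discordance density reaches 4% are
  trimmed back. Both thresholds sit an order of magnitude above the
  error-induced rate and well below the non-IBD rate.

`min_sites = 25` and `min_span_bp = 500 kb` express the prior that a
mappable dominant locus in a multi-generation family lies on a
recombination-bounded haplotype of at least ~0.5 cM scale; both are
ordinary tuning knobs, and the monotonicity property (raising either never
increases the shared span) is tested.

### Intersection and the unaffected member

`shared_regions()` intersects, per chromosome, the union of each affected
pair's segments: a region is rejected unless *every* affected pair shares
it with at least one allele. The unaffected member is not used by default
— the pairwise analysis is defined over affected pairs only. An optional
`exclude_unaffected()` step subtracts ground the unaffected member shares
(with ≥ 1 allele) with every affected member, for the full-penetrance
reading in which the causal haplotype must be absent from healthy
relatives; with incomplete penetrance that subtraction is unsafe, which is
why it is opt-in rather than default. Both modes are provided because the
source description supports either reading.

Coordinates: VCF positions are 1-based; all derived intervals (segments,
regions, gene tracks, SVs) are 0-based half-open internally and in BED
output.

## 2. Candidate prioritization

Gene-level prioritization scores are produced by external phenotype-aware
tools and consumed as TSV (`load_gene_scores()`; the gene and score column
names are configurable because different tools and versions label their
score columns differently). `genes_in_regions()` keeps genes overlapping
≥ 1 bp of any shared region — overlap, not containment, since a gene
straddling a region boundary is still a positional candidate.
`filter_by_score()` discards scores strictly below the cutoff (default
0.5): "less than 0.5 discarded" read literally means 0.5 itself survives.

## 3. Structural-variant consensus

Breakend placement differs between callers, so per-caller call sets are
merged under a two-condition rule with defaults of 50% reciprocal overlap
and 1000 bp breakend distance:

* **Reciprocal overlap** = intersection length divided by the *longer*
  constraint, i.e. `min(ov/len(a), ov/len(b))` — the standard symmetric
  criterion.
* **Breakend distance** must hold at *both* ends by default (a
  `both_breakends = FALSE` mode accepts either end, since the rule's
  quantifier is ambiguous in prose).
* Insertions and breakend records have no meaningful interval length, so
  they merge on breakend distance alone.

Clustering is **single-linkage** (connected components of the pairwise
mergeable graph): this matches the behaviour of the standard SV merging
tools, is order-independent, and is deterministic; clique-based merging
would make cluster membership depend on input order. The consensus
interval is the per-coordinate **median** of members — robust to one
outlier caller. The per-sample consensus genotype is the most severe
non-missing member genotype; read-depth callers that do not genotype
contribute `missing`, which under the dominant-model filter is
non-informative and never rejects an event on its own. Single-caller
events are retained by default (`min_callers = 1`), since requiring
multi-caller support is a stringency choice the analyst should make
explicitly.

Per-caller hard filters are configuration, not code (each caller's
authors publish their own recommendations); the shipped default requires
a PASS flag where a flag is present. Downstream, events are rejected
unless they segregate dominantly (carrier in all affected, reference in
all unaffected) and overlap at least one phenotype-related gene, and —
when shared regions are supplied — lie inside them.

## 4. Reporter-assay statistics

Firefly readings are normalized to the co-transfected renilla control
(`normalize_luciferase()`); the source protocol mentions both renilla and
β-galactosidase normalization in different places, so the divisor column
is an argument and renilla — the control actually co-transfected with
every construct — is the default. The TOP/FOP ratio is the ratio of group means
of normalized activities.

`mann_whitney()` is an exact implementation:

* For pooled $n_1+n_2 \le 20$, the p-value enumerates all
  $\binom{n_1+n_2}{n_1}$ labelings of the pooled midranks — exact also
  under ties (conditional on the tie pattern). Larger samples use the
  tie-corrected normal approximation.
* The reported $z$ always comes from the normal form **without continuity
  correction**, and the effect size is $r = |z|/\sqrt{N}$. This choice is
  deliberate and documented prominently: for fully separated triplicates
  ($U = 9$, $\mu = 4.5$, $\sigma = \sqrt{9\cdot7/12}$),
  $r = (4.5/\sqrt{5.25})/\sqrt{6} \approx 0.802$; with continuity
  correction $r \approx 0.71$. Only the uncorrected form is consistent
  with the conventional r ≈ 0.8 reported for this configuration.
* With three replicates per group, the smallest achievable one-sided exact
  p is $1/20 = 0.05$, attained exactly at complete separation. A
  *two-sided* test of the same data gives 0.10; a borderline p of 0.05
  from separated triplicates therefore implies a one-sided reading, which
  `analyze_reporter_assay()` exposes via `alternative = "greater"` but
  does not default to (the default is two-sided). Note also that exact
  within-group ties (possible only in noise-free simulation) shrink the
  tie-corrected $\sigma$ and push $r$ to ~0.91; the canonical 0.802 is the
  untied value.

## 5. The synthetic-data generator

`simulate_family()` gene-drops founder haplotypes down the pedigree:

* Founder haplotypes are i.i.d. Bernoulli(0.3) per site — 0.3 being a
  typical common-variant alternate-allele frequency that yields a
  realistic mix of informative and non-informative sites.
* Each meiosis receives Poisson crossovers at 1 cM/Mb (1e-8 per bp), the
  genome-wide human average.
* One haplotype of the founder ancestral to all affected members is
  designated the risk haplotype and is forced to transmit to every
  affected member at the risk locus (default: mid-chromosome); crossovers
  elsewhere are free, so truth IBD segments vary by seed and are recorded
  exactly from the realized haplotype ancestries.
* Depths are Poisson(30); alternate read counts are Binomial(DP, p) with
  p ∈ {0.02, 0.5, 0.98} for ref/het/hom — homozygotes see 2% opposite
  reads, emulating sequencing error so the ratio-difference thresholds are
  meaningfully exercised. GQ is a phred-scaled likelihood margin between
  the best and second-best of the three binomial genotype models, capped
  at 99 — not a full genotyper, but realistic around the GQ > 30
  threshold, which is all that matters here.
* Genotype errors (optional rate) replace the true genotype by a uniformly
  different one *before* depths are drawn, so both the call and its reads
  reflect the error; a label-only error would be invisible to an
  allele-balance statistic and would test nothing.

Default scale is a 20 Mb chromosome at one SNV per 1.5 kb (~13,300 sites),
which the tests and the acceptance script use throughout; the full
pipeline on that scale runs in a few seconds. What the generator does
**not** emulate — and what passing tests therefore do not demonstrate —
includes linkage disequilibrium and realistic allele-frequency spectra,
indels and multi-allelic sites, mapping artefacts and depth waves,
population structure, and X-linked inheritance. The truth labels certify
the *segmentation and intersection machinery*, not performance on real
genomes.

`simulate_sv_callsets()` plants non-overlapping 10 kb DEL/DUP events (one
per equal-width bin), jitters breakpoints per caller with Normal(0, 100 bp)
noise, adds Poisson private false positives per caller (rate 0.2 of the
truth count), designates one event as dominantly segregating, and gives
the read-depth pseudo-caller no genotypes. `simulate_assay()` draws
log-normal readings with configurable median activities (defaults 10/6/2
for wt-TOP/variant-TOP/FOP, log-sd 0.15): a modest, not dramatic,
signalling decrease, consistent with a borderline rank-test outcome at
n = 3.

## 6. Numerical and degenerate-input conventions

* Identical seeds reproduce byte-identical simulations; the pipeline is a
  pure function of inputs and parameters (rerun determinism is tested).
* `allelic_ratio()` refuses DP = 0; sites with missing genotypes are
  skipped in pairing rather than treated as discordant.
* A pair with *no* segments yields an empty intersection (a flat segments
  table cannot distinguish a pair that was analysed and found empty from
  one that is absent; both mean "no shared ground", so both give the empty
  result).
* AD sums exceeding DP are flagged (`ad_exceeds_dp`), not rejected.
* Multi-allelic records are skipped by default and counted; an optional
  split mode decomposes them against each ALT with canonicalized allele
  order. Indels and non-autosomes are always excluded from the IBD path.
* Ties in `mann_whitney()` use midranks everywhere — observed U, the
  enumeration, and the tie-corrected normal form — so the three never
  disagree on convention.

## 7. Known limitations

* The segmentation is run-based, not likelihood-based: it has no explicit
  genotype-error model and its parameters, while individually motivated,
  are heuristics. An HMM over IBD states would be the natural next step
  and is deliberately out of scope.
* IBD2 vs IBD1 labelling of mixed segments is coarse (minimum over
  informative sites).
* The dominant-model SV filter assumes full penetrance within the
  sequenced family; the optional unaffected-exclusion step for SNV regions
  makes the same assumption and is therefore opt-in.
* Gene-score prioritization inherits whatever biases the external scoring
  tool has; the package only composes it with positional evidence.
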