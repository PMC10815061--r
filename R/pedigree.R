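#' Read a PED pedigree file
#'
#' Parses the standard 6-column PED format (family, individual, father,
#' mother, sex, phenotype) into a pedigree tibble. `"0"` denotes an absent
#' parent. Phenotype coding follows the usual PED dialect: 2 = affected,
#' 1 = unaffected, 0 or -9 = unknown (treated as unaffected when
#' enumerating affected pairs).
#'
#' @param path Path to a PED file, or a character vector of PED lines.
#' @param strict In strict mode (default) a parent id that is neither `"0"`
#'   nor a declared member is an error; in lenient mode it is recorded as an
#'   un-genotyped founder and dropped from the parent column with a message.
#'
#' @return A tibble of class `pedmapr_pedigree` with columns `family`, `id`,
#'   `father_id`, `mother_id` (`NA` when absent), `sex`
#'   (`"male"`/`"female"`/`"unknown"`) and `affected` (logical; `NA` for
#'   unknown phenotype).
#'
#' @examples
#' ped <- read_pedigree(textConnection(
#'   "FAM II.8 0 0 2 2
#'    FAM II.9 0 0 1 2
#'    FAM II.10 0 0 2 1
#'    FAM III.3 II.9 II.10 1 2
#'    FAM III.7 II.9 II.10 2 2"))
#' affected_pairs(ped)
#' @export
read_pedigree <- function(path, strict = TRUE) {
  lines <- if (inherits(path, "connection")) readLines(path) else {
    if (length(path) == 1L && file.exists(path)) readLines(path) else path
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort("PED input contains no records")
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) {
    abort(sprintf("PED line %d has fewer than 6 columns", bad[1]))
  }
  ped <- tibble(
    family    = purrr::map_chr(fields, 1),
    id        = purrr::map_chr(fields, 2),
    father_id = purrr::map_chr(fields, 3),
    mother_id = purrr::map_chr(fields, 4),
    sex_code  = purrr::map_chr(fields, 5),
    pheno     = purrr::map_chr(fields, 6)
  )
  if (anyDuplicated(ped$id)) {
    abort(sprintf("duplicate individual id in PED: '%s'",
                  ped$id[duplicated(ped$id)][1]))
  }
  ped <- ped %>%
    mutate(
      father_id = ifelse(.data$father_id == "0", NA_character_, .data$father_id),
      mother_id = ifelse(.data$mother_id == "0", NA_character_, .data$mother_id),
      sex = case_when(
        .data$sex_code == "1" ~ "male",
        .data$sex_code == "2" ~ "female",
        TRUE ~ "unknown"
      ),
      affected = case_when(
        .data$pheno == "2" ~ TRUE,
        .data$pheno == "1" ~ FALSE,
        TRUE ~ NA
      )
    ) %>%
    select("family", "id", "father_id", "mother_id", "sex", "affected")

  for (col in c("father_id", "mother_id")) {
    missing_ref <- setdiff(stats::na.omit(ped[[col]]), ped$id)
    if (length(missing_ref)) {
      if (strict) {
        abort(sprintf(
          "parent id '%s' is not a declared member (use strict = FALSE to treat as un-genotyped founder)",
          missing_ref[1]))
      }
      inform(sprintf("treating undeclared parent(s) %s as un-genotyped founders",
                     paste(missing_ref, collapse = ", ")))
      ped[[col]][ped[[col]] %in% missing_ref] <- NA_character_
    }
  }
  validate_pedigree(ped)
}

#' Construct a pedigree tibble from vectors
#'
#' @param id,father_id,mother_id,sex,affected Member attributes; parent ids
#'   use `NA` for absent. `sex` is `"male"`, `"female"` or `"unknown"`.
#' @param family Family label recycled across members.
#' @return A `pedmapr_pedigree` tibble (see [read_pedigree()]).
#' @export
pedigree <- function(id, father_id = NA, mother_id = NA, sex = "unknown",
                     affected = FALSE, family = "FAM") {
  ped <- tibble(
    family = family, id = as.character(id),
    father_id = as.character(father_id), mother_id = as.character(mother_id),
    sex = sex, affected = affected
  )
  if (anyDuplicated(ped$id)) abort("duplicate individual id in pedigree")
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  # cycle check: repeatedly peel members whose parents are all already peeled
  remaining <- ped$id
  parents <- purrr::map(seq_len(nrow(ped)), function(i) {
    stats::na.omit(c(ped$father_id[i], ped$mother_id[i]))
  })
  names(parents) <- ped$id
  done <- character(0)
  repeat {
    peelable <- remaining[purrr::map_lgl(parents[remaining], function(p) {
      all(!(p %in% remaining))
    })]
    if (length(peelable) == 0L) break
    done <- c(done, peelable)
    remaining <- setdiff(remaining, peelable)
  }
  if (length(remaining)) {
    abort(sprintf("pedigree contains an ancestry cycle involving: %s",
                  paste(remaining, collapse = ", ")))
  }
  class(ped) <- c("pedmapr_pedigree", class(tibble()))
  ped
}

#' The default three-generation study family
#'
#' A seven-member pedigree modelled on a family segregating an autosomal
#' dominant limb malformation: two un-genotyped first-generation founders,
#' two affected second-generation sibs (II.8, II.9), the unaffected spouse
#' II.10, and two affected children (III.3, III.7) of the II.9 x II.10
#' couple. Five members (II.8, II.9, II.10, III.3, III.7) are the sequenced
#' subset used throughout the package examples and simulations.
#'
#' @param sequenced_only Drop the un-genotyped founders, leaving the
#'   five-member sequenced subset (the two sibs then appear as founders).
#' @return A `pedmapr_pedigree` tibble.
#' @export
example_pedigree <- function(sequenced_only = FALSE) {
  ped <- pedigree(
    id        = c("I.1", "I.2", "II.8", "II.9", "II.10", "III.3", "III.7"),
    father_id = c(NA, NA, "I.1", "I.1", NA, "II.9", "II.9"),
    mother_id = c(NA, NA, "I.2", "I.2", NA, "II.10", "II.10"),
    sex       = c("male", "female", "female", "male", "female",
                  "male", "female"),
    affected  = c(NA, NA, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  if (sequenced_only) {
    ped <- ped %>%
      filter(.data$id != "I.1", .data$id != "I.2") %>%
      mutate(
        father_id = ifelse(.data$father_id %in% c("I.1", "I.2"),
                           NA_character_, .data$father_id),
        mother_id = ifelse(.data$mother_id %in% c("I.1", "I.2"),
                           NA_character_, .data$mother_id)
      )
    class(ped) <- c("pedmapr_pedigree", class(tibble()))
  }
  ped
}

#' Sequenced sample ids of a pedigree
#'
#' By convention the sequenced members are those listed in `sample_ids`
#' (an attribute set by the caller) or, absent that, every member; helpers
#' below restrict to ids actually present in a genotype table.
#' @noRd
sequenced_ids <- function(ped, calls = NULL) {
  ids <- ped$id
  if (!is.null(calls)) ids <- intersect(ids, unique(calls$sample))
  ids
}

#' Enumerate all unordered pairs of affected members
#'
#' Pairwise IBD analysis compares every affected member against every other,
#' so a family with k affected yields choose(k, 2) pairs.
#'
#' @param ped A pedigree tibble.
#' @param sample_ids Optional character vector restricting to members with
#'   genotype data (e.g. the VCF sample column names).
#' @return A tibble with columns `id1`, `id2` (lexicographic within and
#'   across rows) and `pair` (`"id1|id2"`), possibly zero rows.
#' @export
affected_pairs <- function(ped, sample_ids = NULL) {
  aff <- ped$id[!is.na(ped$affected) & ped$affected]
  if (!is.null(sample_ids)) aff <- intersect(aff, sample_ids)
  aff <- sort(aff)
  if (length(aff) < 2L) {
    return(tibble(id1 = character(), id2 = character(), pair = character()))
  }
  cmb <- combn(aff, 2)
  tibble(id1 = cmb[1, ], id2 = cmb[2, ],
         pair = paste(cmb[1, ], cmb[2, ], sep = "|")) %>%
    arrange(.data$id1, .data$id2)
}

parse_gt <- function(gt) {
  # "0/1", "0|1", "./." or NA -> 2-column integer matrix (NA = missing allele)
  gt <- as.character(gt)
  nsep <- stringr::str_count(gt, "[/|]")
  if (any(!is.na(gt) & gt != "." & nsep != 1L)) {
    abort("genotypes must be diploid (two alleles)")
  }
  parts <- stringr::str_split_fixed(gt, "[/|]", 2)
  a1 <- suppressWarnings(as.integer(parts[, 1]))
  a2 <- suppressWarnings(as.integer(parts[, 2]))
  cbind(a1, a2)
}

gt_alleles <- function(gt) {
  if (is.character(gt) || is.factor(gt)) {
    al <- parse_gt(gt)
  } else if (is.numeric(gt)) {
    if (length(gt) != 2L) abort("genotypes must be diploid (two alleles)")
    al <- matrix(as.integer(gt), nrow = 1)
  } else if (is.null(gt)) {
    al <- matrix(NA_integer_, nrow = 1, ncol = 2)
  } else {
    abort("unsupported genotype representation")
  }
  al
}

#' Mendelian consistency of a child genotype given its parents
#'
#' A trio is consistent when some assignment of one allele from each
#' available parent explains the child. With a single available parent the
#' child must share at least one allele with that parent; with no parents,
#' or with any missing genotype, the site is not testable and passes.
#'
#' Genotypes are `"a/b"` strings (phased `|` accepted) or length-2 integer
#' vectors; `NULL`, `NA` or `"./."` denote missing. All arguments are
#' vectorized over equal-length character vectors.
#'
#' @param child,father,mother Genotypes as described above.
#' @return Logical vector: `TRUE` where the transmission is consistent or
#'   not testable.
#' @examples
#' mendelian_consistent("0/1", "0/0", "1/1")  # TRUE, forced transmission
#' mendelian_consistent("0/1", "0/0", "0/0")  # FALSE, de novo pattern
#' @export
mendelian_consistent <- function(child, father = NULL, mother = NULL) {
  cc <- gt_alleles(child)
  ff <- if (is.null(father)) matrix(NA_integer_, nrow(cc), 2) else gt_alleles(father)
  mm <- if (is.null(mother)) matrix(NA_integer_, nrow(cc), 2) else gt_alleles(mother)
  n <- max(nrow(cc), nrow(ff), nrow(mm))
  rep_rows <- function(m) if (nrow(m) == n) m else m[rep(1L, n), , drop = FALSE]
  cc <- rep_rows(cc); ff <- rep_rows(ff); mm <- rep_rows(mm)
  mendel_ok(cc[, 1], cc[, 2], ff[, 1], ff[, 2], mm[, 1], mm[, 2])
}

# vectorized core over integer allele columns; NA anywhere in a genotype
# makes that genotype "missing"
mendel_ok <- function(c1, c2, f1, f2, m1, m2) {
  c_miss <- is.na(c1) | is.na(c2)
  f_miss <- is.na(f1) | is.na(f2)
  m_miss <- is.na(m1) | is.na(m2)

  from_f <- function(a) !f_miss & (a == f1 | a == f2)
  from_m <- function(a) !m_miss & (a == m1 | a == m2)

  both <- (from_f(c1) & from_m(c2)) | (from_f(c2) & from_m(c1))
  one_f <- from_f(c1) | from_f(c2)
  one_m <- from_m(c1) | from_m(c2)

  out <- rep(TRUE, length(c1))
  testable <- !c_miss & !(f_miss & m_miss)
  full <- testable & !f_miss & !m_miss
  only_f <- testable & !f_miss & m_miss
  only_m <- testable & f_miss & !m_miss
  out[full] <- both[full]
  out[only_f] <- one_f[only_f]
  out[only_m] <- one_m[only_m]
  out
}

#' @export
print.pedmapr_pedigree <- function(x, ...) {
  n_aff <- sum(x$affected, na.rm = TRUE)
  cat(sprintf("# Pedigree: %d members (%d affected, %d founders)\n",
              nrow(x), n_aff,
              sum(is.na(x$father_id) & is.na(x$mother_id))))
  NextMethod()
  invisible(x)
}
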