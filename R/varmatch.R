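# Cohort-vs-catalog variant matching. A cohort variant is IDENTICAL when a
# catalog entry matches (chrom, pos, ref, alt) exactly, SIMILAR when an
# entry shares (chrom, pos) with different alleles, else UNMATCHED.
# Classification is allele-level by design: no trimming or left-alignment
# is applied unless explicitly requested, because representation
# normalization would reclassify pairs that differ only in allele notation.

.site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
.exact_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read cohort variants from a VCF
#'
#' Parses a VCF v4.x file (plain or gzip) and returns one row per
#' (record, ALT allele): multi-allelic records are split. Records with a
#' symbolic ALT (`<DEL>` etc.), breakend notation, or a missing ALT are
#' skipped and counted. Chromosomes are normalized via [normalize_chrom()].
#'
#' @param path Path to a VCF file.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `id`; the number of
#'   skipped alleles is attached as attribute `n_skipped` and reported as a
#'   message.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  empty <- tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), id = character(0))
  if (is.null(fix) || nrow(fix) == 0L) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  fix <- as_tibble(fix)
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  long <- tibble(
    chrom = rep(fix$CHROM, n_alt),
    pos = rep(suppressWarnings(as.integer(fix$POS)), n_alt),
    ref = rep(toupper(fix$REF), n_alt),
    alt = toupper(unlist(alts, use.names = FALSE)),
    id = rep(fix$ID, n_alt)
  )
  symbolic <- str_detect(long$alt, "^<") |
    str_detect(long$alt, "\\[|\\]") |
    long$alt %in% c(".", "*") | !nzchar(long$alt)
  bad <- symbolic | is.na(long$pos) | long$pos < 1L |
    !str_detect(long$ref, "^[ACGTN]+$")
  n_skipped <- sum(bad) + (nrow(fix) - sum(n_alt > 0))
  if (n_skipped > 0L) {
    inform(paste0("read_vcf: skipped ", n_skipped,
                  " symbolic/malformed allele(s)"))
  }
  long <- long[!bad, , drop = FALSE]
  long$chrom <- normalize_chrom(long$chrom)
  long$id[!is.na(long$id) & long$id == "."] <- NA_character_
  attr(long, "n_skipped") <- as.integer(n_skipped)
  long
}

#' Trim shared allele bases (opt-in representation normalization)
#'
#' Removes the common suffix, then the common prefix, of each `ref`/`alt`
#' pair (always keeping at least one base of each) and advances `pos` by
#' the number of prefix bases removed. This makes matching robust to padded
#' indel notations at the cost of deviating from strict verbatim
#' comparison. Full left-alignment against the reference genome is not
#' attempted: the plain-text catalogs this package operates on carry no
#' reference sequence.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` columns.
#' @return The tibble with trimmed alleles and adjusted positions.
#' @export
normalize_variants <- function(variants) {
  trim_one <- function(pos, ref, alt) {
    r <- strsplit(ref, "")[[1]]
    a <- strsplit(alt, "")[[1]]
    while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos <- pos + 1L
    }
    list(pos = pos, ref = paste(r, collapse = ""),
         alt = paste(a, collapse = ""))
  }
  trimmed <- pmap(list(variants$pos, variants$ref, variants$alt), trim_one)
  variants$pos <- map_int(trimmed, "pos")
  variants$ref <- map_chr(trimmed, "ref")
  variants$alt <- map_chr(trimmed, "alt")
  variants
}

#' Build a lookup index over a pathogenic-variant catalog
#'
#' Supports exact lookup by (chrom, pos, ref, alt) and site lookup by
#' (chrom, pos); duplicate exact keys are retained.
#'
#' @param catalog Tibble from [read_variant_catalog()].
#' @return An object of class `rgd_catalog_index`.
#' @export
catalog_index <- function(catalog) {
  structure(
    list(
      catalog = catalog,
      exact = split(seq_len(nrow(catalog)),
                    .exact_key(catalog$chrom, catalog$pos, catalog$ref,
                               catalog$alt)),
      site = split(seq_len(nrow(catalog)),
                   .site_key(catalog$chrom, catalog$pos))
    ),
    class = "rgd_catalog_index"
  )
}

#' Look up all catalog entries sharing a site
#'
#' @param index An `rgd_catalog_index`.
#' @param chrom,pos Site coordinates (chromosome label is normalized).
#' @return Tibble of catalog rows at the site (possibly empty).
#' @export
site_entries <- function(index, chrom, pos) {
  key <- .site_key(normalize_chrom(chrom), as.integer(pos))
  rows <- index$site[[key]]
  if (is.null(rows)) index$catalog[0, ] else index$catalog[rows, ]
}

.severity_rank <- function(category) {
  match(category, significance_categories)
}

# Vectorized classification over a whole cohort; returns the per-variant
# match table plus the long (cohort variant x catalog entry) table.
.classify_cohort <- function(cohort, catalog) {
  cohort <- mutate(cohort, .row = dplyr::row_number())
  cat_tbl <- catalog |>
    mutate(.cat_row = dplyr::row_number(),
           .site = .site_key(.data$chrom, .data$pos))
  entries <- cohort |>
    mutate(.site = .site_key(.data$chrom, .data$pos)) |>
    inner_join(cat_tbl, by = ".site", suffix = c("", "_catalog"),
               relationship = "many-to-many") |>
    mutate(entry_class = ifelse(.data$ref == .data$ref_catalog &
                                  .data$alt == .data$alt_catalog,
                                "IDENTICAL", "SIMILAR"))
  per_variant <- entries |>
    group_by(.data$.row) |>
    summarise(
      match_class = ifelse(any(.data$entry_class == "IDENTICAL"),
                           "IDENTICAL", "SIMILAR"),
      n_matched = dplyr::n(),
      clinvar_ids = paste(unique(.data$clinvar_id), collapse = ";"),
      significance = {
        pref <- if (any(.data$entry_class == "IDENTICAL"))
          .data$entry_class == "IDENTICAL" else rep(TRUE, dplyr::n())
        cats <- .data$significance_category[pref]
        c(cats[which.min(.severity_rank(cats))], NA_character_)[1]
      },
      inheritance = summarize_mode(
        unlist(lapply(.data$conditions, `[[`, "mode"))),
      conditions_all = paste(unique(unlist(
        lapply(.data$conditions, `[[`, "condition"))), collapse = ";"),
      modes_all = paste(unique(unlist(
        lapply(.data$conditions, `[[`, "mode"))), collapse = ";"),
      .groups = "drop"
    )
  out <- cohort |>
    left_join(per_variant, by = ".row") |>
    mutate(
      match_class = replace_na(.data$match_class, "UNMATCHED"),
      n_matched = as.integer(replace_na(.data$n_matched, 0L))
    ) |>
    select(-".row")
  entries_out <- entries |>
    select(cohort_row = ".row", "chrom", "pos", "ref", "alt",
           catalog_row = ".cat_row", ref_catalog = "ref_catalog",
           alt_catalog = "alt_catalog", clinvar_id = "clinvar_id",
           significance_category = "significance_category",
           entry_class = "entry_class")
  list(matches = out, entries = entries_out)
}

#' Classify one cohort variant against a catalog index
#'
#' @param chrom,pos,ref,alt The cohort variant (alleles upper-case).
#' @param index An [catalog_index()] object.
#' @return One-row `rgd_matches` tibble; see [match_cohort()].
#' @export
classify_match <- function(chrom, pos, ref, alt, index) {
  v <- tibble(chrom = normalize_chrom(chrom), pos = as.integer(pos),
              ref = toupper(ref), alt = toupper(alt), id = NA_character_)
  match_cohort(v, index$catalog)
}

#' Match a cohort of variants against a pathogenic-variant catalog
#'
#' Applies the identical/similar/unmatched classification to every cohort
#' variant, in input order. For matched variants the result carries the
#' catalog annotations: all ClinVar ids at the site, the clinical
#' significance of the best-matched entry (identical entries preferred,
#' then most severe category), the variant-level inheritance summary
#' (`MULTI` when matched conditions mix modes), and the ";"-joined matched
#' condition names and modes.
#'
#' @param cohort Tibble of cohort variants (`chrom`, `pos`, `ref`, `alt`,
#'   optionally `id`), e.g. from [read_vcf()].
#' @param catalog Tibble from [read_variant_catalog()].
#' @param normalize If `TRUE`, apply [normalize_variants()] to both sides
#'   before matching (deviation from verbatim comparison; off by default).
#' @return A `rgd_matches` tibble, one row per cohort variant: `chrom`,
#'   `pos`, `ref`, `alt`, `id`, `match_class`, `n_matched`, `clinvar_ids`,
#'   `significance`, `inheritance`, `conditions_all`, `modes_all`. The long
#'   per-(variant, entry) table is attached as attribute `entries`.
#' @examples
#' catalog <- read_variant_catalog(
#'   system.file("extdata", "recessive_variants.tsv", package = "rgdtools"),
#'   default_mode = "AR")
#' match_cohort(catalog[1:3, c("chrom", "pos", "ref", "alt")], catalog)
#' @export
match_cohort <- function(cohort, catalog, normalize = FALSE) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(cohort)))
  cohort <- as_tibble(cohort)
  if (!"id" %in% names(cohort)) cohort$id <- NA_character_
  cohort <- cohort[c("chrom", "pos", "ref", "alt", "id")]
  cohort$chrom <- if (nrow(cohort)) normalize_chrom(cohort$chrom) else
    cohort$chrom
  cohort$pos <- as.integer(cohort$pos)
  cohort$ref <- toupper(cohort$ref)
  cohort$alt <- toupper(cohort$alt)
  if (normalize) {
    cohort <- normalize_variants(cohort)
    catalog <- normalize_variants(catalog)
  }
  if (nrow(cohort) == 0L || nrow(catalog) == 0L) {
    out <- mutate(cohort, match_class = "UNMATCHED", n_matched = 0L,
                  clinvar_ids = NA_character_, significance = NA_character_,
                  inheritance = NA_character_, conditions_all = NA_character_,
                  modes_all = NA_character_)
    attr(out, "entries") <- tibble()
    class(out) <- c("rgd_matches", class(out))
    return(out)
  }
  res <- .classify_cohort(cohort, catalog)
  out <- res$matches
  attr(out, "entries") <- res$entries
  class(out) <- c("rgd_matches", class(out))
  out
}

#' Keep match records carrying a given inheritance mode
#'
#' A record is kept when at least one matched condition has the given mode
#' (`modes_all` membership), regardless of the variant-level summary.
#'
#' @param matches `rgd_matches` tibble.
#' @param mode One of [inheritance_modes].
#' @return Filtered `rgd_matches` tibble.
#' @export
filter_by_inheritance <- function(matches, mode) {
  stopifnot(length(mode) == 1L, mode %in% inheritance_modes)
  keep <- map(str_split(replace_na(matches$modes_all, ""), ";"),
              identity)
  sel <- vapply(keep, function(m) mode %in% m, logical(1))
  matches[sel, , drop = FALSE]
}

#' Count distinct variant sites
#'
#' @param matches Tibble with `chrom` and `pos` columns.
#' @return Number of distinct (chrom, pos) sites.
#' @export
n_sites <- function(matches) {
  dplyr::n_distinct(.site_key(matches$chrom, matches$pos))
}

#' Aggregate matches into a site-level mapping summary
#'
#' Counts are over distinct (chrom, pos) sites, a site being IDENTICAL when
#' any variant at it matched identically, else SIMILAR when any matched.
#' Pathogenic sites are those whose best significance falls in
#' [pathogenic_categories] (pathogenic, likely pathogenic, or conflicting
#' interpretations). The summary satisfies, on every input,
#' `n_mapped_total = n_identical_sites + n_similar_sites` and
#' `n_pathogenic_total = n_pathogenic_identical + n_pathogenic_similar`.
#'
#' @param matches `rgd_matches` tibble from [match_cohort()].
#' @return An object of class `rgd_match_summary`: the six headline counts
#'   plus `by_significance` (site class x significance category) and
#'   `by_inheritance` (mode distribution over identical pathogenic sites).
#' @export
summarize_matches <- function(matches) {
  matched <- matches[matches$match_class != "UNMATCHED", , drop = FALSE]
  sites <- matched |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      site_class = ifelse(any(.data$match_class == "IDENTICAL"),
                          "IDENTICAL", "SIMILAR"),
      significance = c(.data$significance[
        which.min(.severity_rank(.data$significance))], NA_character_)[1],
      inheritance = summarize_mode(unique(unlist(
        str_split(.data$modes_all, ";")))),
      .groups = "drop"
    )
  sites$pathogenic <- sites$significance %in% pathogenic_categories
  by_sig <- sites |>
    count(.data$site_class, .data$significance, name = "n_sites")
  by_inh <- sites |>
    filter(.data$site_class == "IDENTICAL", .data$pathogenic) |>
    count(.data$inheritance, name = "n_sites")
  structure(
    list(
      n_identical_sites = sum(sites$site_class == "IDENTICAL"),
      n_similar_sites = sum(sites$site_class == "SIMILAR"),
      n_mapped_total = nrow(sites),
      n_pathogenic_identical = sum(sites$pathogenic &
                                     sites$site_class == "IDENTICAL"),
      n_pathogenic_similar = sum(sites$pathogenic &
                                   sites$site_class == "SIMILAR"),
      n_pathogenic_total = sum(sites$pathogenic),
      n_unmatched_variants = sum(matches$match_class == "UNMATCHED"),
      by_significance = by_sig,
      by_inheritance = by_inh
    ),
    class = "rgd_match_summary"
  )
}

#' @export
print.rgd_match_summary <- function(x, ...) {
  cat("Cohort-vs-catalog mapping summary (distinct sites)\n")
  cat("  mapped:     ", x$n_mapped_total, " (identical ", x$n_identical_sites,
      ", similar ", x$n_similar_sites, ")\n", sep = "")
  cat("  pathogenic: ", x$n_pathogenic_total, " (identical ",
      x$n_pathogenic_identical, ", similar ", x$n_pathogenic_similar,
      ")\n", sep = "")
  cat("  unmatched cohort variants: ", x$n_unmatched_variants, "\n", sep = "")
  invisible(x)
}

#' @rdname summarize_matches
#' @param x An `rgd_match_summary`.
#' @param ... Unused.
#' @method tidy rgd_match_summary
#' @export
tidy.rgd_match_summary <- function(x, ...) {
  dplyr::bind_rows(
    mutate(x$by_significance, breakdown = "significance",
           group = .data$significance) |>
      select("breakdown", site_class = "site_class", "group", "n_sites"),
    mutate(x$by_inheritance, breakdown = "inheritance_identical_pathogenic",
           site_class = "IDENTICAL", group = .data$inheritance) |>
      select("breakdown", "site_class", "group", "n_sites")
  )
}

#' @rdname summarize_matches
#' @method glance rgd_match_summary
#' @export
glance.rgd_match_summary <- function(x, ...) {
  tibble(
    n_identical_sites = x$n_identical_sites,
    n_similar_sites = x$n_similar_sites,
    n_mapped_total = x$n_mapped_total,
    n_pathogenic_identical = x$n_pathogenic_identical,
    n_pathogenic_similar = x$n_pathogenic_similar,
    n_pathogenic_total = x$n_pathogenic_total,
    n_unmatched_variants = x$n_unmatched_variants
  )
}

#' Write / read the per-variant match table
#'
#' Tab-delimited, "." for missing; `read_matches(write_matches(m))`
#' restores the per-variant columns (the long entries attribute is not
#' serialized).
#'
#' @param matches `rgd_matches` tibble.
#' @param path Output path.
#' @export
write_matches <- function(matches, path) {
  out <- as_tibble(matches)
  for (nm in c("id", "clinvar_ids", "significance", "inheritance",
               "conditions_all", "modes_all")) {
    out[[nm]] <- .na_dot(out[[nm]])
  }
  write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  df <- .read_tsv_quiet(path)
  .require_cols(df, c("chrom", "pos", "ref", "alt", "match_class"),
                "matches table")
  out <- df |>
    mutate(pos = as.integer(.data$pos),
           n_matched = as.integer(.data$n_matched),
           across(c("id", "clinvar_ids", "significance", "inheritance",
                    "conditions_all", "modes_all"), .dot_na))
  class(out) <- c("rgd_matches", class(out))
  out
}

#' Serialize a mapping summary to JSON
#'
#' @param summary An `rgd_match_summary`.
#' @param path Output path.
#' @export
write_summary_json <- function(summary, path) {
  x <- unclass(summary)
  write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
             pretty = TRUE)
  invisible(path)
}
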