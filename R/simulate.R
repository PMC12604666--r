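# Deterministic synthetic-data generators. Every generator runs in its own
# RNG scope seeded from a single integer, so regenerating one fixture never
# perturbs another, and the same seed always yields byte-identical files.
# The planted ground truth (class counts, composition, exhaustive score
# tables) is returned alongside the data so downstream modules can be
# checked against it without any external resource.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

.fixture_chroms <- c(paste0("chr", 1:22), "chrX")

.sig_raw_strings <- c(
  PATHOGENIC = "Pathogenic",
  LIKELY_PATHOGENIC = "Likely pathogenic",
  PATHOGENIC_CONFLICTING = "Conflicting interpretations of pathogenicity",
  BENIGN_OR_LIKELY_BENIGN = "Benign",
  OTHER = "Uncertain significance"
)

.mode_suffix <- c(AD = " (AD)", AR = " (AR)", X_LINKED = " (XL)",
                  UNKNOWN = "")

.check_mix <- function(mix, universe, what) {
  if (is.null(names(mix)) || !all(names(mix) %in% universe) ||
      any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort(paste0(what, " must be named proportions over {",
                 paste(universe, collapse = ", "), "} summing to 1"))
  }
  mix
}

#' Generate a synthetic pathogenic-variant catalog
#'
#' Draws `n` catalog variants with unique (chrom, pos) sites on chr1-chr22
#' and chrX, significance and inheritance-mode composition multinomially
#' sampled from the given mixes, SNV or small-indel alleles, and synthetic
#' condition names carrying the mode token. X-linked conditions are placed
#' on chrX.
#'
#' @param seed Integer seed; fixed seed gives identical output.
#' @param n Number of catalog variants (>= 1).
#' @param significance_mix Named proportions over
#'   [significance_categories]; default 50% pathogenic, 30% likely
#'   pathogenic, 20% conflicting.
#' @param mode_mix Named proportions over `AD`, `AR`, `X_LINKED`,
#'   `UNKNOWN`; default 45/45/5/5.
#' @return List with `catalog` (tibble in [read_variant_catalog()] layout)
#'   and `truth` (seed, per-significance and per-mode planted counts).
#' @export
simulate_variant_catalog <- function(
    seed, n,
    significance_mix = c(PATHOGENIC = 0.5, LIKELY_PATHOGENIC = 0.3,
                         PATHOGENIC_CONFLICTING = 0.2),
    mode_mix = c(AD = 0.45, AR = 0.45, X_LINKED = 0.05, UNKNOWN = 0.05)) {
  stopifnot(n >= 1)
  .check_mix(significance_mix, significance_categories, "significance_mix")
  .check_mix(mode_mix, c("AD", "AR", "X_LINKED", "UNKNOWN"), "mode_mix")
  .with_seed(seed, {
    sig_counts <- drop(rmultinom(1, n, significance_mix))
    mode_counts <- drop(rmultinom(1, n, mode_mix))
    sig <- sample(rep(names(sig_counts), sig_counts))
    mode <- sample(rep(names(mode_counts), mode_counts))
    chrom <- ifelse(mode == "X_LINKED", "chrX",
                    sample(.fixture_chroms[1:22], n, replace = TRUE))
    # positions globally unique (never reused across chromosomes), so
    # (chrom, pos) sites are unique by construction
    stopifnot(n <= 5e7)
    pos <- sample.int(5e7, n)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                  character(1))
    indel <- sample.int(n, size = max(0L, round(n * 0.1)))
    ref[indel] <- paste0(ref[indel],
                         vapply(indel, function(i)
                           paste(sample(bases, 2, TRUE), collapse = ""),
                           character(1)))
    cond <- paste0("Synthetic disorder ", sprintf("%04d", seq_len(n)),
                   unname(.mode_suffix[mode]))
    catalog <- tibble(
      chrom = chrom, pos = pos, ref = unname(ref), alt = unname(alt),
      id = paste0("rs9", sprintf("%07d", sample.int(9999999, n))),
      clinvar_id = as.character(1e6 + seq_len(n)),
      significance = unname(.sig_raw_strings[sig]),
      significance_category = sig,
      condition = cond,
      conditions = lapply(seq_len(n), function(i) {
        tibble(condition = sub(" \\((AD|AR|XL)\\)$", "", cond[i]),
               mode = mode[i])
      }),
      mode = mode,
      gene_symbol = paste0("SYNGENE", sprintf("%04d", seq_len(n)))
    )
    list(
      catalog = catalog,
      truth = list(
        seed = seed, n = n,
        significance_counts = as.list(table(sig)),
        mode_counts = as.list(table(mode))
      )
    )
  })
}

#' Generate a synthetic cohort VCF with planted match classes
#'
#' Plants exactly `n_identical` cohort variants copied verbatim from
#' catalog entries, `n_similar` variants at catalog sites with a perturbed
#' alternate allele (guaranteed not to equal any catalog allele pair at the
#' site, so they classify as similar, never identical or unmatched), and
#' `n_unmatched` variants at sites disjoint from the catalog. Running
#' [match_cohort()] on the output recovers exactly these counts.
#'
#' @param seed Integer seed.
#' @param catalog Catalog tibble (sites must be unique, as produced by
#'   [simulate_variant_catalog()]).
#' @param n_identical,n_similar,n_unmatched Planted class counts; the
#'   identical and similar sets are drawn from disjoint catalog rows, so
#'   `n_identical + n_similar <= nrow(catalog)` must hold.
#' @param identical_rows,similar_rows Optional explicit catalog row indices
#'   (overriding the random draw) for callers that need to control which
#'   entries — e.g. which significance classes — are planted in each group.
#' @param path Optional path; when given, the cohort is also written as a
#'   VCF v4.2 file (sorted by chromosome and position).
#' @return List with `cohort` (tibble: `chrom`, `pos`, `ref`, `alt`, `id`,
#'   `planted_class`), `truth` (planted counts and per-significance
#'   composition) and `path` (or `NULL`).
#' @export
simulate_cohort_vcf <- function(seed, catalog, n_identical, n_similar,
                                n_unmatched, identical_rows = NULL,
                                similar_rows = NULL, path = NULL) {
  n_cat <- nrow(catalog)
  key_cat <- paste(catalog$chrom, catalog$pos)
  if (anyDuplicated(key_cat)) {
    abort("catalog sites must be unique to plant match classes")
  }
  .with_seed(seed, {
    if (is.null(identical_rows) || is.null(similar_rows)) {
      if (n_identical + n_similar > n_cat) {
        abort("infeasible planted counts: n_identical + n_similar exceeds catalog size")
      }
      picked <- sample.int(n_cat, n_identical + n_similar)
      identical_rows <- picked[seq_len(n_identical)]
      similar_rows <- setdiff(picked, identical_rows)
    } else {
      if (length(intersect(identical_rows, similar_rows)) > 0L ||
          length(identical_rows) != n_identical ||
          length(similar_rows) != n_similar) {
        abort("identical_rows and similar_rows must be disjoint and match the requested counts")
      }
    }
    bases <- c("A", "C", "G", "T")
    ident <- catalog[identical_rows,
                     c("chrom", "pos", "ref", "alt"), drop = FALSE]
    simil <- catalog[similar_rows, c("chrom", "pos", "ref", "alt"),
                     drop = FALSE]
    if (nrow(simil)) {
      simil$alt <- vapply(seq_len(nrow(simil)), function(i) {
        taken <- c(simil$alt[i], substr(simil$ref[i], 1, 1))
        sample(setdiff(bases, taken), 1)
      }, character(1))
      simil$ref <- substr(simil$ref, 1, 1)
      clash <- paste(simil$chrom, simil$pos, simil$ref, simil$alt) %in%
        paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
      stopifnot(!any(clash))
    }
    unm <- NULL
    if (n_unmatched > 0L) {
      chrom <- sample(.fixture_chroms, n_unmatched, replace = TRUE)
      # offset beyond the catalog generator's position range keeps these
      # sites disjoint from any catalog site
      pos <- sample.int(5e7, n_unmatched) + 5e7L
      stopifnot(!paste(chrom, pos) %in% key_cat)
      ref <- sample(bases, n_unmatched, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                    character(1))
      unm <- tibble(chrom = chrom, pos = pos, ref = ref,
                    alt = unname(alt))
    }
    cohort <- dplyr::bind_rows(
      if (nrow(ident)) mutate(ident, planted_class = "IDENTICAL"),
      if (nrow(simil)) mutate(simil, planted_class = "SIMILAR"),
      if (!is.null(unm)) mutate(unm, planted_class = "UNMATCHED")
    )
    if (is.null(cohort) || ncol(cohort) == 0L) {
      cohort <- tibble(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       planted_class = character(0))
    }
    cohort$id <- if (nrow(cohort))
      paste0("cohort_", seq_len(nrow(cohort))) else character(0)
    cohort <- arrange(cohort, .data$chrom, .data$pos)
    truth <- list(
      seed = seed, n_identical = n_identical, n_similar = n_similar,
      n_unmatched = n_unmatched,
      significance_identical =
        as.list(table(catalog$significance_category[identical_rows])),
      significance_similar =
        as.list(table(catalog$significance_category[similar_rows])),
      mode_identical = as.list(table(catalog$mode[identical_rows]))
    )
    if (!is.null(path)) write_vcf(cohort, path)
    list(cohort = cohort, truth = truth, path = path)
  })
}

#' Write variants as a minimal sites-only VCF v4.2
#'
#' Emits the eight mandatory columns with `.` placeholders for QUAL,
#' FILTER and INFO; the file reads back through [read_vcf()].
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`, optional `id`.
#' @param path Output path.
#' @export
write_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rgdtools",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  )
  id <- if ("id" %in% names(variants)) .na_dot(variants$id) else
    rep(".", nrow(variants))
  body <- if (nrow(variants)) {
    paste(variants$chrom, variants$pos, id, variants$ref, variants$alt,
          ".", ".", ".", sep = "\t")
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a synthetic disorder + symptom-association catalog
#'
#' Draws `n_disorders` disorders across a handful of synthetic categories
#' and links each to a random subset of an `n_symptoms`-term symptom
#' universe with frequency terms drawn from the full vocabulary. The truth
#' record scripts one symptom selection and carries the exhaustive score
#' table for it, computed by direct summation independent of
#' [score_disorders()], together with the implied full ranking (score
#' descending, name ascending case-insensitively, zero scores dropped).
#'
#' @param seed Integer seed.
#' @param n_disorders,n_symptoms Universe sizes (>= 1).
#' @param n_selected Number of symptoms in the scripted selection.
#' @return List with `disorders`, `associations` (tibbles in the I/O
#'   layouts) and `truth` (selection, `score_table`, `expected_ranking`).
#' @export
simulate_symptom_catalog <- function(seed, n_disorders, n_symptoms,
                                     n_selected = min(3L, n_symptoms)) {
  stopifnot(n_disorders >= 1, n_symptoms >= 1, n_selected >= 1,
            n_selected <= n_symptoms)
  .with_seed(seed, {
    categories <- c("Metabolic disorders", "Neuromuscular disorders",
                    "Blood disorders", "Skin disorders")
    dnames <- paste0("Synthetic disorder ", sprintf("%03d",
                                                    seq_len(n_disorders)))
    disorders <- tibble(
      name = dnames,
      aliases = lapply(seq_len(n_disorders), function(i)
        paste0("SD", sprintf("%03d", i))),
      category = sample(categories, n_disorders, replace = TRUE),
      subcategory = NA_character_,
      inheritance_modes = lapply(seq_len(n_disorders), function(i)
        sample(c("AD", "AR"), 1)),
      genes = lapply(seq_len(n_disorders), function(i)
        paste0("SYNGENE", sprintf("%04d", i))),
      reported_in_india = TRUE
    )
    symptoms <- paste0("symptom_", sprintf("%03d", seq_len(n_symptoms)))
    assoc <- dplyr::bind_rows(lapply(seq_len(n_disorders), function(i) {
      k <- sample.int(min(n_symptoms, 8L), 1)
      s <- sample(symptoms, k)
      tibble(
        disorder_name = dnames[i],
        symptom = s,
        medical_term = NA_character_,
        frequency_term = sample(frequency_terms, k, replace = TRUE),
        description = NA_character_
      )
    }))
    selection <- sort(sample(symptoms, n_selected))
    w <- default_frequency_weights()
    score_table <- vapply(dnames, function(d) {
      rows <- assoc[assoc$disorder_name == d &
                      assoc$symptom %in% selection, ]
      s <- 0
      for (j in seq_len(nrow(rows))) {
        s <- s + w[[rows$frequency_term[j]]]
      }
      s
    }, numeric(1))
    nonzero <- score_table[score_table > 0]
    ranking <- names(nonzero)[order(-nonzero, tolower(names(nonzero)))]
    list(
      disorders = disorders,
      associations = assoc,
      truth = list(seed = seed, selection = selection,
                   score_table = as.list(score_table),
                   expected_ranking = ranking)
    )
  })
}

#' Generate synthetic gene models
#'
#' Spans of 1-20 kb on the fixture chromosomes with 1-8 non-overlapping
#' exons per gene.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (>= 1).
#' @return Gene-model tibble in the [read_gene_models()] layout.
#' @export
simulate_gene_models <- function(seed, n_genes) {
  stopifnot(n_genes >= 1)
  .with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_genes), function(i) {
      start <- sample.int(1e6, 1)
      len <- sample(1000:20000, 1)
      end <- start + len - 1L
      n_ex <- sample.int(8, 1)
      cuts <- sort(sample(seq.int(start, end), 2L * n_ex))
      exons <- tibble(start = cuts[c(TRUE, FALSE)],
                      end = cuts[c(FALSE, TRUE)])
      exons <- exons[exons$start <= exons$end, ]
      keep <- c(TRUE, exons$start[-1] > exons$end[-nrow(exons)])
      exons <- exons[keep, ]
      tibble(symbol = paste0("SYNGENE", sprintf("%04d", i)),
             chrom = sample(.fixture_chroms, 1),
             strand = sample(c("+", "-"), 1),
             start = start, end = end, exons = list(exons))
    }))
  })
}

#' Emit a complete fixture set with its ground truth
#'
#' Writes `disorders.tsv`, `symptoms.tsv`, `variants.tsv`, `genes.tsv`,
#' `cohort.vcf` and `truth.json` under `dir`, all derived deterministically
#' from one seed (each generator runs in its own RNG scope).
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param n_catalog Catalog size.
#' @param n_identical,n_similar,n_unmatched Planted cohort class counts.
#' @param n_disorders,n_symptoms Symptom-catalog universe sizes.
#' @param n_genes Number of synthetic gene models.
#' @return Invisibly, the truth list.
#' @export
simulate_fixture_set <- function(seed, dir, n_catalog = 100,
                                 n_identical = 5, n_similar = 3,
                                 n_unmatched = 2, n_disorders = 20,
                                 n_symptoms = 12, n_genes = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vc <- simulate_variant_catalog(seed + 1L, n_catalog)
  write_variant_catalog(vc$catalog, file.path(dir, "variants.tsv"))
  cv <- simulate_cohort_vcf(seed + 2L, vc$catalog, n_identical, n_similar,
                            n_unmatched, path = file.path(dir, "cohort.vcf"))
  sc <- simulate_symptom_catalog(seed + 3L, n_disorders, n_symptoms)
  write_disorders(sc$disorders, file.path(dir, "disorders.tsv"))
  write_symptom_associations(sc$associations, file.path(dir, "symptoms.tsv"))
  genes <- simulate_gene_models(seed + 4L, n_genes)
  write_gene_models(genes, file.path(dir, "genes.tsv"))
  truth <- list(seed = seed, catalog = vc$truth, cohort = cv$truth,
                symptoms = sc$truth)
  write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  invisible(truth)
}
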