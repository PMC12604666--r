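# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (double loops, direct summation) so they check the
# vectorized implementations from the outside.

# O(n*m) double-loop classifier over (chrom,pos,ref,alt) tables.
brute_force_classify <- function(cohort, catalog) {
  vapply(seq_len(nrow(cohort)), function(i) {
    cls <- "UNMATCHED"
    for (j in seq_len(nrow(catalog))) {
      if (cohort$chrom[i] == catalog$chrom[j] &&
          cohort$pos[i] == catalog$pos[j]) {
        if (cohort$ref[i] == catalog$ref[j] &&
            cohort$alt[i] == catalog$alt[j]) {
          return("IDENTICAL")
        }
        cls <- "SIMILAR"
      }
    }
    cls
  }, character(1))
}

# Direct-summation disorder scorer.
brute_force_scores <- function(associations, selected,
                               weights = default_frequency_weights()) {
  disorders <- unique(associations$disorder_name)
  scores <- numeric(length(disorders))
  names(scores) <- disorders
  for (d in disorders) {
    rows <- associations[associations$disorder_name == d, ]
    for (i in seq_len(nrow(rows))) {
      if (rows$symptom[i] %in% selected) {
        scores[d] <- scores[d] + weights[[rows$frequency_term[i]]]
      }
    }
  }
  scores
}

# Expected ranking under the fixed tie rule.
brute_force_ranking <- function(scores, k) {
  scores <- scores[scores > 0]
  head(names(scores)[order(-scores, tolower(names(scores)))], k)
}

# Minimal in-memory catalog with derived columns, built row-wise.
tiny_catalog <- function(chrom, pos, ref, alt,
                         significance = "Pathogenic",
                         condition = "Test condition (AR)") {
  n <- length(chrom)
  significance <- rep_len(significance, n)
  condition <- rep_len(condition, n)
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    clinvar_id = as.character(seq_len(n)),
    significance = significance, condition = condition
  ), f, progress = FALSE)
  on.exit(unlink(f))
  read_variant_catalog(f)
}

tiny_associations <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(disorder_name = r[[1]], symptom = r[[2]],
                   medical_term = NA_character_, frequency_term = r[[3]],
                   description = NA_character_)
  }))
}

extdata <- function(name) {
  system.file("extdata", name, package = "rgdtools", mustWork = TRUE)
}

random_catalog_tbl <- function(n, n_sites = n) {
  bases <- c("A", "C", "G", "T")
  chrom <- sample(paste0("chr", 1:5), n_sites, replace = TRUE)
  pos <- sample.int(1e5, n_sites, replace = FALSE)
  idx <- sample.int(n_sites, n, replace = TRUE)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tibble::tibble(chrom = chrom[idx], pos = pos[idx], ref = ref,
                 alt = unname(alt))
}

# Cohort sharing sites with the catalog so all three classes occur: about
# a third verbatim copies, a third same-site random alleles, a third fresh
# sites off the catalog.
random_cohort_for <- function(catalog, n) {
  bases <- c("A", "C", "G", "T")
  kind <- sample(1:3, n, replace = TRUE)
  rows <- sample.int(nrow(catalog), n, replace = TRUE)
  out <- catalog[rows, c("chrom", "pos", "ref", "alt")]
  resample <- which(kind == 2L)
  out$ref[resample] <- sample(bases, length(resample), replace = TRUE)
  out$alt[resample] <- vapply(out$ref[resample], function(r)
    sample(setdiff(bases, r), 1), character(1))
  fresh <- which(kind == 3L)
  out$chrom[fresh] <- sample(paste0("chr", 6:9), length(fresh),
                             replace = TRUE)
  out$pos[fresh] <- sample.int(1e5, length(fresh), replace = TRUE)
  out
}
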