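test_that("chromosome normalization canonicalizes dialects and is idempotent", {
  expect_equal(normalize_chrom("13"), "chr13")
  expect_equal(normalize_chrom("chr13"), "chr13")
  expect_equal(normalize_chrom("MT"), "chrM")
  expect_equal(normalize_chrom(normalize_chrom("MT")), "chrM")
  expect_equal(normalize_chrom(c("x", "CHRX", "chrMT")),
               c("chrX", "chrX", "chrM"))
  expect_error(normalize_chrom(""), "non-empty")

  set.seed(11)
  pool <- c(as.character(1:22), "X", "Y", "MT", "chr7", "ChR12", "weird1")
  labels <- sample(pool, 200, replace = TRUE)
  once <- normalize_chrom(labels)
  expect_identical(normalize_chrom(once), once)
})

test_that("inheritance parsing strips mode tokens and splits compound conditions", {
  expect_equal(parse_inheritance("Wilson disease (AR)")$condition,
               "Wilson disease")
  expect_equal(parse_inheritance("Wilson disease (AR)")$mode, "AR")

  two <- parse_inheritance(
    "Van der Woude syndrome 1 (AD) and Popliteal pterygium syndrome (AD)")
  expect_equal(nrow(two), 2L)
  expect_equal(two$condition,
               c("Van der Woude syndrome 1", "Popliteal pterygium syndrome"))
  expect_equal(two$mode, c("AD", "AD"))

  no_token <- parse_inheritance("GM1 gangliosidosis type 2")
  expect_equal(no_token$mode, "UNKNOWN")
  expect_equal(no_token$condition, "GM1 gangliosidosis type 2")

  # "and" inside a name without per-fragment tokens must not split
  keep <- parse_inheritance(
    "Microcephaly, normal intelligence and immunodeficiency (AR)")
  expect_equal(nrow(keep), 1L)
  expect_equal(keep$condition,
               "Microcephaly, normal intelligence and immunodeficiency")
  expect_equal(keep$mode, "AR")

  expect_equal(parse_inheritance("Hypophosphatemic rickets (XL)")$mode,
               "X_LINKED")
  # never throws; names carry no trailing token
  weird <- c("", "   ", "(AR)", "A (AD) and B", "plain name")
  res <- parse_inheritance(weird)
  expect_false(any(grepl("\\((AD|AR|XL)\\)\\s*$", res$condition)))
})

test_that("significance categorization is total, case-insensitive and deterministic", {
  expect_equal(categorize_significance("Pathogenic"), "PATHOGENIC")
  expect_equal(categorize_significance("pathogenic/likely pathogenic"),
               "PATHOGENIC")
  expect_equal(categorize_significance("Likely pathogenic"),
               "LIKELY_PATHOGENIC")
  expect_equal(
    categorize_significance("Conflicting interpretations of pathogenicity"),
    "PATHOGENIC_CONFLICTING")
  expect_equal(categorize_significance("CONFLICTING CLASSIFICATIONS"),
               "PATHOGENIC_CONFLICTING")
  expect_equal(categorize_significance(c("Benign", "likely benign",
                                         "Benign/Likely benign")),
               rep("BENIGN_OR_LIKELY_BENIGN", 3))
  expect_equal(categorize_significance("Uncertain significance"), "OTHER")
  expect_equal(categorize_significance("risk factor"), "OTHER")
  expect_error(categorize_significance(""), "non-empty")

  set.seed(4)
  raws <- replicate(50, paste(sample(letters, 8), collapse = ""))
  expect_true(all(categorize_significance(raws) %in%
                    significance_categories))
})

test_that("frequency-term parsing is case/whitespace-insensitive with NONE fallback", {
  expect_equal(parse_frequency_term("Always"), "ALWAYS")
  expect_equal(parse_frequency_term("  very  frequently "),
               "VERY_FREQUENTLY")
  expect_equal(parse_frequency_term("."), "NONE")
  expect_warning(out <- parse_frequency_term("weekly"), "weekly")
  expect_equal(out, "NONE")
})

test_that("variant-catalog reader parses, normalizes and rejects bad rows", {
  t5 <- read_variant_catalog(extdata("recessive_variants.tsv"),
                             default_mode = "AR")
  expect_equal(nrow(t5), 37L)
  expect_true(all(t5$mode == "AR"))
  wilson <- t5[t5$pos == 51944170, ]
  expect_equal(wilson$chrom, "chr13")
  expect_equal(wilson$conditions[[1]]$condition, "Wilson disease")

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tclinvar_id\tsignificance\tcondition",
               "chr1\tabc\tA\tG\t1\tPathogenic\tX (AD)",
               "chr2\t100\tA\tG\t2\tPathogenic\tY (AR)"), f)
  expect_warning(cat <- read_variant_catalog(f), "rejected 1")
  expect_equal(nrow(cat), 1L)
  expect_equal(cat$chrom, "chr2")

  writeLines("chrom\tpos\tref\talt\tclinvar_id\tsignificance\tcondition", f)
  expect_equal(nrow(read_variant_catalog(f)), 0L)

  writeLines(c("chrom\tpos\tref\talt", "chr1\t1\tA\tG"), f)
  expect_error(read_variant_catalog(f), "missing mandatory column")
})

test_that("all four readers/writers round-trip randomly generated catalogs", {
  for (seed in 1:30) {
    vc <- simulate_variant_catalog(seed, sample(1:40, 1))$catalog
    f <- tempfile(fileext = ".tsv")
    write_variant_catalog(vc, f)
    back <- read_variant_catalog(f)
    expect_equal(as.data.frame(back), as.data.frame(vc))
    unlink(f)

    sc <- simulate_symptom_catalog(seed, sample(1:15, 1), sample(1:10, 1))
    f2 <- tempfile(fileext = ".tsv")
    write_disorders(sc$disorders, f2)
    expect_equal(as.data.frame(read_disorders(f2)),
                 as.data.frame(sc$disorders))
    write_symptom_associations(sc$associations, f2)
    expect_equal(as.data.frame(read_symptom_associations(f2)),
                 as.data.frame(sc$associations))
    unlink(f2)

    g <- simulate_gene_models(seed, sample(1:5, 1))
    f3 <- tempfile(fileext = ".tsv")
    write_gene_models(g, f3)
    expect_equal(as.data.frame(read_gene_models(f3)), as.data.frame(g))
    unlink(f3)
  }
})

test_that("variant-level mode summary flags mixed inheritance as MULTI", {
  expect_equal(summarize_mode(c("AD", "AD")), "AD")
  expect_equal(summarize_mode(c("AD", "AR")), "MULTI")
  expect_equal(summarize_mode(c("UNKNOWN", "X_LINKED")), "X_LINKED")
  expect_equal(summarize_mode(c("UNKNOWN", "UNKNOWN")), "UNKNOWN")
  expect_equal(summarize_mode(character(0)), "UNKNOWN")
})
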