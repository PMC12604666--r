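test_that("VCF reading splits multi-allelic records and skips symbolic alleles", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr13\t51944170\t.\tC\tT\t.\t.\t.",
    "chr1\t100\trs1\tC\tT,G\t.\t.\t.",
    "chr2\t200\t.\tA\t<DEL>\t.\t.\t."
  ), f)
  suppressMessages(v <- read_vcf(f))
  expect_equal(nrow(v), 3L)
  expect_equal(v$chrom[1], "chr13")
  expect_equal(v$pos[1], 51944170L)
  expect_equal(v[v$pos == 100, ]$alt, c("T", "G"))
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_true(is.na(v$id[1]))
  expect_equal(v$id[2], "rs1")
})

test_that("the printed identical/similar example pairs classify as stated", {
  catalog <- tiny_catalog(
    chrom = c("chr13", "chr10"), pos = c(51944170, 89247612),
    ref = c("C", "AC"), alt = c("T", "A"),
    condition = c("Wilson disease (AR)", "Wolman disease (AR)"))
  idx <- catalog_index(catalog)
  wilson <- classify_match("chr13", 51944170, "C", "T", idx)
  expect_equal(wilson$match_class, "IDENTICAL")
  expect_equal(wilson$inheritance, "AR")
  wolman <- classify_match("chr10", 89247612, "C", "T", idx)
  expect_equal(wolman$match_class, "SIMILAR")
  nowhere <- classify_match("chr1", 100, "A", "G", idx)
  expect_equal(nowhere$match_class, "UNMATCHED")
  expect_true(is.na(nowhere$significance))
})

test_that("catalog index supports exact and site lookup with duplicates", {
  catalog <- tiny_catalog(
    chrom = c("chr1", "chr1", "chr2"), pos = c(10, 10, 20),
    ref = c("A", "A", "C"), alt = c("G", "T", "T"))
  idx <- catalog_index(catalog)
  both <- site_entries(idx, "1", 10)
  expect_equal(nrow(both), 2L)
  expect_equal(sort(both$alt), c("G", "T"))
  expect_equal(nrow(site_entries(idx, "chr3", 1)), 0L)
})

test_that("identical takes precedence over similar at multi-entry sites", {
  catalog <- tiny_catalog(
    chrom = c("chr1", "chr1"), pos = c(10, 10),
    ref = c("A", "A"), alt = c("G", "T"))
  m <- match_cohort(tibble::tibble(chrom = "chr1", pos = 10, ref = "A",
                                   alt = "G"), catalog)
  expect_equal(m$match_class, "IDENTICAL")
  expect_equal(m$n_matched, 2L)
})

test_that("cohort classification agrees with the double-loop oracle", {
  seen <- character(0)
  for (seed in 1:12) {
    set.seed(seed)
    n_cat <- sample(20:80, 1)
    catalog_core <- random_catalog_tbl(n_cat, n_sites = 40)
    catalog <- tiny_catalog(catalog_core$chrom, catalog_core$pos,
                            catalog_core$ref, catalog_core$alt)
    cohort <- random_cohort_for(catalog, sample(100:1000, 1))
    m <- match_cohort(cohort, catalog)
    expect_equal(m$match_class, brute_force_classify(cohort, catalog))
    # partition: exactly one class per variant
    expect_true(all(m$match_class %in%
                      c("IDENTICAL", "SIMILAR", "UNMATCHED")))
    expect_equal(nrow(m), nrow(cohort))
    seen <- union(seen, m$match_class)
  }
  # the random instances must actually exercise all three classes
  expect_setequal(seen, c("IDENTICAL", "SIMILAR", "UNMATCHED"))
})

test_that("matching a catalog against itself is 100% identical", {
  vc <- simulate_variant_catalog(42, 150)$catalog
  m <- match_cohort(vc[, c("chrom", "pos", "ref", "alt")], vc)
  expect_true(all(m$match_class == "IDENTICAL"))
  s <- summarize_matches(m)
  expect_equal(s$n_similar_sites, 0L)
  expect_equal(s$n_mapped_total, 150L)
})

test_that("perturbing the alt of an identical match degrades it to similar", {
  for (seed in 1:20) {
    vc <- simulate_variant_catalog(seed, 30)$catalog
    set.seed(seed)
    i <- sample.int(30, 1)
    v <- vc[i, c("chrom", "pos", "ref", "alt")]
    v$ref <- substr(v$ref, 1, 1)
    v$alt <- sample(setdiff(c("A", "C", "G", "T"),
                            c(v$alt, v$ref)), 1)
    m <- match_cohort(v, vc)
    expect_equal(m$match_class, "SIMILAR")
  }
})

test_that("planted identical/similar/unmatched counts are recovered for many seeds", {
  vc <- simulate_variant_catalog(99, 60)$catalog
  for (seed in 1:100) {
    set.seed(seed)
    k <- sample(0:20, 1); mm <- sample(0:20, 1); u <- sample(0:10, 1)
    cv <- simulate_cohort_vcf(seed, vc, k, mm, u)
    m <- match_cohort(cv$cohort, vc)
    got <- table(factor(m$match_class,
                        levels = c("IDENTICAL", "SIMILAR", "UNMATCHED")))
    expect_equal(unname(got[["IDENTICAL"]]), k)
    expect_equal(unname(got[["SIMILAR"]]), mm)
    expect_equal(unname(got[["UNMATCHED"]]), u)
  }
})

test_that("summary identities hold on arbitrary inputs", {
  for (seed in c(5, 17, 23)) {
    vc <- simulate_variant_catalog(seed, 80)$catalog
    cv <- simulate_cohort_vcf(seed + 1, vc, 25, 25, 10)
    s <- summarize_matches(match_cohort(cv$cohort, vc))
    expect_equal(s$n_mapped_total, s$n_identical_sites + s$n_similar_sites)
    expect_equal(s$n_pathogenic_total,
                 s$n_pathogenic_identical + s$n_pathogenic_similar)
    expect_lte(s$n_pathogenic_identical, s$n_identical_sites)
    expect_lte(s$n_pathogenic_similar, s$n_similar_sites)
    expect_equal(sum(s$by_significance$n_sites), s$n_mapped_total)
  }
  empty <- summarize_matches(
    match_cohort(tibble::tibble(chrom = "chr1", pos = 1, ref = "A",
                                alt = "G"),
                 simulate_variant_catalog(1, 5)$catalog))
  expect_equal(empty$n_mapped_total, 0L)
  expect_equal(empty$n_pathogenic_total, 0L)
})

test_that("tidy and glance expose the summary as tibbles", {
  vc <- simulate_variant_catalog(31, 40)$catalog
  cv <- simulate_cohort_vcf(32, vc, 10, 10, 5)
  s <- summarize_matches(match_cohort(cv$cohort, vc))
  g <- glance(s)
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_mapped_total, 20L)
  td <- tidy(s)
  expect_true(all(c("breakdown", "site_class", "group", "n_sites") %in%
                    names(td)))
  expect_equal(sum(td$n_sites[td$breakdown == "significance"]), 20L)
})

test_that("inheritance filtering keeps records with a matching condition mode", {
  t4 <- read_variant_catalog(extdata("dominant_variants.tsv"),
                             default_mode = "AD")
  m4 <- match_cohort(t4[, c("chrom", "pos", "ref", "alt")], t4)
  ad <- filter_by_inheritance(m4[m4$match_class == "IDENTICAL", ], "AD")
  expect_equal(n_sites(ad), 14L)

  t5 <- read_variant_catalog(extdata("recessive_variants.tsv"),
                             default_mode = "AR")
  m5 <- match_cohort(t5[, c("chrom", "pos", "ref", "alt")], t5)
  ar <- filter_by_inheritance(m5[m5$match_class == "IDENTICAL", ], "AR")
  expect_equal(n_sites(ar), 37L)

  expect_equal(nrow(filter_by_inheritance(m5, "X_LINKED")), 0L)
})

test_that("matches round-trip through the TSV interchange format", {
  vc <- simulate_variant_catalog(8, 30)$catalog
  cv <- simulate_cohort_vcf(9, vc, 6, 4, 2)
  m <- match_cohort(cv$cohort[, c("chrom", "pos", "ref", "alt", "id")], vc)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matches(m, f)
  back <- read_matches(f)
  expect_equal(as.data.frame(back), as.data.frame(m),
               ignore_attr = "entries")
  s1 <- glance(summarize_matches(m))
  s2 <- glance(summarize_matches(back))
  expect_equal(s1, s2)
})

test_that("allele trimming normalization reconciles padded representations only on request", {
  catalog <- tiny_catalog("chr10", 89247612, "AC", "A")
  cohort <- tibble::tibble(chrom = "chr10", pos = 89247612, ref = "AC",
                           alt = "A")
  strict <- match_cohort(cohort, catalog)
  expect_equal(strict$match_class, "IDENTICAL")
  padded <- tibble::tibble(chrom = "chr10", pos = 89247611, ref = "GAC",
                           alt = "GA")
  expect_equal(match_cohort(padded, catalog)$match_class, "UNMATCHED")
  expect_equal(match_cohort(padded, catalog, normalize = TRUE)$match_class,
               "IDENTICAL")
})
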