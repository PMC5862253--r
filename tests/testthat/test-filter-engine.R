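# The five filters: classification rules, predicate semantics, chaining

test_that("genotype classification follows the class rules at any ploidy", {
  expect_identical(classify_genotype(c(0L, 0L)), "HOM_REF")
  expect_identical(classify_genotype(c(1L, 1L)), "HOM_ALT")
  expect_identical(classify_genotype(c(0L, 1L)), "HET")
  expect_identical(classify_genotype(c(1L, 2L)), "HET")
  expect_identical(classify_genotype(1L), "HOM_ALT")         # haploid
  expect_identical(classify_genotype(c(0L, 0L, 1L)), "HET")  # triploid
  expect_identical(classify_genotype(c(2L, 2L, 2L)), "HOM_ALT")
  expect_identical(classify_genotype(c(NA_integer_, 1L)), "MISSING")
  expect_identical(classify_genotype("0|1"), "HET")  # phasing ignored
})

test_that("genotype classification is invariant to allele permutation", {
  set.seed(99)
  for (i in 1:100) {
    idx <- sample(c(0:3, NA), sample(1:4, 1), replace = TRUE)
    perm <- idx[sample.int(length(idx))]
    expect_identical(classify_genotype(idx), classify_genotype(perm))
  }
})

test_that("variant classification follows the length rules", {
  expect_identical(classify_variant("A", "G"), "SNP")
  expect_identical(classify_variant("AT", "GC"), "MNP")
  expect_identical(classify_variant("AT", "A"), "INDEL")
  expect_identical(classify_variant("A", "ATT"), "INDEL")
  expect_identical(classify_variant("A", "<DEL>"), NA_character_)
  expect_identical(classify_variant("A", "*"), NA_character_)
  expect_identical(classify_variant("A", "]13:123[AGT"), NA_character_)
})

test_that("strict field predicates and missing handling behave as tabulated on the 5-row QUAL file", {
  wd <- qual5_workdir()
  gt30 <- filter_field(wd, "QUAL", "greater_than", 30)
  expect_same_ranks(gt30, c(2L, 4L))          # 50 and 100; 30 excluded
  expect_identical(filter_field(wd, "QUAL", "greater_than", 30,
                                keep_missing = TRUE)$ranks,
                   c(1L, 2L, 4L))
  pass <- filter_field(wd, "FILTER", "equal_to", "PASS")
  expect_identical(pass$count, 3L)
  expect_error(filter_field(wd, "FILTER", "greater_than", 1),
               "numeric-typed")
  expect_error(filter_field(wd, "QUAL", "contains_keyword", "x"),
               "text-typed")
})

test_that("contains_keyword matches any of a comma-separated list", {
  p <- write_mini_vcf(
    c("1\t100\t.\tA\tG\t50\tPASS\tCSQ=G|missense_variant|BRCA2",
      "1\t200\t.\tC\tT\t40\tPASS\tCSQ=T|intron_variant|TP53",
      "1\t300\t.\tG\tA\t30\tPASS\tCSQ=A|stop_gained&splice_region_variant|EGFR",
      "1\t400\t.\tT\tC\t20\tPASS\tDP=5"),
    csq_format = "Allele|Consequence|SYMBOL")
  wd <- preprocess_vcf(p, "CSQ_Consequence", tempfile("wd"))
  build_index(wd, "CSQ_Consequence")
  ws <- filter_field(wd, "CSQ_Consequence", "contains_keyword",
                     "missense,frameshift,stop_lost,stop_gained")
  expect_same_ranks(ws, c(0L, 2L))
  # case-insensitive substring
  ws2 <- filter_field(wd, "CSQ_Consequence", "contains_keyword", "MISSENSE")
  expect_same_ranks(ws2, 0L)
})

test_that("genotype filter honours scope and quantifier", {
  body <- c(
    "1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/0\t0/0\t0/1",   # de novo pattern
    "1\t200\t.\tC\tT\t50\tPASS\t.\tGT\t0/1\t0/0\t0/1",
    "1\t300\t.\tG\tA\t50\tPASS\t.\tGT\t0/0\t0/0\t1/1",
    "1\t400\t.\tT\tC\t50\tPASS\t.\tGT\t./.\t0/0\t0/1",
    "1\t500\t.\tA\tT\t50\tPASS\t.\tGT\t0/0\t0/0\t0/1"    # de novo pattern
  )
  p <- write_mini_vcf(body, samples = c("mother", "father", "child"))
  wd <- preprocess_vcf(p, "GT", tempfile("wd"))
  parents <- filter_genotype(wd, "HOM_REF", c("mother", "father"), "all")
  denovo <- filter_genotype(wd, "HET", "child", "all", ws = parents)
  expect_same_ranks(denovo, c(0L, 4L))
  # ANY quantifier keeps a row when a single scoped sample matches
  any_het <- filter_genotype(wd, "HET", c("mother", "father"), "any")
  expect_same_ranks(any_het, 1L)
  # MISSING never matches a class
  homref_mother <- filter_genotype(wd, "HOM_REF", "mother", "all")
  expect_false(3L %in% homref_mother$ranks)
  expect_error(filter_genotype(wd, "HET", "uncle", "all"),
               "unknown sample.*mother")
})

test_that("region filter uses a closed 1-based interval and exact names", {
  body <- c("1\t99\t.\tA\tG\t50\tPASS\t.",
            "1\t100\t.\tA\tG\t50\tPASS\t.",
            "1\t150\t.\tA\tG\t50\tPASS\t.",
            "1\t200\t.\tA\tG\t50\tPASS\t.",
            "1\t201\t.\tA\tG\t50\tPASS\t.",
            "2\t150\t.\tA\tG\t50\tPASS\t.",
            "chr1\t150\t.\tA\tG\t50\tPASS\t.")
  wd <- preprocess_vcf(write_mini_vcf(body), character(0), tempfile("wd"))
  ws <- filter_region(wd, "1", 100, 200)
  expect_same_ranks(ws, 1:3)
  expect_error(filter_region(wd, "1", 200, 100), "start.*<=.*end")
})

test_that("variant-type filter uses any-match across ALT alleles", {
  body <- c("1\t100\t.\tA\tG\t50\tPASS\t.",        # SNP
            "1\t200\t.\tAT\tA\t50\tPASS\t.",       # INDEL
            "1\t300\t.\tAT\tGC\t50\tPASS\t.",      # MNP
            "1\t400\t.\tA\tG,ATT\t50\tPASS\t.",    # SNP + INDEL
            "1\t500\t.\tA\t<DEL>\t50\tPASS\t.")    # symbolic: no class
  wd <- preprocess_vcf(write_mini_vcf(body), character(0), tempfile("wd"))
  expect_same_ranks(filter_variant_type(wd, "SNP"), c(0L, 3L))
  expect_same_ranks(filter_variant_type(wd, "INDEL"), c(1L, 3L))
  expect_same_ranks(filter_variant_type(wd, "MNP"), 2L)
  all_snp <- preprocess_vcf(write_mini_vcf("1\t1\t.\tA\tG\t9\tPASS\t."),
                            character(0), tempfile("wd"))
  expect_identical(filter_variant_type(all_snp, "MNP")$count, 0L)
})

test_that("gene-list filter is exact-token, case-insensitive, complementable", {
  p <- write_mini_vcf(
    c("1\t100\t.\tA\tG\t50\tPASS\tCSQ=G|missense_variant|BRCA2",
      "1\t200\t.\tC\tT\t50\tPASS\tCSQ=T|intron_variant|BRCA1P1",
      "1\t300\t.\tG\tA\t50\tPASS\tCSQ=A|stop_gained|BRCA2&TP53",
      "1\t400\t.\tT\tC\t50\tPASS\tCSQ=C|missense_variant|EGFR",
      "1\t500\t.\tA\tT\t50\tPASS\tDP=4"),
    csq_format = "Allele|Consequence|SYMBOL")
  wd <- preprocess_vcf(p, "CSQ_SYMBOL", tempfile("wd"))
  build_index(wd, "CSQ_SYMBOL")
  pos <- filter_gene_list(wd, "BRCA2", "CSQ_SYMBOL", "positive")
  expect_same_ranks(pos, c(0L, 2L))      # BRCA1P1 must not cross-match
  neg <- filter_gene_list(wd, "BRCA2", "CSQ_SYMBOL", "negative")
  expect_same_ranks(neg, c(1L, 3L, 4L))  # missing-symbol row is kept
  lc <- filter_gene_list(wd, "brca2", "CSQ_SYMBOL", "positive")
  expect_identical(lc$ranks, pos$ranks)
  expect_error(filter_gene_list(wd, character(0), "CSQ_SYMBOL"),
               "non-empty")
})

test_that("filtering without an index directs the user to step 2", {
  wd <- qual5_workdir(fields = "QUAL", index = character(0))
  expect_error(filter_field(wd, "QUAL", "greater_than", 10),
               "build_index.*step 2")
})

test_that("chains fold left-to-right and equal predicate intersection", {
  wd <- qual5_workdir()
  f1 <- field_filter("FILTER", "equal_to", "PASS")
  f2 <- field_filter("QUAL", "greater_than", 30)
  chained <- apply_chain(wd, list(f1, f2), record = FALSE)
  a1 <- apply_chain(wd, list(f1), record = FALSE)
  a2 <- apply_chain(wd, list(f2), record = FALSE)
  expect_identical(chained$ranks, intersect(a1$ranks, a2$ranks))
  swapped <- apply_chain(wd, list(f2, f1), record = FALSE)
  expect_identical(chained$ranks, swapped$ranks)
  expect_true(chained$count <= a1$count && chained$count <= a2$count)
  # empty chain is the identity
  expect_identical(apply_chain(wd, list(), record = FALSE)$ranks,
                   all_variants(wd)$ranks)
})

test_that("keep_missing toggling partitions the working set", {
  r <- fixture_workdir(fixture_spec(n_variants = 100, missing_rate = 0.25,
                                    seed = 12),
                       fields = c("QUAL", "AF"))
  for (f in c("QUAL", "AF")) {
    idx <- load_index(r$wd, f)
    keep_f <- filter_field(r$wd, f, "less_than", 0.5)
    keep_t <- filter_field(r$wd, f, "less_than", 0.5, keep_missing = TRUE)
    expect_identical(keep_t$ranks, sort(union(keep_f$ranks, idx$missing)))
    expect_length(intersect(keep_f$ranks, idx$missing), 0)
  }
})
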