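# Field discovery, CSQ expansion and normalization

test_that("discover_fields returns the union of core, INFO and FORMAT", {
  p <- write_mini_vcf("1\t100\t.\tA\tG\t50\tPASS\tAF=0.1;DP=10\tGT\t0/1",
                      samples = "s1")
  df <- discover_fields(p)
  expect_setequal(df$name,
                  c("CHROM+POS", "ID", "REF+ALT", "QUAL", "FILTER",
                    "AF", "DP", "DB", "GT"))
  expect_identical(df$value_type[df$name == "AF"], "FLOAT")
  expect_identical(df$value_type[df$name == "DB"], "FLAG")
  expect_identical(df$origin[df$name == "GT"], "FORMAT")
  expect_false(anyDuplicated(df$name) > 0)
})

test_that("a CSQ declaration is replaced by its named sub-fields", {
  p <- write_mini_vcf(
    "1\t100\t.\tA\tG\t50\tPASS\tCSQ=G|missense_variant|BRCA2",
    csq_format = "Allele|Consequence|SYMBOL")
  df <- discover_fields(p)
  expect_true(all(c("CSQ_Allele", "CSQ_Consequence", "CSQ_SYMBOL") %in%
                    df$name))
  expect_false("CSQ" %in% df$name)
  expect_true(all(df$origin[startsWith(df$name, "CSQ_")] == "CSQ"))
})

test_that("a header with no INFO/FORMAT yields exactly the 5 core fields", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               "1\t100\t.\tA\tG\t50\tPASS\t."), p)
  df <- discover_fields(p)
  expect_identical(df$name,
                   c("CHROM+POS", "ID", "REF+ALT", "QUAL", "FILTER"))
})

test_that("INFO/FORMAT keys used in the body but undeclared are found", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1\t100\t.\tA\tG\t50\tPASS\tMYSTERY=7;SEEN\tGT:XX\t0/1:9"),
             p)
  df <- discover_fields(p)
  for (f in c("MYSTERY", "SEEN", "GT", "XX")) {
    expect_true(f %in% df$name, label = paste("field", f, "discovered"))
  }
  expect_identical(df$value_type[df$name == "MYSTERY"], "STRING")
  expect_identical(df$arity[df$name == "MYSTERY"], ".")
})

test_that("expand_csq splits transcripts and pads short blocks", {
  schema <- c("Allele", "Consequence", "SYMBOL")
  one <- expand_csq("A|missense_variant|BRCA2", schema)
  expect_length(one, 1)
  expect_identical(one[[1]][["CSQ_SYMBOL"]], "BRCA2")
  two <- expand_csq("A|missense_variant|BRCA2,A|intron_variant|BRCA2",
                    schema)
  expect_length(two, 2)
  expect_identical(two[[2]][["CSQ_Consequence"]], "intron_variant")
  gap <- expand_csq("A||BRCA2", schema)
  expect_identical(gap[[1]][["CSQ_Consequence"]], "nan")
  short <- expand_csq("A|stop_gained", schema)
  expect_identical(short[[1]][["CSQ_SYMBOL"]], "nan")
  expect_error(expand_csq("A|x|y|EXTRA", schema), "malformed CSQ")
})

test_that("preprocessing substitutes nan for every missing value", {
  wd <- qual5_workdir(fields = "QUAL", index = character(0))
  tb <- variant_table(wd)
  expect_identical(tb$QUAL, c("10", "nan", "50", "30", "100"))
  expect_identical(nrow(tb), 5L)
})

test_that("empty field selection keeps the key columns only", {
  p <- qual5_vcf()
  wd <- preprocess_vcf(p, character(0), tempfile("wd"))
  tb <- variant_table(wd)
  expect_identical(names(tb), c("chrom", "pos", "rank", "ref", "alts"))
  expect_identical(nrow(tb), 5L)
})

test_that("a multi-transcript CSQ cell carries one value per transcript", {
  p <- write_mini_vcf(
    c("1\t100\t.\tA\tG\t50\tPASS\tCSQ=G|missense_variant|BRCA2,G|intron_variant|TP53",
      "1\t200\t.\tC\tT\t40\tPASS\tDP=9"),
    csq_format = "Allele|Consequence|SYMBOL")
  wd <- preprocess_vcf(p, c("CSQ_Consequence", "CSQ_SYMBOL"),
                       tempfile("wd"))
  tb <- variant_table(wd)
  expect_identical(tb$CSQ_Consequence[1], "missense_variant,intron_variant")
  expect_identical(tb$CSQ_SYMBOL[1], "BRCA2,TP53")
  expect_identical(tb$CSQ_Consequence[2], "nan")   # record without CSQ
})

test_that("unknown selected fields raise a configuration error", {
  p <- qual5_vcf()
  expect_error(preprocess_vcf(p, "NOT_A_FIELD", tempfile("wd")),
               "unknown field.*valid fields")
})

test_that("flags normalize to present/missing", {
  wd <- qual5_workdir(fields = "DB", index = character(0))
  tb <- variant_table(wd)
  expect_identical(tb$DB, c("nan", "nan", "present", "nan", "present"))
})

test_that("row count is conserved for every selection subset", {
  p <- generate_vcf(fixture_spec(n_variants = 30, samples = "s1",
                                 with_csq = TRUE, seed = 5),
                    tempfile(fileext = ".vcf"))
  for (sel in list(character(0), "QUAL", c("QUAL", "AF", "GT"),
                   c("CSQ_Consequence", "DB"))) {
    wd <- preprocess_vcf(p, sel, tempfile("wd"))
    expect_identical(nrow(variant_table(wd)), 30L)
  }
})

test_that("projection is consistent across selection subsets", {
  p <- generate_vcf(fixture_spec(n_variants = 25, samples = "s1",
                                 with_csq = TRUE, seed = 6),
                    tempfile(fileext = ".vcf"))
  s1 <- c("QUAL", "AF")
  s12 <- c("QUAL", "AF", "DP", "CSQ_SYMBOL", "GT")
  t1 <- variant_table(preprocess_vcf(p, s1, tempfile("wd")))
  t12 <- variant_table(preprocess_vcf(p, s12, tempfile("wd")))
  expect_identical(t12[names(t1)], t1)
})

test_that("no literal '.' survives normalization in any selected cell", {
  p <- generate_vcf(fixture_spec(n_variants = 50, samples = c("a", "b"),
                                 with_csq = TRUE, missing_rate = 0.3,
                                 seed = 7),
                    tempfile(fileext = ".vcf"))
  wd <- preprocess_vcf(p, c("QUAL", "FILTER", "AF", "DP", "DB",
                            "CSQ_Consequence", "CSQ_SYMBOL"),
                       tempfile("wd"))
  tb <- variant_table(wd)
  for (col in setdiff(names(tb), c("chrom", "pos", "rank", "ref", "alts"))) {
    vals <- unlist(strsplit(tb[[col]], ","))
    expect_false(any(vals == "." | vals == ""),
                 label = paste("no bare '.' in", col))
  }
})
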