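# Hand-written miniature VCFs for exact-value unit tests; generated
# fixtures (via fixture_spec()/generate_vcf()) cover the randomized cases.

mini_header <- function(samples = character(0), csq_format = NULL,
                        extra = character(0)) {
  h <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##INFO=<ID=DB,Number=0,Type=Flag,Description="In database">'
  )
  if (!is.null(csq_format)) {
    h <- c(h, paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description=',
                     '"VEP. Format: ', csq_format, '">'))
  }
  if (length(samples) > 0) {
    h <- c(h,
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  }
  h <- c(h, extra)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples) > 0) cols <- c(cols, "FORMAT", samples)
  c(h, paste(cols, collapse = "\t"))
}

write_mini_vcf <- function(body, samples = character(0), csq_format = NULL,
                           extra_header = character(0),
                           path = tempfile(fileext = ".vcf")) {
  writeLines(c(mini_header(samples, csq_format, extra_header), body), path)
  path
}

# the canonical 5-row QUAL fixture: QUAL values 10, ., 50, 30, 100
qual5_vcf <- function(path = tempfile(fileext = ".vcf")) {
  body <- c(
    "1\t100\t.\tA\tG\t10\tPASS\tDP=10",
    "1\t200\t.\tC\tT\t.\tq10\tDP=20",
    "1\t300\t.\tG\tA\t50\tPASS\tDP=30;DB",
    "2\t100\t.\tT\tC\t30\tPASS\tDP=40",
    "2\t200\t.\tA\tT\t100\tq10\tDP=50;DB"
  )
  write_mini_vcf(body, path = path)
}

qual5_workdir <- function(fields = c("QUAL", "FILTER", "DP", "DB"),
                          index = fields) {
  p <- qual5_vcf()
  wd <- preprocess_vcf(p, fields, tempfile("wd"))
  for (f in index) build_index(wd, f)
  wd
}

# build a fully indexed workdir for a generated fixture
fixture_workdir <- function(spec, fields, index = fields,
                            path = tempfile(fileext = ".vcf")) {
  generate_vcf(spec, path)
  wd <- preprocess_vcf(path, fields, tempfile("wd"))
  for (f in index) build_index(wd, f)
  list(path = path, wd = wd, truth = read_truth(path))
}

expect_same_ranks <- function(ws, ranks) {
  expect_identical(ws$ranks, sort(as.integer(ranks)))
  expect_identical(ws$count, length(unique(ranks)))
}
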