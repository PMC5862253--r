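# Deterministic synthetic-VCF generator. Fixtures carry a ground-truth
# sidecar (per-variant true type, per-sample true genotype class, true
# annotation values) written at generation time by construction, so tests
# never have to re-derive expectations from the code they check. The same
# seed always produces byte-identical files.

BASES <- c("A", "C", "G", "T")

CONSEQUENCE_POOL <- c(
  "missense_variant", "synonymous_variant", "intron_variant",
  "frameshift_variant", "stop_gained", "stop_lost",
  "splice_region_variant", "upstream_gene_variant",
  "missense_variant&splice_region_variant", "3_prime_UTR_variant"
)

GENE_POOL <- c("BRCA2", "TP53", "EGFR", "PKD1", "CFTR", "BRCA1P1", "MYH7")

#' Specify a synthetic VCF fixture
#'
#' Describes a synthetic single- or multi-sample VCF: variant count, sample
#' names and ploidy, variant-type mix, INFO annotations (allele frequency
#' `AF`, read depth `DP`, a `DB` membership flag), optional VEP-style CSQ
#' annotation with 1-4 transcript blocks per record, per-value missing rate
#' and gzip compression. Chromosome names mix bare (`"1"`) and `"chr"`
#' styles, coordinates may repeat, and some SNP records gain a second,
#' insertion, allele so multi-allelic any-match paths are exercised.
#'
#' @param n_variants Number of data lines.
#' @param samples Character vector of sample names (may be empty).
#' @param ploidy Integer ploidy, recycled over samples (mixed ploidy is
#'   allowed and exercises the non-diploid genotype rules).
#' @param type_mix Named proportions over `SNP`, `INDEL`, `MNP`; must sum
#'   to 1.
#' @param missing_rate Probability that any individual value (QUAL, INFO
#'   value, CSQ annotation, genotype) is missing.
#' @param with_csq Emit a VEP CSQ INFO annotation?
#' @param csq_subfields CSQ sub-field names declared in the header.
#' @param multi_alt_rate Probability that a SNP record gains a second ALT
#'   allele (an insertion).
#' @param phased_rate Probability that a genotype uses the phased `|`
#'   separator.
#' @param gzip Write gzip-compressed output?
#' @param scenario `NULL`, or a preset pattern: see [trio_preset()] and
#'   [tumour_normal_preset()].
#' @param n_target Number of scenario-pattern rows embedded.
#' @param seed Integer seed; the same spec and seed yield byte-identical
#'   files.
#' @return A `fixture_spec` list consumed by [generate_vcf()].
#' @export
fixture_spec <- function(n_variants, samples = character(0), ploidy = 2L,
                         type_mix = c(SNP = 0.7, INDEL = 0.2, MNP = 0.1),
                         missing_rate = 0.1, with_csq = FALSE,
                         csq_subfields = c("Allele", "Consequence",
                                           "IMPACT", "SYMBOL"),
                         multi_alt_rate = 0.05, phased_rate = 0.2,
                         gzip = FALSE, scenario = NULL, n_target = 0L,
                         seed = 1L) {
  stopifnot(n_variants >= 0, missing_rate >= 0, missing_rate <= 1,
            all(ploidy >= 1L))
  type_mix <- type_mix[c("SNP", "INDEL", "MNP")]
  type_mix[is.na(type_mix)] <- 0
  names(type_mix) <- c("SNP", "INDEL", "MNP")
  if (abs(sum(type_mix) - 1) > 1e-9) {
    stop("type_mix proportions must sum to 1", call. = FALSE)
  }
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("trio", "tumour_normal"))
    if (n_target > n_variants) {
      stop("n_target must not exceed n_variants", call. = FALSE)
    }
  }
  structure(
    list(n_variants = as.integer(n_variants), samples = samples,
         ploidy = as.integer(rep_len(ploidy, max(1L, length(samples)))),
         type_mix = type_mix, missing_rate = missing_rate,
         with_csq = isTRUE(with_csq), csq_subfields = csq_subfields,
         multi_alt_rate = multi_alt_rate, phased_rate = phased_rate,
         gzip = isTRUE(gzip), scenario = scenario,
         n_target = as.integer(n_target), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Trio fixture with embedded de novo candidates
#'
#' A three-sample (mother, father, child) joint-calling fixture embedding
#' exactly `n_denovo` rows with the de novo pattern — both parents
#' homozygous reference, child heterozygous — while every other row is
#' guaranteed not to match that pattern. The ground-truth sidecar marks the
#' embedded rows, so the de novo filter chain can be checked for exact
#' recovery.
#'
#' @param n_variants Number of data lines.
#' @param n_denovo Number of embedded de novo rows (`<= n_variants`).
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
trio_preset <- function(n_variants, n_denovo, seed = 1L) {
  fixture_spec(n_variants, samples = c("mother", "father", "child"),
               ploidy = 2L, scenario = "trio", n_target = n_denovo,
               missing_rate = 0.05, seed = seed)
}

#' Matched tumour/normal fixture
#'
#' A two-sample (normal, tumour) fixture embedding exactly `n_somatic` rows
#' where the normal sample is homozygous reference (and the tumour carries
#' the variant, as under joint calling); in every other row the normal
#' sample is non-reference or missing.
#'
#' @param n_variants Number of data lines.
#' @param n_somatic Number of embedded normal-hom-ref rows.
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
tumour_normal_preset <- function(n_variants, n_somatic, seed = 1L) {
  fixture_spec(n_variants, samples = c("normal", "tumour"),
               ploidy = 2L, scenario = "tumour_normal",
               n_target = n_somatic, missing_rate = 0.05, seed = seed)
}

#' Generate a synthetic VCF and its ground-truth sidecar
#'
#' Writes a standards-conformant VCF 4.2 file matching the spec, plus a
#' tab-separated ground-truth sidecar at `<path>.truth.tsv` holding, per
#' variant: key columns, the true class of every ALT allele, the true
#' annotation values and the true genotype class of every sample, plus a
#' `target` flag for scenario presets. Identical specs produce byte-identical
#' files.
#'
#' @param spec A [fixture_spec()].
#' @param path Output path for the VCF.
#' @return `path` (the sidecar sits beside it at `<path>.truth.tsv`).
#' @export
generate_vcf <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(spec$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  n <- spec$n_variants
  miss <- function(k = n) stats::runif(k) < spec$missing_rate

  # coordinates, sorted within chromosome; duplicates legal
  chrom_pool <- c("1", "2", "chr3")
  chrom <- sample(chrom_pool, n, replace = TRUE,
                  prob = c(0.45, 0.35, 0.2))
  chrom <- chrom[order(match(chrom, chrom_pool))]
  pos <- integer(n)
  for (cp in chrom_pool) {
    sel <- chrom == cp
    pos[sel] <- sort(sample.int(999999L, sum(sel), replace = TRUE))
  }

  # alleles by type
  types <- if (n > 0L) {
    sample(names(spec$type_mix), n, replace = TRUE, prob = spec$type_mix)
  } else character(0)
  ref <- character(n); alt <- character(n); var_types <- character(n)
  for (i in seq_len(n)) {
    a <- make_alleles(types[i])
    if (types[i] == "SNP" && stats::runif(1) < spec$multi_alt_rate) {
      ins <- paste0(a$ref, paste(sample(BASES, 2, replace = TRUE),
                                 collapse = ""))
      a$alt <- c(a$alt, ins)                       # SNP + insertion
    }
    ref[i] <- a$ref
    alt[i] <- paste(a$alt, collapse = ",")
    var_types[i] <- paste(vapply(a$alt, function(x) {
      if (nchar(x) != nchar(a$ref)) "INDEL"
      else if (nchar(x) == 1L) "SNP" else "MNP"
    }, character(1L)), collapse = ",")
  }

  id <- ifelse(stats::runif(n) < 0.15,
               paste0("rs", sample.int(10000000L, n, replace = TRUE)), ".")
  qual <- ifelse(miss(), ".", sprintf("%.1f", stats::runif(n, 5, 100)))
  filt <- sample(c("PASS", "q10", "q20"), max(n, 1L), replace = TRUE,
                 prob = c(0.7, 0.15, 0.15))[seq_len(n)]

  # INFO: AF (Float, per-ALT), DP (Integer), DB (Flag), optional CSQ
  n_alts <- lengths(strsplit(alt, ",", fixed = TRUE))
  af <- vapply(seq_len(n), function(i) {
    paste(sprintf("%.4f", stats::runif(n_alts[i], 0.0001, 0.9)),
          collapse = ",")
  }, character(1L))
  af_missing <- miss()
  dp <- sample.int(200L, max(n, 1L), replace = TRUE)[seq_len(n)]
  dp_missing <- miss()
  db <- stats::runif(n) < 0.3

  csq <- rep(NA_character_, n)
  truth_csq_cons <- rep("", n)
  truth_csq_sym <- rep("", n)
  if (spec$with_csq && n > 0L) {
    csq_missing <- miss()
    for (i in seq_len(n)) {
      if (csq_missing[i]) next
      nb <- sample.int(4L, 1L)
      cons <- sample(CONSEQUENCE_POOL, nb, replace = TRUE)
      syms <- sample(GENE_POOL, nb, replace = TRUE)
      # empty sub-values appear routinely in real VEP output
      syms[stats::runif(nb) < 0.1] <- ""
      impact <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), nb,
                       replace = TRUE)
      allele1 <- strsplit(alt[i], ",", fixed = TRUE)[[1L]][1L]
      blocks <- paste(allele1, cons, impact, syms, sep = "|")
      csq[i] <- paste(blocks, collapse = ",")
      truth_csq_cons[i] <- paste(cons, collapse = ",")
      truth_csq_sym[i] <- paste(syms, collapse = ",")
    }
  }

  info <- vapply(seq_len(n), function(i) {
    kv <- character(0)
    if (!af_missing[i]) kv <- c(kv, paste0("AF=", af[i]))
    if (!dp_missing[i]) kv <- c(kv, paste0("DP=", dp[i]))
    if (db[i]) kv <- c(kv, "DB")
    if (!is.na(csq[i])) kv <- c(kv, paste0("CSQ=", csq[i]))
    if (length(kv) == 0L) "." else paste(kv, collapse = ";")
  }, character(1L))
  if (n == 0L) info <- character(0)

  # genotypes
  ns <- length(spec$samples)
  gt <- matrix(character(0), nrow = n, ncol = ns)
  gt_class <- matrix(character(0), nrow = n, ncol = ns)
  target <- rep(FALSE, n)
  if (ns > 0L && n > 0L) {
    gt <- matrix("", n, ns)
    if (!is.null(spec$scenario)) {
      target[sample.int(n, spec$n_target)] <- TRUE
    }
    for (i in seq_len(n)) {
      gt[i, ] <- make_genotypes(spec, n_alts[i], target[i])
    }
    gt_class <- matrix(vapply(gt, true_gt_class, character(1L)), n, ns)
  }

  header <- fixture_header(spec)
  body <- if (n == 0L) character(0) else {
    cols <- cbind(chrom, pos, id, ref, alt, qual, filt, info)
    if (ns > 0L) cols <- cbind(cols, "GT", gt)
    apply(cols, 1L, paste, collapse = "\t")
  }
  con <- if (spec$gzip) gzfile(path, "wt") else file(path, "wt")
  writeLines(c(header, body), con, sep = "\n")
  close(con)

  truth <- data.frame(
    rank = seq_len(n) - 1L, chrom = chrom, pos = pos, ref = ref, alts = alt,
    var_types = var_types,
    qual = qual, filter = filt,
    af = ifelse(af_missing, "", af),
    dp = ifelse(dp_missing, "", as.character(dp)),
    db = as.integer(db),
    csq_consequence = truth_csq_cons, csq_symbol = truth_csq_sym,
    target = as.integer(target),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (n == 0L) truth <- truth[0L, ]
  for (j in seq_len(ns)) {
    truth[[paste0("gt_", spec$samples[j])]] <- gt[, j]
    truth[[paste0("class_", spec$samples[j])]] <- gt_class[, j]
  }
  utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

make_alleles <- function(type) {
  switch(type,
    SNP = {
      r <- sample(BASES, 1L)
      list(ref = r, alt = sample(setdiff(BASES, r), 1L))
    },
    MNP = {
      len <- sample(2:3, 1L)
      r <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      repeat {
        a <- paste(sample(BASES, len, replace = TRUE), collapse = "")
        if (a != r) break
      }
      list(ref = r, alt = a)
    },
    INDEL = {
      extra <- paste(sample(BASES, sample(1:3, 1L), replace = TRUE),
                     collapse = "")
      anchor <- sample(BASES, 1L)
      if (stats::runif(1) < 0.5) {
        list(ref = anchor, alt = paste0(anchor, extra))   # insertion
      } else {
        list(ref = paste0(anchor, extra), alt = anchor)   # deletion
      }
    }
  )
}

# one GT string per sample for one record; scenario presets override the
# random pattern so target rows match it exactly and non-target rows cannot
make_genotypes <- function(spec, n_alt, is_target) {
  ns <- length(spec$samples)
  random_gt <- function(p) {
    if (stats::runif(1) < spec$missing_rate) {
      return(paste(rep(".", p), collapse = "/"))
    }
    sep <- if (stats::runif(1) < spec$phased_rate) "|" else "/"
    paste(sample(0:min(n_alt, 2L), p, replace = TRUE,
                 prob = c(0.55, 0.35, 0.1)[seq_len(min(n_alt, 2L) + 1L)]),
          collapse = sep)
  }
  if (is.null(spec$scenario)) {
    return(vapply(spec$ploidy[seq_len(ns)], random_gt, character(1L)))
  }
  if (spec$scenario == "trio") {
    # samples are (mother, father, child)
    if (is_target) return(c("0/0", "0/0", "0/1"))
    repeat {
      g <- vapply(rep(2L, 3L), random_gt, character(1L))
      cls <- vapply(g, true_gt_class, character(1L))
      denovo <- cls[1L] == "HOM_REF" && cls[2L] == "HOM_REF" &&
        cls[3L] == "HET"
      if (!denovo) return(g)
      g[3L] <- "0/0"   # break the pattern deterministically
      return(g)
    }
  }
  if (spec$scenario == "tumour_normal") {
    # samples are (normal, tumour)
    if (is_target) {
      return(c("0/0", sample(c("0/1", "1/1"), 1L, prob = c(0.7, 0.3))))
    }
    normal <- sample(c("0/1", "1/1", "./."), 1L, prob = c(0.5, 0.3, 0.2))
    tumour <- random_gt(2L)
    return(c(normal, tumour))
  }
  stop("unknown scenario: ", spec$scenario)
}

# ground-truth genotype classification, by construction at generation time
true_gt_class <- function(g) {
  tk <- strsplit(g, "[/|]")[[1L]]
  if (length(tk) == 0L || any(tk == ".")) return("MISSING")
  idx <- as.integer(tk)
  if (all(idx == 0L)) "HOM_REF"
  else if (all(idx == idx[1L])) "HOM_ALT"
  else "HET"
}

fixture_header <- function(spec) {
  h <- c(
    "##fileformat=VCFv4.2",
    "##source=vcfsift-fixture-generator",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##INFO=<ID=DB,Number=0,Type=Flag,Description="Database membership">'
  )
  if (spec$with_csq) {
    h <- c(h, paste0(
      '##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence ',
      'annotations from Ensembl VEP. Format: ',
      paste(spec$csq_subfields, collapse = "|"), '">'))
  }
  if (length(spec$samples) > 0L) {
    h <- c(h, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  }
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(spec$samples) > 0L) cols <- c(cols, "FORMAT", spec$samples)
  c(h, paste(cols, collapse = "\t"))
}

#' Read a fixture's ground-truth sidecar
#'
#' @param path The VCF path passed to [generate_vcf()].
#' @return The ground-truth `data.frame`.
#' @export
read_truth <- function(path) {
  utils::read.delim(paste0(path, ".truth.tsv"), sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
}
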