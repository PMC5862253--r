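# Step 3: the five filter types. Each is a pure per-variant predicate: it
# takes a working set and returns the subset satisfying the predicate, so
# chaining filters is set intersection and the surviving count never
# increases. Multi-valued cells (multi-allelic ALTs, multi-transcript CSQ
# values, arity A/R/G INFO fields) use any-match semantics: the record is
# kept or dropped whole.

GT_CLASSES <- c("HOM_REF", "HET", "HOM_ALT")
VARIANT_KINDS <- c("SNP", "INDEL", "MNP")
FIELD_OPS <- c("greater_than", "less_than", "equal_to", "contains_keyword")

#' Classify a genotype call
#'
#' Applies the genotype-class rules at any ploidy: `MISSING` if any allele
#' index is missing; `HOM_REF` if all indices are 0; `HOM_ALT` if all indices
#' are equal and non-zero; `HET` if at least two distinct indices occur.
#' Phasing is ignored (`"0|1"` classifies like `"0/1"`).
#'
#' @param call A [parse_genotype()] result, a raw GT string, or an integer
#'   vector of allele indices (`NA` = missing).
#' @return One of `"HOM_REF"`, `"HET"`, `"HOM_ALT"`, `"MISSING"`.
#' @examples
#' classify_genotype("0/1")
#' classify_genotype(c(1L, 2L))   # two distinct non-reference alleles
#' classify_genotype("2")         # haploid hom-alt
#' @export
classify_genotype <- function(call) {
  idx <- if (inherits(call, "genotype_call")) {
    call$allele_indices
  } else if (is.character(call)) {
    parse_genotype(call)$allele_indices
  } else {
    as.integer(call)
  }
  if (length(idx) == 0L || anyNA(idx)) return("MISSING")
  if (all(idx == 0L)) return("HOM_REF")
  if (all(idx == idx[1L])) return("HOM_ALT")
  "HET"
}

# vectorized classification of raw GT text cells ("nan" = no GT value)
classify_gt_cells <- function(cells) {
  out <- rep("MISSING", length(cells))
  todo <- cells != MISSING & nzchar(cells)
  toks <- strsplit(cells[todo], "[/|]")
  out[todo] <- vapply(toks, function(tk) {
    if (length(tk) == 0L || any(tk == ".") ||
        anyNA(suppressWarnings(idx <- as.integer(tk)))) {
      return("MISSING")
    }
    if (all(idx == 0L)) "HOM_REF"
    else if (all(idx == idx[1L])) "HOM_ALT"
    else "HET"
  }, character(1L))
  out
}

#' Classify a REF/ALT allele pair as SNP, InDel or MNP
#'
#' `SNP` when both alleles are single bases; `MNP` when they have the same
#' length greater than one; `INDEL` when lengths differ. Symbolic or breakend
#' alternates (`<DEL>`, `]`-notation, `*`, `.`) belong to none of the three
#' classes and return `NA`.
#'
#' @param ref Reference allele(s), character vector.
#' @param alt Single alternate allele(s), character vector (recycled against
#'   `ref`).
#' @return Character vector: `"SNP"`, `"INDEL"`, `"MNP"` or `NA`.
#' @examples
#' classify_variant("A", "G")      # SNP
#' classify_variant("AT", "GC")    # MNP
#' classify_variant("AT", "A")     # INDEL
#' classify_variant("A", "<DEL>")  # NA: symbolic
#' @export
classify_variant <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  symbolic <- grepl("[][<>]", alt) | alt %in% c(".", "*", "", MISSING)
  lr <- nchar(ref)
  la <- nchar(alt)
  out <- ifelse(lr != la, "INDEL", ifelse(lr == 1L, "SNP", "MNP"))
  out[symbolic] <- NA_character_
  out
}

# ---- filter 1: annotation field --------------------------------------------

#' Filter a working set on an annotation field
#'
#' Keeps the variants whose value of `field` satisfies the predicate.
#' `greater_than`/`less_than` are strict numeric comparisons and require a
#' numeric-typed field; `equal_to` compares numerically on numeric fields and
#' by exact string on text fields; `contains_keyword` splits `value` on
#' commas and keeps a variant if any keyword is a case-insensitive substring
#' of any of its values. Variants whose values are all missing are kept iff
#' `keep_missing` — e.g. `AF less_than 0.01, keep_missing = TRUE` keeps both
#' rare variants and variants absent from the frequency database.
#'
#' @param wd A `vcf_workdir` handle or path; `field` must have a built index.
#' @param field Field name.
#' @param op One of `"greater_than"`, `"less_than"`, `"equal_to"`,
#'   `"contains_keyword"`.
#' @param value Numeric cut-off, or for `contains_keyword` a comma-separated
#'   keyword list.
#' @param keep_missing Keep variants with only missing values?
#' @param ws Input `working_set` (default: all variants).
#' @return The surviving `working_set`.
#' @export
filter_field <- function(wd, field, op, value, keep_missing = FALSE,
                         ws = NULL) {
  op <- match.arg(tolower(op), FIELD_OPS)
  meta <- wd_field_meta(wd, field)
  if (is.null(meta)) {
    stop("field ", sQuote(field), " is not in the pre-processed table",
         call. = FALSE)
  }
  numeric_field <- meta$value_type %in% c("INTEGER", "FLOAT") ||
    field == "QUAL"
  if (op %in% c("greater_than", "less_than") && !numeric_field) {
    stop(op, " requires a numeric-typed field, but ", sQuote(field),
         " has type ", meta$value_type, call. = FALSE)
  }
  if (op == "contains_keyword" && numeric_field) {
    stop("contains_keyword requires a text-typed field, but ",
         sQuote(field), " has type ", meta$value_type, call. = FALSE)
  }
  idx <- load_index(wd, field)
  keep <- index_matches(idx, op, value)
  if (isTRUE(keep_missing)) keep <- sort(union(keep, idx$missing))
  ws <- if (is.null(ws)) all_variants(wd) else as_working_set(ws)
  working_set(ws$ranks[ws$ranks %in% keep], origin = "filter_field")
}

# ---- filter 2: genotype class ----------------------------------------------

#' Filter on genotype class in one, some or all samples
#'
#' Keeps variants where the genotype class of the scoped samples matches
#' `gt_class` under the quantifier: `"all"` requires every scoped sample to
#' match, `"any"` at least one. Missing genotypes never match any class.
#' This realizes family designs — e.g. de novo candidates are
#' `HOM_REF` in `c("mother", "father")` (all) chained with `HET` in
#' `"child"` — and tumour/normal designs (`HOM_REF` in the normal sample).
#'
#' @param wd A `vcf_workdir` handle or path; `GT` must be a selected field.
#' @param gt_class `"HOM_REF"`, `"HET"` or `"HOM_ALT"`.
#' @param samples Non-empty character vector of sample names.
#' @param quantifier `"all"` or `"any"` over `samples`.
#' @param ws Input `working_set` (default: all variants).
#' @return The surviving `working_set`.
#' @export
filter_genotype <- function(wd, gt_class, samples, quantifier = "all",
                            ws = NULL) {
  gt_class <- match.arg(toupper(gt_class), GT_CLASSES)
  quantifier <- match.arg(tolower(quantifier), c("all", "any"))
  if (length(samples) == 0L) {
    stop("samples must be a non-empty sample-name list", call. = FALSE)
  }
  valid <- wd_samples(wd)
  bad <- setdiff(samples, valid)
  if (length(bad) > 0L) {
    stop("unknown sample(s): ", paste(bad, collapse = ", "),
         "; valid samples are: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  if (!"GT" %in% wd_fields(wd)) {
    stop("the GT field is not in the pre-processed table; ",
         "add it with add_field() first", call. = FALSE)
  }
  tb <- wd_table(wd)
  match_mat <- vapply(samples, function(s) {
    classify_gt_cells(tb[[paste0("GT.", s)]]) == gt_class
  }, logical(nrow(tb)))
  if (nrow(tb) == 1L) match_mat <- matrix(match_mat, nrow = 1L)
  keep_row <- if (quantifier == "all") {
    rowSums(match_mat) == length(samples)
  } else {
    rowSums(match_mat) > 0L
  }
  ws <- if (is.null(ws)) all_variants(wd) else as_working_set(ws)
  working_set(intersect(ws$ranks, tb$rank[keep_row]),
              origin = "filter_genotype")
}

# ---- filter 3: genomic region ----------------------------------------------

#' Filter on a genomic region
#'
#' Keeps variants with `chrom` equal to the given chromosome (matched as
#' literal text, no name normalization) and position inside the closed,
#' 1-based interval `[start, end]`.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param chrom Chromosome name, matched exactly.
#' @param start,end 1-based inclusive bounds; `start <= end`.
#' @param ws Input `working_set` (default: all variants).
#' @return The surviving `working_set`.
#' @export
filter_region <- function(wd, chrom, start, end, ws = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid region: start (", start, ") must be <= end (", end, ")",
         call. = FALSE)
  }
  tb <- wd_table(wd)
  keep_row <- tb$chrom == as.character(chrom) &
    tb$pos >= start & tb$pos <= end
  ws <- if (is.null(ws)) all_variants(wd) else as_working_set(ws)
  working_set(intersect(ws$ranks, tb$rank[keep_row]),
              origin = "filter_region")
}

# ---- filter 4: variant type ------------------------------------------------

#' Filter on variant type (SNP, InDel, MNP)
#'
#' Keeps variants where any alternate allele classifies as `kind` (see
#' [classify_variant()]); multi-allelic records are kept or dropped whole.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param kind `"SNP"`, `"INDEL"` or `"MNP"`.
#' @param ws Input `working_set` (default: all variants).
#' @return The surviving `working_set`.
#' @export
filter_variant_type <- function(wd, kind, ws = NULL) {
  kind <- match.arg(toupper(kind), VARIANT_KINDS)
  tb <- wd_table(wd)
  keep_row <- vapply(seq_len(nrow(tb)), function(i) {
    alts <- strsplit(tb$alts[i], ",", fixed = TRUE)[[1L]]
    any(classify_variant(tb$ref[i], alts) == kind, na.rm = TRUE)
  }, logical(1L))
  ws <- if (is.null(ws)) all_variants(wd) else as_working_set(ws)
  working_set(intersect(ws$ranks, tb$rank[keep_row]),
              origin = "filter_variant_type")
}

# ---- filter 5: gene list ---------------------------------------------------

#' Filter on a user-defined gene list
#'
#' A variant is associated with the list iff any of its values of `field`
#' equals (case-insensitive, exact token, values split at `&`, `,` and `;`)
#' any listed gene. `mode = "positive"` keeps associated variants;
#' `mode = "negative"` keeps the complement within the working set —
#' variants with only missing values are not associated, hence kept by a
#' negative query.
#'
#' @param wd A `vcf_workdir` handle or path; `field` must have a built index.
#' @param genes Non-empty character vector of gene symbols.
#' @param field Annotation field holding gene symbols (e.g. `"CSQ_SYMBOL"`).
#' @param mode `"positive"` or `"negative"`.
#' @param ws Input `working_set` (default: all variants).
#' @return The surviving `working_set`.
#' @export
filter_gene_list <- function(wd, genes, field, mode = "positive",
                             ws = NULL) {
  mode <- match.arg(tolower(mode), c("positive", "negative"))
  if (length(genes) == 0L || !any(nzchar(genes))) {
    stop("genes must be a non-empty list of gene symbols", call. = FALSE)
  }
  idx <- load_index(wd, field)
  associated <- index_gene_matches(idx, genes)
  ws <- if (is.null(ws)) all_variants(wd) else as_working_set(ws)
  keep <- if (mode == "positive") {
    ws$ranks[ws$ranks %in% associated]
  } else {
    ws$ranks[!ws$ranks %in% associated]
  }
  working_set(keep, origin = "filter_gene_list")
}

# ---- filter specifications and chains --------------------------------------

#' Filter-step specifications
#'
#' Constructors for the serializable specification of one filter step — the
#' form recorded in the filter history, exported in reports and consumed by
#' [apply_chain()] and the CLI.
#'
#' @param field,op,value,keep_missing See [filter_field()].
#' @return A `filter_spec` list with a `type` and the step's parameters.
#' @seealso [apply_chain()], [apply_filter()]
#' @export
field_filter <- function(field, op, value, keep_missing = FALSE) {
  filter_spec("field", field = field, op = match.arg(tolower(op), FIELD_OPS),
              value = value, keep_missing = isTRUE(keep_missing))
}

#' @rdname field_filter
#' @param gt_class,samples,quantifier See [filter_genotype()].
#' @export
genotype_filter <- function(gt_class, samples, quantifier = "all") {
  filter_spec("genotype", gt_class = match.arg(toupper(gt_class), GT_CLASSES),
              samples = as.character(samples),
              quantifier = match.arg(tolower(quantifier), c("all", "any")))
}

#' @rdname field_filter
#' @param chrom,start,end See [filter_region()].
#' @export
region_filter <- function(chrom, start, end) {
  filter_spec("region", chrom = as.character(chrom),
              start = as.numeric(start), end = as.numeric(end))
}

#' @rdname field_filter
#' @param kind See [filter_variant_type()].
#' @export
variant_type_filter <- function(kind) {
  filter_spec("variant_type", kind = match.arg(toupper(kind), VARIANT_KINDS))
}

#' @rdname field_filter
#' @param genes,mode See [filter_gene_list()].
#' @export
gene_filter <- function(genes, field, mode = "positive") {
  filter_spec("gene_list", genes = as.character(genes), field = field,
              mode = match.arg(tolower(mode), c("positive", "negative")))
}

filter_spec <- function(type, ...) {
  structure(list(type = type, ...), class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("filter step:", x$type, " ",
      jsonlite::toJSON(unclass(x), auto_unbox = TRUE), "\n")
  invisible(x)
}

# evaluate one spec against a working set, no history side effects
apply_spec <- function(wd, spec, ws) {
  switch(
    spec$type,
    field = filter_field(wd, spec$field, spec$op, spec$value,
                         isTRUE(spec$keep_missing), ws = ws),
    genotype = filter_genotype(wd, spec$gt_class,
                               unlist(spec$samples), spec$quantifier,
                               ws = ws),
    region = filter_region(wd, spec$chrom, spec$start, spec$end, ws = ws),
    variant_type = filter_variant_type(wd, spec$kind, ws = ws),
    gene_list = filter_gene_list(wd, unlist(spec$genes), spec$field,
                                 spec$mode, ws = ws),
    stop("unknown filter type: ", spec$type, call. = FALSE)
  )
}

#' Apply one filter step and record it in the history
#'
#' The step is applied to the current working set (the output of the last
#' recorded step, or all variants when the history is empty), its output key
#' set is persisted, and a history entry with input/output counts is
#' appended.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param spec A `filter_spec` (see [field_filter()] and friends).
#' @return The surviving `working_set`, invisibly.
#' @export
apply_filter <- function(wd, spec) {
  ws_in <- current_variants(wd)
  ws_out <- apply_spec(wd, spec, ws_in)
  record_step(wd, spec, ws_in$count, ws_out)
  invisible(ws_out)
}

#' Apply an ordered chain of filters
#'
#' Folds the steps left to right, each consuming the previous step's output —
#' filters are applied sequentially, so each one only sees the variants that
#' passed all previous filters. By default each step is recorded in the
#' workdir history; with `record = FALSE` the chain is evaluated purely.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param steps List of `filter_spec` objects.
#' @param initial Starting `working_set`; default is the current set (the
#'   last recorded output, or all variants).
#' @param record Append each step to the filter history?
#' @return The final `working_set`.
#' @export
apply_chain <- function(wd, steps, initial = NULL, record = TRUE) {
  ws <- if (!is.null(initial)) {
    as_working_set(initial)
  } else if (record) {
    current_variants(wd)
  } else {
    all_variants(wd)
  }
  for (spec in steps) {
    ws_out <- apply_spec(wd, spec, ws)
    if (record) record_step(wd, spec, ws$count, ws_out)
    ws <- ws_out
  }
  ws
}
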