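# Naive re-parse-and-scan oracle: a deliberately simple, independent
# implementation of the five filters that re-reads the raw VCF text for
# every query. It shares no code with the package's preprocess/index/filter
# path and exists solely so index-backed answers can be compared against a
# brute-force linear scan. All functions return 0-based record ranks.

oracle_parse <- function(path) {
  con <- gzfile(path, "rt")   # reads plain files transparently too
  lines <- readLines(con, warn = FALSE)
  close(con)
  meta <- lines[startsWith(lines, "##")]
  colline <- lines[startsWith(lines, "#CHROM")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  cols <- strsplit(sub("^#", "", colline), "\t")[[1]]
  rows <- strsplit(body, "\t")
  list(meta = meta, cols = cols,
       samples = if (length(cols) > 9) cols[-(1:9)] else character(0),
       rows = rows)
}

oracle_csq_schema <- function(meta) {
  ln <- meta[grepl("^##INFO=<ID=CSQ[,>]", meta)]
  if (length(ln) == 0) return(character(0))
  m <- regmatches(ln, regexec('Format: ([^"]*)"', ln))[[1]]
  if (length(m) < 2) return(character(0))
  strsplit(m[2], "|", fixed = TRUE)[[1]]
}

# all values of one field for one row, NA for missing; any-match semantics
# are applied by the callers over this vector
oracle_values <- function(row, field, samples, schema) {
  blank <- function(v) ifelse(v %in% c(".", ""), NA_character_, v)
  if (field == "QUAL") return(blank(row[6]))
  if (field == "FILTER") return(blank(row[7]))
  if (field == "ID") return(blank(row[3]))
  if (field == "CHROM+POS") return(paste0(row[1], ":", row[2]))
  if (field == "REF+ALT") return(paste0(row[4], ">", row[5]))
  if (startsWith(field, "CSQ_")) {
    sub_name <- sub("^CSQ_", "", field)
    j <- match(sub_name, schema)
    kv <- strsplit(row[8], ";")[[1]]
    hit <- kv[startsWith(kv, "CSQ=")]
    if (length(hit) == 0) return(NA_character_)
    blocks <- strsplit(sub("^CSQ=", "", hit[1]), ",")[[1]]
    vals <- vapply(blocks, function(b) {
      parts <- strsplit(b, "|", fixed = TRUE)[[1]]
      if (j <= length(parts)) parts[j] else ""
    }, character(1))
    return(blank(vals))
  }
  if (field %in% samples_format_keys(row)) {
    fmt <- strsplit(row[9], ":")[[1]]
    j <- match(field, fmt)
    vals <- vapply(seq_along(samples), function(s) {
      sv <- strsplit(row[9 + s], ":")[[1]]
      if (!is.na(j) && j <= length(sv)) sv[j] else NA_character_
    }, character(1))
    return(blank(vals))
  }
  # INFO key or flag
  kv <- strsplit(row[8], ";")[[1]]
  hit <- kv[kv == field | startsWith(kv, paste0(field, "="))]
  if (length(hit) == 0) return(NA_character_)
  if (!grepl("=", hit[1])) return("present")
  blank(strsplit(sub("^[^=]*=", "", hit[1]), ",")[[1]])
}

samples_format_keys <- function(row) {
  if (length(row) >= 9) strsplit(row[9], ":")[[1]] else character(0)
}

oracle_filter_field <- function(path, field, op, value,
                                keep_missing = FALSE) {
  p <- oracle_parse(path)
  schema <- oracle_csq_schema(p$meta)
  keep <- vapply(p$rows, function(row) {
    vals <- oracle_values(row, field, p$samples, schema)
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(keep_missing)
    switch(op,
           greater_than = any(suppressWarnings(as.numeric(vals)) >
                                as.numeric(value), na.rm = TRUE),
           less_than = any(suppressWarnings(as.numeric(vals)) <
                             as.numeric(value), na.rm = TRUE),
           equal_to = {
             nv <- suppressWarnings(as.numeric(vals))
             tv <- suppressWarnings(as.numeric(value))
             if (!is.na(tv) && any(!is.na(nv))) {
               any(nv == tv, na.rm = TRUE)
             } else {
               any(vals == as.character(value))
             }
           },
           contains_keyword = {
             kws <- tolower(trimws(strsplit(as.character(value), ",")[[1]]))
             any(vapply(kws, function(k) {
               any(grepl(k, tolower(vals), fixed = TRUE))
             }, logical(1)))
           })
  }, logical(1))
  which(keep) - 1L
}

oracle_gt_class <- function(g) {
  if (is.na(g)) return("MISSING")
  tk <- strsplit(g, "[/|]")[[1]]
  if (length(tk) == 0 || any(tk == ".")) return("MISSING")
  i <- as.integer(tk)
  if (all(i == 0)) "HOM_REF" else if (all(i == i[1])) "HOM_ALT" else "HET"
}

oracle_filter_genotype <- function(path, gt_class, scope,
                                   quantifier = "all") {
  p <- oracle_parse(path)
  keep <- vapply(p$rows, function(row) {
    fmt <- strsplit(row[9], ":")[[1]]
    j <- match("GT", fmt)
    hits <- vapply(scope, function(s) {
      k <- match(s, p$samples)
      sv <- strsplit(row[9 + k], ":")[[1]]
      g <- if (!is.na(j) && j <= length(sv)) sv[j] else NA_character_
      if (!is.na(g) && g %in% c(".", "")) g <- NA_character_
      oracle_gt_class(g) == gt_class
    }, logical(1))
    if (quantifier == "all") all(hits) else any(hits)
  }, logical(1))
  which(keep) - 1L
}

oracle_filter_region <- function(path, chrom, start, end) {
  p <- oracle_parse(path)
  keep <- vapply(p$rows, function(row) {
    row[1] == chrom && as.integer(row[2]) >= start &&
      as.integer(row[2]) <= end
  }, logical(1))
  which(keep) - 1L
}

oracle_variant_kind <- function(ref, alt) {
  if (grepl("[][<>]", alt) || alt %in% c(".", "*", "")) {
    return(NA_character_)
  }
  if (nchar(ref) != nchar(alt)) "INDEL"
  else if (nchar(ref) == 1) "SNP" else "MNP"
}

oracle_filter_type <- function(path, kind) {
  p <- oracle_parse(path)
  keep <- vapply(p$rows, function(row) {
    alts <- strsplit(row[5], ",")[[1]]
    any(vapply(alts, oracle_variant_kind, character(1),
               ref = row[4]) == kind, na.rm = TRUE)
  }, logical(1))
  which(keep) - 1L
}

oracle_filter_genes <- function(path, genes, field, mode = "positive") {
  p <- oracle_parse(path)
  schema <- oracle_csq_schema(p$meta)
  genes <- tolower(trimws(genes))
  assoc <- vapply(p$rows, function(row) {
    vals <- oracle_values(row, field, p$samples, schema)
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(FALSE)
    toks <- trimws(unlist(strsplit(tolower(vals), "[&,;]")))
    any(toks %in% genes)
  }, logical(1))
  if (mode == "positive") which(assoc) - 1L else which(!assoc) - 1L
}
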