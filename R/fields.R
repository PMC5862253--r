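# Field discovery: core columns, INFO/FORMAT keys (declared or merely
# observed in the body), and VEP CSQ sub-fields.

CORE_FIELDS <- data.frame(
  name = c("CHROM+POS", "ID", "REF+ALT", "QUAL", "FILTER"),
  origin = "CORE",
  value_type = c("STRING", "STRING", "STRING", "FLOAT", "STRING"),
  arity = "1",
  description = c("Chromosome and 1-based position",
                  "Variant identifier",
                  "Reference and alternate allele(s)",
                  "Phred-scaled quality score",
                  "Filter status"),
  stringsAsFactors = FALSE
)

#' Discover every filterable annotation field in a VCF
#'
#' Returns the union of the five core columns (`CHROM+POS`, `ID`, `REF+ALT`,
#' `QUAL`, `FILTER`), every INFO key and every FORMAT key — whether declared
#' in the header or merely used in the body (undeclared keys get type
#' `STRING`, arity `"."`) — and, when a VEP `CSQ` declaration is present, one
#' field per CSQ sub-field named `CSQ_<subfield>`. The raw `CSQ` key itself is
#' replaced by its sub-fields.
#'
#' @param x A path to a VCF file or a [read_vcf()] object.
#' @return A `data.frame` with columns `name`, `origin` (`CORE`, `INFO`,
#'   `FORMAT` or `CSQ`), `value_type` (`INTEGER`, `FLOAT`, `STRING`, `FLAG`,
#'   `CHAR`), `arity` (VCF `Number`: `"1"`, `"A"`, `"R"`, `"G"`, `"."`) and
#'   `description`.
#' @examples
#' p <- generate_vcf(fixture_spec(n_variants = 3, with_csq = TRUE, seed = 1),
#'                   file.path(tempdir(), "dis.vcf"))
#' discover_fields(p)$name
#' @export
discover_fields <- function(x) {
  vcf <- as_vcf(x)
  info_decl <- parse_header_decls(vcf$header, "INFO")
  fmt_decl <- parse_header_decls(vcf$header, "FORMAT")

  # keys observed in the body but undeclared in the header
  obs_info <- observed_info_keys(vcf$records$info)
  obs_fmt <- observed_format_keys(vcf$records$format)
  for (k in setdiff(obs_info, info_decl$name)) {
    info_decl <- rbind(info_decl, data.frame(
      name = k, origin = "INFO", value_type = "STRING", arity = ".",
      description = "(undeclared; observed in body)",
      stringsAsFactors = FALSE))
  }
  for (k in setdiff(obs_fmt, fmt_decl$name)) {
    fmt_decl <- rbind(fmt_decl, data.frame(
      name = k, origin = "FORMAT", value_type = "STRING", arity = ".",
      description = "(undeclared; observed in body)",
      stringsAsFactors = FALSE))
  }

  schema <- csq_schema(vcf$header)
  if (length(schema) > 0L) {
    info_decl <- info_decl[info_decl$name != "CSQ", , drop = FALSE]
    csq <- data.frame(
      name = paste0("CSQ_", schema), origin = "CSQ",
      value_type = "STRING", arity = ".",
      description = paste("VEP CSQ sub-field", schema),
      stringsAsFactors = FALSE)
    info_decl <- rbind(info_decl, csq)
  }
  out <- rbind(CORE_FIELDS, info_decl, fmt_decl)
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$name))
  out
}

as_vcf <- function(x) {
  if (inherits(x, "vcf")) x else read_vcf(x)
}

# ##INFO=<ID=...,Number=...,Type=...,Description="...">
parse_header_decls <- function(header, what) {
  pat <- paste0("^##", what, "=<")
  lines <- header[grepl(pat, header)]
  rows <- lapply(lines, function(ln) {
    body <- sub(">\\s*$", "", sub(pat, "", ln))
    id <- extract_attr(body, "ID")
    type <- extract_attr(body, "Type")
    num <- extract_attr(body, "Number")
    desc <- extract_attr(body, "Description")
    if (is.na(id)) return(NULL)
    vt <- switch(toupper(if (is.na(type)) "STRING" else type),
                 INTEGER = "INTEGER", FLOAT = "FLOAT", FLAG = "FLAG",
                 CHARACTER = "CHAR", "STRING")
    data.frame(name = id, origin = what, value_type = vt,
               arity = if (is.na(num)) "." else num,
               description = if (is.na(desc)) "" else desc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(name = character(0), origin = character(0),
                      value_type = character(0), arity = character(0),
                      description = character(0), stringsAsFactors = FALSE)
  }
  out[!duplicated(out$name), , drop = FALSE]
}

extract_attr <- function(body, key) {
  # Description is quoted and may contain commas; other attrs are bare
  m <- regmatches(body, regexec(paste0(key, '="([^"]*)"'), body))[[1L]]
  if (length(m) == 2L) return(m[2L])
  m <- regmatches(body, regexec(paste0("(?:^|,)", key, "=([^,>]*)"),
                                body))[[1L]]
  if (length(m) == 2L) m[2L] else NA_character_
}

observed_info_keys <- function(info) {
  if (length(info) == 0L) return(character(0))
  keys <- unlist(lapply(strsplit(info[info != "."], ";", fixed = TRUE),
                        function(kv) sub("=.*$", "", kv)))
  unique(keys[nzchar(keys) & keys != "."])
}

observed_format_keys <- function(format) {
  if (length(format) == 0L) return(character(0))
  unique(unlist(strsplit(format[format != "."], ":", fixed = TRUE)))
}

#' Extract the VEP CSQ sub-field schema from a VCF header
#'
#' The sub-field names are taken verbatim from the text after `Format: ` in
#' the `##INFO=<ID=CSQ,...>` declaration, in declaration order.
#'
#' @param header Character vector of `##` meta-lines (or a `vcf` object).
#' @return Character vector of sub-field names; empty when no CSQ
#'   declaration exists.
#' @export
csq_schema <- function(header) {
  if (inherits(header, "vcf")) header <- header$header
  ln <- header[grepl("^##INFO=<ID=CSQ[,>]", header)]
  if (length(ln) == 0L) return(character(0))
  desc <- extract_attr(sub(">\\s*$", "", sub("^##INFO=<", "", ln[1L])),
                       "Description")
  if (is.na(desc) || !grepl("Format: ", desc, fixed = TRUE)) {
    return(character(0))
  }
  spec <- sub("^.*Format: ", "", desc)
  strsplit(spec, "|", fixed = TRUE)[[1L]]
}

#' Expand a raw CSQ annotation string into per-transcript values
#'
#' A VEP `CSQ` value packs one `|`-separated block per transcript, blocks
#' separated by commas. Each block is split positionally against the header
#' schema; blocks with fewer sub-values than the schema are right-padded with
#' the missing marker, and empty sub-values normalize to missing (`"nan"`).
#'
#' @param csq_value Raw CSQ text (the value of the `CSQ` INFO key).
#' @param schema Character vector of sub-field names ([csq_schema()]).
#' @param record Optional label used in the error message for malformed CSQ.
#' @return A list with one named character vector per transcript block; names
#'   are `CSQ_<subfield>`.
#' @examples
#' expand_csq("A|missense_variant|BRCA2", c("Allele", "Consequence", "SYMBOL"))
#' @export
expand_csq <- function(csq_value, schema, record = NULL) {
  stopifnot(length(schema) > 0L)
  if (is.na(csq_value) || csq_value %in% c(".", "", "nan")) return(list())
  blocks <- strsplit(csq_value, ",", fixed = TRUE)[[1L]]
  lapply(blocks, function(b) {
    vals <- strsplit(b, "|", fixed = TRUE)[[1L]]
    if (b == "" || length(vals) == 0L) vals <- ""
    # a trailing empty sub-value is dropped by strsplit; pad back
    if (endsWith(b, "|")) vals <- c(vals, "")
    if (length(vals) > length(schema)) {
      stop("malformed CSQ annotation",
           if (!is.null(record)) paste0(" at ", record),
           ": ", length(vals), " sub-values but schema declares ",
           length(schema), call. = FALSE)
    }
    vals <- c(vals, rep("", length(schema) - length(vals)))
    vals[vals == "" | vals == "."] <- MISSING
    names(vals) <- paste0("CSQ_", schema)
    vals
  })
}

# canonical missing marker: every ".", empty string or absent value becomes
# the literal string "nan"
MISSING <- "nan"

normalize_value <- function(v) {
  v[is.na(v) | v == "." | v == ""] <- MISSING
  v
}

# normalize each comma-separated sub-value of a multi-valued cell
normalize_cell <- function(v) {
  vapply(strsplit(normalize_value(v), ",", fixed = TRUE), function(parts) {
    if (length(parts) == 0L) return(MISSING)
    paste(normalize_value(parts), collapse = ",")
  }, character(1L))
}

# split a normalized cell back into its individual values
cell_values <- function(cell) strsplit(cell, ",", fixed = TRUE)

cell_is_all_missing <- function(cell) {
  vapply(cell_values(cell), function(v) all(v == MISSING), logical(1L))
}
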