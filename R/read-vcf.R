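#' Read a VCF file into memory
#'
#' Parses a VCF 4.x file — plain or gzip-compressed (detected from the file's
#' magic bytes, not its name) — into a `vcf` object holding the header
#' meta-lines and one row per data line. Every data line receives a `rank`,
#' its 0-based ordinal in the file, so that lines sharing the same
#' `(CHROM, POS)` remain distinct: `(chrom, pos, rank)` is the unique variant
#' key used throughout the package.
#'
#' All values are kept as the raw text printed in the file; normalization of
#' missing values and CSQ expansion happen later, in [preprocess_vcf()].
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return An object of class `vcf`: a list with elements
#'   \describe{
#'     \item{`path`}{the source path,}
#'     \item{`header`}{character vector of `##` meta-lines,}
#'     \item{`samples`}{character vector of sample names (may be empty),}
#'     \item{`n`}{number of data lines,}
#'     \item{`records`}{a `data.frame` with columns `chrom`, `pos` (integer),
#'       `rank` (integer, 0-based), `id`, `ref`, `alt`, `qual`, `filter`,
#'       `info`, `format`, and one raw-text column per sample.}
#'   }
#' @examples
#' vcf <- read_vcf(generate_vcf(fixture_spec(n_variants = 5, seed = 1),
#'                              file.path(tempdir(), "ex.vcf")))
#' vcf$n
#' head(vcf$records)
#' @seealso [discover_fields()], [preprocess_vcf()]
#' @export
read_vcf <- function(path) {
  lines <- read_vcf_lines(path)
  hdr_mask <- startsWith(lines, "##")
  # meta-lines must be a prefix of the file
  header <- lines[hdr_mask & cumsum(!hdr_mask) == 0L]
  if (length(header) == 0L || !startsWith(header[1L], "##fileformat=")) {
    stop("not a VCF file (no '##fileformat=' line): ", path, call. = FALSE)
  }
  rest <- lines[seq_along(lines) > length(header)]
  if (length(rest) == 0L || !startsWith(rest[1L], "#CHROM")) {
    stop("malformed VCF: no '#CHROM' column header line in ", path,
         call. = FALSE)
  }
  columns <- strsplit(sub("^#", "", rest[1L]), "\t", fixed = TRUE)[[1L]]
  samples <- if (length(columns) > 9L) columns[-(1:9)] else character(0)
  body <- rest[-1L]
  body <- body[nzchar(body)]

  ncol_expected <- max(8L, length(columns))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 8L)) {
    bad <- which(nf < 8L)[1L]
    stop("malformed VCF record at line ", length(header) + 1L + bad,
         ": fewer than 8 tab-separated columns", call. = FALSE)
  }
  if (any(nf > ncol_expected)) {
    bad <- which(nf > ncol_expected)[1L]
    stop("malformed VCF record at line ", length(header) + 1L + bad,
         ": more columns than declared in the #CHROM line", call. = FALSE)
  }
  n <- length(body)
  recs <- if (n == 0L) {
    empty_records(samples)
  } else {
    # pad short lines (trailing columns dropped by upstream tools) with "."
    mat <- matrix(".", nrow = n, ncol = ncol_expected)
    for (i in seq_len(n)) mat[i, seq_len(nf[i])] <- parts[[i]]
    pos <- suppressWarnings(as.integer(mat[, 2L]))
    if (anyNA(pos)) {
      bad <- which(is.na(pos))[1L]
      stop("malformed VCF record at line ", length(header) + 1L + bad,
           ": POS is not an integer", call. = FALSE)
    }
    df <- data.frame(
      chrom = mat[, 1L], pos = pos, rank = seq_len(n) - 1L,
      id = mat[, 3L], ref = mat[, 4L], alt = mat[, 5L],
      qual = mat[, 6L], filter = mat[, 7L], info = mat[, 8L],
      format = if (ncol_expected >= 9L) mat[, 9L] else ".",
      stringsAsFactors = FALSE, check.names = FALSE
    )
    for (j in seq_along(samples)) df[[samples[j]]] <- mat[, 9L + j]
    df
  }
  structure(
    list(path = path, header = header, samples = samples,
         n = nrow(recs), records = recs),
    class = "vcf"
  )
}

empty_records <- function(samples) {
  df <- data.frame(
    chrom = character(0), pos = integer(0), rank = integer(0),
    id = character(0), ref = character(0), alt = character(0),
    qual = character(0), filter = character(0), info = character(0),
    format = character(0), stringsAsFactors = FALSE, check.names = FALSE
  )
  for (s in samples) df[[s]] <- character(0)
  df
}

# Read all lines, transparently decompressing gzip input. Compression is
# recognized from the two magic bytes 0x1f 0x8b, never from the file name.
read_vcf_lines <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read VCF: file not found: ", path, call. = FALSE)
  }
  magic <- readBin(path, "raw", n = 2L)
  con <- if (length(magic) == 2L && magic[1L] == as.raw(0x1f) &&
             magic[2L] == as.raw(0x8b)) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' @export
print.vcf <- function(x, ...) {
  cat("VCF file:", x$path, "\n")
  cat("  header meta-lines:", length(x$header), "\n")
  cat("  data lines:", x$n, "\n")
  cat("  samples:",
      if (length(x$samples)) paste(x$samples, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Parse a GT genotype string
#'
#' Splits a VCF `GT` value of arbitrary ploidy on both the unphased (`/`) and
#' phased (`|`) separators. Missing allele markers (`.`) are preserved as
#' `NA` indices. Works for haploid, diploid and polyploid calls alike.
#'
#' @param gt_text A GT-syntax string, e.g. `"0/1"`, `"1|1"`, `"2"`, `"./."`.
#' @return An object of class `genotype_call`: list with `allele_indices`
#'   (integer vector, `NA` for missing), `phased` (logical) and `raw`.
#' @examples
#' parse_genotype("0/1")$allele_indices
#' parse_genotype("1|1")$phased
#' parse_genotype("2")$allele_indices   # haploid
#' @seealso [classify_genotype()]
#' @export
parse_genotype <- function(gt_text) {
  if (!is.character(gt_text) || length(gt_text) != 1L || !nzchar(gt_text)) {
    stop("invalid GT value: expected a non-empty genotype string",
         call. = FALSE)
  }
  tokens <- strsplit(gt_text, "[/|]")[[1L]]
  if (length(tokens) == 0L || !all(grepl("^([0-9]+|\\.)$", tokens))) {
    stop("invalid GT value: ", sQuote(gt_text), call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(tokens))
  structure(
    list(allele_indices = idx,
         phased = grepl("|", gt_text, fixed = TRUE),
         raw = gt_text),
    class = "genotype_call"
  )
}

#' @export
print.genotype_call <- function(x, ...) {
  cat("genotype", sQuote(x$raw), "->",
      paste(ifelse(is.na(x$allele_indices), ".", x$allele_indices),
            collapse = if (x$phased) "|" else "/"),
      sprintf("[%s, %s]", classify_genotype(x),
              if (x$phased) "phased" else "unphased"), "\n")
  invisible(x)
}
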