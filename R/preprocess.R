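# Step 1: single-pass pre-processing of a VCF into a columnar working table.
#
# The table holds the key columns (chrom, pos, rank, ref, alts) plus one
# normalized column per selected field (FORMAT fields get one column per
# sample). Missing values are canonicalized to the string "nan"; multi-valued
# cells (arity A/R/G/"." and per-transcript CSQ values) keep all values,
# comma-joined. The table and a JSON manifest persist under a working
# directory that all later steps (indexing, filtering, history) read.

KEY_COLUMNS <- c("chrom", "pos", "rank", "ref", "alts")

#' Pre-process a VCF file into a working directory
#'
#' Reads the file once, normalizes the selected fields (missing values
#' `"."`/empty become `"nan"`, flags become `"present"`/missing, CSQ
#' sub-fields are expanded per transcript) and persists the resulting table
#' plus a manifest under `workdir`. Key columns (chromosome, position, rank,
#' REF, ALT) are always included. Further fields can be added later with
#' [add_field()] without redoing this step.
#'
#' @param path Path to the VCF file (plain or gzip).
#' @param fields Character vector of field names to extract, from
#'   [discover_fields()]. May be empty: the table then holds key columns only.
#' @param workdir Directory to create/use for the persisted table, manifest,
#'   indexes and filter history.
#' @return A `vcf_workdir` handle (invisibly usable by all later steps).
#' @examples
#' p <- generate_vcf(fixture_spec(n_variants = 5, seed = 1),
#'                   file.path(tempdir(), "pp.vcf"))
#' wd <- preprocess_vcf(p, fields = c("QUAL", "FILTER"),
#'                      workdir = file.path(tempdir(), "pp_wd"))
#' wd
#' @export
preprocess_vcf <- function(path, fields = character(0), workdir) {
  vcf <- read_vcf(path)
  descs <- discover_fields(vcf)
  unknown <- setdiff(fields, descs$name)
  if (length(unknown) > 0L) {
    stop("unknown field(s): ", paste(unknown, collapse = ", "),
         "; valid fields are: ", paste(descs$name, collapse = ", "),
         call. = FALSE)
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(workdir, "indexes"), showWarnings = FALSE)

  table <- key_table(vcf)
  field_meta <- list()
  for (f in fields) {
    cols <- extract_field_columns(vcf, descs[descs$name == f, ])
    for (nm in names(cols)) table[[nm]] <- cols[[nm]]
    field_meta[[f]] <- field_manifest_entry(descs[descs$name == f, ],
                                            names(cols))
  }
  write_work_table(table, workdir)
  manifest <- list(
    source = normalizePath(path),
    n = vcf$n,
    samples = as.list(vcf$samples),
    csq_schema = as.list(csq_schema(vcf$header)),
    fields = field_meta,
    built = list()
  )
  write_manifest(manifest, workdir)
  hist_path <- file.path(workdir, "history.json")
  if (!file.exists(hist_path)) {
    write_history(list(base_count = vcf$n, steps = list()), workdir)
  }
  invisible(open_workdir(workdir))
}

key_table <- function(vcf) {
  r <- vcf$records
  data.frame(chrom = r$chrom, pos = r$pos, rank = r$rank,
             ref = r$ref, alts = r$alt,
             stringsAsFactors = FALSE, check.names = FALSE)
}

field_manifest_entry <- function(desc, columns) {
  list(name = desc$name, origin = desc$origin,
       value_type = desc$value_type, arity = desc$arity,
       columns = as.list(columns))
}

# Returns a named list of character columns for one field descriptor.
# FORMAT fields yield one column per sample, named "<field>.<sample>".
extract_field_columns <- function(vcf, desc) {
  r <- vcf$records
  name <- desc$name
  out <- switch(
    desc$origin,
    CORE = {
      col <- switch(name,
                    "CHROM+POS" = paste0(r$chrom, ":", r$pos),
                    "ID" = r$id,
                    "REF+ALT" = paste0(r$ref, ">", r$alt),
                    "QUAL" = r$qual,
                    "FILTER" = r$filter,
                    stop("unknown core field: ", name))
      stats::setNames(list(normalize_cell(col)), name)
    },
    INFO = {
      vals <- info_values(r$info, name, flag = desc$value_type == "FLAG")
      stats::setNames(list(normalize_cell(vals)), name)
    },
    FORMAT = {
      cols <- lapply(vcf$samples, function(s) {
        normalize_cell(format_values(r$format, r[[s]], name))
      })
      if (length(cols) == 0L) {
        stop("cannot extract FORMAT field ", sQuote(name),
             ": the file has no sample columns", call. = FALSE)
      }
      stats::setNames(cols, paste0(name, ".", vcf$samples))
    },
    CSQ = {
      schema <- csq_schema(vcf$header)
      raw <- info_values(r$info, "CSQ", flag = FALSE)
      col <- vapply(seq_along(raw), function(i) {
        maps <- expand_csq(raw[i], schema,
                           record = paste0(r$chrom[i], ":", r$pos[i]))
        if (length(maps) == 0L) return(MISSING)
        paste(vapply(maps, `[[`, character(1L), name), collapse = ",")
      }, character(1L))
      if (length(raw) == 0L) col <- character(0)
      stats::setNames(list(col), name)
    },
    stop("unknown field origin: ", desc$origin)
  )
  out
}

# Extract one INFO key's raw value per record ("nan" when absent); flags
# yield "present" when set, missing otherwise.
info_values <- function(info, key, flag = FALSE) {
  vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
    hit <- kv[kv == key | startsWith(kv, paste0(key, "="))]
    if (length(hit) == 0L) return(MISSING)
    if (flag || !grepl("=", hit[1L], fixed = TRUE)) return("present")
    sub("^[^=]*=", "", hit[1L])
  }, character(1L))
}

format_values <- function(format, sample_col, key) {
  fk <- strsplit(format, ":", fixed = TRUE)
  sv <- strsplit(sample_col, ":", fixed = TRUE)
  vapply(seq_along(fk), function(i) {
    j <- match(key, fk[[i]])
    if (is.na(j) || j > length(sv[[i]])) MISSING else sv[[i]][j]
  }, character(1L))
}

write_work_table <- function(table, workdir) {
  utils::write.table(table, file.path(workdir, "table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = MISSING)
}

read_work_table <- function(workdir) {
  path <- file.path(workdir, "table.tsv")
  if (!file.exists(path)) {
    stop("no pre-processed table under ", workdir,
         "; run preprocess_vcf() (step 1) first", call. = FALSE)
  }
  tb <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  tb$pos <- as.integer(tb$pos)
  tb$rank <- as.integer(tb$rank)
  tb
}
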