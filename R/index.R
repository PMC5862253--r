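# Step 2: one compact, queryable index per selected field, persisted as a
# sorted value->rank association under workdir/indexes/. Multi-valued cells
# contribute one entry per value; a variant sits in the missing set iff ALL
# its values are missing. Numeric fields are indexed as doubles so
# integer-typed values compare numerically ("30" matches 30.0).

#' Build the index for one selected field
#'
#' Tabulates every value of `field` across the pre-processed table into a
#' sorted value-to-variant association persisted under the workdir. For a
#' FORMAT field the values of all samples are pooled. Rebuilding an existing
#' index replaces it idempotently. With `cores > 1` rows are tabulated in
#' parallel chunks; the resulting artifact is identical to a single-core
#' build — parallelism is an implementation detail, determinism is the
#' contract.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param field A field name present in the workdir manifest (i.e. selected
#'   at [preprocess_vcf()] time or added with [add_field()]).
#' @param cores Number of worker processes for the tabulation (>= 1).
#' @return The `field_index`, invisibly.
#' @examples
#' p <- generate_vcf(fixture_spec(n_variants = 5, seed = 1),
#'                   file.path(tempdir(), "bi.vcf"))
#' wd <- preprocess_vcf(p, "QUAL", file.path(tempdir(), "bi_wd"))
#' build_index(wd, "QUAL")
#' @export
build_index <- function(wd, field, cores = 1L) {
  meta <- wd_field_meta(wd, field)
  if (is.null(meta)) {
    stop("field ", sQuote(field), " is not in the pre-processed table; ",
         "selected fields are: ",
         paste(wd_fields(wd), collapse = ", "),
         ". Use add_field() to extract it first.", call. = FALSE)
  }
  tb <- wd_table(wd)
  cols <- unlist(meta$columns)
  idx <- tabulate_index(tb, cols, field,
                        numeric = meta$value_type %in% c("INTEGER", "FLOAT") ||
                          field == "QUAL",
                        cores = cores)
  write_index(idx, wd)
  manifest <- read_manifest(wd)
  manifest$built[[field]] <- index_filename(field)
  write_manifest(manifest, wd)
  invisible(idx)
}

tabulate_index <- function(tb, cols, field, numeric, cores = 1L) {
  n <- nrow(tb)
  rows <- seq_len(n)
  chunks <- if (cores > 1L && n > 1L) {
    split(rows, cut(rows, breaks = min(cores, n), labels = FALSE))
  } else {
    list(rows)
  }
  tab_chunk <- function(rr) {
    vals <- vector("list", length(cols))
    for (k in seq_along(cols)) vals[[k]] <- cell_values(tb[[cols[k]]][rr])
    pairs_v <- list(); pairs_r <- list(); miss <- list()
    for (i in seq_along(rr)) {
      v <- unique(unlist(lapply(vals, `[[`, i)))
      v <- v[v != MISSING]
      if (length(v) == 0L) {
        miss[[length(miss) + 1L]] <- tb$rank[rr[i]]
      } else {
        pairs_v[[length(pairs_v) + 1L]] <- v
        pairs_r[[length(pairs_r) + 1L]] <- rep(tb$rank[rr[i]], length(v))
      }
    }
    list(values = unlist(pairs_v) %||% character(0),
         ranks = as.integer(unlist(pairs_r) %||% integer(0)),
         missing = as.integer(unlist(miss) %||% integer(0)))
  }
  parts <- if (length(chunks) > 1L && .Platform$OS.type != "windows") {
    parallel::mclapply(chunks, tab_chunk, mc.cores = length(chunks))
  } else {
    lapply(chunks, tab_chunk)
  }
  values <- unlist(lapply(parts, `[[`, "values")) %||% character(0)
  ranks <- as.integer(unlist(lapply(parts, `[[`, "ranks")) %||% integer(0))
  missing <- as.integer(unlist(lapply(parts, `[[`, "missing")) %||%
                          integer(0))
  # canonical order: numeric or C-locale lexicographic by value, then rank —
  # identical regardless of chunking
  ord <- if (numeric) {
    order(suppressWarnings(as.numeric(values)), ranks,
          method = "radix", na.last = TRUE)
  } else {
    order(values, ranks, method = "radix")
  }
  structure(
    list(field = field, numeric = numeric,
         values = values[ord], ranks = ranks[ord],
         missing = sort(missing)),
    class = "field_index"
  )
}

index_filename <- function(field) {
  paste0(gsub("[^A-Za-z0-9._-]", "_", field), ".idx.tsv")
}

write_index <- function(idx, wd) {
  path <- file.path(wd_dir(wd), "indexes", index_filename(idx$field))
  dir.create(dirname(path), showWarnings = FALSE)
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wt")
  writeLines(c(paste0("#field\t", idx$field),
               paste0("#numeric\t", as.integer(idx$numeric))), con)
  # missing variants are stored under the canonical missing marker, which by
  # construction never occurs as a real value
  if (length(idx$values) > 0L || length(idx$missing) > 0L) {
    writeLines(c(paste0(idx$values, "\t", idx$ranks),
                 if (length(idx$missing)) {
                   paste0(MISSING, "\t", idx$missing)
                 }), con)
  }
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Load a previously built field index
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param field Field name.
#' @return A `field_index` object.
#' @export
load_index <- function(wd, field) {
  manifest <- read_manifest(wd)
  if (is.null(manifest$built[[field]])) {
    stop("no index built for field ", sQuote(field),
         "; run build_index() (step 2) for it first", call. = FALSE)
  }
  path <- file.path(wd_dir(wd), "indexes", manifest$built[[field]])
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  numeric <- sub("^#numeric\t", "", hdr[startsWith(hdr, "#numeric")]) == "1"
  if (length(body) == 0L) {
    return(structure(list(field = field, numeric = numeric,
                          values = character(0), ranks = integer(0),
                          missing = integer(0)),
                     class = "field_index"))
  }
  tabpos <- regexpr("\t", body, fixed = TRUE)
  values <- substr(body, 1L, tabpos - 1L)
  ranks <- as.integer(substring(body, tabpos + 1L))
  miss <- values == MISSING
  structure(
    list(field = field, numeric = numeric,
         values = values[!miss], ranks = ranks[!miss],
         missing = sort(ranks[miss])),
    class = "field_index"
  )
}

#' @export
print.field_index <- function(x, ...) {
  cat("index on field", sQuote(x$field),
      if (x$numeric) "(numeric)" else "(text)", "\n")
  cat("  distinct values:", length(unique(x$values)),
      "| entries:", length(x$values),
      "| variants with only missing values:", length(x$missing), "\n")
  invisible(x)
}

#' Add a field to an existing workdir
#'
#' Re-passes the source VCF once to extract and normalize one more field,
#' appends it to the persisted table, then builds its index. Previously built
#' indexes are untouched; adding an already-present field is a no-op.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param field A field name discoverable in the source VCF.
#' @param cores Passed to [build_index()].
#' @return The workdir handle, invisibly.
#' @export
add_field <- function(wd, field, cores = 1L) {
  wd <- open_workdir(wd)
  manifest <- read_manifest(wd)
  if (field %in% wd_fields(wd)) {
    if (is.null(manifest$built[[field]])) build_index(wd, field, cores)
    return(invisible(wd))
  }
  vcf <- read_vcf(manifest$source)
  descs <- discover_fields(vcf)
  if (!field %in% descs$name) {
    stop("unknown field ", sQuote(field), "; valid fields are: ",
         paste(descs$name, collapse = ", "), call. = FALSE)
  }
  cols <- extract_field_columns(vcf, descs[descs$name == field, ])
  tb <- wd_table(wd)
  for (nm in names(cols)) tb[[nm]] <- cols[[nm]]
  write_work_table(tb, wd_dir(wd))
  manifest$fields[[field]] <-
    field_manifest_entry(descs[descs$name == field, ], names(cols))
  write_manifest(manifest, wd)
  build_index(wd, field, cores)
  invisible(wd)
}

# index-backed answer sets -----------------------------------------------

index_matches <- function(idx, op, value) {
  if (length(idx$values) == 0L) return(integer(0))
  sel <- switch(
    op,
    greater_than = suppressWarnings(as.numeric(idx$values)) >
      as.numeric(value),
    less_than = suppressWarnings(as.numeric(idx$values)) <
      as.numeric(value),
    equal_to = if (idx$numeric) {
      !is.na(suppressWarnings(as.numeric(idx$values))) &
        suppressWarnings(as.numeric(idx$values)) == as.numeric(value)
    } else {
      idx$values == as.character(value)
    },
    contains_keyword = {
      kws <- keyword_list(value)
      lv <- tolower(idx$values)
      Reduce(`|`, lapply(kws, function(k) grepl(k, lv, fixed = TRUE)),
             accumulate = FALSE, init = rep(FALSE, length(lv)))
    },
    stop("unknown operator: ", op)
  )
  sel[is.na(sel)] <- FALSE
  sort(unique(idx$ranks[sel]))
}

keyword_list <- function(value) {
  kws <- trimws(strsplit(as.character(value), ",", fixed = TRUE)[[1L]])
  kws <- tolower(kws[nzchar(kws)])
  if (length(kws) == 0L) {
    stop("contains_keyword requires at least one non-empty keyword",
         call. = FALSE)
  }
  kws
}

# gene-list association: case-insensitive exact token match, values split at
# "&", "," and ";" so compound annotations match but BRCA1 never matches
# BRCA1P1
index_gene_matches <- function(idx, genes) {
  if (length(idx$values) == 0L) return(integer(0))
  genes <- tolower(trimws(genes))
  toks <- strsplit(tolower(idx$values), "[&,;]")
  hit <- vapply(toks, function(tk) any(trimws(tk) %in% genes), logical(1L))
  sort(unique(idx$ranks[hit]))
}
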