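# The working directory is the unit of state: manifest.json (source path,
# selected fields, row count, CSQ schema, built indexes), table.tsv (the
# pre-processed table), indexes/ (one file per indexed field) and
# history.json (the filter ledger). Every function in steps 2-3 and the CLI
# takes a workdir (path or handle); nothing is kept in the R session, so any
# sequence of calls — or of CLI invocations — over the same workdir is
# equivalent.

#' Open an existing working directory
#'
#' @param workdir Path previously populated by [preprocess_vcf()].
#' @return A `vcf_workdir` handle: an environment caching the manifest and
#'   table; all step-2/step-3 functions accept either the handle or the path.
#' @export
open_workdir <- function(workdir) {
  if (inherits(workdir, "vcf_workdir")) return(workdir)
  if (!dir.exists(workdir) ||
      !file.exists(file.path(workdir, "manifest.json"))) {
    stop("not a vcfsift working directory (no manifest.json): ", workdir,
         "; run preprocess_vcf() (step 1) first", call. = FALSE)
  }
  wd <- new.env(parent = emptyenv())
  wd$dir <- workdir
  class(wd) <- "vcf_workdir"
  wd
}

wd_dir <- function(wd) if (inherits(wd, "vcf_workdir")) wd$dir else wd

read_manifest <- function(wd) {
  jsonlite::read_json(file.path(wd_dir(wd), "manifest.json"),
                      simplifyVector = FALSE)
}

write_manifest <- function(manifest, workdir) {
  # atomic replace so a failed build never corrupts the manifest
  path <- file.path(wd_dir(workdir), "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  file.rename(tmp, path)
}

wd_table <- function(wd) {
  if (inherits(wd, "vcf_workdir")) {
    tpath <- file.path(wd$dir, "table.tsv")
    mt <- file.mtime(tpath)
    if (is.null(wd$table) || !identical(wd$table_mtime, mt)) {
      wd$table <- read_work_table(wd$dir)
      wd$table_mtime <- mt
    }
    wd$table
  } else {
    read_work_table(wd)
  }
}

wd_fields <- function(wd) {
  vapply(read_manifest(wd)$fields, `[[`, character(1L), "name")
}

wd_samples <- function(wd) {
  unlist(read_manifest(wd)$samples) %||% character(0)
}

wd_field_meta <- function(wd, field) {
  m <- read_manifest(wd)
  for (f in m$fields) if (f$name == field) return(f)
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vcf_workdir <- function(x, ...) {
  m <- read_manifest(x)
  cat("vcfsift working directory:", x$dir, "\n")
  cat("  source VCF:", m$source, "\n")
  cat("  variants:", m$n, "\n")
  cat("  samples:", if (length(m$samples)) {
    paste(unlist(m$samples), collapse = ", ")
  } else "(none)", "\n")
  cat("  selected fields:", if (length(m$fields)) {
    paste(names(m$fields), collapse = ", ")
  } else "(none)", "\n")
  cat("  indexed:", if (length(m$built)) {
    paste(names(m$built), collapse = ", ")
  } else "(none)", "\n")
  h <- read_history(x)
  cat("  filter steps applied:", length(h$steps), "\n")
  invisible(x)
}

# ---- working sets -----------------------------------------------------------

#' The working set of all variants in a workdir
#'
#' A working set is the ordered (file-order) set of variant keys currently
#' surviving the filter chain; each key is identified by its rank, the
#' 0-based ordinal of the data line in the source file.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @return A `working_set` object with elements `ranks` (sorted integer
#'   vector), `count` and `origin`.
#' @export
all_variants <- function(wd) {
  tb <- wd_table(wd)
  working_set(tb$rank, origin = "all variants")
}

working_set <- function(ranks, origin = "all variants") {
  ranks <- sort(unique(as.integer(ranks)))
  structure(list(ranks = ranks, count = length(ranks), origin = origin),
            class = "working_set")
}

as_working_set <- function(x) {
  if (inherits(x, "working_set")) return(x)
  working_set(x)
}

#' @export
print.working_set <- function(x, ...) {
  cat("working set of", x$count, "variants (origin:",
      if (is.character(x$origin)) x$origin else "filter step", ")\n")
  invisible(x)
}

#' @export
length.working_set <- function(x) x$count

#' Look up the table rows of a working set
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param ws A `working_set` (default: all variants).
#' @return The pre-processed table restricted to `ws`, in file order.
#' @export
variant_table <- function(wd, ws = NULL) {
  tb <- wd_table(wd)
  if (is.null(ws)) return(tb)
  ws <- as_working_set(ws)
  out <- tb[match(ws$ranks, tb$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
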