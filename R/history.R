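# Filter history: a ledger with one entry per applied filter (type,
# parameters, input -> output counts, timestamp) plus the persisted output
# key set of every step, kept as machine-replayable JSON beside the manifest
# and rendered to a human-readable plain-text report on export.

read_history <- function(wd) {
  path <- file.path(wd_dir(wd), "history.json")
  if (!file.exists(path)) {
    stop("no filter history under ", wd_dir(wd),
         "; run preprocess_vcf() first", call. = FALSE)
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}

write_history <- function(history, wd) {
  path <- file.path(wd_dir(wd), "history.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(history, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  file.rename(tmp, path)
}

step_keys_file <- function(wd, ordinal) {
  file.path(wd_dir(wd), "history", sprintf("step_%04d.keys", ordinal))
}

#' The current working set of a workdir
#'
#' The output of the last recorded filter step, or all variants when no
#' filter has been applied yet.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @return A `working_set`.
#' @export
current_variants <- function(wd) {
  h <- read_history(wd)
  n <- length(h$steps)
  if (n == 0L) return(all_variants(wd))
  ranks <- as.integer(readLines(step_keys_file(wd, n), warn = FALSE))
  working_set(ranks, origin = paste0("step ", n))
}

#' Record an applied filter step
#'
#' Appends one entry to the filter history and persists the step's output
#' key set to disk. The step's input count must equal the previous step's
#' output count (or the base count for the first step) — a mismatch signals
#' that the engine and the history have come apart and raises an error.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param spec The `filter_spec` applied.
#' @param input_count Variant count the filter consumed.
#' @param ws_out The output `working_set`.
#' @return The updated history, invisibly.
#' @export
record_step <- function(wd, spec, input_count, ws_out) {
  h <- read_history(wd)
  expected <- if (length(h$steps) == 0L) {
    h$base_count
  } else {
    h$steps[[length(h$steps)]]$output_count
  }
  if (input_count != expected) {
    stop("history inconsistency: step input count (", input_count,
         ") does not match the current working-set count (", expected, ")",
         call. = FALSE)
  }
  ws_out <- as_working_set(ws_out)
  ordinal <- length(h$steps) + 1L
  dir.create(file.path(wd_dir(wd), "history"), showWarnings = FALSE)
  writeLines(as.character(ws_out$ranks), step_keys_file(wd, ordinal))
  h$steps[[ordinal]] <- list(
    ordinal = ordinal,
    filter_type = spec$type,
    parameters = unclass(spec)[setdiff(names(spec), "type")],
    input_count = input_count,
    output_count = ws_out$count,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    output_ref = basename(step_keys_file(wd, ordinal))
  )
  write_history(h, wd)
  invisible(h)
}

#' Summarize the filter history
#'
#' @param wd A `vcf_workdir` handle or path.
#' @return A `data.frame` with one row per applied step: `ordinal`,
#'   `filter_type`, `parameters` (compact JSON), `input_count`,
#'   `output_count`, `timestamp`; the base variant count is attached as
#'   attribute `"base_count"`.
#' @export
filter_history <- function(wd) {
  h <- read_history(wd)
  df <- if (length(h$steps) == 0L) {
    data.frame(ordinal = integer(0), filter_type = character(0),
               parameters = character(0), input_count = integer(0),
               output_count = integer(0), timestamp = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(h$steps, function(s) {
      data.frame(ordinal = s$ordinal, filter_type = s$filter_type,
                 parameters = as.character(
                   jsonlite::toJSON(s$parameters, auto_unbox = TRUE)),
                 input_count = s$input_count,
                 output_count = s$output_count,
                 timestamp = s$timestamp, stringsAsFactors = FALSE)
    }))
  }
  attr(df, "base_count") <- h$base_count
  df
}

#' Delete a filter step and all later steps
#'
#' Each step's output depends on its predecessors, so deletion truncates:
#' steps `ordinal..n` are removed together with their persisted key sets and
#' the working set reverts to step `ordinal - 1`'s output (or to the full
#' variant set).
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param ordinal Step number to delete from (1-based).
#' @return The reverted `working_set`, invisibly.
#' @export
delete_steps <- function(wd, ordinal) {
  h <- read_history(wd)
  n <- length(h$steps)
  if (!is.numeric(ordinal) || length(ordinal) != 1L || is.na(ordinal) ||
      ordinal < 1L || ordinal > n) {
    stop("step ordinal out of range: ", ordinal, " (history has ", n,
         " step", if (n != 1L) "s", ")", call. = FALSE)
  }
  for (k in seq(from = ordinal, to = n)) {
    unlink(step_keys_file(wd, k))
  }
  h$steps <- h$steps[seq_len(ordinal - 1L)]
  write_history(h, wd)
  invisible(current_variants(wd))
}

#' Export the filter history as a plain-text report
#'
#' Writes a human-readable record of the whole session for posterity and
#' reproducibility: source file, selected fields, base variant count, then
#' one tab-separated line per step with its ordinal, type, exact parameters
#' (compact JSON, machine re-parseable), input/output counts and timestamp.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_history <- function(wd, path) {
  m <- read_manifest(wd)
  h <- read_history(wd)
  lines <- c(
    "vcfsift filter history",
    paste0("source:\t", m$source),
    paste0("selected fields:\t", paste(names(m$fields), collapse = ", ")),
    paste0("base variants:\t", h$base_count),
    ""
  )
  for (s in h$steps) {
    lines <- c(lines, paste(
      paste0("#", s$ordinal), s$filter_type,
      jsonlite::toJSON(s$parameters, auto_unbox = TRUE),
      paste0("in=", s$input_count), paste0("out=", s$output_count),
      s$timestamp,
      sep = "\t"))
  }
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write history report to ", path, call. = FALSE)
  invisible(path)
}

#' Export the current variants as a tab-separated file
#'
#' Writes a spreadsheet-compatible TSV: a header row with the table's column
#' names (key columns plus the selected fields), then one row per surviving
#' variant in file order. Missing values are rendered as `"nan"`; any tab or
#' newline inside a cell is replaced by a space so every row has the same
#' column count.
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param path Output file path.
#' @param ws A `working_set` (default: the current set, see
#'   [current_variants()]).
#' @return `path`, invisibly.
#' @export
export_tsv <- function(wd, path, ws = NULL) {
  if (is.null(ws)) ws <- current_variants(wd)
  tb <- variant_table(wd, ws)
  for (j in seq_along(tb)) {
    if (is.character(tb[[j]])) {
      tb[[j]] <- gsub("[\t\r\n]", " ", tb[[j]])
    }
  }
  ok <- tryCatch({
    utils::write.table(tb, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = MISSING,
                       eol = "\n", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write TSV to ", path, call. = FALSE)
  invisible(path)
}

#' Preview the top variants of the current working set
#'
#' @param wd A `vcf_workdir` handle or path.
#' @param n Maximum number of rows (default 100, the classic top-100 panel).
#' @param ws A `working_set` (default: the current set).
#' @return The first `min(n, count)` rows of the variant table, file order.
#' @export
preview <- function(wd, n = 100L, ws = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  if (is.null(ws)) ws <- current_variants(wd)
  tb <- variant_table(wd, ws)
  utils::head(tb, n)
}

#' Re-parse an exported history report
#'
#' Reconstructs the step specifications from a report written by
#' [export_history()], so a session can be replayed: the returned list of
#' `filter_spec` objects can be fed straight to [apply_chain()].
#'
#' @param path Path to a report file.
#' @return List with `base_count` and `steps` (list of `filter_spec`).
#' @export
parse_history_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  base <- as.integer(sub("^base variants:\t", "",
                         lines[startsWith(lines, "base variants:")]))
  step_lines <- lines[startsWith(lines, "#")]
  steps <- lapply(step_lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    params <- jsonlite::fromJSON(parts[3L], simplifyVector = TRUE)
    do.call(filter_spec, c(list(type = parts[2L]), params))
  })
  list(base_count = base, steps = steps)
}
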