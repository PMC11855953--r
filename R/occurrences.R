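#' Assemble a validated occurrence dataset
#'
#' Builds the long-format presence dataset that every analysis in the package
#' consumes: one row per (epiphyte taxon, host taxon, grid cell, geographic
#' area) presence. Labels are trimmed and internal whitespace collapsed, rows
#' duplicated at the (epiphyte, host, cell) level are dropped (records assert
#' presence only, so repeats carry no information), and each cell must belong
#' to exactly one geographic area.
#'
#' @param records data frame with columns `lichen_taxon`, `host_taxon`,
#'   `cell_id`, `area_id` (character).
#' @return An object of class `occurrence_dataset`: a list with `records`
#'   (the deduplicated data frame), `cell_to_area` (named character vector),
#'   `n_raw` and `duplicates_dropped`.
#' @export
occurrence_dataset <- function(records) {
  required <- c("lichen_taxon", "host_taxon", "cell_id", "area_id")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop_hostpref("missing required column(s): ",
                  paste(missing_cols, collapse = ", "),
                  class = "hostpref_format_error")
  }
  records <- as.data.frame(records)[required]
  for (col in required) records[[col]] <- normalize_label(records[[col]])

  empties <- which(Reduce(`|`, lapply(records, function(x) is.na(x) | x == "")))
  if (length(empties) > 0) {
    stop_hostpref("empty or missing field in row(s): ",
                  paste(utils::head(empties, 10), collapse = ", "),
                  class = "hostpref_validation_error")
  }

  # one area per cell
  ca <- unique(records[c("cell_id", "area_id")])
  dup_cells <- unique(ca$cell_id[duplicated(ca$cell_id)])
  if (length(dup_cells) > 0) {
    stop_hostpref("cell(s) assigned to more than one area: ",
                  paste(dup_cells, collapse = ", "),
                  class = "hostpref_consistency_error")
  }

  n_raw <- nrow(records)
  dup <- duplicated(records[c("lichen_taxon", "host_taxon", "cell_id")])
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL

  structure(
    list(records = records,
         cell_to_area = stats::setNames(ca$area_id, ca$cell_id),
         n_raw = n_raw,
         duplicates_dropped = sum(dup)),
    class = "occurrence_dataset"
  )
}

#' Read occurrence records from a delimited file
#'
#' Reads CSV or TSV presence records, validates and deduplicates them (see
#' [occurrence_dataset()]). The delimiter is inferred from the file extension
#' (`.tsv`/`.tab` mean tab) unless given explicitly. Column names can be
#' remapped for files using different headers.
#'
#' @param path path to a UTF-8 CSV/TSV file with a header row.
#' @param dialect `"auto"` (default, by extension), `"csv"` or `"tsv"`.
#' @param col_map optional named character vector mapping the canonical names
#'   `lichen_taxon`, `host_taxon`, `cell_id`, `area_id` to the column names
#'   used in the file, e.g. `c(lichen_taxon = "species")`.
#' @return An `occurrence_dataset`.
#' @export
read_occurrences <- function(path, dialect = c("auto", "csv", "tsv"),
                             col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_hostpref("file not found: ", path, class = "hostpref_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", comment.char = "")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop_hostpref("column mapping names absent column: ", src,
                      class = "hostpref_format_error")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  occurrence_dataset(raw)
}

#' Write an occurrence dataset back to CSV/TSV
#'
#' @param ds an `occurrence_dataset`.
#' @param path output file path.
#' @param dialect `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(ds, path, dialect = c("auto", "csv", "tsv")) {
  stopifnot(inherits(ds, "occurrence_dataset"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(ds$records, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarise a dataset for a validation report
#'
#' @param ds an `occurrence_dataset`.
#' @return list of counts: raw rows, duplicates dropped, records kept, and
#'   distinct epiphytes / hosts / cells / areas.
#' @export
validation_report <- function(ds) {
  stopifnot(inherits(ds, "occurrence_dataset"))
  r <- ds$records
  list(
    n_raw = ds$n_raw,
    duplicates_dropped = ds$duplicates_dropped,
    n_records = nrow(r),
    n_lichens = length(unique(r$lichen_taxon)),
    n_hosts = length(unique(r$host_taxon)),
    n_cells = length(unique(r$cell_id)),
    n_areas = length(unique(r$area_id))
  )
}

#' @export
print.occurrence_dataset <- function(x, ...) {
  v <- validation_report(x)
  cat("Occurrence dataset:", v$n_records, "presence records",
      sprintf("(%d raw, %d duplicates dropped)\n", v$n_raw, v$duplicates_dropped))
  cat(sprintf("  %d epiphyte taxa x %d host taxa over %d cells in %d areas\n",
              v$n_lichens, v$n_hosts, v$n_cells, v$n_areas))
  invisible(x)
}
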