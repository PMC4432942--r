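# Subset export: CSV metadata, GFF3 annotations, FASTA sequences.

#' Export a contig selection
#'
#' Writes the selected contigs in one of three formats, preserving original
#' table order:
#' * `csv` — one row per selected contig, all columns, header first.
#'   Numeric values are rendered at full (shortest round-trip) precision.
#' * `gff` — all features on selected contigs, coordinates unchanged, with
#'   the `##gff-version 3` pragma.
#' * `fasta` — selected sequences verbatim under their original ids,
#'   wrapped at 80 columns.
#'
#' @param dataset An `mg_dataset`. `fasta` requires sequences attached,
#'   `gff` requires annotations.
#' @param selection An `mg_selection` (ids must belong to the dataset).
#' @param format `"csv"`, `"gff"` or `"fasta"`.
#' @param path Output file.
#' @return Invisibly, a list with `path` and `n_records` (rows for csv,
#'   features for gff, sequences for fasta).
#' @export
export_subset <- function(dataset, selection, format = c("csv", "gff", "fasta"),
                          path) {
  stopifnot(inherits(dataset, "mg_dataset"), inherits(selection, "mg_selection"))
  format <- match.arg(format)
  ids <- contig_ids(dataset)
  unknown <- setdiff(selection$contig_ids, ids)
  if (length(unknown) > 0L) {
    stop("selection contains unknown contig(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  sel <- ids %in% selection$contig_ids

  n <- switch(format,
    csv = export_csv(dataset, sel, path),
    gff = export_gff(dataset, sel, path),
    fasta = export_fasta(dataset, sel, path))
  invisible(list(path = path, n_records = n))
}

export_csv <- function(dataset, sel, path) {
  df <- dataset$table$data[sel, , drop = FALSE]
  # as.character gives the shortest representation that parses back exactly
  out <- as.data.frame(lapply(df, function(col) {
    s <- as.character(col)
    s[is.na(col)] <- "NA"
    s
  }), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  nrow(out)
}

export_gff <- function(dataset, sel, path) {
  if (is.null(dataset$annotations)) {
    stop("gff export requested but no annotations are attached", call. = FALSE)
  }
  ann <- dataset$annotations
  keep <- ann$contig_id %in% contig_ids(dataset)[sel]
  ann <- ann[keep, , drop = FALSE]
  attr_text <- vapply(ann$attributes, function(a) {
    if (length(a) == 0L) "." else
      paste(paste0(names(a), "=", gff_escape(unname(a))), collapse = ";")
  }, "")
  lines <- c("##gff-version 3",
             if (nrow(ann) > 0L)
               paste(ann$contig_id, ann$source, ann$type, ann$start, ann$end,
                     ann$score, ann$strand, ann$phase, attr_text, sep = "\t"))
  writeLines(lines, path)
  nrow(ann)
}

export_fasta <- function(dataset, sel, path) {
  if (is.null(dataset$sequences)) {
    stop("fasta export requested but no sequences are attached", call. = FALSE)
  }
  ids <- contig_ids(dataset)[sel]
  ids <- ids[ids %in% names(dataset$sequences)]
  seqs <- Biostrings::DNAStringSet(dataset$sequences[ids])
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  length(seqs)
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` keeping only the first
#' whitespace-delimited token of each header as the id.
#' @param file FASTA path (plain or gzip).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file) {
  dss <- Biostrings::readDNAStringSet(file)
  nms <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nms)) stop("duplicate FASTA ids", call. = FALSE)
  stats::setNames(as.character(dss), nms)
}

#' Write sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path,
                              width = 80L)
  invisible(path)
}

#' Write a contig table back to delimited text
#'
#' Inverse of [read_metadata_table()]: writing then re-reading yields an
#' identical table (column order, kinds, values).
#' @param table A `contig_table`.
#' @param path Output path.
#' @param dialect `"comma"` (default) or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(table, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else "\t"
  df <- as.data.frame(lapply(table$data, function(col) {
    s <- as.character(col)
    s[is.na(col)] <- "NA"
    s
  }), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}
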