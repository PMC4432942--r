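# Ingestion and validation of contig metadata tables, sequences and
# annotations into one coherent dataset.

MISSING_MARKERS <- c("", "NA")

#' Read a delimited contig metadata table
#'
#' Reads a tab- or comma-delimited table, one row per contig, with column
#' headings in the first row. Column kinds are inferred: a column is
#' `numeric` when every non-missing cell parses as a real number (scientific
#' notation accepted; values with thousands separators do not parse and make
#' the column `ordinal`). All column roles start as `info`; see
#' [assign_roles()].
#'
#' Missing cells are the empty string or `NA` and become `NA` in the parsed
#' table. Plain and gzip-compressed files are accepted.
#'
#' @param file Path to a delimited text file (optionally `.gz`).
#' @param dialect `"auto"` (default), `"tab"` or `"comma"`. `"auto"` decides
#'   by counting tabs vs commas in the header line; a tie is an error.
#' @return A `contig_table`: a list with `data` (data.frame, typed columns)
#'   and `columns` (data.frame of `name`, `kind`, `role`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,gc,taxon", "c1,0.51,Bacteria", "c2,0.62,Archaea"), f)
#' tab <- read_metadata_table(f)
#' tab$columns
#' @export
read_metadata_table <- function(file, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(file)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    stop("empty metadata table: ", file, call. = FALSE)
  }
  sep <- resolve_dialect(lines[1L], dialect)

  nf <- utils::count.fields(textConnection(lines), sep = sep, quote = "\"",
                            comment.char = "")
  keep <- !is.na(nf)  # count.fields NAs lines inside multi-line quotes
  if (any(!keep)) stop("unbalanced quotes in metadata table", call. = FALSE)
  n_header <- nf[1L]
  bad <- which(nf != n_header)
  if (length(bad) > 0L) {
    stop(sprintf("row %d has %d fields, expected %d", bad[1L], nf[bad[1L]],
                 n_header), call. = FALSE)
  }

  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          na.strings = character(0), stringsAsFactors = FALSE)
  nms <- names(df)
  if (anyDuplicated(nms)) {
    stop("duplicate column name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }

  kinds <- character(length(nms))
  for (j in seq_along(nms)) {
    cell <- df[[j]]
    cell[cell %in% MISSING_MARKERS] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    ok <- all(is.na(cell) | !is.na(num))
    if (ok && any(!is.na(cell))) {
      df[[j]] <- num
      kinds[j] <- "numeric"
    } else {
      df[[j]] <- cell
      kinds[j] <- "ordinal"
    }
  }

  new_contig_table(df, data.frame(name = nms, kind = kinds,
                                  role = rep("info", length(nms)),
                                  stringsAsFactors = FALSE))
}

new_contig_table <- function(data, columns) {
  structure(list(data = data, columns = columns), class = "contig_table")
}

#' @export
print.contig_table <- function(x, ...) {
  cat(sprintf("<contig_table> %d contigs x %d columns\n",
              nrow(x$data), nrow(x$columns)))
  print(x$columns)
  invisible(x)
}

resolve_dialect <- function(header, dialect) {
  if (dialect == "tab") return("\t")
  if (dialect == "comma") return(",")
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab > n_com) return("\t")
  if (n_com > n_tab) return(",")
  stop("cannot decide delimiter: header has ", n_tab, " tabs and ", n_com,
       " commas; pass dialect explicitly", call. = FALSE)
}

read_text_lines <- function(file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "rt") else file(file, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Assign column roles and create a dataset
#'
#' Applies a name-to-role mapping (`id`, `x`, `y`, `size`, `color`) to a
#' contig table. Every numeric column not mapped to a plot property becomes
#' a `filter` parameter automatically; non-numeric unmapped columns are
#' `info`. Exactly one column must be mapped to `id` and its values must be
#' unique and non-empty. Columns mapped to `x`, `y` or `size` must be
#' numeric.
#'
#' @param table A `contig_table` from [read_metadata_table()].
#' @param roles Named character vector, `column name -> role`.
#' @return An `mg_dataset` with the table's roles set and no sequences or
#'   annotations attached.
#' @export
assign_roles <- function(table, roles) {
  stopifnot(inherits(table, "contig_table"))
  cols <- table$columns
  unknown <- setdiff(names(roles), cols$name)
  if (length(unknown) > 0L) {
    stop("role mapping names unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  valid <- c("id", "x", "y", "size", "color", "filter", "info")
  if (!all(roles %in% valid)) {
    stop("unknown role(s): ", paste(setdiff(roles, valid), collapse = ", "),
         call. = FALSE)
  }
  if (sum(roles == "id") != 1L) {
    stop("exactly one column must be assigned role 'id'", call. = FALSE)
  }
  for (r in c("x", "y", "size", "color")) {
    if (sum(roles == r) > 1L) stop("role '", r, "' assigned twice", call. = FALSE)
  }

  role <- rep("info", nrow(cols))
  names(role) <- cols$name
  role[names(roles)] <- roles
  for (r in c("x", "y", "size")) {
    nm <- names(roles)[roles == r]
    if (length(nm) == 1L && cols$kind[cols$name == nm] != "numeric") {
      stop("column '", nm, "' mapped to ", r, " is not numeric", call. = FALSE)
    }
  }
  auto <- role == "info" & cols$kind == "numeric"
  role[auto] <- "filter"

  id_col <- names(roles)[roles == "id"]
  ids <- as.character(table$data[[id_col]])
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("id column '", id_col, "' has empty values", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("id column '", id_col, "' has duplicate values: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "),
         call. = FALSE)
  }

  cols$role <- unname(role[cols$name])
  make_dataset(new_contig_table(table$data, cols))
}

#' Compute length and GC content from sequences
#'
#' GC content is the fraction of G and C among unambiguous bases
#' (A, C, G, T, case-insensitive); N and IUPAC ambiguity codes are excluded
#' from the denominator. When a sequence has no unambiguous base, GC is `NA`.
#' Length counts all characters.
#'
#' @param sequences Named character vector of nucleotide sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return data.frame with `contig_id`, `length`, `gc`.
#' @export
compute_sequence_stats <- function(sequences) {
  seqs <- as_sequence_set(sequences)
  if (any(!nzchar(seqs))) {
    stop("empty sequence(s): ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  dss <- Biostrings::DNAStringSet(toupper(seqs))
  freq <- Biostrings::letterFrequency(dss, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  gc <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
  data.frame(contig_id = names(seqs), length = nchar(seqs), gc = unname(gc),
             stringsAsFactors = FALSE, row.names = NULL)
}

as_sequence_set <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences) || is.null(names(sequences))) {
    stop("sequences must be a named character vector or DNAStringSet",
         call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence ids", call. = FALSE)
  }
  sequences
}

#' Read gene annotations from a GFF3 file
#'
#' Parses the nine tab-separated GFF3 columns; `#` comment and pragma lines
#' are ignored. Coordinates are 1-based inclusive; `start > end` or
#' non-integer coordinates are errors carrying the offending line number.
#' All `key=value` attribute pairs are preserved in order.
#'
#' @param file Path to a GFF3 file (optionally `.gz`).
#' @return data.frame with columns `contig_id`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase` and a list-column `attributes` of
#'   named character vectors.
#' @export
read_annotations <- function(file) {
  lines <- read_text_lines(file)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_annotations())

  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    i <- which(nf != 9L)[1L]
    stop(sprintf("GFF line %d: expected 9 tab-separated fields, got %d",
                 idx[i], nf[i]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  start_num <- suppressWarnings(as.numeric(m[, 4L]))
  end_num <- suppressWarnings(as.numeric(m[, 5L]))
  bad <- is.na(start_num) | is.na(end_num) |
    start_num != floor(start_num) | end_num != floor(end_num)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("GFF line %d: non-integer coordinates '%s'..'%s'",
                 idx[i], m[i, 4L], m[i, 5L]), call. = FALSE)
  }
  start <- as.integer(start_num); end <- as.integer(end_num)
  bad <- start > end | start < 1L
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("GFF line %d: invalid coordinates start=%d end=%d",
                 idx[i], start[i], end[i]), call. = FALSE)
  }
  strand <- m[, 7L]
  bad <- !strand %in% c("+", "-", ".")
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("GFF line %d: invalid strand '%s'", idx[i], strand[i]),
         call. = FALSE)
  }

  attrs <- lapply(m[, 9L], parse_gff_attributes)
  ann <- data.frame(contig_id = m[, 1L], source = m[, 2L], type = m[, 3L],
                    start = start, end = end, score = m[, 6L],
                    strand = strand, phase = m[, 8L],
                    stringsAsFactors = FALSE, row.names = NULL)
  ann$attributes <- attrs
  ann
}

empty_annotations <- function() {
  ann <- data.frame(contig_id = character(0), source = character(0),
                    type = character(0), start = integer(0), end = integer(0),
                    score = character(0), strand = character(0),
                    phase = character(0), stringsAsFactors = FALSE)
  ann$attributes <- list()
  ann
}

parse_gff_attributes <- function(text) {
  if (!nzchar(text) || text == ".") return(stats::setNames(character(0), character(0)))
  pairs <- strsplit(text, ";", fixed = TRUE)[[1L]]
  pairs <- trimws(pairs)
  pairs <- pairs[nzchar(pairs)]
  kv <- regmatches(pairs, regexpr("=", pairs, fixed = TRUE), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) if (length(p) > 1L) p[2L] else "", "")
  stats::setNames(gff_unescape(vals), keys)
}

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

gff_unescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%09", "\t", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Assemble a validated dataset from its components
#'
#' Cross-references sequences and annotations against the contig table:
#' sequence ids absent from the table are an error; annotation features on
#' unknown contigs are dropped with a warning reporting their count and ids.
#'
#' @param table A `contig_table` (roles may or may not be assigned; an id
#'   role is required to resolve contig ids, otherwise the first column is
#'   used).
#' @param sequences Optional named character vector / `DNAStringSet`.
#' @param annotations Optional annotation data.frame from
#'   [read_annotations()].
#' @return An `mg_dataset` list with elements `table`, `sequences`,
#'   `annotations`.
#' @export
make_dataset <- function(table, sequences = NULL, annotations = NULL) {
  stopifnot(inherits(table, "contig_table"))
  ds <- structure(list(table = table, sequences = NULL, annotations = NULL),
                  class = "mg_dataset")
  ids <- contig_ids(ds)
  if (anyDuplicated(ids)) stop("duplicate contig ids in table", call. = FALSE)

  if (!is.null(sequences)) {
    sequences <- as_sequence_set(sequences)
    missing <- setdiff(names(sequences), ids)
    if (length(missing) > 0L) {
      stop("sequence id(s) absent from table: ",
           paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
    }
    ds$sequences <- sequences
  }
  if (!is.null(annotations)) {
    unknown <- !annotations$contig_id %in% ids
    if (any(unknown)) {
      warning(sprintf("dropping %d feature(s) on unknown contig(s): %s",
                      sum(unknown),
                      paste(utils::head(unique(annotations$contig_id[unknown]), 10),
                            collapse = ", ")), call. = FALSE)
      annotations <- annotations[!unknown, , drop = FALSE]
    }
    ds$annotations <- annotations
  }
  ds
}

#' @export
print.mg_dataset <- function(x, ...) {
  cat(sprintf("<mg_dataset> %d contigs, %d columns; sequences: %s; features: %s\n",
              nrow(x$table$data), nrow(x$table$columns),
              if (is.null(x$sequences)) "none" else length(x$sequences),
              if (is.null(x$annotations)) "none" else nrow(x$annotations)))
  invisible(x)
}

#' Contig identifiers of a dataset
#'
#' Uses the column with role `id` when one is assigned, else the first
#' column.
#' @param dataset An `mg_dataset` or `contig_table`.
#' @return Character vector of contig ids in table order.
#' @export
contig_ids <- function(dataset) {
  tab <- if (inherits(dataset, "mg_dataset")) dataset$table else dataset
  idc <- id_column(tab)
  as.character(tab$data[[idc]])
}

id_column <- function(table) {
  hit <- table$columns$name[table$columns$role == "id"]
  if (length(hit) == 1L) hit else table$columns$name[1L]
}

#' Fill length/GC metadata columns from attached sequences
#'
#' Adds (or completes) numeric `length` and `gc` columns computed with
#' [compute_sequence_stats()] for contigs that have a sequence. Existing
#' non-missing values are kept.
#' @param dataset An `mg_dataset` with sequences attached.
#' @return The dataset with updated table.
#' @export
add_sequence_stats <- function(dataset) {
  stopifnot(inherits(dataset, "mg_dataset"))
  if (is.null(dataset$sequences)) {
    stop("dataset has no sequences attached", call. = FALSE)
  }
  stats <- compute_sequence_stats(dataset$sequences)
  ids <- contig_ids(dataset)
  for (col in c("length", "gc")) {
    vals <- stats[[col]][match(ids, stats$contig_id)]
    if (!col %in% dataset$table$columns$name) {
      dataset$table$data[[col]] <- vals
      dataset$table$columns <- rbind(
        dataset$table$columns,
        data.frame(name = col, kind = "numeric", role = "filter",
                   stringsAsFactors = FALSE))
    } else {
      cur <- dataset$table$data[[col]]
      fill <- is.na(cur) & !is.na(vals)
      cur[fill] <- vals[fill]
      dataset$table$data[[col]] <- cur
    }
  }
  dataset
}
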