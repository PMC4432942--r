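# Search, range filters, group visibility, and GC x coverage genome-bin
# gating.

#' Construct a numeric range filter
#'
#' @param column Numeric column name.
#' @param min,max Inclusive bounds (default unbounded).
#' @return A `filter_range` list.
#' @export
filter_range <- function(column, min = -Inf, max = Inf) {
  stopifnot(is.character(column), length(column) == 1L, min <= max)
  structure(list(column = column, min = min, max = max),
            class = "filter_range")
}

#' Apply numeric range filters to a dataset
#'
#' Filters combine as a conjunction with inclusive bounds. Contigs with a
#' missing value in any filtered column are excluded (conservative). An
#' empty filter list selects every contig.
#'
#' @param dataset An `mg_dataset`.
#' @param filters List of [filter_range()] objects.
#' @return An `mg_selection`: list with `contig_ids` and `provenance`.
#' @export
apply_filters <- function(dataset, filters = list()) {
  stopifnot(inherits(dataset, "mg_dataset"))
  if (inherits(filters, "filter_range")) filters <- list(filters)
  tab <- dataset$table
  keep <- rep(TRUE, nrow(tab$data))
  for (f in filters) {
    stopifnot(inherits(f, "filter_range"))
    j <- match(f$column, tab$columns$name)
    if (is.na(j)) stop("filter column '", f$column, "' not found", call. = FALSE)
    if (tab$columns$kind[j] != "numeric") {
      stop("filter column '", f$column, "' is not numeric", call. = FALSE)
    }
    v <- tab$data[[f$column]]
    keep <- keep & !is.na(v) & v >= f$min & v <= f$max
  }
  desc <- if (length(filters) == 0L) "all contigs" else
    paste(vapply(filters, function(f)
      sprintf("%s in [%g, %g]", f$column, f$min, f$max), ""), collapse = " & ")
  new_selection(contig_ids(dataset)[keep], paste("filter:", desc))
}

new_selection <- function(ids, provenance) {
  structure(list(contig_ids = ids, provenance = provenance),
            class = "mg_selection")
}

#' @export
print.mg_selection <- function(x, ...) {
  cat(sprintf("<mg_selection> %d contigs (%s)\n",
              length(x$contig_ids), x$provenance))
  invisible(x)
}

#' Search all metadata fields and annotations
#'
#' Case-insensitive substring match over the text rendering of every
#' metadata column (numeric values match their canonical text form) and over
#' annotation feature types and attribute values. The per-contig hit count
#' is the number of matching metadata fields plus the number of features
#' with a matching type or attribute value. Contigs with zero hits are
#' omitted.
#'
#' @param dataset An `mg_dataset`.
#' @param term Search term, non-empty after trimming.
#' @param regex Interpret `term` as a regular expression instead of a plain
#'   substring (default `FALSE`).
#' @return A `search_result`: list with `term` and `hits` (named integer
#'   vector, contig id -> hit count >= 1).
#' @export
search_dataset <- function(dataset, term, regex = FALSE) {
  stopifnot(inherits(dataset, "mg_dataset"))
  term <- trimws(term)
  if (!nzchar(term)) stop("empty search term", call. = FALSE)
  matches <- function(x) {
    x <- as.character(x)
    hit <- if (regex) grepl(term, x, ignore.case = TRUE)
           else grepl(tolower(term), tolower(x), fixed = TRUE)
    hit & !is.na(x)
  }

  tab <- dataset$table
  ids <- contig_ids(dataset)
  field_hits <- integer(nrow(tab$data))
  for (j in seq_len(ncol(tab$data))) {
    field_hits <- field_hits + matches(tab$data[[j]])
  }
  counts <- stats::setNames(field_hits, ids)

  ann <- dataset$annotations
  if (!is.null(ann) && nrow(ann) > 0L) {
    feat_hit <- matches(ann$type) |
      vapply(ann$attributes, function(a) any(matches(a)), TRUE)
    if (any(feat_hit)) {
      per_contig <- table(ann$contig_id[feat_hit])
      counts[names(per_contig)] <- counts[names(per_contig)] +
        as.integer(per_contig)
    }
  }
  counts <- counts[counts > 0L]
  structure(list(term = term, hits = counts), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> '%s': %d contigs, %d total hits\n",
              x$term, length(x$hits), sum(x$hits)))
  invisible(x)
}

#' Summarize search hits by taxon group
#'
#' @param result A `search_result`.
#' @param partition A `taxon_partition` covering every hit contig.
#' @return data.frame `(group, n_contigs, total_hits)`, groups with zero
#'   hits omitted, ordered by descending total hits (name tie-break). Totals
#'   conserve the per-contig hit sums.
#' @export
summarize_hits_by_group <- function(result, partition) {
  stopifnot(inherits(result, "search_result"),
            inherits(partition, "taxon_partition"))
  if (length(result$hits) == 0L) {
    return(data.frame(group = character(0), n_contigs = integer(0),
                      total_hits = integer(0), stringsAsFactors = FALSE))
  }
  grp <- partition$assignment[names(result$hits)]
  if (anyNA(grp)) {
    stop("contig(s) absent from partition: ",
         paste(utils::head(names(result$hits)[is.na(grp)], 5), collapse = ", "),
         call. = FALSE)
  }
  agg_n <- tapply(result$hits, grp, length)
  agg_h <- tapply(result$hits, grp, sum)
  df <- data.frame(group = names(agg_h), n_contigs = as.integer(agg_n),
                   total_hits = as.integer(agg_h), stringsAsFactors = FALSE)
  df <- df[order(-df$total_hits, df$group), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select contigs by hiding taxon groups
#'
#' @param dataset An `mg_dataset`.
#' @param partition A `taxon_partition`.
#' @param hidden Character vector of group labels to hide (must be a subset
#'   of `partition$groups`).
#' @return An `mg_selection` of contigs whose group is not hidden.
#' @export
toggle_groups <- function(dataset, partition, hidden = character(0)) {
  stopifnot(inherits(dataset, "mg_dataset"),
            inherits(partition, "taxon_partition"))
  unknown <- setdiff(hidden, partition$groups)
  if (length(unknown) > 0L) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ids <- contig_ids(dataset)
  grp <- partition$assignment[ids]
  keep <- !grp %in% hidden
  new_selection(ids[keep],
                paste("hide:", if (length(hidden)) paste(hidden, collapse = ",")
                      else "<none>"))
}

#' Construct a rectangular GC x coverage gate
#'
#' @param label Bin label.
#' @param gc_min,gc_max GC bounds (fractions), inclusive.
#' @param cov_min,cov_max Coverage bounds, inclusive.
#' @return A `gate_rect` list.
#' @export
gate_rect <- function(label, gc_min, gc_max, cov_min, cov_max) {
  stopifnot(gc_min <= gc_max, cov_min <= cov_max)
  structure(list(label = label, gc_min = gc_min, gc_max = gc_max,
                 cov_min = cov_min, cov_max = cov_max), class = "gate_rect")
}

#' Assign contigs to genome bins with rectangular gates
#'
#' Each contig receives exactly one label: the first gate (in list order)
#' whose GC and coverage ranges both contain it, or `"unbinned"` when no
#' gate matches or either value is missing.
#'
#' @param dataset An `mg_dataset`.
#' @param gates List of [gate_rect()] objects.
#' @param gc_column,coverage_column Names of the numeric GC and coverage
#'   columns (defaults `"gc"`, `"coverage"`).
#' @return Named character vector, contig id -> gate label or `"unbinned"`.
#' @export
gate_bins <- function(dataset, gates, gc_column = "gc",
                      coverage_column = "coverage") {
  stopifnot(inherits(dataset, "mg_dataset"))
  tab <- dataset$table
  for (col in c(gc_column, coverage_column)) {
    j <- match(col, tab$columns$name)
    if (is.na(j)) stop("column '", col, "' not found", call. = FALSE)
    if (tab$columns$kind[j] != "numeric") {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
  }
  gc <- tab$data[[gc_column]]
  cov <- tab$data[[coverage_column]]
  labels <- rep("unbinned", nrow(tab$data))
  for (g in rev(gates)) {  # reverse so earlier gates overwrite: first wins
    stopifnot(inherits(g, "gate_rect"))
    hit <- !is.na(gc) & !is.na(cov) &
      gc >= g$gc_min & gc <= g$gc_max & cov >= g$cov_min & cov <= g$cov_max
    labels[hit] <- g$label
  }
  stats::setNames(labels, contig_ids(dataset))
}

#' Write a selection as CSV
#' @param selection An `mg_selection`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  df <- data.frame(contig_id = selection$contig_ids, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a selection written by [write_selection()]
#' @param path CSV with a `contig_id` column.
#' @return An `mg_selection`.
#' @export
read_selection <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  new_selection(df$contig_id, paste("file:", path))
}
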