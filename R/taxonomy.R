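# Lineage parsing, contig-count-weighted taxonomy trees, and collapse to a
# bounded set of group taxa for legend coloring.

#' Parse a complete-lineage string
#'
#' Splits on the delimiter, trims whitespace and drops empty segments. An
#' empty or `NA` string yields an empty lineage (unclassified contig). Total
#' function: never errors.
#'
#' @param text Lineage string, root-first (e.g.
#'   `"Bacteria;Proteobacteria;Gammaproteobacteria"`).
#' @param delimiter Rank separator, default `";"`.
#' @return Character vector of rank names, root-first (possibly empty).
#' @export
parse_lineage <- function(text, delimiter = ";") {
  if (length(text) == 0L || is.na(text) || !nzchar(trimws(text))) {
    return(character(0))
  }
  ranks <- trimws(strsplit(text, delimiter, fixed = TRUE)[[1L]])
  ranks[nzchar(ranks)]
}

#' Build a contig-count-weighted taxonomy tree
#'
#' Each distinct lineage prefix becomes one node; a node's count is the
#' number of contigs whose lineage passes through it. Contigs with an empty
#' lineage are tallied separately as unclassified and do not enter the tree.
#'
#' @param dataset An `mg_dataset`.
#' @param lineage_column Name of the lineage column.
#' @param delimiter Rank separator passed to [parse_lineage()].
#' @return The root `tax_node` (name `"Root"`, depth 0). Contig lineages and
#'   unclassified ids are carried along for [collapse_to_groups()].
#' @export
build_taxonomy_tree <- function(dataset, lineage_column = "lineage",
                                delimiter = ";") {
  stopifnot(inherits(dataset, "mg_dataset"))
  tab <- dataset$table
  if (!lineage_column %in% tab$columns$name) {
    stop("lineage column '", lineage_column, "' not found", call. = FALSE)
  }
  ids <- contig_ids(dataset)
  texts <- as.character(tab$data[[lineage_column]])
  lineages <- lapply(texts, parse_lineage, delimiter = delimiter)
  names(lineages) <- ids
  build_tree_from_lineages(lineages)
}

# lineages: named list contig_id -> character vector of ranks
build_tree_from_lineages <- function(lineages) {
  classified <- lengths(lineages) > 0L
  root <- new_tax_node("Root", 0L)
  for (i in which(classified)) {
    root <- insert_lineage(root, lineages[[i]])
  }
  root$count <- sum(classified)
  attr(root, "lineages") <- lineages[classified]
  attr(root, "unclassified") <- names(lineages)[!classified]
  root
}

new_tax_node <- function(name, depth) {
  structure(list(name = name, depth = depth, count = 0L, term_count = 0L,
                 children = list()), class = "tax_node")
}

insert_lineage <- function(node, ranks) {
  node$count <- node$count + 1L
  if (length(ranks) == 0L) {
    node$term_count <- node$term_count + 1L
    return(node)
  }
  head <- ranks[1L]
  child <- node$children[[head]]
  if (is.null(child)) child <- new_tax_node(head, node$depth + 1L)
  node$children[[head]] <- insert_lineage(child, ranks[-1L])
  node
}

#' @export
print.tax_node <- function(x, max_depth = 2L, ...) {
  walk <- function(n, indent) {
    cat(strrep("  ", indent), n$name, " (", n$count, ")\n", sep = "")
    if (indent < max_depth) for (ch in n$children) walk(ch, indent + 1L)
  }
  walk(x, 0L)
  invisible(x)
}

# A frontier is a list of paths (character vectors of rank names from the
# root, root itself = character(0)). get_node resolves a path.
get_node <- function(root, path) {
  node <- root
  for (nm in path) node <- node$children[[nm]]
  node
}

#' Collapse a taxonomy tree to a bounded set of group taxa
#'
#' Greedy frontier refinement: the frontier starts at the root; repeatedly
#' the frontier node with the largest contig count that has at least one
#' child is replaced by its children, provided the resulting frontier size
#' stays within `k_max` (ties broken by lexicographic node name; a node at
#' which some contigs' lineages terminate is retained alongside its children
#' so those contigs keep a selected ancestor). Refinement stops when no
#' expansion fits. Each classified contig is assigned to its deepest
#' selected ancestor; unclassified contigs go to the reserved
#' `"Unclassified"` group.
#'
#' @param root A `tax_node` from [build_taxonomy_tree()].
#' @param k_max Maximum number of non-reserved groups (default 30).
#' @return A `taxon_partition`: list with `groups` (labels ordered by
#'   descending contig count, name tie-break), `assignment` (named character,
#'   contig id -> group label) and `k_max`.
#' @export
collapse_to_groups <- function(root, k_max = 30L) {
  stopifnot(inherits(root, "tax_node"), k_max >= 1L)
  lineages <- attr(root, "lineages")
  unclassified <- attr(root, "unclassified")

  frontier <- list(character(0))
  repeat {
    info <- frontier_candidates(root, frontier)
    expanded <- FALSE
    if (nrow(info) > 0L) {
      ord <- order(-info$count, info$name)
      for (i in ord) {
        node <- get_node(root, frontier[[info$idx[i]]])
        delta <- length(node$children) - if (node$term_count > 0L) 0L else 1L
        if (length(frontier) + delta <= k_max) {
          path <- frontier[[info$idx[i]]]
          kids <- lapply(names(node$children), function(nm) c(path, nm))
          if (node$term_count > 0L) {
            frontier <- c(frontier, kids)
          } else {
            frontier <- c(frontier[-info$idx[i]], kids)
          }
          expanded <- TRUE
          break
        }
      }
    }
    if (!expanded) break
  }

  assignment <- assign_to_frontier(frontier, lineages)
  if (length(unclassified) > 0L) {
    assignment <- c(assignment,
                    stats::setNames(rep("Unclassified", length(unclassified)),
                                    unclassified))
  }
  groups <- order_groups(assignment)
  structure(list(groups = groups, assignment = assignment, k_max = k_max,
                 frontier = frontier),
            class = "taxon_partition")
}

# data.frame of expandable frontier nodes: index, count, name
frontier_candidates <- function(root, frontier) {
  idx <- integer(0); count <- integer(0); name <- character(0)
  for (i in seq_along(frontier)) {
    node <- get_node(root, frontier[[i]])
    unexpanded <- length(node$children) > 0L &&
      !all(vapply(names(node$children),
                  function(nm) path_in(frontier, c(frontier[[i]], nm)),
                  TRUE))
    if (unexpanded) {
      idx <- c(idx, i); count <- c(count, node$count); name <- c(name, node$name)
    }
  }
  data.frame(idx = idx, count = count, name = name, stringsAsFactors = FALSE)
}

path_in <- function(frontier, path) {
  any(vapply(frontier, identical, TRUE, y = path))
}

# deepest frontier node that is a prefix of (or equals) each lineage
assign_to_frontier <- function(frontier, lineages) {
  if (length(lineages) == 0L) return(stats::setNames(character(0), character(0)))
  depths <- lengths(frontier)
  labels <- vapply(frontier, function(p) {
    if (length(p) == 0L) "Root" else p[length(p)]
  }, "")
  keys <- vapply(frontier, paste, "", collapse = "\r")
  out <- vapply(lineages, function(ranks) {
    best <- -1L; lab <- NA_character_
    for (d in 0:length(ranks)) {
      key <- paste(ranks[seq_len(d)], collapse = "\r")
      hit <- which(keys == key & depths == d)
      if (length(hit) == 1L && d > best) { best <- d; lab <- labels[hit] }
    }
    lab
  }, "")
  if (anyNA(out)) stop("internal error: contig without selected ancestor")
  out
}

order_groups <- function(assignment) {
  if (length(assignment) == 0L) return(character(0))
  tab <- table(assignment)
  nms <- names(tab)
  nms[order(-as.integer(tab), nms)]
}

#' @export
print.taxon_partition <- function(x, ...) {
  cat(sprintf("<taxon_partition> %d groups over %d contigs (k_max = %d)\n",
              length(x$groups), length(x$assignment), x$k_max))
  print(utils::head(group_counts(x), 10))
  invisible(x)
}

#' Contig counts per taxon group
#'
#' @param partition A `taxon_partition`.
#' @return data.frame `(group, n_contigs)` ordered by descending count,
#'   stable name tie-break. Counts sum to the total number of contigs.
#' @export
group_counts <- function(partition) {
  stopifnot(inherits(partition, "taxon_partition"))
  if (length(partition$assignment) == 0L) {
    return(data.frame(group = character(0), n_contigs = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(partition$assignment)
  df <- data.frame(group = names(tab), n_contigs = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_contigs, df$group), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Number of non-reserved groups in a partition
#' @param partition A `taxon_partition`.
#' @return Integer count of groups excluding `"Unclassified"`.
#' @export
n_taxon_groups <- function(partition) {
  sum(partition$groups != "Unclassified")
}

#' Write a partition as a two-column CSV
#' @param partition A `taxon_partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(contig_id = names(partition$assignment),
                   group = unname(partition$assignment),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a partition written by [write_partition()]
#' @param path CSV with columns `contig_id`, `group`.
#' @return A `taxon_partition` (with `k_max = NA`).
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  assignment <- stats::setNames(df$group, df$contig_id)
  structure(list(groups = order_groups(assignment), assignment = assignment,
                 k_max = NA_integer_, frontier = NULL),
            class = "taxon_partition")
}
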