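# Independent oracle for the taxonomy collapse: exhaustive breadth-first
# enumeration of every frontier reachable by single-node refinement,
# independent of the greedy implementation.

frontier_key <- function(frontier) {
  paste(sort(vapply(frontier, function(p) paste(c("Root", p), collapse = "/"),
                    "")), collapse = "|")
}

# all refinements of `frontier` by expanding one node
oracle_expansions <- function(root, frontier) {
  out <- list()
  keys <- vapply(frontier, paste, "", collapse = "/")
  for (i in seq_along(frontier)) {
    node <- contigscape:::get_node(root, frontier[[i]])
    if (length(node$children) == 0L) next
    kid_paths <- lapply(names(node$children), function(nm) c(frontier[[i]], nm))
    kid_keys <- vapply(kid_paths, paste, "", collapse = "/")
    if (all(kid_keys %in% keys)) next  # already expanded (term node retained)
    base <- if (node$term_count > 0L) frontier else frontier[-i]
    out[[length(out) + 1L]] <- c(base, kid_paths)
  }
  out
}

# every reachable frontier, as a named list key -> frontier
enumerate_frontiers <- function(root) {
  start <- list(character(0))
  seen <- new.env(parent = emptyenv())
  assign(frontier_key(start), start, envir = seen)
  queue <- list(start)
  while (length(queue) > 0L) {
    f <- queue[[1L]]; queue <- queue[-1L]
    for (g in oracle_expansions(root, f)) {
      k <- frontier_key(g)
      if (!exists(k, envir = seen)) {
        assign(k, g, envir = seen)
        queue[[length(queue) + 1L]] <- g
      }
    }
  }
  mget(ls(seen), envir = seen)
}

# maximal frontiers within the size bound
oracle_maximal_frontiers <- function(root, k_max) {
  all_f <- enumerate_frontiers(root)
  keep <- vapply(all_f, function(f) {
    if (length(f) > k_max) return(FALSE)
    exps <- oracle_expansions(root, f)
    all(vapply(exps, length, 0L) > k_max)
  }, TRUE)
  all_f[keep]
}

# direct property checks on a partition against its tree
check_partition_properties <- function(root, part, k_max) {
  lineages <- attr(root, "lineages")
  unclassified <- attr(root, "unclassified")
  n <- length(lineages) + length(unclassified)
  cover <- length(part$assignment) == n &&
    !anyDuplicated(names(part$assignment)) &&
    setequal(names(part$assignment), c(names(lineages), unclassified))
  bound <- n_taxon_groups(part) <= k_max
  exps <- oracle_expansions(root, part$frontier)
  maximal <- all(vapply(exps, length, 0L) > k_max)
  list(cover = cover, bound = bound, maximal = maximal)
}

# random tree generator for the oracle sweep: returns lineage strings
# (rank names are unique across the tree)
random_lineages <- function(n_internal_max = 12L) {
  lineages <- character(0)
  grow <- function(path, name_prefix, depth, budget) {
    n_kids <- sample(2:3, 1L)
    for (i in seq_len(n_kids)) {
      nm <- paste0(name_prefix, letters[i])
      new_path <- if (nzchar(path)) paste0(path, ";", nm) else nm
      deeper <- depth < 3L && budget$left > 0L && stats::runif(1) < 0.5
      if (deeper) {
        budget$left <- budget$left - 1L
        # occasionally a contig terminates at this internal node
        if (stats::runif(1) < 0.3) lineages <<- c(lineages, new_path)
        grow(new_path, nm, depth + 1L, budget)
      } else {
        reps <- sample(1:3, 1L)
        lineages <<- c(lineages, rep(new_path, reps))
      }
    }
  }
  budget <- new.env(); budget$left <- n_internal_max - 2L
  grow("", "", 1L, budget)
  lineages
}

# random binary tree, contigs only at leaves: every refinement step grows
# the frontier by exactly one node, the regime in which assignment depth is
# provably monotone in k_max
binary_lineages <- function(max_depth = 4L) {
  lineages <- character(0)
  grow <- function(path, name_prefix, depth) {
    for (i in 1:2) {
      nm <- paste0(name_prefix, letters[i])
      new_path <- if (nzchar(path)) paste0(path, ";", nm) else nm
      if (depth < max_depth && stats::runif(1) < 0.6) {
        grow(new_path, nm, depth + 1L)
      } else {
        lineages <<- c(lineages, rep(new_path, sample(1:4, 1L)))
      }
    }
  }
  grow("", "", 1L)
  lineages
}

count_leaves <- function(node) {
  if (length(node$children) == 0L) return(1L)
  sum(vapply(node$children, count_leaves, 0L))
}
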