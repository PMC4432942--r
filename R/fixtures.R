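# Seeded synthetic-assembly generator: multi-genome communities with known
# GC/coverage structure, lineages, gene models and planted annotation
# tokens, so every pipeline stage is testable without external data.

#' Describe one synthetic genome
#'
#' Contig lengths and coverages are log-normal (matching the heavy-tailed
#' size and abundance distributions of real assemblies); per-contig GC is
#' Normal(`gc_mean`, `gc_sd`) truncated to (0, 1) and realized base by base.
#'
#' @param label Genome label (ground-truth bin name).
#' @param lineage Complete lineage string (`;`-separated, root-first); empty
#'   for unclassified contigs.
#' @param gc_mean,gc_sd Mean and SD of per-contig GC fraction.
#' @param coverage_mean Median fold coverage (log-normal location).
#' @param coverage_sdlog Log-scale coverage SD.
#' @param n_contigs Number of contigs.
#' @param length_meanlog,length_sdlog Log-normal contig length parameters
#'   (bp); `length_sdlog = 0` gives fixed lengths.
#' @param tokens Planted annotation tokens: a list of lists with elements
#'   `token` (e.g. `"PF00810"`), `carriers` (number of carrier contigs) and
#'   optional `hits` (integer vector, features carrying the token per
#'   carrier; default all 1).
#' @return A `genome_model` list.
#' @export
genome_model <- function(label, lineage, gc_mean, coverage_mean,
                         n_contigs, gc_sd = 0.012, coverage_sdlog = 0.15,
                         length_meanlog = log(3000), length_sdlog = 0.5,
                         tokens = list()) {
  stopifnot(gc_mean > 0, gc_mean < 1, coverage_mean > 0, n_contigs >= 1)
  for (tk in tokens) {
    stopifnot(!is.null(tk$token), tk$carriers >= 1, tk$carriers <= n_contigs)
  }
  structure(list(label = label, lineage = lineage, gc_mean = gc_mean,
                 gc_sd = gc_sd, coverage_mean = coverage_mean,
                 coverage_sdlog = coverage_sdlog, n_contigs = n_contigs,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 tokens = tokens),
            class = "genome_model")
}

#' Generate a synthetic metagenome assembly
#'
#' For each model: contig lengths are drawn log-normally (floor 200 bp),
#' each contig's sequence is generated with a per-base GC probability drawn
#' from the model's truncated normal, the coverage metadata column is drawn
#' log-normally, and the lineage string is copied. Gene features (CDS,
#' 300-1500 bp, alternating strands) are tiled along every contig with
#' Pfam-shaped background tokens; planted tokens replace background tokens
#' on the designated carrier contigs. Deterministic for a fixed seed.
#'
#' @param models List of [genome_model()] objects.
#' @param seed Integer seed.
#' @param background_tokens Pool of background Pfam-shaped tokens; kept
#'   disjoint from every planted token.
#' @return List with `table` (`contig_table`: id, length, gc, coverage,
#'   lineage, n_genes), `sequences`, `annotations` and `truth` (list:
#'   `genomes` named contig -> label; `tokens` named list token -> named
#'   integer of planted per-contig feature counts).
#' @export
generate_assembly <- function(models, seed,
                              background_tokens = sprintf("PF9%04d", 1:40)) {
  stopifnot(length(models) >= 1L)
  planted <- unlist(lapply(models, function(m)
    vapply(m$tokens, function(tk) tk$token, "")))
  if (length(intersect(planted, background_tokens)) > 0L) {
    stop("background token pool overlaps planted tokens", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), generate_assembly_impl(
    models, background_tokens))
}

generate_assembly_impl <- function(models, background_tokens) {
  rows <- list(); seqs <- character(0); anns <- list()
  truth_genome <- character(0)
  truth_tokens <- list()
  counter <- 0L

  for (m in models) {
    lens <- pmax(200L, as.integer(round(stats::rlnorm(
      m$n_contigs, meanlog = m$length_meanlog, sdlog = m$length_sdlog))))
    gcs <- pmin(0.99, pmax(0.01, stats::rnorm(m$n_contigs, m$gc_mean, m$gc_sd)))
    covs <- round(stats::rlnorm(m$n_contigs, meanlog = log(m$coverage_mean),
                                sdlog = m$coverage_sdlog), 2)
    ids <- sprintf("contig_%04d", counter + seq_len(m$n_contigs))
    counter <- counter + m$n_contigs

    model_anns <- vector("list", m$n_contigs)
    for (i in seq_len(m$n_contigs)) {
      p <- gcs[i]
      seq <- paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE,
                          prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)),
                   collapse = "")
      seqs[ids[i]] <- seq
      model_anns[[i]] <- tile_genes(ids[i], lens[i], background_tokens)
    }

    # plant tokens on randomly chosen carrier contigs of this genome
    planted_set <- vapply(m$tokens, function(tk) tk$token, character(1))
    for (tk in m$tokens) {
      hits <- if (is.null(tk$hits)) rep(1L, tk$carriers) else as.integer(tk$hits)
      stopifnot(length(hits) == tk$carriers)
      eligible <- which(vapply(model_anns, nrow, 0L) > 0L)
      if (length(eligible) < tk$carriers) {
        stop("not enough gene-bearing contigs to plant token ", tk$token,
             call. = FALSE)
      }
      carriers <- eligible[sample.int(length(eligible), tk$carriers)]
      planted_counts <- integer(0)
      for (ci in seq_along(carriers)) {
        i <- carriers[ci]
        model_anns[[i]] <- plant_token(model_anns[[i]], tk$token, hits[ci],
                                       lens[i], planted_set)
        planted_counts[ids[i]] <- hits[ci]
      }
      truth_tokens[[tk$token]] <- c(truth_tokens[[tk$token]], planted_counts)
    }

    n_genes <- vapply(model_anns, nrow, 0L)
    gc_real <- round(compute_sequence_stats(seqs[ids])$gc, 4)
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = ids, length = lens, gc = gc_real, coverage = covs,
      lineage = rep(if (nzchar(m$lineage)) m$lineage else NA_character_,
                    m$n_contigs),
      n_genes = n_genes,
      stringsAsFactors = FALSE)
    truth_genome[ids] <- m$label
    anns <- c(anns, model_anns)
  }

  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  columns <- data.frame(
    name = c("contig_id", "length", "gc", "coverage", "lineage", "n_genes"),
    kind = c("ordinal", "numeric", "numeric", "numeric", "ordinal", "numeric"),
    role = c("id", "size", "y", "x", "info", "filter"),
    stringsAsFactors = FALSE)
  ann <- do.call(rbind, anns[vapply(anns, nrow, 0L) > 0L])
  if (is.null(ann)) ann <- empty_annotations()
  rownames(ann) <- NULL

  list(table = new_contig_table(data, columns), sequences = seqs,
       annotations = ann,
       truth = list(genomes = truth_genome, tokens = truth_tokens))
}

# tile CDS gene models along a contig, alternating strands
tile_genes <- function(contig_id, len, background_tokens) {
  if (len < 300L) return(empty_annotations())
  starts <- integer(0); ends <- integer(0)
  pos <- 1L + sample.int(100L, 1L)
  while (pos + 299L <= len) {
    glen <- sample(300:1500, 1L)
    end <- min(pos + glen - 1L, len)
    starts <- c(starts, pos); ends <- c(ends, end)
    pos <- end + sample(20:200, 1L)
  }
  n <- length(starts)
  if (n == 0L) return(empty_annotations())
  ann <- data.frame(
    contig_id = rep(contig_id, n), source = rep("sim", n),
    type = rep("CDS", n), start = starts, end = ends,
    score = rep(".", n), strand = rep(c("+", "-"), length.out = n),
    phase = rep("0", n), stringsAsFactors = FALSE)
  toks <- sample(background_tokens, n, replace = TRUE)
  ann$attributes <- lapply(seq_len(n), function(i) {
    c(ID = paste0(contig_id, "_g", i),
      product = "hypothetical protein",
      pfam = toks[i])
  })
  ann
}

# overwrite the pfam attribute of `hits` features (append extra features if
# the contig has too few genes); never claims a feature already carrying a
# planted token of another family
plant_token <- function(ann, token, hits, len, planted_set) {
  n <- nrow(ann)
  free <- which(!vapply(ann$attributes, function(a) a[["pfam"]], "") %in%
                  planted_set)
  take <- min(hits, length(free))
  slots <- free[sample.int(length(free), take)]
  for (i in slots) ann$attributes[[i]][["pfam"]] <- token
  extra <- hits - take
  if (extra > 0L) {
    for (j in seq_len(extra)) {
      add <- ann[n, , drop = FALSE]
      add$start <- max(1L, len - 120L * j)
      add$end <- len
      add$attributes <- list(c(ID = paste0(ann$contig_id[1L], "_gx", j),
                               product = "hypothetical protein",
                               pfam = token))
      ann <- rbind(ann, add)
    }
  }
  ann
}

#' Genome models behind the demo community
#'
#' Six methane-cycle archaeal-like genomes with well-separated GC and
#' coverage centroids, plus a short low-coverage unclassified background
#' and one very large, extremely over-represented contig (a mobile-element
#' stand-in).
#' @return Named list: `genomes` (the six binnable models), `background`,
#'   `outlier`.
#' @export
demo_models <- function() {
  lin <- function(...) paste(c("Archaea", ...), collapse = ";")
  tokens7 <- list(  # seven Pfam-shaped token families, methane-cycle style
    list(token = "PF00810", carriers = 4L),
    list(token = "PF01282", carriers = 3L, hits = c(2L, 1L, 1L)),
    list(token = "PF02007", carriers = 4L),
    list(token = "PF02240", carriers = 3L, hits = c(3L, 1L, 1L)),
    list(token = "PF02289", carriers = 3L),
    list(token = "PF02745", carriers = 4L, hits = c(2L, 2L, 1L, 1L)),
    list(token = "PF04208", carriers = 4L, hits = c(2L, 1L, 1L, 1L)))
  split_tokens <- function(idx) tokens7[idx]
  genomes <- list(
    genome_model("bin_1", lin("Euryarchaeota", "Methanomicrobia",
                              "Methanosarcinales", "ANME-2", "ANME-2 sp. A"),
                 gc_mean = 0.34, coverage_mean = 30, n_contigs = 50L,
                 length_meanlog = log(8000), tokens = split_tokens(1)),
    genome_model("bin_2", lin("Euryarchaeota", "Methanomicrobia",
                              "Methanosarcinales", "ANME-2", "ANME-2 sp. B"),
                 gc_mean = 0.42, coverage_mean = 120, n_contigs = 50L,
                 length_meanlog = log(8000), tokens = split_tokens(2)),
    genome_model("bin_3", lin("Euryarchaeota", "Methanomicrobia",
                              "Methanomicrobiales", "Methanoculleus",
                              "Methanoculleus sp."),
                 gc_mean = 0.50, coverage_mean = 40, n_contigs = 50L,
                 length_meanlog = log(8000), tokens = split_tokens(3)),
    genome_model("bin_4", lin("Euryarchaeota", "Methanobacteria",
                              "Methanobacteriales", "Methanobacterium",
                              "Methanobacterium sp."),
                 gc_mean = 0.58, coverage_mean = 200, n_contigs = 50L,
                 length_meanlog = log(8000), tokens = split_tokens(c(4, 5))),
    genome_model("bin_5", lin("Euryarchaeota", "ANME-1", "ANME-1 cluster",
                              "ANME-1 sp."),
                 gc_mean = 0.66, coverage_mean = 60, n_contigs = 50L,
                 length_meanlog = log(8000), tokens = split_tokens(6)),
    genome_model("bin_6", lin("Euryarchaeota", "Methanococci",
                              "Methanococcales", "Methanococcus",
                              "Methanococcus sp."),
                 gc_mean = 0.45, coverage_mean = 300, n_contigs = 50L,
                 length_meanlog = log(8000), tokens = split_tokens(7)))
  background <- genome_model("background", lineage = "", gc_mean = 0.50,
                             gc_sd = 0.08, coverage_mean = 5,
                             coverage_sdlog = 0.4, n_contigs = 60L,
                             length_meanlog = log(800), length_sdlog = 0.4)
  outlier <- genome_model("bin_6", lin("Euryarchaeota", "Methanococci",
                                       "Methanococcales", "Methanococcus",
                                       "Methanococcus sp."),
                          gc_mean = 0.45, gc_sd = 0.005,
                          coverage_mean = 3051, coverage_sdlog = 0.001,
                          n_contigs = 1L,
                          length_meanlog = log(44000), length_sdlog = 0)
  list(genomes = genomes, background = background, outlier = outlier)
}

#' Generate the demo community dataset
#'
#' A canned configuration emulating a seep-sediment community at desk
#' scale: six archaeal genomes separable by GC and coverage, a short
#' low-coverage unclassified background, one 44 kb contig at ~3051x
#' coverage, and seven planted Pfam-shaped token families with known
#' single- and multi-hit carriers.
#'
#' @param seed Integer seed (default 1).
#' @return List with `dataset` (an `mg_dataset` with sequences and
#'   annotations attached), `truth` and `models` (as in [demo_models()]).
#' @export
demo_assembly <- function(seed = 1L) {
  m <- demo_models()
  gen <- generate_assembly(c(m$genomes, list(m$background, m$outlier)),
                           seed = seed)
  ds <- make_dataset(gen$table, gen$sequences, gen$annotations)
  list(dataset = ds, truth = gen$truth, models = m)
}

#' Rectangular gates around genome-model centroids
#'
#' GC bounds are `gc_mean +/- n_sd * gc_sd`; coverage bounds are
#' `coverage_mean * exp(+/- n_sd * coverage_sdlog)` (log-normal model).
#' @param models List of [genome_model()] objects (one gate per model).
#' @param n_sd Half-width in SDs (default 3).
#' @return List of [gate_rect()] objects.
#' @export
model_gates <- function(models, n_sd = 3) {
  lapply(models, function(m) {
    gate_rect(m$label,
              gc_min = m$gc_mean - n_sd * m$gc_sd,
              gc_max = m$gc_mean + n_sd * m$gc_sd,
              cov_min = m$coverage_mean * exp(-n_sd * m$coverage_sdlog),
              cov_max = m$coverage_mean * exp(n_sd * m$coverage_sdlog))
  })
}

#' Genome models spanning a rich taxonomy
#'
#' A deterministic survey of 2 domains x 3 phyla x 4 genera x 5 species =
#' 120 species-level lineages (6 phyla), two contigs per species; used to
#' exercise the taxonomy collapse on a tree far wider than the group cap.
#' @param n_contigs Contigs per species (default 2).
#' @return List of 120 [genome_model()] objects.
#' @export
taxonomy_survey_models <- function(n_contigs = 2L) {
  models <- list()
  for (d in 1:2) for (p in 1:3) for (g in 1:4) for (s in 1:5) {
    lineage <- sprintf("Domain_%d;Phylum_%d_%d;Genus_%d_%d_%d;Species_%d_%d_%d_%d",
                       d, d, p, d, p, g, d, p, g, s)
    models[[length(models) + 1L]] <- genome_model(
      label = sprintf("sp_%d_%d_%d_%d", d, p, g, s), lineage = lineage,
      gc_mean = 0.5, coverage_mean = 10, n_contigs = n_contigs,
      length_meanlog = log(500), length_sdlog = 0)
  }
  models
}

#' Write a generated assembly to disk
#'
#' Emits the same dialects the ingest functions read: `metadata.csv`,
#' `contigs.fasta`, `annotations.gff`, `truth_genomes.csv` and
#' `truth_tokens.csv`.
#' @param gen Output of [generate_assembly()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assembly <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metadata_table(gen$table, file.path(dir, "metadata.csv"))
  write_fasta(gen$sequences, file.path(dir, "contigs.fasta"))
  ds <- make_dataset(gen$table, gen$sequences, gen$annotations)
  sel <- new_selection(contig_ids(ds), "all contigs")
  export_subset(ds, sel, "gff", file.path(dir, "annotations.gff"))
  utils::write.csv(
    data.frame(contig_id = names(gen$truth$genomes),
               genome = unname(gen$truth$genomes), stringsAsFactors = FALSE),
    file.path(dir, "truth_genomes.csv"), row.names = FALSE)
  tok <- gen$truth$tokens
  tok_df <- do.call(rbind, lapply(names(tok), function(t)
    data.frame(token = t, contig_id = names(tok[[t]]),
               planted_hits = unname(tok[[t]]), stringsAsFactors = FALSE)))
  if (is.null(tok_df)) {
    tok_df <- data.frame(token = character(0), contig_id = character(0),
                         planted_hits = integer(0))
  }
  utils::write.csv(tok_df, file.path(dir, "truth_tokens.csv"),
                   row.names = FALSE)
  invisible(dir)
}
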