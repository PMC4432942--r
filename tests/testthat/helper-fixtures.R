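# Shared fixtures (generated once per test run) and small builders.

.fixture_cache <- new.env(parent = emptyenv())

demo_fixture <- function() {
  if (is.null(.fixture_cache$demo)) .fixture_cache$demo <- demo_assembly(seed = 1)
  .fixture_cache$demo
}

survey_fixture <- function() {
  if (is.null(.fixture_cache$survey)) {
    gen <- generate_assembly(taxonomy_survey_models(), seed = 1)
    .fixture_cache$survey <- make_dataset(gen$table, gen$sequences,
                                          gen$annotations)
  }
  .fixture_cache$survey
}

# tiny typed contig table without going through a file
tiny_table <- function(df) {
  kinds <- vapply(df, function(col) if (is.numeric(col)) "numeric" else
                  "ordinal", "")
  contigscape:::new_contig_table(
    df, data.frame(name = names(df), kind = unname(kinds),
                   role = c("id", rep("info", ncol(df) - 1L)),
                   stringsAsFactors = FALSE))
}

tiny_dataset <- function(df, sequences = NULL, annotations = NULL) {
  make_dataset(tiny_table(df), sequences, annotations)
}

# build a taxonomy tree directly from lineage strings (one contig each,
# repeats allowed)
tree_from_strings <- function(lineages, ids = sprintf("c%d", seq_along(lineages))) {
  lin <- lapply(lineages, function(x) parse_lineage(x))
  names(lin) <- ids
  contigscape:::build_tree_from_lineages(lin)
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
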