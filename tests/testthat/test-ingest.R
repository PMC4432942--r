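test_that("delimited tables parse with inferred column kinds", {
  f <- write_lines_tmp(c("id,gc,taxon", "c1,0.51,Bacteria", "c2,0.62,Archaea"))
  tab <- read_metadata_table(f)
  expect_equal(tab$columns$name, c("id", "gc", "taxon"))
  expect_equal(tab$columns$kind, c("ordinal", "numeric", "ordinal"))
  expect_equal(tab$columns$role, rep("info", 3))
  expect_equal(nrow(tab$data), 2L)
  expect_identical(tab$data$gc, c(0.51, 0.62))
})

test_that("comma and tab dialects parse to equal tables", {
  fc <- write_lines_tmp(c("id,gc,taxon", "c1,0.51,Bacteria", "c2,0.62,Archaea"))
  ft <- write_lines_tmp(c("id\tgc\ttaxon", "c1\t0.51\tBacteria",
                          "c2\t0.62\tArchaea"), ext = ".tsv")
  expect_equal(read_metadata_table(fc, "auto"), read_metadata_table(ft, "auto"))
  expect_equal(read_metadata_table(ft, "tab"), read_metadata_table(fc))
})

test_that("malformed tables are rejected with informative errors", {
  expect_error(read_metadata_table(write_lines_tmp(character(0))), "empty")
  expect_error(read_metadata_table(write_lines_tmp(c("id,id", "a,b"))),
               "duplicate column")
  f <- write_lines_tmp(c("id,gc", "c1,0.5", "c2,0.6,extra"))
  expect_error(read_metadata_table(f), "row 3")
  # dialect tie: one tab and one comma in the header
  f2 <- write_lines_tmp(c("id,a\tb", "c1,1\t2"))
  expect_error(read_metadata_table(f2, "auto"), "delimiter")
})

test_that("numeric detection accepts scientific notation, rejects separators", {
  f <- write_lines_tmp(c("id,a,b", "c1,1e5,\"1,000\"", "c2,-2.5e-3,\"2,000\""))
  tab <- read_metadata_table(f)
  expect_equal(tab$columns$kind, c("ordinal", "numeric", "ordinal"))
  expect_equal(tab$data$a, c(1e5, -2.5e-3))
})

test_that("missing cells become NA and leave kinds intact", {
  f <- write_lines_tmp(c("id,cov,tax", "c1,10,", "c2,NA,Bacteria", "c3,3,X"))
  tab <- read_metadata_table(f)
  expect_equal(tab$columns$kind, c("ordinal", "numeric", "ordinal"))
  expect_identical(tab$data$cov, c(10, NA, 3))
  expect_identical(tab$data$tax, c(NA, "Bacteria", "X"))
})

test_that("role assignment auto-fills filters on unmapped numeric columns", {
  df <- data.frame(id = c("c1", "c2"), gc = c(0.4, 0.5), cov = c(10, 20),
                   len = c(100, 200), taxon = c("A", "B"),
                   stringsAsFactors = FALSE)
  tab <- tiny_table(df)
  ds <- assign_roles(tab, c(id = "id", gc = "y", cov = "x", len = "size"))
  roles <- setNames(ds$table$columns$role, ds$table$columns$name)
  expect_equal(unname(roles["taxon"]), "info")
  expect_false(any(roles == "filter"))

  df$n_genes <- c(3, 5)
  ds2 <- assign_roles(tiny_table(df),
                      c(id = "id", gc = "y", cov = "x", len = "size"))
  roles2 <- setNames(ds2$table$columns$role, ds2$table$columns$name)
  expect_equal(unname(roles2["n_genes"]), "filter")
})

test_that("role assignment validates id and axis columns", {
  df <- data.frame(id = c("c1", "c2"), gc = c("x", "y"), cov = c(1, 2),
                   stringsAsFactors = FALSE)
  tab <- tiny_table(df)
  expect_error(assign_roles(tab, c(gc = "x", id = "id")), "not numeric")
  expect_error(assign_roles(tab, c(cov = "x")), "role 'id'")
  dup <- tiny_table(data.frame(id = c("c1", "c1"), v = c(1, 2),
                               stringsAsFactors = FALSE))
  expect_error(assign_roles(dup, c(id = "id")), "duplicate")
})

test_that("sequence stats follow the unambiguous-base GC definition", {
  st <- compute_sequence_stats(c(a = "GGCC", b = "ATATN", c = "NNNN"))
  expect_equal(st$length, c(4L, 5L, 4L))
  expect_equal(st$gc, c(1.0, 0.0, NA))
  expect_error(compute_sequence_stats(c(a = "")), "empty sequence")
})

test_that("GC is invariant under case change and reversal", {
  withr::with_seed(7, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T", "N", "R"), 50, TRUE),
                 collapse = "")
      base <- compute_sequence_stats(c(x = s))$gc
      lower <- compute_sequence_stats(c(x = tolower(s)))$gc
      rev <- compute_sequence_stats(
        c(x = paste(rev(strsplit(s, "")[[1]]), collapse = "")))$gc
      expect_equal(lower, base)
      expect_equal(rev, base)
    }
  })
})

test_that("GFF3 features parse with coordinates, strand and attributes", {
  f <- write_lines_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tCDS\t10\t300\t.\t+\t0\tID=g1;product=hypothetical protein",
    "c1\tsrc\tCDS\t400\t500\t.\t-\t0\tID=g2;pfam=PF00880"), ext = ".gff")
  ann <- read_annotations(f)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$strand, c("+", "-"))
  expect_equal(ann$start, c(10L, 400L))
  expect_equal(ann$attributes[[1]][["product"]], "hypothetical protein")
  expect_equal(ann$attributes[[2]][["pfam"]], "PF00880")
})

test_that("GFF errors carry the offending line number", {
  f <- write_lines_tmp(c("##gff-version 3",
                         "c1\tsrc\tCDS\t300\t10\t.\t+\t0\tID=g1"),
                       ext = ".gff")
  expect_error(read_annotations(f), "line 2.*start=300 end=10")
  f2 <- write_lines_tmp(c("c1\tsrc\tCDS\tten\t20\t.\t+\t0\tID=g1"),
                        ext = ".gff")
  expect_error(read_annotations(f2), "line 1.*non-integer")
  f3 <- write_lines_tmp(c("c1\tsrc\tCDS\t1\t20\t.\t+\t0"), ext = ".gff")
  expect_error(read_annotations(f3), "9 tab-separated")
})

test_that("attribute escaping survives a GFF round trip", {
  ann <- data.frame(contig_id = "c1", source = "s", type = "CDS",
                    start = 1L, end = 10L, score = ".", strand = "+",
                    phase = "0", stringsAsFactors = FALSE)
  ann$attributes <- list(c(ID = "g1", note = "a;b=c%d"))
  ds <- tiny_dataset(data.frame(id = "c1", v = 1, stringsAsFactors = FALSE),
                     annotations = ann)
  f <- withr::local_tempfile(fileext = ".gff")
  export_subset(ds, contigscape:::new_selection("c1", "t"), "gff", f)
  back <- read_annotations(f)
  expect_identical(back$attributes[[1]][["note"]], "a;b=c%d")
})

test_that("dataset assembly cross-validates components", {
  df <- data.frame(id = c("c1", "c2"), v = c(1, 2), stringsAsFactors = FALSE)
  seqs <- c(c1 = "ACGT", c2 = "GGCC")
  ann <- data.frame(contig_id = "c1", source = "s", type = "CDS", start = 1L,
                    end = 4L, score = ".", strand = "+", phase = "0",
                    stringsAsFactors = FALSE)
  ann$attributes <- list(c(ID = "g1"))
  ds <- tiny_dataset(df, seqs, ann)
  expect_s3_class(ds, "mg_dataset")
  expect_equal(length(ds$sequences), 2L)

  expect_error(tiny_dataset(df[1, ], seqs), "c2")
  ds2 <- tiny_dataset(df)
  expect_null(ds2$sequences)
  expect_null(ds2$annotations)
  expect_warning(tiny_dataset(df, annotations = transform(ann, contig_id = "cX")),
                 "1 feature.*cX")
})

test_that("metadata tables survive a write/read round trip in both dialects", {
  demo <- demo_fixture()
  tab <- demo$dataset$table
  fc <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_metadata_table(tab, fc, "comma")
  write_metadata_table(tab, ft, "tab")
  back_c <- read_metadata_table(fc)
  back_t <- read_metadata_table(ft)
  expect_equal(back_c$data, tab$data)
  expect_equal(back_c$columns$kind, tab$columns$kind)
  expect_equal(back_t$data, back_c$data)
})

test_that("sequence-derived stats fill metadata columns", {
  df <- data.frame(id = c("c1", "c2"), stringsAsFactors = FALSE)
  ds <- tiny_dataset(df, c(c1 = "GGCC", c2 = "ATAT"))
  ds <- add_sequence_stats(ds)
  expect_equal(ds$table$data$gc, c(1, 0))
  expect_equal(ds$table$data$length, c(4L, 4L))
  kinds <- setNames(ds$table$columns$kind, ds$table$columns$name)
  expect_equal(unname(kinds[c("length", "gc")]), c("numeric", "numeric"))
})
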