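viz_fixture <- function(lengths = c(1000, 4000, 2000),
                        coverage = c(10, 100, 0)) {
  df <- data.frame(id = paste0("c", seq_along(lengths)),
                   length = lengths, gc = seq(0.3, 0.6,
                                              length.out = length(lengths)),
                   coverage = coverage,
                   lineage = rep("Bacteria;Proteo", length(lengths)),
                   stringsAsFactors = FALSE)
  tiny_dataset(df)
}

viz_partition <- function(ds) {
  collapse_to_groups(build_taxonomy_tree(ds, "lineage"), k_max = 5)
}

test_that("mark area is proportional to the size value", {
  ds <- viz_fixture(lengths = c(1000, 4000), coverage = c(10, 100))
  part <- viz_partition(ds)
  spec <- build_plot_spec(ds, axis_spec("coverage"), axis_spec("gc"),
                          "length", part, ordinal_colors(part$groups),
                          r_min = 2, r_max = 40)
  off <- spec$marks$radius - 2
  # lengths L and 4L: radius offsets in sqrt ratio 1:2
  expect_equal(off[2] / off[1], 2, tolerance = 1e-12)
  expect_true(all(spec$marks$radius >= 2 & spec$marks$radius <= 40))
})

test_that("log axes drop non-positive values with an accounted count", {
  ds <- viz_fixture()  # c3 has coverage 0
  part <- viz_partition(ds)
  spec <- build_plot_spec(ds, axis_spec("coverage", "log10"), axis_spec("gc"),
                          "length", part, ordinal_colors(part$groups))
  expect_equal(nrow(spec$marks), 2L)
  expect_equal(spec$counts$dropped_log, 1L)
  expect_false("c3" %in% spec$marks$contig_id)
})

test_that("search hits are outlined on exactly the planted contigs", {
  demo <- demo_fixture()
  ds <- demo$dataset
  part <- collapse_to_groups(build_taxonomy_tree(ds, "lineage"))
  res <- search_dataset(ds, "PF02007")
  spec <- build_plot_spec(ds, axis_spec("coverage", "log10"),
                          axis_spec("gc"), "length", part,
                          ordinal_colors(part$groups), search = res)
  outlined <- spec$marks$contig_id[spec$marks$outlined]
  expect_setequal(outlined, names(demo$truth$tokens[["PF02007"]]))
})

test_that("mark counts conserve: marks + filtered + hidden + dropped = total", {
  demo <- demo_fixture()
  ds <- demo$dataset
  part <- collapse_to_groups(build_taxonomy_tree(ds, "lineage"))
  scheme <- ordinal_colors(part$groups)
  withr::with_seed(13, {
    for (i in 1:10) {
      sel <- apply_filters(ds, list(
        filter_range("length", min = stats::runif(1, 200, 5000)),
        filter_range("gc", max = stats::runif(1, 0.3, 0.9))))
      hidden <- sample(part$groups, sample(0:3, 1))
      scale <- sample(c("linear", "log10"), 1)
      spec <- build_plot_spec(ds, axis_spec("coverage", scale),
                              axis_spec("gc"), "length", part, scheme,
                              selection = sel, hidden_groups = hidden)
      with(spec$counts,
           expect_equal(marks + filtered_out + hidden + dropped_log, total))
    }
  })
})

test_that("plot spec validates its inputs", {
  ds <- viz_fixture()
  part <- viz_partition(ds)
  scheme <- ordinal_colors(part$groups)
  expect_error(build_plot_spec(ds, axis_spec("lineage"), axis_spec("gc"),
                               "length", part, scheme), "not numeric")
  empty <- tiny_dataset(data.frame(id = character(0), v = numeric(0),
                                   stringsAsFactors = FALSE))
  ep <- structure(list(groups = character(0),
                       assignment = setNames(character(0), character(0)),
                       k_max = 5L, frontier = NULL),
                  class = "taxon_partition")
  expect_error(build_plot_spec(empty, axis_spec("v"), axis_spec("v"), "v",
                               ep, scheme), "empty dataset")
})

test_that("gradient-colored plots require and use the color column", {
  ds <- viz_fixture(coverage = c(10, 100, 50))
  part <- viz_partition(ds)
  grad <- contigscape:::new_color_scheme(
    "gradient", character(0), endpoints = c("#000000", "#FF0000"))
  expect_error(build_plot_spec(ds, axis_spec("coverage"), axis_spec("gc"),
                               "length", part, grad), "color_column")
  spec <- build_plot_spec(ds, axis_spec("coverage"), axis_spec("gc"),
                          "length", part, grad, color_column = "coverage")
  expect_equal(spec$marks$color[ds$table$data$coverage == 10], "#000000")
  expect_equal(spec$marks$color[ds$table$data$coverage == 100], "#FF0000")
})

track_fixture <- function(starts, ends, strands = NULL) {
  n <- length(starts)
  if (is.null(strands)) strands <- rep(c("+", "-"), length.out = n)
  ann <- data.frame(contig_id = rep("c1", n), source = "s", type = "CDS",
                    start = as.integer(starts), end = as.integer(ends),
                    score = ".", strand = strands, phase = "0",
                    stringsAsFactors = FALSE)
  ann$attributes <- lapply(seq_len(n), function(i) c(ID = paste0("g", i)))
  tiny_dataset(data.frame(id = c("c1", "c2"), length = c(1000, 500),
                          stringsAsFactors = FALSE), annotations = ann)
}

test_that("track glyphs take lanes greedily without overlap", {
  ds <- track_fixture(c(1, 200, 400), c(100, 300, 500))
  tr <- build_contig_track(ds, "c1")
  expect_equal(tr$glyphs$lane, c(0L, 0L, 0L))

  ds2 <- track_fixture(c(1, 50), c(100, 150))
  tr2 <- build_contig_track(ds2, "c1")
  expect_equal(sort(tr2$glyphs$lane), c(0L, 1L))

  # property: no two glyphs in one lane overlap (inclusive coordinates)
  withr::with_seed(21, {
    starts <- sort(sample(1:900, 25))
    ends <- pmin(1000L, starts + sample(10:200, 25, replace = TRUE))
    tr3 <- build_contig_track(track_fixture(starts, ends), "c1")
    g <- tr3$glyphs
    for (lane in unique(g$lane)) {
      gl <- g[g$lane == lane, ]
      gl <- gl[order(gl$start), ]
      if (nrow(gl) > 1) expect_true(all(gl$start[-1] > gl$end[-nrow(gl)]))
    }
  })
})

test_that("track windows use the inclusive overlap rule", {
  ds <- track_fixture(c(150, 500), c(400, 600))
  tr <- build_contig_track(ds, "c1", window = c(100, 200))
  expect_equal(nrow(tr$glyphs), 1L)
  expect_equal(tr$glyphs$start, 150L)

  # default window spans the whole contig (length column)
  tr_all <- build_contig_track(ds, "c1")
  expect_equal(tr_all$window, c(1, 1000))
  expect_equal(nrow(tr_all$glyphs), 2L)

  # strand orientation mapping
  expect_equal(tr_all$glyphs$orientation,
               ifelse(tr_all$glyphs$strand == "-", "reverse", "forward"))
})

test_that("tracks handle empty and unknown contigs per contract", {
  ds <- track_fixture(1, 100)
  tr <- build_contig_track(ds, "c2")  # no features: not an error
  expect_equal(nrow(tr$glyphs), 0L)
  expect_error(build_contig_track(ds, "cX"), "unknown contig")
  no_ann <- tiny_dataset(data.frame(id = "c1", stringsAsFactors = FALSE))
  expect_error(build_contig_track(no_ann, "c1"), "no annotations")
})

test_that("rendered HTML embeds the full payload deterministically", {
  demo <- demo_fixture()
  ds <- demo$dataset
  part <- collapse_to_groups(build_taxonomy_tree(ds, "lineage"))
  sel <- contigscape:::new_selection(contig_ids(ds)[1:100], "first 100")
  spec <- build_plot_spec(ds, axis_spec("coverage", "log10"),
                          axis_spec("gc"), "length", part,
                          ordinal_colors(part$groups), selection = sel)
  f1 <- withr::local_tempfile(fileext = ".html")
  f2 <- withr::local_tempfile(fileext = ".html")
  out <- render_html(spec, f1)
  expect_true(file.exists(f1))
  payload <- jsonlite::fromJSON(read_html_payload(f1))
  expect_equal(nrow(payload$marks), nrow(spec$marks))
  expect_equal(payload$marks$contig_id, spec$marks$contig_id)

  render_html(spec, f2)
  expect_identical(read_html_payload(f1), read_html_payload(f2))
})

test_that("empty plots and track specs still render valid documents", {
  ds <- viz_fixture()
  part <- viz_partition(ds)
  spec <- build_plot_spec(ds, axis_spec("coverage"), axis_spec("gc"),
                          "length", part, ordinal_colors(part$groups),
                          selection = contigscape:::new_selection(character(0),
                                                                  "none"))
  expect_equal(nrow(spec$marks), 0L)
  f <- withr::local_tempfile(fileext = ".html")
  render_html(spec, f)
  payload <- jsonlite::fromJSON(read_html_payload(f))
  expect_equal(payload$counts$marks, 0L)

  tr <- build_contig_track(track_fixture(1, 100), "c1")
  ft <- withr::local_tempfile(fileext = ".html")
  render_html(tr, ft)
  tp <- jsonlite::fromJSON(read_html_payload(ft))
  expect_equal(tp$kind, "contig_track")
})
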