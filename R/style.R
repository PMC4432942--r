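# Deterministic color assignment: ordinal palettes, statistical (quantile)
# binning, and gradient heat-map coloring.

#' Default qualitative palette
#'
#' A fixed list of 20 qualitative colors used for taxon groups; labels
#' beyond the palette length wrap around.
#' @return Character vector of 20 hex colors.
#' @export
default_palette <- function() {
  c("#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD",
    "#8C564B", "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF",
    "#AEC7E8", "#FFBB78", "#98DF8A", "#FF9896", "#C5B0D5",
    "#C49C94", "#F7B6D2", "#C7C7C7", "#DBDB8D", "#9EDAE5")
}

new_color_scheme <- function(mode, mapping, bin_edges = NULL,
                             endpoints = NULL, range = NULL) {
  structure(list(mode = mode, mapping = mapping, bin_edges = bin_edges,
                 endpoints = endpoints, range = range),
            class = "color_scheme")
}

#' @export
print.color_scheme <- function(x, ...) {
  cat(sprintf("<color_scheme> mode=%s, %d entries\n", x$mode,
              length(x$mapping)))
  invisible(x)
}

#' Assign colors to ordinal labels
#'
#' Label `i` receives `palette[(i - 1) %% length(palette) + 1]`;
#' deterministic across runs.
#'
#' @param labels Ordered character vector of labels.
#' @param palette Non-empty character vector of hex colors.
#' @return A `color_scheme` with `mode = "ordinal"` and a named
#'   label -> color `mapping` (empty for an empty label list).
#' @export
ordinal_colors <- function(labels, palette = default_palette()) {
  stopifnot(length(palette) >= 1L)
  if (length(labels) == 0L) {
    return(new_color_scheme("ordinal", stats::setNames(character(0), character(0))))
  }
  cols <- palette[(seq_along(labels) - 1L) %% length(palette) + 1L]
  new_color_scheme("ordinal", stats::setNames(cols, labels))
}

#' Equal-frequency (quantile) bin edges
#'
#' Interior edges are the `ceiling(j * n / k)`-th order statistics
#' (nearest rank) for `j = 1..k-1`, deduplicated and stripped of edges
#' equal to the extremes. Bins are left-open right-closed except the first,
#' so every value falls in exactly one bin; see [assign_bins()].
#'
#' @param values Numeric vector; missing values are ignored.
#' @param k Number of bins, `>= 1`.
#' @return Strictly ascending numeric vector of interior edges (length
#'   `<= k - 1`; may be shorter when values repeat).
#' @export
quantile_bins <- function(values, k) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (n == 0L) stop("no non-missing values", call. = FALSE)
  if (k == 1L) return(numeric(0))
  j <- seq_len(k - 1L)
  edges <- v[ceiling(j * n / k)]
  edges <- unique(edges)
  edges[edges > v[1L] & edges < v[n]]
}

#' Equal-width bin edges
#'
#' `k - 1` interior edges evenly spaced over the observed range; offered as
#' an alternative to [quantile_bins()].
#' @inheritParams quantile_bins
#' @return Strictly ascending numeric vector of interior edges.
#' @export
width_bins <- function(values, k) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("no non-missing values", call. = FALSE)
  r <- range(v)
  if (k == 1L || r[1L] == r[2L]) return(numeric(0))
  seq(r[1L], r[2L], length.out = k + 1L)[2:k]
}

#' Assign values to bins delimited by interior edges
#'
#' Bin 1 is `(-Inf, e1]` over observed values (so it is closed at the
#' observed minimum); bin `i > 1` is `(e_{i-1}, e_i]`; the last bin is open
#' above. Missing values get `NA`.
#' @param values Numeric vector.
#' @param edges Ascending interior edges from [quantile_bins()] or
#'   [width_bins()].
#' @return Integer bin index in `1..(length(edges) + 1)`.
#' @export
assign_bins <- function(values, edges) {
  if (length(edges) == 0L) return(ifelse(is.na(values), NA_integer_, 1L))
  as.integer(cut(values, breaks = c(-Inf, edges, Inf), right = TRUE,
                 labels = FALSE))
}

#' Binned color scheme for a quantitative column
#'
#' Statistical binning of the values (equal-frequency by default), one
#' palette color per bin.
#' @param values Numeric vector.
#' @param k Number of bins.
#' @param palette Colors to cycle over bins.
#' @param method `"quantile"` (default) or `"width"`.
#' @return A `color_scheme` with `mode = "binned"`, `bin_edges`, and a
#'   bin-index -> color mapping.
#' @export
binned_colors <- function(values, k, palette = default_palette(),
                          method = c("quantile", "width")) {
  method <- match.arg(method)
  edges <- if (method == "quantile") quantile_bins(values, k)
           else width_bins(values, k)
  n_bins <- length(edges) + 1L
  cols <- palette[(seq_len(n_bins) - 1L) %% length(palette) + 1L]
  new_color_scheme("binned", stats::setNames(cols, as.character(seq_len(n_bins))),
                   bin_edges = edges)
}

hex_to_rgb <- function(hex) grDevices::col2rgb(hex)[, 1L]

rgb_to_hex <- function(r, g, b) {
  sprintf("#%02X%02X%02X", as.integer(round(r)), as.integer(round(g)),
          as.integer(round(b)))
}

#' Gradient (heat-map) colors over a value range
#'
#' Linear channel-wise interpolation between `low` and `high` across the
#' observed `[min, max]`: the minimum maps exactly to `low`, the maximum
#' exactly to `high`; a constant column maps everything to `low`. Missing
#' values get `NA`.
#'
#' @param values Numeric vector.
#' @param low,high Hex colors for the range endpoints.
#' @return Character vector of hex colors aligned with `values`, with the
#'   value range in attribute `"range"` and endpoints in `"endpoints"`.
#' @export
gradient_colors <- function(values, low = "#2166AC", high = "#B2182B") {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("no non-missing values", call. = FALSE)
  lo <- hex_to_rgb(low); hi <- hex_to_rgb(high)
  rng <- range(v)
  t <- if (rng[1L] == rng[2L]) rep(0, length(values))
       else (values - rng[1L]) / (rng[2L] - rng[1L])
  out <- rep(NA_character_, length(values))
  ok <- !is.na(values)
  out[ok] <- rgb_to_hex(lo[1L] + t[ok] * (hi[1L] - lo[1L]),
                        lo[2L] + t[ok] * (hi[2L] - lo[2L]),
                        lo[3L] + t[ok] * (hi[3L] - lo[3L]))
  attr(out, "range") <- rng
  attr(out, "endpoints") <- c(low = low, high = high)
  out
}

#' Write a color scheme as CSV
#' @param scheme A `color_scheme`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_color_scheme <- function(scheme, path) {
  df <- data.frame(label = names(scheme$mapping),
                   color = unname(scheme$mapping), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
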