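# Declarative bubble-plot and contig-track specifications, and their
# rendering to a standalone interactive HTML document. The tested contract
# is the spec payload, not pixels.

#' Describe a plot axis
#'
#' @param column Numeric column name.
#' @param scale `"linear"` or `"log10"`. On a log10 axis, contigs with a
#'   non-positive value are dropped (counted, not silently lost).
#' @param range Optional fixed `c(lo, hi)`; default auto.
#' @return An `axis_spec` list.
#' @export
axis_spec <- function(column, scale = c("linear", "log10"), range = NULL) {
  scale <- match.arg(scale)
  structure(list(column = column, scale = scale, range = range),
            class = "axis_spec")
}

#' Build a bubble-plot specification
#'
#' One mark per visible contig, positioned by the x/y axis columns, sized by
#' `size_column` and colored by taxon group (or by a quantitative column
#' under a binned/gradient scheme). Mark *area* is proportional to the size
#' value: `radius = r_min + (r_max - r_min) * sqrt(v / v_max)`. Contigs are
#' removed, in order, by the selection (range filters), by hidden groups,
#' and by the log-axis drop rule (non-positive or missing axis/size
#' values); each removal is counted so that
#' `marks + filtered_out + hidden + dropped = total`.
#'
#' @param dataset An `mg_dataset`.
#' @param x,y [axis_spec()] objects over numeric columns.
#' @param size_column Numeric column controlling mark size.
#' @param partition A `taxon_partition` supplying groups.
#' @param scheme A `color_scheme`; `mode = "ordinal"` maps groups,
#'   `"binned"`/`"gradient"` require `color_column`.
#' @param selection Optional `mg_selection` restricting the plotted contigs.
#' @param hidden_groups Groups hidden via the legend.
#' @param search Optional `search_result`; hit contigs are outlined.
#' @param color_column Quantitative column for binned/gradient coloring.
#' @param r_min,r_max Radius clamp in display units (defaults 2 and 40).
#' @param title Plot title.
#' @return A `plot_spec`: axes, `marks` data.frame (contig_id, x, y, radius,
#'   color, group, outlined, emphasized plus hover columns), `legend`
#'   data.frame, `counts` list and `hover_columns`.
#' @export
build_plot_spec <- function(dataset, x, y, size_column, partition, scheme,
                            selection = NULL, hidden_groups = character(0),
                            search = NULL, color_column = NULL,
                            r_min = 2, r_max = 40, title = "") {
  stopifnot(inherits(dataset, "mg_dataset"), inherits(x, "axis_spec"),
            inherits(y, "axis_spec"), inherits(partition, "taxon_partition"),
            inherits(scheme, "color_scheme"))
  tab <- dataset$table
  if (nrow(tab$data) == 0L) stop("empty dataset", call. = FALSE)
  for (col in c(x$column, y$column, size_column)) {
    j <- match(col, tab$columns$name)
    if (is.na(j)) stop("column '", col, "' not found", call. = FALSE)
    if (tab$columns$kind[j] != "numeric") {
      stop("axis/size column '", col, "' is not numeric", call. = FALSE)
    }
  }

  ids <- contig_ids(dataset)
  n_total <- length(ids)
  in_sel <- if (is.null(selection)) rep(TRUE, n_total)
            else ids %in% selection$contig_ids
  n_filtered <- sum(!in_sel)

  grp <- unname(partition$assignment[ids])
  hidden <- in_sel & grp %in% hidden_groups
  n_hidden <- sum(hidden)

  xv <- tab$data[[x$column]]
  yv <- tab$data[[y$column]]
  sv <- tab$data[[size_column]]
  droppable <- is.na(xv) | is.na(yv) | is.na(sv) |
    (x$scale == "log10" & xv <= 0) | (y$scale == "log10" & yv <= 0)
  visible <- in_sel & !hidden
  dropped <- visible & droppable
  n_dropped <- sum(dropped)
  show <- visible & !dropped

  v <- sv[show]
  v_max <- if (any(show) && max(v) > 0) max(v) else 1
  radius <- r_min + (r_max - r_min) * sqrt(pmax(v, 0) / v_max)

  color <- character(sum(show))
  if (scheme$mode == "ordinal") {
    color <- unname(scheme$mapping[grp[show]])
    color[is.na(color)] <- "#999999"
  } else {
    if (is.null(color_column)) {
      stop("color_column is required for scheme mode '", scheme$mode, "'",
           call. = FALSE)
    }
    cv <- tab$data[[color_column]]
    if (is.null(cv)) stop("column '", color_column, "' not found", call. = FALSE)
    if (scheme$mode == "binned") {
      bin <- assign_bins(cv[show], scheme$bin_edges)
      color <- unname(scheme$mapping[as.character(bin)])
      color[is.na(color)] <- "#999999"
    } else {
      g <- gradient_colors(cv, low = scheme$endpoints[1L],
                           high = scheme$endpoints[2L])
      color <- as.character(g[show])
      color[is.na(color)] <- "#999999"
    }
  }

  outlined <- if (is.null(search)) rep(FALSE, sum(show))
              else ids[show] %in% names(search$hits)
  hover_cols <- tab$columns$name[tab$columns$role %in% c("info", "filter")]

  marks <- data.frame(contig_id = ids[show],
                      x = xv[show], y = yv[show],
                      radius = radius, color = color, group = grp[show],
                      outlined = outlined, emphasized = outlined,
                      stringsAsFactors = FALSE, row.names = NULL)
  for (col in hover_cols) marks[[paste0("hover_", col)]] <- tab$data[[col]][show]

  legend_groups <- partition$groups
  legend <- data.frame(group = legend_groups,
                       color = if (scheme$mode == "ordinal")
                         unname(scheme$mapping[legend_groups]) else NA_character_,
                       visible = !legend_groups %in% hidden_groups,
                       stringsAsFactors = FALSE)

  structure(list(x_axis = x, y_axis = y, size_column = size_column,
                 marks = marks, legend = legend, title = title,
                 hover_columns = hover_cols,
                 counts = list(total = n_total, marks = nrow(marks),
                               filtered_out = n_filtered, hidden = n_hidden,
                               dropped_log = n_dropped)),
            class = "plot_spec")
}

#' @export
print.plot_spec <- function(x, ...) {
  cat(sprintf("<plot_spec> %s vs %s; %d marks (of %d contigs: %d filtered, %d hidden, %d dropped)\n",
              x$y_axis$column, x$x_axis$column, x$counts$marks,
              x$counts$total, x$counts$filtered_out, x$counts$hidden,
              x$counts$dropped_log))
  invisible(x)
}

#' Build a contig annotation track
#'
#' Collects the features of one contig that overlap the window (inclusive
#' coordinates; a feature overlaps when `start <= window_end` and
#' `end >= window_start`) and assigns display lanes greedily in start order
#' so overlapping glyphs never share a lane. Forward-strand glyphs are
#' oriented `forward`, `-` strand `reverse` (unstranded features draw
#' forward).
#'
#' @param dataset An `mg_dataset` with annotations attached.
#' @param contig_id Contig to display.
#' @param window Optional `c(start, end)` in bp; default the whole contig
#'   (from the `length` column when present, else the furthest feature end).
#' @param selected Optional integer indices (within the returned glyph
#'   table) to flag as selected.
#' @return A `track_spec`: contig id, window, `glyphs` data.frame (start,
#'   end, strand, orientation, type, lane, selected, label) and
#'   `feature_attributes` (list of named vectors, for the detail table).
#' @export
build_contig_track <- function(dataset, contig_id, window = NULL,
                               selected = integer(0)) {
  stopifnot(inherits(dataset, "mg_dataset"))
  if (is.null(dataset$annotations)) {
    stop("dataset has no annotations attached", call. = FALSE)
  }
  ids <- contig_ids(dataset)
  if (!contig_id %in% ids) {
    stop("unknown contig '", contig_id, "'", call. = FALSE)
  }
  ann <- dataset$annotations
  ann <- ann[ann$contig_id == contig_id, , drop = FALSE]

  if (is.null(window)) {
    len <- NA_real_
    if ("length" %in% dataset$table$columns$name) {
      len <- dataset$table$data$length[match(contig_id, ids)]
    }
    if (is.na(len)) len <- if (nrow(ann) > 0L) max(ann$end) else 1
    window <- c(1, len)
  }
  stopifnot(length(window) == 2L, window[1L] <= window[2L])

  keep <- ann$start <= window[2L] & ann$end >= window[1L]
  ann <- ann[keep, , drop = FALSE]
  ord <- order(ann$start, ann$end)
  ann <- ann[ord, , drop = FALSE]

  n <- nrow(ann)
  lane <- integer(n)
  lane_end <- numeric(0)  # last occupied end per lane
  for (i in seq_len(n)) {
    free <- which(lane_end < ann$start[i])
    if (length(free) > 0L) {
      lane[i] <- free[1L]
      lane_end[free[1L]] <- ann$end[i]
    } else {
      lane_end <- c(lane_end, ann$end[i])
      lane[i] <- length(lane_end)
    }
  }

  label <- vapply(seq_len(n), function(i) {
    a <- ann$attributes[[i]]
    if ("ID" %in% names(a)) a[["ID"]] else paste0(ann$type[i], "_", i)
  }, "")
  glyphs <- data.frame(start = ann$start, end = ann$end, strand = ann$strand,
                       orientation = ifelse(ann$strand == "-", "reverse",
                                            "forward"),
                       type = ann$type, lane = lane - 1L,
                       selected = seq_len(n) %in% selected,
                       label = label,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(contig_id = contig_id, window = window, glyphs = glyphs,
                 feature_attributes = ann$attributes),
            class = "track_spec")
}

#' @export
print.track_spec <- function(x, ...) {
  cat(sprintf("<track_spec> %s [%g..%g]: %d glyphs in %d lane(s)\n",
              x$contig_id, x$window[1L], x$window[2L], nrow(x$glyphs),
              if (nrow(x$glyphs)) max(x$glyphs$lane) + 1L else 0L))
  invisible(x)
}

#' JSON payload of a plot or track specification
#'
#' The backend-independent serialization embedded in rendered HTML;
#' deterministic for a fixed spec.
#' @param spec A `plot_spec` or `track_spec`.
#' @return A JSON string.
#' @export
spec_payload_json <- function(spec) {
  obj <- if (inherits(spec, "plot_spec")) {
    list(kind = "bubble_plot", title = spec$title,
         x_axis = spec$x_axis[c("column", "scale")],
         y_axis = spec$y_axis[c("column", "scale")],
         size_column = spec$size_column,
         counts = spec$counts, legend = spec$legend, marks = spec$marks)
  } else if (inherits(spec, "track_spec")) {
    list(kind = "contig_track", contig_id = spec$contig_id,
         window = spec$window, glyphs = spec$glyphs,
         feature_attributes = lapply(spec$feature_attributes, as.list))
  } else stop("spec must be a plot_spec or track_spec", call. = FALSE)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null"))
}

#' Render a specification to a standalone interactive HTML document
#'
#' Writes a single self-contained file: the spec payload as an embedded
#' JSON block plus a small inline SVG renderer with hover tooltips,
#' wheel zoom and drag panning (bubble plots) or a lane track with glyph
#' tooltips (contig tracks). Re-rendering the same spec yields a
#' byte-identical payload section.
#'
#' @param spec A `plot_spec` or `track_spec`.
#' @param path Output `.html` path.
#' @return `path` invisibly, with the payload mark count in attribute
#'   `"n_records"`.
#' @export
render_html <- function(spec, path) {
  payload <- spec_payload_json(spec)
  n <- if (inherits(spec, "plot_spec")) nrow(spec$marks) else nrow(spec$glyphs)
  title <- if (inherits(spec, "plot_spec") && nzchar(spec$title)) spec$title
           else "contigscape"
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n",
    "<title>", html_escape(title), "</title>\n",
    "<style>body{font-family:sans-serif;margin:0}#plot{width:100vw;height:90vh}",
    ".tip{position:fixed;background:#fff;border:1px solid #888;padding:4px 6px;",
    "font-size:12px;pointer-events:none;display:none;white-space:pre}</style>\n",
    "</head>\n<body>\n",
    "<script type=\"application/json\" id=\"payload\">\n", payload,
    "\n</script>\n",
    "<div id=\"plot\"></div><div class=\"tip\" id=\"tip\"></div>\n",
    "<script>\n", viewer_js(), "\n</script>\n</body>\n</html>\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(html, con, eos = NULL)
  invisible(structure(path, n_records = n))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Minimal dependency-free SVG viewer; interactivity contract only
# (pan/zoom/hover) -- the tested artifact is the JSON payload above.
viewer_js <- function() {
  paste(
    "var spec=JSON.parse(document.getElementById('payload').textContent);",
    "var div=document.getElementById('plot'),tip=document.getElementById('tip');",
    "var W=div.clientWidth||900,H=div.clientHeight||600,P=50;",
    "var svgNS='http://www.w3.org/2000/svg';",
    "var svg=document.createElementNS(svgNS,'svg');",
    "svg.setAttribute('width',W);svg.setAttribute('height',H);div.appendChild(svg);",
    "var g=document.createElementNS(svgNS,'g');svg.appendChild(g);",
    "var tx=0,ty=0,k=1;function apply(){g.setAttribute('transform','translate('+tx+','+ty+') scale('+k+')');}",
    "function tfm(v,s){return s==='log10'?Math.log(v)/Math.LN10:v;}",
    "if(spec.kind==='bubble_plot'){",
    " var ms=spec.marks||[];if(!Array.isArray(ms))ms=[ms];",
    " var xs=ms.map(function(m){return tfm(m.x,spec.x_axis.scale);});",
    " var ys=ms.map(function(m){return tfm(m.y,spec.y_axis.scale);});",
    " var x0=Math.min.apply(null,xs),x1=Math.max.apply(null,xs);",
    " var y0=Math.min.apply(null,ys),y1=Math.max.apply(null,ys);",
    " if(!isFinite(x0)){x0=0;x1=1;}if(!isFinite(y0)){y0=0;y1=1;}",
    " if(x0===x1){x1=x0+1;}if(y0===y1){y1=y0+1;}",
    " ms.forEach(function(m,i){",
    "  var c=document.createElementNS(svgNS,'circle');",
    "  c.setAttribute('cx',P+(xs[i]-x0)/(x1-x0)*(W-2*P));",
    "  c.setAttribute('cy',H-P-(ys[i]-y0)/(y1-y0)*(H-2*P));",
    "  c.setAttribute('r',m.radius);c.setAttribute('fill',m.color);",
    "  c.setAttribute('fill-opacity',0.7);",
    "  if(m.outlined){c.setAttribute('stroke','#000');c.setAttribute('stroke-width',2);}",
    "  c.addEventListener('mousemove',function(e){tip.style.display='block';",
    "   tip.style.left=(e.clientX+12)+'px';tip.style.top=(e.clientY+12)+'px';",
    "   var t=m.contig_id+'\\ngroup: '+m.group;",
    "   Object.keys(m).forEach(function(kk){if(kk.indexOf('hover_')===0)t+='\\n'+kk.slice(6)+': '+m[kk];});",
    "   tip.textContent=t;});",
    "  c.addEventListener('mouseout',function(){tip.style.display='none';});",
    "  g.appendChild(c);});",
    "}else{",
    " var gs=spec.glyphs||[];if(!Array.isArray(gs))gs=[gs];",
    " var w0=spec.window[0],w1=spec.window[1];",
    " gs.forEach(function(f){",
    "  var r=document.createElementNS(svgNS,'rect');",
    "  r.setAttribute('x',P+(f.start-w0)/(w1-w0+1)*(W-2*P));",
    "  r.setAttribute('width',Math.max(2,(f.end-f.start+1)/(w1-w0+1)*(W-2*P)));",
    "  r.setAttribute('y',60+f.lane*22);r.setAttribute('height',16);",
    "  r.setAttribute('fill',f.selected?'#E8C547':(f.orientation==='forward'?'#C0392B':'#222'));",
    "  r.addEventListener('mousemove',function(e){tip.style.display='block';",
    "   tip.style.left=(e.clientX+12)+'px';tip.style.top=(e.clientY+12)+'px';",
    "   tip.textContent=f.label+' ['+f.start+'..'+f.end+'] '+f.strand;});",
    "  r.addEventListener('mouseout',function(){tip.style.display='none';});",
    "  g.appendChild(r);});",
    "}",
    "svg.addEventListener('wheel',function(e){e.preventDefault();",
    " var f=e.deltaY<0?1.15:1/1.15;k*=f;tx=e.offsetX-(e.offsetX-tx)*f;",
    " ty=e.offsetY-(e.offsetY-ty)*f;apply();});",
    "var drag=null;svg.addEventListener('mousedown',function(e){drag=[e.clientX-tx,e.clientY-ty];});",
    "window.addEventListener('mousemove',function(e){if(drag){tx=e.clientX-drag[0];ty=e.clientY-drag[1];apply();}});",
    "window.addEventListener('mouseup',function(){drag=null;});",
    sep = "\n")
}

#' Extract the embedded JSON payload from a rendered HTML file
#' @param path Path written by [render_html()].
#' @return The payload JSON string.
#' @export
read_html_payload <- function(path) {
  lines <- readLines(path, warn = FALSE)
  open <- grep("<script type=\"application/json\" id=\"payload\">", lines,
               fixed = TRUE)
  close <- grep("^</script>$", lines)
  close <- close[close > open][1L]
  paste(lines[(open + 1L):(close - 1L)], collapse = "\n")
}
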