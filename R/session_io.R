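SESSION_FORMAT_VERSION <- "1.0"

# --- canonical JSON ---------------------------------------------------------
# Deterministic serializer used for sessions and filter documents: object
# keys sorted, numbers in fixed decimal notation (up to 15 significant
# digits, a representation stable under parse -> format), no insignificant
# whitespace. Guarantees save -> load -> save byte identity.

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  paste0("\"", s, "\"")
}

json_num <- function(x) {
  if (is.na(x)) return("null")
  if (!is.finite(x)) stop("cannot serialize non-finite number to JSON")
  if (x == floor(x) && abs(x) < 2^53) sprintf("%.0f", x)
  else format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && length(x) > 0) {
      o <- order(nm)
      items <- vapply(o, function(i)
        paste0(json_escape(nm[i]), ":", canonical_json(x[[i]])), "")
      return(paste0("{", paste(items, collapse = ","), "}"))
    }
    if (!is.null(nm)) return("{}")
    return(paste0("[", paste(vapply(x, canonical_json, ""), collapse = ","), "]"))
  }
  if (length(x) != 1) # atomic vector -> array
    return(paste0("[", paste(vapply(x, canonical_json, ""), collapse = ","), "]"))
  if (is.na(x) && !is.nan(x)) return("null")
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(json_num(as.numeric(x)))
  json_escape(as.character(x))
}

# empty named list (serializes to {})
emptyobj <- function() structure(list(), names = character())

# --- session state ----------------------------------------------------------

#' Snapshot the full analysis state
#'
#' The session is self-contained: it carries all mapped panel content
#' (relative intervals, expression, neighbours, show flags), the settings
#' and the filter chain, so the analysis can be re-initiated without access
#' to any original input file. The file manifest is provenance only.
#'
#' @param panels list of `gene_panel`.
#' @param settings a [panel_settings()].
#' @param chain a `filter_chain` (default: empty).
#' @param genome_label free-text label of the genome/build.
#' @param file_manifest named list of original file names -> `c(cell, mark)`.
#' @return a `session_state`.
#' @export
session_state <- function(panels, settings, chain = filter_chain(),
                          genome_label = "unspecified",
                          file_manifest = list()) {
  structure(list(format_version = SESSION_FORMAT_VERSION,
                 genome_label = genome_label, settings = settings,
                 panels = panels, chain = chain,
                 file_manifest = file_manifest),
            class = "session_state")
}

#' @export
print.session_state <- function(x, ...) {
  cat(sprintf("<session_state> v%s '%s': %d panel(s) (%d shown), %d filter(s)\n",
              x$format_version, x$genome_label, length(x$panels),
              sum(vapply(x$panels, `[[`, TRUE, "show")),
              length(x$chain$filters)))
  invisible(x)
}

intervals_to_list <- function(df, cols) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, cols, drop = FALSE])
    lapply(row, function(v) if (is.numeric(v) && is.na(v)) NULL else v)
  })
}

list_to_intervals <- function(l, cols, types) {
  if (length(l) == 0) {
    df <- stats::setNames(lapply(types, function(t) vector(t, 0)), cols)
    return(as.data.frame(df, stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(l, function(row) {
    vals <- lapply(seq_along(cols), function(j) {
      v <- row[[cols[j]]]
      if (is.null(v)) if (types[j] == "numeric") NA_real_ else NA_character_
      else if (types[j] == "numeric") as.numeric(v) else as.character(v)
    })
    as.data.frame(stats::setNames(vals, cols), stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

panel_to_list <- function(p) {
  g <- p$gene
  tracks <- if (length(p$tracks) == 0) emptyobj()
    else lapply(p$tracks, intervals_to_list,
                cols = c("rel_start", "rel_end", "score", "signal_value", "name"))
  expression <- if (length(p$expression) == 0) emptyobj()
    else lapply(as.list(p$expression), function(v) if (is.na(v)) NULL else v)
  list(gene = list(gene_id = g$gene_id, aliases = as.list(g$aliases),
                   chrom = g$chrom, strand = g$strand,
                   span_start = g$span_start, span_end = g$span_end,
                   exons = lapply(seq_len(nrow(g$exons)), function(i)
                     list(g$exons[i, 1], g$exons[i, 2])),
                   description = g$description),
       flank_up = p$flank_up, flank_down = p$flank_down,
       gene_length = p$gene_length,
       tracks = tracks, expression = expression,
       neighbors = intervals_to_list(p$neighbors,
         cols = c("gene_id", "rel_start", "rel_end", "orientation")),
       exons_rel = intervals_to_list(p$exons_rel,
         cols = c("rel_start", "rel_end")),
       show = p$show)
}

panel_from_list <- function(l) {
  gl <- l$gene
  exons <- if (length(gl$exons))
    do.call(rbind, lapply(gl$exons, function(e) c(as.numeric(e[[1]]),
                                                  as.numeric(e[[2]]))))
  else matrix(numeric(), ncol = 2)
  gene <- gene_model(gl$gene_id, gl$chrom, gl$strand,
                     as.numeric(gl$span_start), as.numeric(gl$span_end),
                     exons = exons,
                     aliases = as.character(unlist(gl$aliases)),
                     description = gl$description %||% "")
  tracks <- lapply(l$tracks, list_to_intervals,
                   cols = c("rel_start", "rel_end", "score", "signal_value", "name"),
                   types = c("numeric", "numeric", "numeric", "numeric", "character"))
  expression <- vapply(l$expression, function(v)
    if (is.null(v)) NA_real_ else as.numeric(v), 0)
  if (length(expression) == 0) expression <- stats::setNames(numeric(), character())
  structure(list(gene = gene,
                 flank_up = as.numeric(l$flank_up),
                 flank_down = as.numeric(l$flank_down),
                 gene_length = as.numeric(l$gene_length),
                 tracks = tracks, expression = expression,
                 neighbors = list_to_intervals(l$neighbors,
                   cols = c("gene_id", "rel_start", "rel_end", "orientation"),
                   types = c("character", "numeric", "numeric", "character")),
                 exons_rel = list_to_intervals(l$exons_rel,
                   cols = c("rel_start", "rel_end"),
                   types = c("numeric", "numeric")),
                 show = isTRUE(l$show)),
            class = "gene_panel")
}

settings_to_list <- function(s) {
  list(flank_up = s$flank_up, flank_down = s$flank_down,
       min_peak_score = s$min_peak_score, min_peak_size = s$min_peak_size,
       max_peak_size = if (is.finite(s$max_peak_size)) s$max_peak_size
                       else NULL,   # null = unbounded
       expr_scale_lo = s$expr_scale_lo, expr_scale_hi = s$expr_scale_hi)
}

settings_from_list <- function(l) {
  panel_settings(flank_up = as.numeric(l$flank_up),
                 flank_down = as.numeric(l$flank_down),
                 min_peak_score = as.numeric(l$min_peak_score %||% 0),
                 min_peak_size = as.numeric(l$min_peak_size %||% 0),
                 max_peak_size = if (is.null(l$max_peak_size)) Inf
                                 else as.numeric(l$max_peak_size),
                 expr_scale_lo = if (is.null(l$expr_scale_lo)) NULL
                                 else as.numeric(l$expr_scale_lo),
                 expr_scale_hi = if (is.null(l$expr_scale_hi)) NULL
                                 else as.numeric(l$expr_scale_hi))
}

session_to_list <- function(state) {
  list(format_version = state$format_version,
       genome_label = state$genome_label,
       settings = settings_to_list(state$settings),
       panels = lapply(state$panels, panel_to_list),
       filter_chain = lapply(state$chain$filters, filter_to_list),
       filter_trace = as.list(state$chain$trace),
       file_manifest = if (length(state$file_manifest) == 0) emptyobj()
                       else lapply(state$file_manifest, as.list))
}

session_from_list <- function(l) {
  chain <- filter_chain(lapply(l$filter_chain, filter_from_list))
  chain$trace <- as.integer(unlist(l$filter_trace) %||% integer())
  st <- session_state(panels = lapply(l$panels, panel_from_list),
                      settings = settings_from_list(l$settings),
                      chain = chain,
                      genome_label = l$genome_label,
                      file_manifest = lapply(l$file_manifest,
                                             function(m) unlist(m)))
  st$format_version <- l$format_version
  st
}

# --- schema validation ------------------------------------------------------
# Structural check of a parsed session document; returns the paths that
# fail. The schema is documented in inst/extdata/session.schema.json.

validate_session_list <- function(l) {
  bad <- character()
  need <- function(obj, key, path) {
    if (!is.list(obj) || is.null(obj[[key]])) bad <<- c(bad, paste0(path, key))
  }
  for (k in c("format_version", "genome_label", "settings", "panels",
              "filter_chain", "file_manifest"))
    if (!k %in% names(l)) bad <- c(bad, paste0("$.", k))
  if (is.list(l$settings))
    for (k in c("flank_up", "flank_down"))
      need(l$settings, k, "$.settings.")
  if (is.list(l$panels)) {
    for (i in seq_along(l$panels)) {
      p <- l$panels[[i]]
      pp <- sprintf("$.panels[%d].", i)
      for (k in c("gene", "flank_up", "flank_down", "gene_length",
                  "tracks", "expression", "neighbors", "exons_rel", "show"))
        if (!is.list(p) || !k %in% names(p)) bad <- c(bad, paste0(pp, k))
      if (is.list(p) && is.list(p$gene))
        for (k in c("gene_id", "chrom", "strand", "span_start", "span_end",
                    "exons"))
          need(p$gene, k, paste0(pp, "gene."))
    }
  }
  bad
}

#' Save a session to a self-contained canonical JSON file
#'
#' The document is schema-validated and written in canonical form (sorted
#' keys, fixed number formatting), so `save -> load -> save` is
#' byte-identical.
#'
#' @param state a `session_state`.
#' @param path output file.
#' @export
save_session <- function(state, path) {
  stopifnot(inherits(state, "session_state"))
  l <- session_to_list(state)
  bad <- validate_session_list(l)
  if (length(bad)) stop("session fails schema validation at: ",
                        paste(bad, collapse = ", "))
  con <- file(path, open = "wb")   # byte-exact: no platform EOL translation
  on.exit(close(con))
  writeLines(canonical_json(l), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Load a session from a JSON file
#'
#' @param path session file written by [save_session()].
#' @return a `session_state` deep-equal to the saved one.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path)
  l <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("session file is not valid JSON: ",
                                         conditionMessage(e), call. = FALSE))
  bad <- validate_session_list(l)
  if (length(bad)) stop("session fails schema validation at: ",
                        paste(bad, collapse = ", "))
  ver <- as.character(l$format_version)
  major <- strsplit(ver, ".", fixed = TRUE)[[1]][1]
  if (!identical(major, strsplit(SESSION_FORMAT_VERSION, ".", fixed = TRUE)[[1]][1]))
    stop("unsupported session format version '", ver, "' (supported: ",
         SESSION_FORMAT_VERSION, ")")
  session_from_list(l)
}

# --- summary export ---------------------------------------------------------

#' Export a human-readable analysis summary
#'
#' Reports the inputs, settings, each filter with its surviving-gene count,
#' and the final list of genes passing all filters.
#'
#' @param state a `session_state`.
#' @param path output text file.
#' @export
export_summary <- function(state, path) {
  p <- state$panels
  shown <- vapply(p, `[[`, TRUE, "show")
  ln <- c("# Analysis summary",
          paste0("genome: ", state$genome_label),
          paste0("genes loaded: ", length(p)),
          "",
          "## Settings")
  s <- state$settings
  ln <- c(ln,
          paste0("flank_up: ", s$flank_up, " bp"),
          paste0("flank_down: ", s$flank_down, " bp"),
          paste0("min_peak_score: ", s$min_peak_score),
          paste0("peak_size: [", s$min_peak_size, ", ", s$max_peak_size, "] bp"),
          "", "## Input files")
  if (length(state$file_manifest) == 0) ln <- c(ln, "(none recorded)")
  else for (nm in names(state$file_manifest))
    ln <- c(ln, paste0("- ", nm, " (",
                       paste(state$file_manifest[[nm]], collapse = ", "), ")"))
  ln <- c(ln, "", "## Filters")
  fs <- state$chain$filters
  if (length(fs) == 0) ln <- c(ln, "(none; all genes pass)")
  else for (i in seq_along(fs)) {
    n <- if (length(state$chain$trace) >= i)
      paste0(" -> ", state$chain$trace[i], " gene(s)") else ""
    ln <- c(ln, sprintf("%d. %s%s", i, describe_filter(fs[[i]]), n))
  }
  ln <- c(ln, "",
          sprintf("## Passing genes (%d of %d)", sum(shown), length(p)),
          vapply(p[shown], function(x) x$gene$gene_id, ""))
  writeLines(ln, path)
  invisible(path)
}

#' Read back the passing-gene list from an exported summary
#' @param path a summary file written by [export_summary()].
#' @return character vector of gene ids.
#' @export
read_summary_genes <- function(path) {
  ln <- readLines(path, warn = FALSE)
  i <- grep("^## Passing genes", ln)
  if (length(i) == 0) stop("not a summary file: ", path)
  ln <- ln[(i[1] + 1L):length(ln)]
  ln[nzchar(ln)]
}

# --- SVG export -------------------------------------------------------------

# Linear opacity ramp over the loaded score range; a flat range renders at
# full opacity.
opacity_for_score <- function(score, lo, hi, floor_opacity = 0.3) {
  if (hi <= lo) return(rep(1, length(score)))
  floor_opacity + (1 - floor_opacity) * (score - lo) / (hi - lo)
}

mark_palette <- function(marks) {
  pal <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
           "#a65628", "#f781bf", "#17becf")
  stats::setNames(pal[(seq_along(marks) - 1L) %% length(pal) + 1L], marks)
}

#' Export shown gene panels to a single SVG document
#'
#' One group per shown gene and cell type: a scale line with 0 at the TSS,
#' the gene as a filled bar, neighbours as grey bars placed strand-
#' specifically (same-strand above, opposite below the scale line), one
#' coloured track per mark with bar opacity a linear function of the peak
#' score over the loaded score range, and an expression swatch on the
#' settings' grey scale.
#'
#' @param panels list of `gene_panel` (only `show = TRUE` ones render).
#' @param settings a [panel_settings()] (expression scale bounds used when
#'   set; otherwise derived from the loaded values).
#' @param path output `.svg` file.
#' @param floor_opacity opacity assigned to the minimal score (default 0.3).
#' @return the path, invisibly.
#' @export
export_svg <- function(panels, settings, path, floor_opacity = 0.3) {
  shown <- panels[vapply(panels, `[[`, TRUE, "show")]
  if (length(shown) == 0) stop("no shown gene panels to render")
  track_ids <- names(shown[[1]]$tracks)
  parts <- strsplit(track_ids, "|", fixed = TRUE)
  cells <- unique(c(vapply(parts, `[[`, "", 1),
                    names(shown[[1]]$expression)))
  if (length(cells) == 0) cells <- "all"
  marks <- unique(vapply(parts, function(x) x[2], ""))
  colors <- mark_palette(marks)
  scores <- unlist(lapply(shown, function(p)
    lapply(p$tracks, function(tr) tr$score)))
  slo <- if (length(scores)) min(scores) else 0
  shi <- if (length(scores)) max(scores) else 0
  evals <- unlist(lapply(shown, `[[`, "expression"))
  es <- c(settings$expr_scale_lo, settings$expr_scale_hi)
  if (length(es) != 2)
    es <- if (length(evals) && any(!is.na(evals)))
      expression_scale(evals[!is.na(evals)]) else c(0, 1)

  col_w <- 560; swatch_w <- 30; plot_w <- col_w - swatch_w - 30
  track_h <- 12; header_h <- 16
  row_h <- header_h + 8 + length(marks) * track_h + 34
  width <- 60 + length(cells) * col_w
  height <- 20 + length(shown) * row_h

  doc <- xml2::xml_new_root("svg",
    xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    width = as.character(width), height = as.character(height))
  add <- function(parent, name, ...) {
    at <- list(...)
    node <- xml2::xml_add_child(parent, name)
    for (nm in names(at)) xml2::xml_set_attr(node, nm, as.character(at[[nm]]))
    node
  }
  for (gi in seq_along(shown)) {
    p <- shown[[gi]]
    w <- panel_window(p)
    xmap <- function(rel) 20 + (pmax(w[1], pmin(w[2], rel)) - w[1]) /
      (w[2] - w[1]) * plot_w
    y0 <- 20 + (gi - 1) * row_h
    ggene <- add(doc, "g", class = "gene-panel", id = p$gene$gene_id)
    add(ggene, "text", x = 60, y = y0 + header_h - 4, class = "gene-label")
    xml2::xml_set_text(xml2::xml_find_first(ggene, ".//*[@class='gene-label']"),
                       sprintf("%s (%s, %d bp)", p$gene$gene_id,
                               p$gene$strand, as.integer(p$gene_length)))
    for (ci in seq_along(cells)) {
      cell <- cells[ci]
      gx <- 60 + (ci - 1) * col_w
      gcell <- add(ggene, "g", class = "cell-column",
                   transform = sprintf("translate(%d,%d)", gx, y0 + header_h))
      ybase <- length(marks) * track_h + 16
      # scale line across the window, tick at the TSS (rel 0)
      add(gcell, "line", class = "scale", x1 = xmap(w[1]), x2 = xmap(w[2]),
          y1 = ybase, y2 = ybase, stroke = "#3070b0", "stroke-width" = 1)
      add(gcell, "line", class = "tss-tick", x1 = xmap(0), x2 = xmap(0),
          y1 = ybase - 4, y2 = ybase + 4, stroke = "#3070b0")
      add(gcell, "rect", class = "gene-body", x = xmap(0),
          y = ybase - 3, width = max(1, xmap(p$gene_length) - xmap(0)),
          height = 6, fill = "#222222")
      if (nrow(p$neighbors) > 0) for (ni in seq_len(nrow(p$neighbors))) {
        same <- p$neighbors$orientation[ni] == "same"
        add(gcell, "rect", class = "neighbor",
            x = xmap(p$neighbors$rel_start[ni]),
            y = if (same) ybase - 10 else ybase + 4,
            width = max(1, xmap(p$neighbors$rel_end[ni]) -
                          xmap(p$neighbors$rel_start[ni])),
            height = 5, fill = "#999999",
            "data-orientation" = p$neighbors$orientation[ni])
      }
      for (mi in seq_along(marks)) {
        tid <- track_id(cell, marks[mi])
        tr <- p$tracks[[tid]]
        if (is.null(tr) || nrow(tr) == 0) next
        yt <- (mi - 1) * track_h
        opac <- opacity_for_score(tr$score, slo, shi, floor_opacity)
        for (k in seq_len(nrow(tr)))
          add(gcell, "rect", class = "peak",
              x = xmap(tr$rel_start[k]),
              y = yt, height = track_h - 3,
              width = max(1, xmap(tr$rel_end[k]) - xmap(tr$rel_start[k])),
              fill = colors[[marks[mi]]],
              "fill-opacity" = sprintf("%.3f", opac[k]),
              "data-track" = tid)
      }
      if (cell %in% names(p$expression)) {
        v <- p$expression[[cell]]
        frac <- if (is.na(v)) NA
                else pmax(0, pmin(1, (v - es[1]) / max(es[2] - es[1], 1e-12)))
        fill <- if (is.na(frac)) "none"
                else grDevices::gray(1 - frac)
        add(gcell, "rect", class = "expression", x = plot_w + 26,
            y = 0, width = swatch_w, height = ybase,
            fill = fill, stroke = "#555555",
            "data-value" = if (is.na(v)) "NA" else v)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
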