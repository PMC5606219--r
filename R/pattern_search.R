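#' Gap between two half-open relative intervals
#'
#' 0 if the intervals overlap or abut; otherwise the number of bases strictly
#' between them. `[0,10)` vs `[10,20)` abut (gap 0); `[0,10)` vs `[510,520)`
#' have 500 intervening bases.
#'
#' @param a,b numeric `c(rel_start, rel_end)`.
#' @return gap in bp, `>= 0`.
#' @export
interval_gap <- function(a, b) {
  max(0, max(a[[1]], b[[1]]) - min(a[[2]], b[[2]]))
}

new_filter <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "epi_filter")
}

#' Gene-name filter
#' @param names identifiers to keep (case-insensitive, matched against the
#'   gene id and all aliases), or `NULL` to use `pattern`.
#' @param pattern regular expression matched against the gene id.
#' @return an `epi_filter`.
#' @export
filter_name <- function(names = NULL, pattern = NULL) {
  if (is.null(names) && is.null(pattern))
    stop("provide names or pattern")
  new_filter("name", names = names, pattern = pattern)
}

#' Gene-size filter
#' @param op one of `<, <=, =, >=, >`.
#' @param bp gene length threshold in bp.
#' @return an `epi_filter`.
#' @export
filter_gene_size <- function(op, bp) {
  op_fun(op); stopifnot_scalar_num(bp, "bp")
  new_filter("gene_size", op = op, bp = bp)
}

#' Chromosome filter
#' @param chroms chromosome names to keep.
#' @return an `epi_filter`.
#' @export
filter_chrom <- function(chroms) new_filter("chrom", chroms = as.character(chroms))

#' Expression (transcript-level) filter
#'
#' A gene with no expression value for the cell type fails the filter (it is
#' dropped, never silently treated as zero).
#'
#' @param cell_type cell type whose expression is tested.
#' @param op one of `<, <=, =, >=, >`.
#' @param value FPKM-like threshold.
#' @return an `epi_filter`.
#' @export
filter_expression <- function(cell_type, op, value) {
  op_fun(op); stopifnot_scalar_num(value, "value")
  new_filter("expression", cell_type = cell_type, op = op, value = value)
}

#' Feature-count filter ("presence or absence of peaks")
#'
#' Counts the intervals of one (cell type, mark) track that overlap a
#' TSS-relative window and compares the count. Presence is `op = ">="`,
#' `count = 1`; absence is `op = "="`, `count = 0`.
#'
#' @param cell_type,mark the track.
#' @param window_rel TSS-relative window `c(a, b)`, half-open, `a < b`;
#'   `NULL` means the whole panel window.
#' @param op comparison operator.
#' @param count non-negative integer threshold.
#' @return an `epi_filter`.
#' @export
filter_feature_count <- function(cell_type, mark, window_rel = NULL,
                                 op = ">=", count = 1) {
  op_fun(op); stopifnot(count >= 0)
  if (!is.null(window_rel)) stopifnot(window_rel[1] < window_rel[2])
  new_filter("feature_count", cell_type = cell_type, mark = mark,
             window_rel = window_rel, op = op, count = count)
}

#' Feature-overlap filter (bivalent domains, juxtaposed peaks, exon proximity)
#'
#' True for a gene iff some peak of `(cell_type, mark_a)` and some interval of
#' the target track (another mark, or the gene's exons) both overlap
#' `window_rel` and stand in the requested relation:
#' `near` -- gap at most `max_distance` (0 means overlapping or abutting);
#' `a_upstream_of_b` -- the `mark_a` peak ends at or before the target starts,
#' within `max_distance`; `a_downstream_of_b` -- mirrored.
#'
#' @param cell_type cell type of both tracks.
#' @param mark_a first mark.
#' @param target second mark name, or `"exons"` for the gene's exons.
#' @param relation `"near"`, `"a_upstream_of_b"` or `"a_downstream_of_b"`.
#' @param max_distance maximum separation in bp (`>= 0`).
#' @param window_rel TSS-relative window both partners must overlap; `NULL`
#'   means the whole panel window.
#' @return an `epi_filter`.
#' @export
filter_feature_overlap <- function(cell_type, mark_a, target = "exons",
                                   relation = c("near", "a_upstream_of_b",
                                                "a_downstream_of_b"),
                                   max_distance = 0, window_rel = NULL) {
  relation <- match.arg(relation)
  stopifnot(max_distance >= 0)
  if (!is.null(window_rel)) stopifnot(window_rel[1] < window_rel[2])
  new_filter("feature_overlap", cell_type = cell_type, mark_a = mark_a,
             target = target, relation = relation,
             max_distance = max_distance, window_rel = window_rel)
}

#' @export
print.epi_filter <- function(x, ...) {
  cat("<epi_filter>", describe_filter(x), "\n"); invisible(x)
}

describe_filter <- function(f) {
  win <- function(w) if (is.null(w)) "panel window"
                     else sprintf("[%s, %s)", w[1], w[2])
  switch(f$type,
    name = if (!is.null(f$names))
      paste0("name in {", paste(f$names, collapse = ", "), "}")
    else paste0("name matches /", f$pattern, "/"),
    gene_size = sprintf("gene size %s %s bp", f$op, f$bp),
    chrom = paste0("chrom in {", paste(f$chroms, collapse = ", "), "}"),
    expression = sprintf("expression[%s] %s %s", f$cell_type, f$op, f$value),
    feature_count = sprintf("count(%s) in %s %s %s",
                            track_id(f$cell_type, f$mark), win(f$window_rel),
                            f$op, f$count),
    feature_overlap = sprintf("%s %s %s (max distance %s bp) in %s",
                              track_id(f$cell_type, f$mark_a), f$relation,
                              if (identical(f$target, "exons")) "exons"
                              else track_id(f$cell_type, f$target),
                              f$max_distance, win(f$window_rel)),
    f$type)
}

# Intervals of a data.frame(rel_start, rel_end, ...) overlapping a window.
in_window <- function(df, w) {
  df[df$rel_start < w[2] & df$rel_end > w[1], , drop = FALSE]
}

get_track <- function(panel, cell_type, mark) {
  id <- track_id(cell_type, mark)
  tr <- panel$tracks[[id]]
  if (is.null(tr))
    stop("track '", id, "' is not loaded (available: ",
         paste(names(panel$tracks), collapse = ", "), ")")
  tr
}

# Effective window of a filter on a panel: the filter's window intersected
# with the panel window (or the panel window itself).
effective_window <- function(window_rel, panel) {
  pw <- panel_window(panel)
  if (is.null(window_rel)) pw
  else c(max(window_rel[1], pw[1]), min(window_rel[2], pw[2]))
}

#' Evaluate one filter on one gene panel
#'
#' @param f an `epi_filter`.
#' @param panel a `gene_panel`.
#' @return `TRUE` iff the gene satisfies the filter.
#' @export
eval_filter <- function(f, panel) {
  switch(f$type,
    name = {
      if (!is.null(f$names))
        any(tolower(c(panel$gene$gene_id, panel$gene$aliases)) %in%
              tolower(f$names))
      else grepl(f$pattern, panel$gene$gene_id, ignore.case = TRUE)
    },
    gene_size = op_fun(f$op)(panel$gene_length, f$bp),
    chrom = panel$gene$chrom %in% f$chroms,
    expression = {
      if (!f$cell_type %in% names(panel$expression))
        stop("no expression data loaded for cell type '", f$cell_type, "'")
      v <- panel$expression[[f$cell_type]]
      !is.na(v) && op_fun(f$op)(v, f$value)
    },
    feature_count = {
      w <- effective_window(f$window_rel, panel)
      tr <- get_track(panel, f$cell_type, f$mark)
      n <- if (w[1] >= w[2]) 0L else nrow(in_window(tr, w))
      op_fun(f$op)(n, f$count)
    },
    feature_overlap = {
      w <- effective_window(f$window_rel, panel)
      if (w[1] >= w[2]) return(FALSE)
      a <- in_window(get_track(panel, f$cell_type, f$mark_a), w)
      b <- in_window(if (identical(f$target, "exons")) panel$exons_rel
                     else get_track(panel, f$cell_type, f$target), w)
      if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
      for (i in seq_len(nrow(a))) {
        p <- c(a$rel_start[i], a$rel_end[i])
        ok <- switch(f$relation,
          near = pmax(0, pmax(p[1], b$rel_start) - pmin(p[2], b$rel_end)) <=
            f$max_distance,
          a_upstream_of_b = p[2] <= b$rel_start &
            b$rel_start - p[2] <= f$max_distance,
          a_downstream_of_b = p[1] >= b$rel_end &
            p[1] - b$rel_end <= f$max_distance)
        if (any(ok)) return(TRUE)
      }
      FALSE
    },
    stop("unknown filter type: ", f$type))
}

#' Build a filter chain
#'
#' @param ... `epi_filter` objects (or a single list of them).
#' @return a `filter_chain`.
#' @export
filter_chain <- function(...) {
  fs <- list(...)
  if (length(fs) == 1 && is.list(fs[[1]]) && !inherits(fs[[1]], "epi_filter"))
    fs <- fs[[1]]
  stopifnot(all(vapply(fs, inherits, TRUE, "epi_filter")))
  structure(list(filters = fs, trace = integer()), class = "filter_chain")
}

#' @export
print.filter_chain <- function(x, ...) {
  cat(sprintf("<filter_chain> %d filter(s)\n", length(x$filters)))
  for (i in seq_along(x$filters)) {
    cat(sprintf("  %d. %s", i, describe_filter(x$filters[[i]])))
    if (length(x$trace) >= i) cat(sprintf("  -> %d gene(s)", x$trace[i]))
    cat("\n")
  }
  invisible(x)
}

#' Apply a filter chain to gene panels
#'
#' Filters run sequentially; each stage evaluates only the genes surviving
#' the previous stages (contextual chaining). The `show` flag is set `TRUE`
#' on survivors and `FALSE` otherwise -- panel data is never mutated. The
#' trace records the number of surviving genes after each stage.
#'
#' @param chain a `filter_chain` (an empty chain keeps every gene).
#' @param panels list of `gene_panel`.
#' @return list with `panels` (show flags updated), `chain` (trace filled
#'   in), `trace` (integer vector) and `surviving` (gene ids).
#' @export
apply_chain <- function(chain, panels) {
  stopifnot(inherits(chain, "filter_chain"))
  alive <- rep(TRUE, length(panels))
  trace <- integer(length(chain$filters))
  for (k in seq_along(chain$filters)) {
    f <- chain$filters[[k]]
    for (i in which(alive)) if (!eval_filter(f, panels[[i]])) alive[i] <- FALSE
    trace[k] <- sum(alive)
  }
  for (i in seq_along(panels)) panels[[i]]$show <- alive[i]
  chain$trace <- trace
  list(panels = panels, chain = chain, trace = trace,
       surviving = vapply(panels[alive], function(p) p$gene$gene_id, ""))
}

# --- JSON (de)serialization of filter chains --------------------------------

filter_to_list <- function(f) {
  out <- unclass(f)
  out[!vapply(out, is.null, TRUE)]
}

filter_from_list <- function(l) {
  type <- l$type
  wr <- if (!is.null(l$window_rel)) as.numeric(unlist(l$window_rel))
  switch(type,
    name = filter_name(names = if (!is.null(l$names)) unlist(l$names),
                       pattern = l$pattern),
    gene_size = filter_gene_size(l$op, as.numeric(l$bp)),
    chrom = filter_chrom(unlist(l$chroms)),
    expression = filter_expression(l$cell_type, l$op, as.numeric(l$value)),
    feature_count = filter_feature_count(l$cell_type, l$mark,
                                         window_rel = wr, op = l$op,
                                         count = as.numeric(l$count)),
    feature_overlap = filter_feature_overlap(l$cell_type, l$mark_a,
                                             target = l$target,
                                             relation = l$relation,
                                             max_distance = as.numeric(l$max_distance),
                                             window_rel = wr),
    stop("unknown filter type in document: ", type))
}

#' Serialize a filter chain to a JSON document
#' @param chain a `filter_chain`.
#' @param path optional file; when `NULL` the JSON text is returned.
#' @return the JSON text, invisibly when written to a file.
#' @export
filters_to_json <- function(chain, path = NULL) {
  txt <- canonical_json(lapply(chain$filters, filter_to_list))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a filter chain from a JSON document
#' @param path file containing a JSON array of typed filter objects (or the
#'   JSON text itself).
#' @return a `filter_chain`.
#' @export
filters_from_json <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "\n") else path
  l <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  filter_chain(lapply(l, filter_from_list))
}
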