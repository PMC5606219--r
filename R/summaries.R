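contributing_panels <- function(panels, shown_only) {
  if (!shown_only) return(panels)
  panels[vapply(panels, `[[`, TRUE, "show")]
}

#' Average feature profile across genes
#'
#' The per-bin statistic is gene occupancy: the fraction of contributing
#' genes with at least one interval of the track overlapping the bin. In
#' `tss` mode, bins of `bin_size` bp tile `[-flank_up, +flank_down)` around
#' the TSS. In `genebody` mode each gene body `[0, L)` is rescaled to
#' `n_bins` equal fractions (metagene scaling) and bin edges are reported in
#' percent of the body.
#'
#' @param panels list of `gene_panel`.
#' @param key a `track_key` or its `"cell|mark"` string.
#' @param mode `"tss"` or `"genebody"`.
#' @param bin_size bin width in bp (tss mode; default 500).
#' @param n_bins number of body bins (genebody mode; default 100).
#' @param shown_only use only `show = TRUE` panels (default).
#' @return a `feature_profile`: `mode`, `bin_edges`, `values` in `[0, 1]`,
#'   `n_genes`.
#' @export
average_feature_profile <- function(panels, key, mode = c("tss", "genebody"),
                                    bin_size = 500, n_bins = 100,
                                    shown_only = TRUE) {
  mode <- match.arg(mode)
  id <- if (inherits(key, "track_key")) track_id(key) else key
  panels <- contributing_panels(panels, shown_only)
  if (length(panels) == 0) stop("no contributing gene panels")
  for (p in panels) if (is.null(p$tracks[[id]]))
    stop("track '", id, "' is not loaded")
  if (mode == "tss") {
    fu <- panels[[1]]$flank_up; fd <- panels[[1]]$flank_down
    edges <- seq(-fu, fd, by = bin_size)
    if (edges[length(edges)] < fd) edges <- c(edges, fd)
    hit <- matrix(0, nrow = length(panels), ncol = length(edges) - 1L)
    for (i in seq_along(panels)) {
      tr <- panels[[i]]$tracks[[id]]
      if (nrow(tr) == 0) next
      for (j in seq_len(length(edges) - 1L))
        hit[i, j] <- any(olap(tr$rel_start, tr$rel_end, edges[j], edges[j + 1L]))
    }
  } else {
    edges <- seq(0, 100, length.out = n_bins + 1L)
    hit <- matrix(0, nrow = length(panels), ncol = n_bins)
    for (i in seq_along(panels)) {
      p <- panels[[i]]
      tr <- p$tracks[[id]]
      if (nrow(tr) == 0) next
      # clip to the body, then test against bin edges scaled to this gene
      s <- pmax(tr$rel_start, 0); e <- pmin(tr$rel_end, p$gene_length)
      ok <- s < e
      if (!any(ok)) next
      bs <- edges[-length(edges)] / 100 * p$gene_length
      be <- edges[-1L] / 100 * p$gene_length
      for (j in seq_len(n_bins))
        hit[i, j] <- any(olap(s[ok], e[ok], bs[j], be[j]))
    }
  }
  structure(list(mode = mode, key = id, bin_edges = edges,
                 values = colMeans(hit), n_genes = length(panels)),
            class = "feature_profile")
}

#' @export
print.feature_profile <- function(x, ...) {
  cat(sprintf("<feature_profile> %s, %s mode, %d bin(s), %d gene(s), occupancy %.3f-%.3f\n",
              x$key, x$mode, length(x$values), x$n_genes,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Histogram of peak sizes or scores
#'
#' Bins are right-open; peaks falling outside the edges are counted in
#' separate underflow/overflow tallies, so that
#' `sum(counts) + underflow + overflow = |peaks|`.
#'
#' @param ps a `peak_set`.
#' @param attribute `"size"` (end - start, bp) or `"score"`.
#' @param bin_edges strictly increasing numeric vector.
#' @return a `feature_histogram`.
#' @export
feature_histogram <- function(ps, attribute = c("size", "score"), bin_edges) {
  attribute <- match.arg(attribute)
  stopifnot(length(bin_edges) >= 2, all(diff(bin_edges) > 0))
  x <- if (attribute == "size") ps$peaks$end - ps$peaks$start else ps$peaks$score
  counts <- integer(length(bin_edges) - 1L)
  for (j in seq_along(counts))
    counts[j] <- sum(x >= bin_edges[j] & x < bin_edges[j + 1L])
  structure(list(attribute = attribute, bin_edges = bin_edges,
                 counts = counts,
                 underflow = sum(x < bin_edges[1]),
                 overflow = sum(x >= bin_edges[length(bin_edges)])),
            class = "feature_histogram")
}

#' @export
print.feature_histogram <- function(x, ...) {
  cat(sprintf("<feature_histogram> %s: counts [%s], underflow %d, overflow %d\n",
              x$attribute, paste(x$counts, collapse = ", "),
              x$underflow, x$overflow))
  invisible(x)
}

#' Default expression display scale from loaded data
#'
#' Returns the 5th and 95th percentiles (linear interpolation between order
#' statistics) of the loaded expression values; a degenerate range is
#' widened by a small epsilon for display.
#'
#' @param values numeric vector of expression values (length >= 1).
#' @param lo_pct,hi_pct percentile bounds (defaults 5 and 95).
#' @return `c(lo, hi)`.
#' @export
expression_scale <- function(values, lo_pct = 5, hi_pct = 95) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no expression values")
  qs <- stats::quantile(values, probs = c(lo_pct, hi_pct) / 100,
                        type = 7, names = FALSE)
  if (qs[1] == qs[2]) {
    eps <- 1e-6 * max(1, abs(qs[1]))
    qs <- qs + c(-eps, eps)
  }
  c(lo = qs[1], hi = qs[2])
}

#' Expression scatter data for two cell types
#'
#' One point per contributing gene with expression present in both cell
#' types; genes missing either value are listed separately, never silently
#' dropped.
#'
#' @param panels list of `gene_panel`.
#' @param cell_x,cell_y cell-type labels (must be loaded).
#' @param shown_only use only shown panels (default).
#' @return list with `points` (`gene_id`, `x`, `y`) and `missing` (gene ids).
#' @export
expression_scatter <- function(panels, cell_x, cell_y, shown_only = TRUE) {
  panels <- contributing_panels(panels, shown_only)
  for (ct in c(cell_x, cell_y))
    if (length(panels) > 0 && !ct %in% names(panels[[1]]$expression))
      stop("no expression data loaded for cell type '", ct, "'")
  pts <- list(); missing <- character()
  for (p in panels) {
    x <- p$expression[[cell_x]]; y <- p$expression[[cell_y]]
    if (is.na(x) || is.na(y)) missing <- c(missing, p$gene$gene_id)
    else pts[[length(pts) + 1L]] <- data.frame(gene_id = p$gene$gene_id,
                                               x = x, y = y,
                                               stringsAsFactors = FALSE)
  }
  list(points = if (length(pts)) do.call(rbind, pts)
       else data.frame(gene_id = character(), x = numeric(), y = numeric()),
       missing = missing)
}

#' Tabulate gene and per-track information
#'
#' One row per panel: gene identity, genomic span, strand, length, per-track
#' peak counts within the window, and per-cell-type expression. The gene-ID
#' column can be copied out as a plain list for downstream GO or other
#' analysis.
#'
#' @param panels list of `gene_panel`.
#' @param filtered_only restrict to `show = TRUE` panels.
#' @return a `data.frame`, sortable on any column.
#' @export
gene_table <- function(panels, filtered_only = FALSE) {
  panels <- contributing_panels(panels, filtered_only)
  if (length(panels) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      span_start = numeric(), span_end = numeric(),
                      strand = character(), gene_length = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(panels, function(p) {
    base <- data.frame(gene_id = p$gene$gene_id, chrom = p$gene$chrom,
                       span_start = p$gene$span_start,
                       span_end = p$gene$span_end, strand = p$gene$strand,
                       gene_length = p$gene_length, stringsAsFactors = FALSE)
    counts <- vapply(p$tracks, nrow, 0L)
    if (length(counts))
      base[paste0("n_", gsub("[^A-Za-z0-9]+", "_", names(counts)))] <-
        as.list(counts)
    if (length(p$expression))
      base[paste0("expr_", gsub("[^A-Za-z0-9]+", "_", names(p$expression)))] <-
        as.list(unname(p$expression))
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
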