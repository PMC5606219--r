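#' Analysis settings
#'
#' @param flank_up,flank_down flanking window in bp around each gene
#'   (default 20000 bp each, i.e. 20 kb upstream and downstream).
#' @param min_peak_score,min_peak_size,max_peak_size peak quality/size cutoffs
#'   applied before mapping.
#' @param expr_scale_lo,expr_scale_hi expression display bounds; `NULL` means
#'   derive from the loaded data via [expression_scale()].
#' @return a `panel_settings` object.
#' @export
panel_settings <- function(flank_up = 20000, flank_down = 20000,
                           min_peak_score = 0, min_peak_size = 0,
                           max_peak_size = Inf,
                           expr_scale_lo = NULL, expr_scale_hi = NULL) {
  stopifnot(flank_up >= 0, flank_down >= 0,
            min_peak_size >= 0, min_peak_size <= max_peak_size)
  if (!is.null(expr_scale_lo) && !is.null(expr_scale_hi))
    stopifnot(expr_scale_lo <= expr_scale_hi)
  structure(list(flank_up = flank_up, flank_down = flank_down,
                 min_peak_score = min_peak_score,
                 min_peak_size = min_peak_size,
                 max_peak_size = max_peak_size,
                 expr_scale_lo = expr_scale_lo,
                 expr_scale_hi = expr_scale_hi),
            class = "panel_settings")
}

# Vectorized genomic -> TSS-relative transform. The gene body occupies
# [0, L) on both strands; for minus-strand genes the TSS anchor is span_end
# (the exclusive bound), so rel = (span_end - end, span_end - start).
rel_coords <- function(starts, ends, gene) {
  if (gene$strand == "+")
    cbind(rel_start = starts - gene$span_start,
          rel_end = ends - gene$span_start)
  else
    cbind(rel_start = gene$span_end - ends,
          rel_end = gene$span_end - starts)
}

#' Convert a genomic interval to TSS-relative, strand-corrected coordinates
#'
#' Position 0 is the gene's TSS; negative positions are upstream of the TSS
#' after orientation correction, and the gene body occupies
#' `[0, gene_length)` regardless of strand.
#'
#' @param interval numeric `c(start, end)` (0-based half-open), or a list
#'   with `$chrom`, `$start`, `$end` (the chromosome is then checked).
#' @param gene a `gene_model`.
#' @return numeric `c(rel_start, rel_end)`.
#' @export
to_relative <- function(interval, gene) {
  if (is.list(interval)) {
    if (!is.null(interval$chrom) && interval$chrom != gene$chrom)
      stop("interval on ", interval$chrom, " but gene ", gene$gene_id,
           " is on ", gene$chrom)
    interval <- c(interval$start, interval$end)
  }
  if (interval[1] >= interval[2]) stop("interval start must be < end")
  r <- rel_coords(interval[1], interval[2], gene)
  c(rel_start = r[1, 1], rel_end = r[1, 2])
}

#' Convert a TSS-relative interval back to genomic coordinates
#'
#' Exact inverse of [to_relative()].
#'
#' @param rel numeric `c(rel_start, rel_end)`.
#' @param gene a `gene_model`.
#' @return numeric `c(start, end)` genomic, 0-based half-open.
#' @export
to_absolute <- function(rel, gene) {
  if (gene$strand == "+")
    c(start = gene$span_start + rel[[1]], end = gene$span_start + rel[[2]])
  else
    c(start = gene$span_end - rel[[2]], end = gene$span_end - rel[[1]])
}

# Map the peaks of one peak set into a gene's relative window. Peaks are
# stored unclipped; admission is by >= 1 bp overlap with the window
# [-flank_up, L + flank_down).
map_track <- function(peaks, gene, flank_up, flank_down) {
  L <- gene_length(gene)
  on_chrom <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0)
    return(data.frame(rel_start = numeric(), rel_end = numeric(),
                      score = numeric(), signal_value = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  r <- rel_coords(on_chrom$start, on_chrom$end, gene)
  keep <- r[, "rel_end"] > -flank_up & r[, "rel_start"] < L + flank_down
  out <- data.frame(rel_start = r[keep, "rel_start"],
                    rel_end = r[keep, "rel_end"],
                    score = on_chrom$score[keep],
                    signal_value = on_chrom$signal_value[keep],
                    name = on_chrom$name[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$rel_start, out$rel_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble per-gene panels of TSS-relative tracks, expression and neighbours
#'
#' The mapper: for each gene, every feature track is cut down to the window
#' `[-flank_up, gene_length + flank_down)`, transformed to TSS-relative
#' orientation-corrected coordinates (intervals kept unclipped, admitted by
#' overlap), exons and neighbouring genes are mapped the same way, and
#' expression values are joined by any gene alias. Panels start with
#' `show = TRUE`.
#'
#' @param genes list of `gene_model` (e.g. `resolve_genes(...)$resolved`).
#' @param peaksets list of `peak_set`.
#' @param expr list of `expression_table` (may be empty).
#' @param settings a [panel_settings()] object; score/size cutoffs are
#'   applied here.
#' @param ann the `annotation_set`, used for neighbour lookup.
#' @return list of `gene_panel` objects.
#' @export
build_panels <- function(genes, peaksets, expr = list(),
                         settings = panel_settings(), ann = NULL) {
  stopifnot(inherits(settings, "panel_settings"))
  peaksets <- lapply(peaksets, apply_cutoffs,
                     min_score = settings$min_peak_score,
                     min_size = settings$min_peak_size,
                     max_size = settings$max_peak_size)
  tids <- vapply(peaksets, function(ps) track_id(ps$key), "")
  if (anyDuplicated(tids)) stop("duplicate track keys: ",
                                paste(unique(tids[duplicated(tids)]),
                                      collapse = ", "))
  lapply(genes, function(gene) {
    L <- gene_length(gene)
    tracks <- stats::setNames(lapply(peaksets, function(ps)
      map_track(ps$peaks, gene, settings$flank_up, settings$flank_down)), tids)
    tracks <- tracks[order(names(tracks))]   # canonical track order
    ex <- rel_coords(gene$exons[, 1], gene$exons[, 2], gene)
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    exons_rel <- data.frame(rel_start = ex[, 1], rel_end = ex[, 2])
    nb <- if (is.null(ann)) list()
          else find_neighbors(gene, settings$flank_up, settings$flank_down, ann)
    neighbors <- if (length(nb) == 0)
      data.frame(gene_id = character(), rel_start = numeric(),
                 rel_end = numeric(), orientation = character(),
                 stringsAsFactors = FALSE)
    else {
      nd <- do.call(rbind, lapply(nb, function(n) {
        r <- rel_coords(n$gene$span_start, n$gene$span_end, gene)
        data.frame(gene_id = n$gene$gene_id, rel_start = r[1, 1],
                   rel_end = r[1, 2], orientation = n$orientation,
                   stringsAsFactors = FALSE)
      }))
      nd <- nd[order(nd$rel_start, nd$rel_end, nd$gene_id), , drop = FALSE]
      rownames(nd) <- NULL
      nd
    }
    known <- tolower(c(gene$gene_id, gene$aliases))
    evals <- vapply(expr, function(et) {
      hit <- match(known, tolower(names(et$values)))
      hit <- hit[!is.na(hit)]
      if (length(hit) == 0) NA_real_ else unname(et$values[hit[1]])
    }, 0)
    expression <- stats::setNames(evals,
                                  vapply(expr, `[[`, "", "cell_type"))
    expression <- expression[order(names(expression))]
    structure(list(gene = gene, flank_up = settings$flank_up,
                   flank_down = settings$flank_down, gene_length = L,
                   tracks = tracks, expression = expression,
                   neighbors = neighbors, exons_rel = exons_rel,
                   show = TRUE),
              class = "gene_panel")
  })
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %s (%s, %d bp), window [%d, %d), %d track(s), show=%s\n",
              x$gene$gene_id, x$gene$strand, x$gene_length,
              -x$flank_up, x$gene_length + x$flank_down,
              length(x$tracks), x$show))
  invisible(x)
}

# Relative window of a panel: [-flank_up, gene_length + flank_down).
panel_window <- function(panel) c(-panel$flank_up,
                                  panel$gene_length + panel$flank_down)

#' Re-map panels with new flanking windows
#'
#' Equivalent to rebuilding the panels from scratch with the new flanks;
#' the show flags of the current panels are preserved.
#'
#' @param panels existing list of `gene_panel`.
#' @param peaksets,expr,ann the original inputs.
#' @param settings current [panel_settings()].
#' @param flank_up,flank_down new flanks in bp.
#' @return list of rebuilt `gene_panel` objects.
#' @export
set_flanks <- function(panels, peaksets, expr, settings, ann,
                       flank_up, flank_down) {
  stopifnot(flank_up >= 0, flank_down >= 0)
  settings$flank_up <- flank_up
  settings$flank_down <- flank_down
  genes <- lapply(panels, `[[`, "gene")
  out <- build_panels(genes, peaksets, expr, settings, ann)
  for (i in seq_along(out)) out[[i]]$show <- panels[[i]]$show
  out
}
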