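# Independent brute-force oracles, written against the definitions (per-pair
# and per-base reasoning), not against the implementation.

# bases strictly between two half-open integer intervals, by enumeration
bf_gap <- function(a, b) {
  if (a[1] < b[2] && b[1] < a[2]) return(0)          # overlap
  lo <- min(a[2], b[2]); hi <- max(a[1], b[1])
  between <- seq_len(max(0, hi - lo)) - 1 + lo       # bases lo .. hi-1
  length(between)
}

# all-pairs scan of every gene against a window, per the window definition
bf_neighbors <- function(gene, flank_up, flank_down, genes) {
  if (gene$strand == "+") {
    lo <- gene$span_start - flank_up; hi <- gene$span_end + flank_down
  } else {
    lo <- gene$span_start - flank_down; hi <- gene$span_end + flank_up
  }
  out <- list()
  for (other in genes) {
    if (other$gene_id == gene$gene_id) next
    if (other$chrom != gene$chrom) next
    if (other$span_start < hi && other$span_end > lo)
      out[[length(out) + 1L]] <- list(
        gene = other,
        orientation = if (other$strand == gene$strand) "same" else "opposite")
  }
  out
}

# window admission oracle: which peaks of a raw peak table land in a gene's
# relative window, recomputed from first principles
bf_window_peaks <- function(peaks, gene, flank_up, flank_down) {
  L <- gene$span_end - gene$span_start
  hits <- integer()
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != gene$chrom) next
    if (gene$strand == "+") {
      rs <- peaks$start[i] - gene$span_start
      re <- peaks$end[i] - gene$span_start
    } else {
      rs <- gene$span_end - peaks$end[i]
      re <- gene$span_end - peaks$start[i]
    }
    if (rs < L + flank_down && re > -flank_up) hits <- c(hits, i)
  }
  hits
}

# O(n*m) all-pairs oracle for the overlap filter on one panel
bf_overlap <- function(panel, cell_type, mark_a, target, relation,
                       max_distance, window_rel = NULL) {
  w <- if (is.null(window_rel)) c(-panel$flank_up,
                                  panel$gene_length + panel$flank_down)
       else c(max(window_rel[1], -panel$flank_up),
              min(window_rel[2], panel$gene_length + panel$flank_down))
  if (w[1] >= w[2]) return(FALSE)
  a <- panel$tracks[[paste(cell_type, mark_a, sep = "|")]]
  b <- if (identical(target, "exons")) panel$exons_rel
       else panel$tracks[[paste(cell_type, target, sep = "|")]]
  for (i in seq_len(nrow(a))) {
    if (!(a$rel_start[i] < w[2] && a$rel_end[i] > w[1])) next
    for (j in seq_len(nrow(b))) {
      if (!(b$rel_start[j] < w[2] && b$rel_end[j] > w[1])) next
      p <- c(a$rel_start[i], a$rel_end[i])
      q <- c(b$rel_start[j], b$rel_end[j])
      ok <- switch(relation,
        near = bf_gap(p, q) <= max_distance,
        a_upstream_of_b = p[2] <= q[1] && q[1] - p[2] <= max_distance,
        a_downstream_of_b = p[1] >= q[2] && p[1] - q[2] <= max_distance)
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# count oracle for the feature-count filter on one panel
bf_count <- function(panel, cell_type, mark, window_rel = NULL) {
  w <- if (is.null(window_rel)) c(-panel$flank_up,
                                  panel$gene_length + panel$flank_down)
       else c(max(window_rel[1], -panel$flank_up),
              min(window_rel[2], panel$gene_length + panel$flank_down))
  if (w[1] >= w[2]) return(0L)
  tr <- panel$tracks[[paste(cell_type, mark, sep = "|")]]
  n <- 0L
  for (i in seq_len(nrow(tr)))
    if (tr$rel_start[i] < w[2] && tr$rel_end[i] > w[1]) n <- n + 1L
  n
}

# per-base coverage oracle for occupancy profiles (small windows only)
bf_profile_tss <- function(panels, key, bin_size) {
  fu <- panels[[1]]$flank_up; fd <- panels[[1]]$flank_down
  edges <- seq(-fu, fd, by = bin_size)
  if (edges[length(edges)] < fd) edges <- c(edges, fd)
  vals <- numeric(length(edges) - 1L)
  for (j in seq_along(vals)) {
    bases <- seq(edges[j], edges[j + 1L] - 1)
    n_occ <- 0
    for (p in panels) {
      tr <- p$tracks[[key]]
      cov <- rep(FALSE, length(bases))
      for (i in seq_len(nrow(tr)))
        cov <- cov | (bases >= tr$rel_start[i] & bases < tr$rel_end[i])
      if (any(cov)) n_occ <- n_occ + 1
    }
    vals[j] <- n_occ / length(panels)
  }
  vals
}

# sort-and-interpolate percentile oracle (linear interpolation between
# order statistics, the type-7 definition written out)
bf_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
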