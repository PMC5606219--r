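# Deterministic synthetic genomes, peak landscapes and expression tables
# with plantable epigenetic patterns. Every generator consumes an explicit
# seed through one RNG stream, so any artifact is bit-reproducible.

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes of random length and strand along
#' `n_chroms` chromosomes (round-robin), separated by random intergenic
#' gaps, each with 1-10 exons tiling part of its body.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chroms number of chromosomes.
#' @param length_range gene length range in bp.
#' @param seed integer seed; identical arguments give identical output.
#' @param gap_range intergenic gap range in bp (default keeps default-flank
#'   windows of distinct TSSs from piling up).
#' @param chrom_length optional fixed chromosome length; an error is raised
#'   if the genes do not fit.
#' @return an `annotation_set`.
#' @export
make_annotation <- function(n_genes, n_chroms = 2,
                            length_range = c(2000, 20000), seed = 1,
                            gap_range = c(25000, 60000),
                            chrom_length = NULL) {
  stopifnot(n_genes >= 1, n_chroms >= 1, length_range[1] >= 200)
  with_seed(seed, {
    chrom_of <- rep(paste0("chr", seq_len(n_chroms)), length.out = n_genes)
    genes <- vector("list", n_genes)
    cursor <- stats::setNames(rep(10000, n_chroms),
                              paste0("chr", seq_len(n_chroms)))
    for (i in seq_len(n_genes)) {
      ch <- chrom_of[i]
      L <- round(stats::runif(1, length_range[1], length_range[2]))
      s <- cursor[[ch]] + round(stats::runif(1, gap_range[1], gap_range[2]))
      e <- s + L
      if (!is.null(chrom_length) && e > chrom_length)
        stop("genome too small to place ", n_genes, " genes (chromosome ",
             ch, " needs > ", e, " bp)")
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(1:10, 1)
      # exon/intron tiling: 2*n_ex sorted breakpoints, consecutive pairs
      # are exons, the gaps between pairs are introns
      bounds <- sort(c(0, stats::runif(2 * n_ex - 2, 0, 1), 1))
      ex <- matrix(round(s + bounds * L), ncol = 2, byrow = TRUE)
      ex <- ex[ex[, 1] < ex[, 2], , drop = FALSE]
      if (nrow(ex) == 0) ex <- matrix(c(s, e), ncol = 2)
      ex[1, 1] <- s; ex[nrow(ex), 2] <- e   # first/last exon at the ends
      genes[[i]] <- gene_model(sprintf("G%04d", i), ch, strand, s, e,
                               exons = ex,
                               aliases = sprintf("TX%04d", i),
                               description = "synthetic gene")
      cursor[[ch]] <- e
    }
    cl <- if (is.null(chrom_length)) NULL
          else stats::setNames(rep(chrom_length, n_chroms),
                               paste0("chr", seq_len(n_chroms)))
    build_annotation_set(genes, chrom_lengths = cl)
  })
}

#' Generate gene-independent background peaks
#'
#' Peak counts are Poisson in the genome length at `rate_per_100kb` peaks
#' per 100 kb, placed uniformly with uniform sizes and scores.
#'
#' @param ann an `annotation_set` (provides chromosome lengths).
#' @param key a `track_key` for the generated track.
#' @param rate_per_100kb expected peaks per 100 kb (>= 0).
#' @param size_range,score_range peak size (bp) and score ranges.
#' @param seed integer seed.
#' @return a `peak_set`.
#' @export
make_background_peaks <- function(ann, key, rate_per_100kb = 2,
                                  size_range = c(200, 2000),
                                  score_range = c(100, 1000), seed = 1) {
  stopifnot(rate_per_100kb >= 0)
  with_seed(seed, {
    rows <- list()
    for (ch in names(ann$chrom_lengths)) {
      len <- ann$chrom_lengths[[ch]]
      n <- stats::rpois(1, rate_per_100kb * len / 1e5)
      if (n == 0) next
      start <- round(stats::runif(n, 0, len - size_range[2]))
      size <- round(stats::runif(n, size_range[1], size_range[2]))
      rows[[ch]] <- data.frame(chrom = ch, start = start, end = start + size,
                               name = sprintf("%s_bg%04d", ch, seq_len(n)),
                               score = round(stats::runif(n, score_range[1],
                                                          score_range[2])),
                               strand = ".", signal_value = NA_real_,
                               p_value = NA_real_, q_value = NA_real_,
                               summit_offset = -1, stringsAsFactors = FALSE)
    }
    peaks <- if (length(rows)) do.call(rbind, rows) else empty_peaks_df()
    peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
    rownames(peaks) <- NULL
    new_peak_set(peaks, key = key, source = "<synthetic>", format = "bed")
  })
}

#' Generate a synthetic expression table
#'
#' Log-normal FPKM-like values for every gene of the annotation, keyed by
#' gene id.
#'
#' @param ann an `annotation_set`.
#' @param cell_type label for the generated table.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal parameters (defaults roughly match the
#'   skewed shape of RNA-seq FPKM distributions).
#' @return an `expression_table`.
#' @export
make_expression <- function(ann, cell_type, seed = 1,
                            meanlog = 0, sdlog = 1.2) {
  with_seed(seed, {
    ids <- vapply(ann$genes, `[[`, "", "gene_id")
    vals <- round(stats::rlnorm(length(ids), meanlog, sdlog), 3)
    structure(list(cell_type = cell_type,
                   values = stats::setNames(vals, ids),
                   source = "<synthetic>",
                   parse_reports = data.frame(line = integer(),
                                              reason = character())),
              class = "expression_table")
  })
}

#' Describe a plantable epigenetic pattern
#'
#' @param kind `"bivalent_tss"` (overlapping pair of marks near the TSS),
#'   `"exon_proximal"` (a mark within `max_distance` of an exon),
#'   `"upstream_pair"` (mark_a upstream of mark_b within `max_distance`),
#'   `"expression_high"` (expression at or above `threshold`),
#'   `"mark_present"` / `"mark_absent"` (presence/absence of one mark in a
#'   window).
#' @param target_genes gene ids that must carry the pattern; all other genes
#'   are guaranteed not to carry it (de-confounding by removal).
#' @param cell_type cell type of the involved tracks.
#' @param marks the mark (or pair of marks) involved.
#' @param window_rel TSS-relative window `c(a, b)` the pattern lives in.
#' @param max_distance separation bound in bp for proximity patterns.
#' @param threshold,value_range expression threshold and planted value range
#'   for `expression_high`.
#' @param absent_marks marks whose peaks are removed from the target genes'
#'   windows (e.g. to construct "clean" bivalent promoters).
#' @return a `pattern_spec`.
#' @export
pattern_spec <- function(kind = c("bivalent_tss", "exon_proximal",
                                  "upstream_pair", "expression_high",
                                  "mark_present", "mark_absent"),
                         target_genes, cell_type = NULL, marks = NULL,
                         window_rel = c(-5000, 2000), max_distance = 0,
                         threshold = NULL, value_range = NULL,
                         absent_marks = character()) {
  kind <- match.arg(kind)
  if (!is.null(window_rel)) stopifnot(window_rel[1] < window_rel[2])
  stopifnot(max_distance >= 0)
  structure(list(kind = kind, target_genes = as.character(target_genes),
                 cell_type = cell_type, marks = marks,
                 window_rel = window_rel, max_distance = max_distance,
                 threshold = threshold, value_range = value_range,
                 absent_marks = absent_marks),
            class = "pattern_spec")
}

# index of the peak set with the given key
find_ps <- function(peaksets, cell_type, mark) {
  id <- track_id(cell_type, mark)
  ids <- vapply(peaksets, function(ps) track_id(ps$key), "")
  i <- match(id, ids)
  if (is.na(i)) stop("no peak set with key '", id, "'")
  i
}

# genomic interval of a TSS-relative window on a gene
window_abs <- function(gene, window_rel) to_absolute(window_rel, gene)

# drop peaks of a set overlapping a genomic interval, keeping planted ones
drop_in <- function(ps, chrom, s, e, keep_planted = TRUE) {
  p <- ps$peaks
  hit <- p$chrom == chrom & p$start < e & p$end > s
  if (keep_planted) hit <- hit & !grepl("^planted_", p$name)
  ps$peaks <- p[!hit, , drop = FALSE]
  rownames(ps$peaks) <- NULL
  ps
}

add_peak <- function(ps, chrom, s, e, name, score = 900) {
  ps$peaks <- rbind(ps$peaks,
                    data.frame(chrom = chrom, start = s, end = e, name = name,
                               score = score, strand = ".",
                               signal_value = NA_real_, p_value = NA_real_,
                               q_value = NA_real_, summit_offset = -1,
                               stringsAsFactors = FALSE))
  o <- order(ps$peaks$chrom, ps$peaks$start, ps$peaks$end)
  ps$peaks <- ps$peaks[o, , drop = FALSE]
  rownames(ps$peaks) <- NULL
  ps
}

#' Plant an epigenetic pattern into synthetic data
#'
#' For each target gene, inserts intervals or expression values guaranteed to
#' satisfy the pattern's matching filter; every non-target gene is
#' additionally guaranteed *not* to satisfy it -- accidental instances are
#' removed rather than resampled (de-confounding), so filter recovery is an
#' exact set equality.
#'
#' @param ann the `annotation_set` the peaks/expression belong to.
#' @param peaksets list of `peak_set` (modified copies are returned).
#' @param expr list of `expression_table`.
#' @param spec a [pattern_spec()].
#' @param seed integer seed for planted positions/values.
#' @return `list(peaksets = ..., expr = ...)`.
#' @export
plant_pattern <- function(ann, peaksets, expr, spec, seed = 1) {
  stopifnot(inherits(spec, "pattern_spec"))
  ids <- vapply(ann$genes, `[[`, "", "gene_id")
  if (!all(spec$target_genes %in% ids))
    stop("target_genes contain ids absent from the annotation")
  is_target <- ids %in% spec$target_genes

  with_seed(seed, {
    if (spec$kind == "expression_high") {
      stopifnot(!is.null(spec$threshold))
      vr <- spec$value_range %||% c(spec$threshold, spec$threshold * 3)
      ci <- match(spec$cell_type, vapply(expr, `[[`, "", "cell_type"))
      if (is.na(ci)) stop("no expression table for cell type '",
                          spec$cell_type, "'")
      et <- expr[[ci]]
      for (i in seq_along(ids)) {
        g <- ann$genes[[i]]
        keys <- intersect(c(g$gene_id, g$aliases), names(et$values))
        if (length(keys) == 0) { keys <- g$gene_id; et$values[keys] <- 0 }
        if (is_target[i]) {
          et$values[keys] <- round(stats::runif(1, vr[1], vr[2]), 3)
        } else if (any(et$values[keys] >= spec$threshold)) {
          et$values[keys] <- round(stats::runif(1, 0,
                                                spec$threshold * 0.9), 3)
        }
      }
      expr[[ci]] <- et
      return(list(peaksets = peaksets, expr = expr))
    }

    marks <- spec$marks
    if (spec$kind %in% c("bivalent_tss", "upstream_pair") &&
        length(marks) != 2)
      stop(spec$kind, " needs exactly two marks")
    ai <- find_ps(peaksets, spec$cell_type, marks[1])
    bi <- if (length(marks) >= 2) find_ps(peaksets, spec$cell_type, marks[2])

    for (i in seq_along(ids)) {
      g <- ann$genes[[i]]
      # NULL window = the full default 20 kb-flank panel window of this gene
      w <- spec$window_rel %||% c(-20000, gene_length(g) + 20000)
      wa <- window_abs(g, w)   # genomic span of the relative window
      if (is_target[i]) {
        mid <- round(mean(w))
        if (spec$kind == "bivalent_tss") {
          a_rel <- c(mid - 300, mid + 100)
          b_rel <- c(mid - 100, mid + 300)   # overlapping pair
          aa <- to_absolute(a_rel, g); bb <- to_absolute(b_rel, g)
          peaksets[[ai]] <- add_peak(peaksets[[ai]], g$chrom, aa[1], aa[2],
                                     paste0("planted_", g$gene_id, "_a"))
          peaksets[[bi]] <- add_peak(peaksets[[bi]], g$chrom, bb[1], bb[2],
                                     paste0("planted_", g$gene_id, "_b"))
        } else if (spec$kind == "upstream_pair") {
          d <- min(spec$max_distance, 200)
          a_rel <- c(mid - 400, mid - d)
          b_rel <- c(mid, mid + 400)
          aa <- to_absolute(a_rel, g); bb <- to_absolute(b_rel, g)
          peaksets[[ai]] <- add_peak(peaksets[[ai]], g$chrom, aa[1], aa[2],
                                     paste0("planted_", g$gene_id, "_a"))
          peaksets[[bi]] <- add_peak(peaksets[[bi]], g$chrom, bb[1], bb[2],
                                     paste0("planted_", g$gene_id, "_b"))
        } else if (spec$kind == "exon_proximal") {
          # peak just downstream of the first exon end, within max_distance
          ex <- rel_coords(g$exons[, 1], g$exons[, 2], g)
          ex <- ex[order(ex[, 1]), , drop = FALSE]
          d <- floor(spec$max_distance / 2)
          p_rel <- c(ex[1, 2] + d, ex[1, 2] + d + 300)
          aa <- to_absolute(p_rel, g)
          peaksets[[ai]] <- add_peak(peaksets[[ai]], g$chrom, aa[1], aa[2],
                                     paste0("planted_", g$gene_id))
        } else if (spec$kind == "mark_present") {
          aa <- to_absolute(c(mid - 200, mid + 200), g)
          peaksets[[ai]] <- add_peak(peaksets[[ai]], g$chrom, aa[1], aa[2],
                                     paste0("planted_", g$gene_id))
        } else if (spec$kind == "mark_absent") {
          peaksets[[ai]] <- drop_in(peaksets[[ai]], g$chrom, wa[1], wa[2],
                                    keep_planted = FALSE)
        }
        for (m in spec$absent_marks) {
          mi <- find_ps(peaksets, spec$cell_type, m)
          peaksets[[mi]] <- drop_in(peaksets[[mi]], g$chrom, wa[1], wa[2],
                                    keep_planted = FALSE)
        }
      } else {
        # de-confound: make sure this gene cannot satisfy the pattern
        if (spec$kind %in% c("bivalent_tss", "upstream_pair")) {
          repeat {
            pa <- peaksets[[ai]]$peaks
            pb <- peaksets[[bi]]$peaks
            ina <- which(pa$chrom == g$chrom & pa$start < wa[2] & pa$end > wa[1] &
                           !grepl("^planted_", pa$name))
            inb <- which(pb$chrom == g$chrom & pb$start < wa[2] & pb$end > wa[1])
            if (length(ina) == 0 || length(inb) == 0) break
            ra <- rel_coords(pa$start[ina], pa$end[ina], g)
            rb <- rel_coords(pb$start[inb], pb$end[inb], g)
            offend <- integer()
            for (k in seq_along(ina)) {
              gap_ok <- if (spec$kind == "bivalent_tss")
                pmax(0, pmax(ra[k, 1], rb[, 1]) - pmin(ra[k, 2], rb[, 2])) <=
                  spec$max_distance
              else ra[k, 2] <= rb[, 1] & rb[, 1] - ra[k, 2] <= spec$max_distance
              if (any(gap_ok)) offend <- c(offend, ina[k])
            }
            if (length(offend) == 0) break
            peaksets[[ai]]$peaks <- pa[-offend, , drop = FALSE]
            rownames(peaksets[[ai]]$peaks) <- NULL
          }
        } else if (spec$kind == "exon_proximal") {
          pa <- peaksets[[ai]]$peaks
          ina <- which(pa$chrom == g$chrom & pa$start < wa[2] & pa$end > wa[1] &
                         !grepl("^planted_", pa$name))
          if (length(ina)) {
            ra <- rel_coords(pa$start[ina], pa$end[ina], g)
            ex <- rel_coords(g$exons[, 1], g$exons[, 2], g)
            offend <- ina[vapply(seq_along(ina), function(k)
              any(pmax(0, pmax(ra[k, 1], ex[, 1]) -
                         pmin(ra[k, 2], ex[, 2])) <= spec$max_distance),
              TRUE)]
            if (length(offend)) {
              peaksets[[ai]]$peaks <- pa[-offend, , drop = FALSE]
              rownames(peaksets[[ai]]$peaks) <- NULL
            }
          }
        } else if (spec$kind == "mark_present") {
          peaksets[[ai]] <- drop_in(peaksets[[ai]], g$chrom, wa[1], wa[2],
                                    keep_planted = TRUE)
        }
        # mark_absent: nothing to enforce on non-targets
      }
    }
    list(peaksets = peaksets, expr = expr)
  })
}

# --- file writers so end-to-end runs can work from disk artifacts -----------

#' Write an annotation set as a UCSC-style table plus ID-map document
#' @param ann an `annotation_set`.
#' @param table_path output TSV path.
#' @param id_map_path optional output path for the JSON ID map.
#' @export
write_annotation <- function(ann, table_path, id_map_path = NULL) {
  rows <- vapply(ann$genes, function(g) {
    paste(c(g$aliases[1] %||% g$gene_id, g$chrom, g$strand,
            format(g$span_start, scientific = FALSE),
            format(g$span_end, scientific = FALSE),
            paste0(paste(format(g$exons[, 1], scientific = FALSE, trim = TRUE),
                         collapse = ","), ","),
            paste0(paste(format(g$exons[, 2], scientific = FALSE, trim = TRUE),
                         collapse = ","), ","),
            g$gene_id, g$description), collapse = "\t")
  }, "")
  writeLines(c(paste(c("name", "chrom", "strand", "txStart", "txEnd",
                       "exonStarts", "exonEnds", "name2", "description"),
                     collapse = "\t"), rows), table_path)
  if (!is.null(id_map_path))
    writeLines(canonical_json(default_id_map()), id_map_path)
  invisible(table_path)
}

#' Write a plain one-identifier-per-line gene list
#' @param ids character vector of gene identifiers.
#' @param path output path.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
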