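# Fixture builders used across the suite. All randomness is seeded.

# Minimal in-memory gene panel with explicit tracks, used by filter and
# summary unit tests.
mk_panel <- function(gene_id = "G1", strand = "+", L = 10000,
                     flank_up = 20000, flank_down = 20000,
                     tracks = list(), expression = numeric(),
                     exons = NULL, show = TRUE) {
  gene <- gene_model(gene_id, "chr1", strand, 100000, 100000 + L,
                     exons = exons)
  tr <- lapply(tracks, function(m) {
    data.frame(rel_start = m[, 1], rel_end = m[, 2],
               score = if (ncol(m) >= 3) m[, 3] else rep(500, nrow(m)),
               signal_value = rep(NA_real_, nrow(m)),
               name = sprintf("p%d", seq_len(nrow(m))),
               stringsAsFactors = FALSE)
  })
  ex <- if (is.null(exons)) matrix(c(0, L), ncol = 2)
        else {
          r <- cbind(exons[, 1] - 100000, exons[, 2] - 100000)
          if (strand == "-") r <- cbind(L - r[, 2], L - r[, 1])
          r[order(r[, 1]), , drop = FALSE]
        }
  structure(list(gene = gene, flank_up = flank_up, flank_down = flank_down,
                 gene_length = L, tracks = tr,
                 expression = expression,
                 neighbors = data.frame(gene_id = character(),
                                        rel_start = numeric(),
                                        rel_end = numeric(),
                                        orientation = character(),
                                        stringsAsFactors = FALSE),
                 exons_rel = data.frame(rel_start = ex[, 1],
                                        rel_end = ex[, 2]),
                 show = show),
            class = "gene_panel")
}

rel_track <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# Random small instance: annotation + background tracks + panels
mk_instance <- function(seed, n_genes = 20, tracks = 2, rate = 3,
                        flank_up = 20000, flank_down = 20000) {
  ann <- make_annotation(n_genes, n_chroms = 2, seed = seed)
  marks <- c("H3K4me3", "H3K27me3", "H3K36me3")[seq_len(tracks)]
  peaksets <- lapply(seq_along(marks), function(i)
    make_background_peaks(ann, track_key("cellA", marks[i]),
                          rate_per_100kb = rate, seed = seed * 13 + i))
  settings <- panel_settings(flank_up = flank_up, flank_down = flank_down)
  panels <- build_panels(ann$genes, peaksets, list(), settings, ann)
  list(ann = ann, peaksets = peaksets, settings = settings,
       panels = panels, marks = marks)
}

# Mirror-image genome: every coordinate x -> C - x on its chromosome,
# strands flipped, exon order reversed.
reflect_annotation <- function(ann) {
  genes <- lapply(ann$genes, function(g) {
    C <- ann$chrom_lengths[[g$chrom]]
    gene_model(g$gene_id, g$chrom, if (g$strand == "+") "-" else "+",
               C - g$span_end, C - g$span_start,
               exons = cbind(C - g$exons[, 2], C - g$exons[, 1]),
               aliases = g$aliases, description = g$description)
  })
  epipanel:::build_annotation_set(genes, chrom_lengths = ann$chrom_lengths)
}

reflect_peaks <- function(ps, chrom_lengths) {
  C <- chrom_lengths[ps$peaks$chrom]
  s <- C - ps$peaks$end
  e <- C - ps$peaks$start
  ps$peaks$start <- s
  ps$peaks$end <- e
  ps$peaks <- ps$peaks[order(ps$peaks$chrom, ps$peaks$start, ps$peaks$end), ,
                       drop = FALSE]
  rownames(ps$peaks) <- NULL
  ps
}

# Use-case fixtures ---------------------------------------------------------
# Structural mirrors of the two published workflows, built on synthetic data:
# a bivalent-promoter search (overlap + two absence filters over a 330-gene
# panel recovering 13 planted genes, narrowed to 1 by cell-type-resolution
# filters) and an exon-proximal H3K36me3 search (97 genes, 19 of them highly
# expressed).

mk_usecase1 <- function(seed = 1, n_genes = 330, n_biv = 13) {
  esc <- "H1-hESC"; k562 <- "K562"
  win <- c(-5000, 2000)
  ann <- make_annotation(n_genes, n_chroms = 4, seed = seed)
  ids <- vapply(ann$genes, `[[`, "", "gene_id")
  keys <- list(track_key(esc, "H3K4me3"), track_key(esc, "H3K27me3"),
               track_key(esc, "H3K36me3"), track_key(esc, "H3K9ac"),
               track_key(k562, "H3K4me3"), track_key(k562, "H3K27me3"))
  peaksets <- lapply(seq_along(keys), function(i)
    make_background_peaks(ann, keys[[i]], rate_per_100kb = 2,
                          seed = seed * 101 + i))
  targets <- with_seed(seed + 7, sample(ids, n_biv))
  single <- targets[1]
  planted <- plant_pattern(ann, peaksets, list(),
                           pattern_spec("bivalent_tss", targets,
                                        cell_type = esc,
                                        marks = c("H3K4me3", "H3K27me3"),
                                        window_rel = win, max_distance = 0,
                                        absent_marks = c("H3K36me3", "H3K9ac")),
                           seed = seed + 11)
  planted <- plant_pattern(ann, planted$peaksets, list(),
                           pattern_spec("mark_present", single,
                                        cell_type = k562, marks = "H3K4me3",
                                        window_rel = win),
                           seed = seed + 12)
  planted <- plant_pattern(ann, planted$peaksets, list(),
                           pattern_spec("mark_absent", single,
                                        cell_type = k562, marks = "H3K27me3",
                                        window_rel = win),
                           seed = seed + 13)
  chain <- filter_chain(
    filter_feature_overlap(esc, "H3K4me3", target = "H3K27me3",
                           relation = "near", max_distance = 0,
                           window_rel = win),
    filter_feature_count(esc, "H3K36me3", window_rel = win, op = "=", count = 0),
    filter_feature_count(esc, "H3K9ac", window_rel = win, op = "=", count = 0))
  chain_ext <- filter_chain(c(chain$filters, list(
    filter_feature_count(k562, "H3K4me3", window_rel = win,
                         op = ">=", count = 1),
    filter_feature_count(k562, "H3K27me3", window_rel = win,
                         op = "=", count = 0))))
  list(ann = ann, peaksets = planted$peaksets, targets = sort(targets),
       single = single, chain = chain, chain_ext = chain_ext,
       cells = c(esc, k562))
}

mk_usecase2 <- function(seed = 2, n_genes = 330, n_prox = 97, n_high = 19) {
  esc <- "H1-hESC"
  ann <- make_annotation(n_genes, n_chroms = 4, seed = seed)
  ids <- vapply(ann$genes, `[[`, "", "gene_id")
  peaksets <- list(make_background_peaks(ann, track_key(esc, "H3K36me3"),
                                         rate_per_100kb = 2,
                                         seed = seed * 101 + 1))
  expr <- list(make_expression(ann, esc, seed = seed * 101 + 2))
  prox <- with_seed(seed + 7, sample(ids, n_prox))
  high <- with_seed(seed + 8, sample(prox, n_high))
  planted <- plant_pattern(ann, peaksets, expr,
                           pattern_spec("exon_proximal", prox,
                                        cell_type = esc, marks = "H3K36me3",
                                        window_rel = NULL,
                                        max_distance = 500),
                           seed = seed + 11)
  planted <- plant_pattern(ann, planted$peaksets, planted$expr,
                           pattern_spec("expression_high", high,
                                        cell_type = esc, threshold = 3.2,
                                        value_range = c(3.3, 12)),
                           seed = seed + 12)
  chain <- filter_chain(
    filter_feature_overlap(esc, "H3K36me3", target = "exons",
                           relation = "near", max_distance = 500),
    filter_expression(esc, ">=", 3.2))
  list(ann = ann, peaksets = planted$peaksets, expr = planted$expr,
       prox = sort(prox), high = sort(high), chain = chain, cell = esc)
}
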