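#' Construct a gene model
#'
#' A gene model is one gene after isoform collapse: its genomic span, strand
#' and exon structure. All coordinates are 0-based half-open (BED convention).
#'
#' @param gene_id canonical symbol.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param span_start,span_end genomic bp, 0-based half-open, `span_start < span_end`.
#' @param exons two-column matrix of exon `[start, end)` intervals, sorted and
#'   non-overlapping, all within the span.
#' @param aliases character vector of alternate identifiers.
#' @param description free text.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, span_start, span_end,
                       exons = NULL, aliases = character(), description = "") {
  span_start <- as.numeric(span_start); span_end <- as.numeric(span_end)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!(span_start >= 0 && span_start < span_end))
    stop("invalid span for gene ", gene_id, ": [", span_start, ", ", span_end, ")")
  if (is.null(exons)) exons <- matrix(c(span_start, span_end), ncol = 2)
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) > 0) {
    o <- order(exons[, 1], exons[, 2])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[, 1] >= exons[, 2]) ||
        any(exons[, 1] < span_start) || any(exons[, 2] > span_end))
      stop("exons of gene ", gene_id, " violate span/ordering invariants")
    if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
      stop("exons of gene ", gene_id, " overlap")
  }
  structure(list(gene_id = gene_id,
                 aliases = unique(as.character(aliases)),
                 chrom = chrom, strand = strand,
                 span_start = span_start, span_end = span_end,
                 exons = exons, description = description),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s)\n", x$gene_id,
              x$chrom, x$span_start, x$span_end, x$strand, nrow(x$exons)))
  invisible(x)
}

gene_length <- function(gene) gene$span_end - gene$span_start

# Default ID-map document: UCSC Table Browser export column roles.
default_id_map <- function() {
  list(columns = list(transcript_id = "name", gene_id = "name2",
                      chrom = "chrom", strand = "strand",
                      tx_start = "txStart", tx_end = "txEnd",
                      exon_starts = "exonStarts", exon_ends = "exonEnds",
                      description = "description"),
       alias_columns = list("name"))
}

# Parse a UCSC comma-terminated position list ("100,300," -> c(100, 300)).
parse_comma_list <- function(x) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  suppressWarnings(as.numeric(parts))
}

#' Load a genome annotation table with its ID-map document
#'
#' Reads a UCSC Table Browser-style tab-separated annotation (one row per
#' transcript) together with a JSON ID map naming which columns carry which
#' roles and which columns hold gene aliases. Transcript rows are collapsed to
#' one model per gene (largest genomic span, ties broken by file order) and
#' indexed by every known identifier, case-insensitively.
#'
#' @param table_path path to the tab-separated annotation table.
#' @param id_map_path optional path to the JSON ID-map document; when `NULL`
#'   the standard UCSC column names are assumed.
#' @return an `annotation_set`: collapsed `genes`, the raw `transcripts` table,
#'   an identifier index, a per-chromosome interval index and per-chromosome
#'   lengths. `$parse_reports` lists rows skipped with reasons.
#' @export
load_annotation <- function(table_path, id_map_path = NULL) {
  if (!file.exists(table_path)) stop("annotation file not found: ", table_path)
  idm <- if (is.null(id_map_path)) default_id_map()
         else jsonlite::fromJSON(id_map_path, simplifyVector = FALSE)
  cols <- idm$columns
  tab <- utils::read.delim(table_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#", check.names = FALSE)
  required <- c("transcript_id", "gene_id", "chrom", "strand",
                "tx_start", "tx_end", "exon_starts", "exon_ends")
  miss <- vapply(required, function(role) {
    cn <- cols[[role]]
    if (is.null(cn) || !cn %in% names(tab))
      paste0("'", cn %||% role, "' (role: ", role, ")")
    else NA_character_
  }, "")
  miss <- miss[!is.na(miss)]
  if (length(miss))
    stop("annotation table is missing required column",
         if (length(miss) > 1) "s" else "", " ",
         paste(miss, collapse = ", "))
  desc_col <- cols[["description"]]
  alias_cols <- unlist(idm$alias_columns)

  reports <- list(); keep <- logical(nrow(tab))
  tx <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, , drop = FALSE]
    s <- suppressWarnings(as.numeric(row[[cols$tx_start]]))
    e <- suppressWarnings(as.numeric(row[[cols$tx_end]]))
    strand <- as.character(row[[cols$strand]])
    reason <- NULL
    ex_s <- parse_comma_list(as.character(row[[cols$exon_starts]]))
    ex_e <- parse_comma_list(as.character(row[[cols$exon_ends]]))
    if (is.na(s) || is.na(e)) reason <- "unparsable coordinate"
    else if (!(s >= 0 && s < e)) reason <- "span_start >= span_end"
    else if (!strand %in% c("+", "-")) reason <- "invalid strand"
    else if (length(ex_s) != length(ex_e) || anyNA(ex_s) || anyNA(ex_e))
      reason <- "unparsable exon list"
    else if (length(ex_s) > 0 &&
             (any(ex_s >= ex_e) || any(ex_s < s) || any(ex_e > e)))
      reason <- "exon outside span"
    if (!is.null(reason)) {
      reports[[length(reports) + 1L]] <- data.frame(line = i + 1L,
                                                    reason = reason)
      next
    }
    keep[i] <- TRUE
    tx[[i]] <- list(transcript_id = as.character(row[[cols$transcript_id]]),
                    gene_id = as.character(row[[cols$gene_id]]),
                    chrom = as.character(row[[cols$chrom]]),
                    strand = strand, tx_start = s, tx_end = e,
                    exon_starts = ex_s, exon_ends = ex_e,
                    description = if (!is.null(desc_col) && desc_col %in% names(tab))
                      as.character(row[[desc_col]]) else "",
                    aliases = unique(as.character(unlist(
                      row[intersect(alias_cols, names(tab))]))))
  }
  tx <- tx[keep]
  if (length(tx) == 0) stop("annotation table contains no valid rows")

  # Isoform collapse: per gene_id, keep the transcript with the largest
  # genomic span; ties keep the first occurrence in the file.
  gid <- vapply(tx, `[[`, "", "gene_id")
  spans <- vapply(tx, function(t) t$tx_end - t$tx_start, 0)
  genes <- list()
  for (g in unique(gid)) {
    idx <- which(gid == g)
    best <- idx[which.max(spans[idx])]   # which.max -> first max = file order
    t <- tx[[best]]
    aliases <- unique(c(unlist(lapply(tx[idx], `[[`, "aliases")),
                        vapply(tx[idx], `[[`, "", "transcript_id")))
    genes[[length(genes) + 1L]] <-
      gene_model(g, t$chrom, t$strand, t$tx_start, t$tx_end,
                 exons = cbind(t$exon_starts, t$exon_ends),
                 aliases = setdiff(aliases, g), description = t$description)
  }
  build_annotation_set(genes,
                       transcripts = tx,
                       parse_reports = if (length(reports))
                         do.call(rbind, reports)
                       else data.frame(line = integer(), reason = character()))
}

# Assemble an annotation_set from a list of gene_model objects.
build_annotation_set <- function(genes, transcripts = NULL,
                                 parse_reports = NULL, chrom_lengths = NULL) {
  ids <- character(); tgt <- integer()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    for (id in tolower(unique(c(g$gene_id, g$aliases)))) {
      if (id %in% ids) {
        if (tgt[match(id, ids)] != i)
          warning("identifier '", id, "' maps to multiple genes; keeping first")
        next
      }
      ids <- c(ids, id); tgt <- c(tgt, i)
    }
  }
  id_index <- stats::setNames(tgt, ids)
  chroms <- vapply(genes, `[[`, "", "chrom")
  gr <- GenomicRanges::GRanges(
    seqnames = chroms,
    ranges = IRanges::IRanges(
      start = vapply(genes, `[[`, 0, "span_start") + 1,
      end = vapply(genes, `[[`, 0, "span_end")))
  if (is.null(chrom_lengths)) {
    ends <- vapply(genes, `[[`, 0, "span_end")
    chrom_lengths <- tapply(ends, chroms, max) + 10000
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  structure(list(genes = genes, transcripts = transcripts,
                 id_index = id_index, chrom_index = gr,
                 chrom_lengths = chrom_lengths,
                 parse_reports = parse_reports),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d gene(s) on %d chromosome(s); %d identifier(s) indexed\n",
              length(x$genes), length(x$chrom_lengths), length(x$id_index)))
  invisible(x)
}

#' Resolve gene identifiers to gene models
#'
#' Looks up each name case-insensitively across all known identifiers and
#' aliases. Duplicate input names are de-duplicated preserving first-seen
#' order; unresolvable names are returned, never raised.
#'
#' @param names character vector of identifiers.
#' @param ann an `annotation_set`.
#' @return `list(resolved = <list of gene_model>, unresolved = <character>)`.
#' @export
resolve_genes <- function(names, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (length(names) == 0) stop("names must be non-empty")
  names <- as.character(names)
  names <- names[!duplicated(tolower(names))]
  hit <- ann$id_index[tolower(names)]
  resolved <- ann$genes[hit[!is.na(hit)]]
  # the same gene may be hit through several of the requested identifiers
  resolved <- resolved[!duplicated(vapply(resolved, `[[`, "", "gene_id"))]
  list(resolved = resolved, unresolved = names[is.na(hit)])
}

# Genomic analysis window of a gene: span extended strand-aware, flank_up on
# the TSS side, flank_down beyond the transcription end.
gene_window <- function(gene, flank_up, flank_down) {
  if (gene$strand == "+")
    c(gene$span_start - flank_up, gene$span_end + flank_down)
  else
    c(gene$span_start - flank_down, gene$span_end + flank_up)
}

#' Find neighboring or overlapping genes
#'
#' Returns every other gene whose genomic span overlaps the target gene's
#' analysis window (its span extended by the flanks, strand-aware), together
#' with its orientation relative to the target.
#'
#' @param gene a `gene_model`.
#' @param flank_up,flank_down flanks in bp (`>= 0`); `flank_up` extends the
#'   TSS side.
#' @param ann the `annotation_set` containing the neighbourhood.
#' @return list of `list(gene = <gene_model>, orientation = "same"|"opposite")`.
#' @export
find_neighbors <- function(gene, flank_up, flank_down, ann) {
  stopifnot(flank_up >= 0, flank_down >= 0)
  w <- gene_window(gene, flank_up, flank_down)
  q <- GenomicRanges::GRanges(gene$chrom,
                              IRanges::IRanges(start = w[1] + 1,
                                               end = max(w[2], w[1] + 1)))
  hits <- GenomicRanges::findOverlaps(q, ann$chrom_index)
  idx <- S4Vectors::subjectHits(hits)
  out <- list()
  for (i in idx) {
    other <- ann$genes[[i]]
    if (identical(other$gene_id, gene$gene_id)) next
    out[[length(out) + 1L]] <- list(
      gene = other,
      orientation = if (other$strand == gene$strand) "same" else "opposite")
  }
  out
}
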