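#' Track key: the (cell type, mark) identity of a feature file
#'
#' @param cell_type,mark non-empty labels.
#' @return a `track_key` object. Its canonical string form is
#'   `"<cell_type>|<mark>"` (see [track_id()]).
#' @export
track_key <- function(cell_type, mark) {
  if (!nzchar(cell_type) || !nzchar(mark))
    stop("cell_type and mark must be non-empty")
  structure(list(cell_type = cell_type, mark = mark), class = "track_key")
}

#' Canonical string form of a track key
#' @param key a `track_key` (or the cell type, with `mark` given separately).
#' @param mark optional mark label when `key` is a cell-type string.
#' @return `"<cell_type>|<mark>"`.
#' @export
track_id <- function(key, mark = NULL) {
  if (inherits(key, "track_key")) paste(key$cell_type, key$mark, sep = "|")
  else paste(key, mark, sep = "|")
}

#' @export
print.track_key <- function(x, ...) {
  cat("<track_key>", track_id(x), "\n"); invisible(x)
}

empty_peaks_df <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             signal_value = numeric(), p_value = numeric(),
             q_value = numeric(), summit_offset = numeric(),
             stringsAsFactors = FALSE)
}

new_peak_set <- function(peaks, key = NULL, source = "<memory>",
                         format = "bed", parse_reports = NULL) {
  if (is.null(parse_reports))
    parse_reports <- data.frame(line = integer(), reason = character())
  structure(list(key = key, peaks = peaks, source = source, format = format,
                 parse_reports = parse_reports),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s: %d peak(s) [%s], %d malformed line(s)\n",
              if (is.null(x$key)) x$source else track_id(x$key),
              nrow(x$peaks), x$format, nrow(x$parse_reports)))
  invisible(x)
}

# Missing-value sentinels per the ENCODE conventions: "." or -1 in the
# signal/p/q columns means "not provided" (stored as NA); summit -1 means
# no summit call.
num_or_na <- function(x) {
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  out[x == "." | (!is.na(out) & out == -1)] <- NA_real_
  out
}

parse_peak_fields <- function(f, format) {
  n <- length(f)
  start <- suppressWarnings(as.numeric(f[2]))
  end <- suppressWarnings(as.numeric(f[3]))
  if (is.na(start) || is.na(end)) return("unparsable coordinate")
  if (start < 0) return("negative coordinate")
  if (start >= end) return("start >= end")
  name <- if (n >= 4) f[4] else "."
  score <- if (n >= 5) suppressWarnings(as.numeric(f[5])) else 0
  if (is.na(score)) score <- 0
  if (score < 0) return("negative score")
  strand <- if (n >= 6) f[6] else "."
  if (!strand %in% c("+", "-", ".")) return("invalid strand")
  signal <- p <- q <- NA_real_
  summit <- -1
  if (format %in% c("broadPeak", "narrowPeak")) {
    signal <- num_or_na(f[7]); p <- num_or_na(f[8]); q <- num_or_na(f[9])
  }
  if (format == "narrowPeak") {
    summit <- suppressWarnings(as.numeric(f[10]))
    if (is.na(summit)) return("unparsable summit offset")
    if (summit != -1 && (summit < 0 || summit >= end - start))
      return("summit offset outside peak")
  }
  data.frame(chrom = f[1], start = start, end = end, name = name,
             score = score, strand = strand, signal_value = signal,
             p_value = p, q_value = q, summit_offset = summit,
             stringsAsFactors = FALSE)
}

infer_peak_format <- function(path, ncol) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "narrowpeak" || ncol == 10) "narrowPeak"
  else if (ext == "broadpeak" || ncol == 9) "broadPeak"
  else "bed"
}

#' Read a BED / broadPeak / narrowPeak feature file
#'
#' Parses one peak per well-formed line; malformed lines are skipped and
#' reported with their line number and reason. Lines starting with `#`,
#' `track` or `browser` are treated as headers. Scores above the nominal BED
#' cap of 1000 are accepted with a warning (real ENCODE files exceed it).
#'
#' @param path input file.
#' @param format `"bed"`, `"broadPeak"`, `"narrowPeak"` or `"auto"`
#'   (inferred from extension and column count).
#' @param key optional `track_key`; when `NULL` it is auto-mapped from the
#'   file name via [auto_map_attributes()].
#' @param manifest optional named list mapping file names to
#'   `c(cell_type, mark)`, overriding auto-mapping.
#' @return a `peak_set`.
#' @export
read_peaks <- function(path, format = c("auto", "bed", "broadPeak", "narrowPeak"),
                       key = NULL, manifest = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("feature file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  body_idx <- which(!is_comment)
  rows <- list(); reports <- list()
  fmt <- if (format == "auto" && length(body_idx))
    infer_peak_format(path, length(strsplit(lines[body_idx[1]], "\t")[[1]]))
  else if (format == "auto") "bed" else format
  min_cols <- switch(fmt, narrowPeak = 10L, broadPeak = 9L, 3L)
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < min_cols) {
      reports[[length(reports) + 1L]] <-
        data.frame(line = i, reason = sprintf("expected >= %d columns, got %d",
                                              min_cols, length(f)))
      next
    }
    res <- parse_peak_fields(f, fmt)
    if (is.character(res))
      reports[[length(reports) + 1L]] <- data.frame(line = i, reason = res)
    else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0) stop("no well-formed lines in ", path)
  peaks <- do.call(rbind, rows)
  if (any(peaks$score > 1000))
    warning("scores above the nominal BED cap of 1000 in ", basename(path))
  if (is.null(key)) key <- auto_map_attributes(path, manifest = manifest)
  new_peak_set(peaks, key = key, source = path, format = fmt,
               parse_reports = if (length(reports)) do.call(rbind, reports)
                               else NULL)
}

#' Write a peak set back to a BED-family file
#'
#' Emits the columns of the set's format so that parsing the written file
#' reproduces the peak set (round-trip identity).
#'
#' @param ps a `peak_set`.
#' @param path output path.
#' @param format output dialect; defaults to the set's own.
#' @export
write_peaks <- function(ps, path, format = NULL) {
  format <- format %||% ps$format
  p <- ps$peaks
  dot <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  cols <- list(p$chrom, format(p$start, scientific = FALSE, trim = TRUE),
               format(p$end, scientific = FALSE, trim = TRUE),
               p$name, format(p$score, scientific = FALSE, trim = TRUE),
               p$strand)
  if (format %in% c("broadPeak", "narrowPeak"))
    cols <- c(cols, list(dot(p$signal_value), dot(p$p_value), dot(p$q_value)))
  if (format == "narrowPeak")
    cols <- c(cols, list(format(p$summit_offset, scientific = FALSE, trim = TRUE)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Auto-map a feature file name to its (cell type, mark) attributes
#'
#' The file-name stem is split on its first underscore into cell type and
#' mark, e.g. `"H1-hESC_H3K4me3.narrowPeak"` maps to `(H1-hESC, H3K4me3)`.
#' A manifest entry for the file overrides the rule; a stem with no
#' underscore yields mark `"unknown"` with a warning.
#'
#' @param filename path or file name.
#' @param manifest optional named list `list("<basename>" = c(cell, mark))`.
#' @return a `track_key`.
#' @export
auto_map_attributes <- function(filename, manifest = NULL) {
  base <- basename(filename)
  if (!is.null(manifest) && base %in% names(manifest)) {
    m <- manifest[[base]]
    return(track_key(m[[1]], m[[2]]))
  }
  stem <- tools::file_path_sans_ext(base)
  if (!grepl("_", stem, fixed = TRUE)) {
    warning("file name '", base, "' has no cell-type/mark delimiter; ",
            "mark set to 'unknown'")
    return(track_key(stem, "unknown"))
  }
  parts <- regmatches(stem, regexpr("_", stem, fixed = TRUE), invert = TRUE)[[1]]
  track_key(parts[1], parts[2])
}

#' Read a two-column expression table
#'
#' Tab-separated `identifier<TAB>value` rows with FPKM-like non-negative
#' values. Duplicate identifiers keep the maximum value (with a warning);
#' malformed lines are reported and skipped.
#'
#' @param path input file.
#' @param cell_type label of the cell type / condition the table belongs to.
#' @return an `expression_table` with `$values` (named numeric) and
#'   `$parse_reports`.
#' @export
read_expression <- function(path, cell_type) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!grepl("^\\s*($|#)", lines))
  vals <- numeric(); ids <- character(); reports <- list()
  dup_warned <- FALSE
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    v <- if (length(f) >= 2) suppressWarnings(as.numeric(f[2])) else NA_real_
    reason <- if (length(f) < 2) "expected 2 columns"
              else if (is.na(v) || is.nan(v)) "unparsable value"
              else if (v < 0) "negative value"
              else NULL
    if (!is.null(reason)) {
      reports[[length(reports) + 1L]] <- data.frame(line = i, reason = reason)
      next
    }
    j <- match(f[1], ids)
    if (!is.na(j)) {
      if (!dup_warned) {
        warning("duplicate identifiers in ", basename(path),
                "; keeping the maximum value")
        dup_warned <- TRUE
      }
      vals[j] <- max(vals[j], v)
    } else {
      ids <- c(ids, f[1]); vals <- c(vals, v)
    }
  }
  if (length(vals) == 0) stop("no valid expression rows in ", path)
  structure(list(cell_type = cell_type,
                 values = stats::setNames(vals, ids),
                 source = path,
                 parse_reports = if (length(reports)) do.call(rbind, reports)
                                 else data.frame(line = integer(),
                                                 reason = character())),
            class = "expression_table")
}

#' Write an expression table to a two-column TSV
#' @param tbl an `expression_table`.
#' @param path output path.
#' @export
write_expression <- function(tbl, path) {
  writeLines(paste(names(tbl$values),
                   format(tbl$values, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Filter a peak set on score and size cutoffs
#'
#' Keeps peaks with `score >= min_score` and size (end - start) within
#' `[min_size, max_size]`. The input set is not modified.
#'
#' @param ps a `peak_set`.
#' @param min_score minimum peak score.
#' @param min_size,max_size peak size bounds in bp.
#' @return a new `peak_set` with the surviving peaks.
#' @export
apply_cutoffs <- function(ps, min_score = 0, min_size = 0, max_size = Inf) {
  stopifnot(min_size >= 0, min_size <= max_size)
  p <- ps$peaks
  size <- p$end - p$start
  keep <- p$score >= min_score & size >= min_size & size <= max_size
  out <- ps
  out$peaks <- p[keep, , drop = FALSE]
  rownames(out$peaks) <- NULL
  out
}
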