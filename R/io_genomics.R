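# Readers/writers for the genomic plain-text formats the tool touches:
# BED3+/narrowPeak peak files and BED4 chromatin-state segmentations.
# Coordinates are 0-based half-open throughout (BED convention).

#' Construct a PeakSet
#'
#' A `PeakSet` holds one protein's ChIP-seq peak intervals, sorted by
#' (chromosome, start) with natural chromosome ordering. Zero-length
#' intervals are invalid.
#'
#' @param peaks data.frame with columns `chrom` (character), `start`, `end`
#'   (integers, 0-based half-open) and optionally `label`.
#' @param protein protein / transcription-factor name.
#' @param source free-text provenance tag (file path and dialect).
#' @return object of class `PeakSet`: a list with elements `protein`,
#'   `peaks` (sorted data.frame) and `source`.
#' @export
peak_set <- function(peaks, protein, source = NA_character_) {
  stopifnot(is.data.frame(peaks))
  if (!all(c("chrom", "start", "end") %in% names(peaks)))
    abort("peaks must have columns chrom, start, end")
  if (is.null(peaks$label)) peaks$label <- NA_character_
  peaks <- peaks[, c("chrom", "start", "end", "label")]
  peaks$chrom <- as.character(peaks$chrom)
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  validate_intervals(peaks)
  if (any(peaks$end <= peaks$start))
    abort("PeakSet contains zero- or negative-length peaks")
  ord <- order(natural_chrom_rank(peaks$chrom), peaks$start, peaks$end)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(protein = as.character(protein), peaks = peaks,
                 source = source),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peaks on %d chromosome(s)\n",
              x$protein, nrow(x$peaks), length(unique(x$peaks$chrom))))
  invisible(x)
}

#' Construct a StateSegmentation
#'
#' A chromatin-state segmentation: labeled genome windows (e.g. diHMM
#' domain-level states "D1", "D5", ...). Windows on the same chromosome
#' must not overlap.
#'
#' @param windows data.frame with columns `chrom`, `start`, `end`, `label`.
#' @return object of class `StateSegmentation`: list with `windows` (sorted
#'   data.frame) and `states` (sorted unique labels).
#' @export
state_segmentation <- function(windows) {
  stopifnot(is.data.frame(windows))
  if (!all(c("chrom", "start", "end", "label") %in% names(windows)))
    abort("segmentation windows must have columns chrom, start, end, label")
  windows <- windows[, c("chrom", "start", "end", "label")]
  windows$chrom <- as.character(windows$chrom)
  windows$start <- as.integer(windows$start)
  windows$end <- as.integer(windows$end)
  windows$label <- as.character(windows$label)
  validate_intervals(windows)
  if (any(windows$end <= windows$start))
    abort("segmentation contains empty windows")
  ord <- order(natural_chrom_rank(windows$chrom), windows$start)
  windows <- windows[ord, , drop = FALSE]
  rownames(windows) <- NULL
  # overlap check within each chromosome on the sorted windows
  for (chrom in unique(windows$chrom)) {
    w <- windows[windows$chrom == chrom, , drop = FALSE]
    if (nrow(w) > 1L) {
      bad <- which(w$start[-1L] < w$end[-nrow(w)])
      if (length(bad)) {
        i <- bad[1L]
        abort(sprintf(
          "overlapping windows on %s: [%d,%d) '%s' and [%d,%d) '%s'",
          chrom, w$start[i], w$end[i], w$label[i],
          w$start[i + 1L], w$end[i + 1L], w$label[i + 1L]))
      }
    }
  }
  structure(list(windows = windows, states = sort(unique(windows$label))),
            class = "StateSegmentation")
}

#' @export
print.StateSegmentation <- function(x, ...) {
  cat(sprintf("StateSegmentation: %d windows, %d states (%s)\n",
              nrow(x$windows), length(x$states),
              paste(utils::head(x$states, 6), collapse = ", ")))
  invisible(x)
}

validate_intervals <- function(df) {
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
    abort("chromosome names must be non-empty")
  if (anyNA(df$start) || anyNA(df$end))
    abort("start/end must be integers")
  if (any(df$start < 0))
    abort("start positions must be >= 0")
  invisible(df)
}

# Shared line-oriented parser: skips 'track', 'browser' and '#' header lines
# and returns a list(fields = list of character vectors, lineno = integer).
read_bed_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser)\\b|^#|^\\s*$", lines)
  list(fields = strsplit(lines[keep], "[\t ]+"),
       lineno = which(keep))
}

#' Read a peak file (BED or ENCODE narrowPeak)
#'
#' Header lines starting with `track`, `browser` or `#` are skipped. BED
#' requires at least 3 tab-separated columns; narrowPeak requires exactly 10.
#' The narrowPeak summit column is parsed but not used: downstream the event
#' location is always the interval center (see [peak_centers()]).
#'
#' @param path path to the peak file.
#' @param dialect `"bed"` or `"narrowPeak"`.
#' @param protein protein name; defaults to the file stem.
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, dialect = c("bed", "narrowPeak"),
                       protein = NULL) {
  dialect <- match.arg(dialect)
  parsed <- read_bed_lines(path)
  if (!length(parsed$fields))
    abort(sprintf("no data lines in %s", path))
  min_cols <- if (dialect == "narrowPeak") 10L else 3L
  rows <- lapply(seq_along(parsed$fields), function(i) {
    f <- parsed$fields[[i]]
    ln <- parsed$lineno[i]
    if (length(f) < min_cols)
      abort(sprintf("%s line %d: expected >= %d columns, got %d",
                    path, ln, min_cols, length(f)))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      abort(sprintf("%s line %d: non-integer coordinates", path, ln))
    if (end <= start)
      abort(sprintf("%s line %d: end (%d) <= start (%d)", path, ln,
                    end, start))
    data.frame(chrom = f[1], start = start, end = end,
               label = if (length(f) >= 4L) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  if (is.null(protein))
    protein <- sub("\\.[^.]*$", "", basename(path))
  peak_set(do.call(rbind, rows), protein = protein,
           source = paste0(path, " [", dialect, "]"))
}

#' Write a PeakSet as BED4
#'
#' @param ps a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(ps, path) {
  stopifnot(inherits(ps, "PeakSet"))
  df <- ps$peaks
  df$label[is.na(df$label)] <- "."
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, df$label),
             path)
  invisible(path)
}

#' Read a chromatin-state segmentation (BED4)
#'
#' Column 4 must carry the state label (e.g. diHMM "D5"). Windows
#' overlapping within a chromosome are rejected with an error naming the
#' first offending pair.
#'
#' @param path path to the BED-like file.
#' @return a [state_segmentation()].
#' @export
read_segmentation <- function(path) {
  parsed <- read_bed_lines(path)
  if (!length(parsed$fields))
    abort(sprintf("no data lines in %s", path))
  rows <- lapply(seq_along(parsed$fields), function(i) {
    f <- parsed$fields[[i]]
    ln <- parsed$lineno[i]
    if (length(f) < 4L)
      abort(sprintf("%s line %d: missing state label column (need 4 columns)",
                    path, ln))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      abort(sprintf("%s line %d: non-integer coordinates", path, ln))
    if (end <= start)
      abort(sprintf("%s line %d: end (%d) <= start (%d)", path, ln, end, start))
    data.frame(chrom = f[1], start = start, end = end, label = f[4],
               stringsAsFactors = FALSE)
  })
  state_segmentation(do.call(rbind, rows))
}

#' Write a StateSegmentation as BED4
#'
#' @param seg a [state_segmentation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "StateSegmentation"))
  df <- seg$windows
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, df$label),
             path)
  invisible(path)
}

#' Peak centers as point events
#'
#' The center of each peak interval is treated as a single binary binding
#' event: `floor((start + end) / 2)`. Order of the peaks is preserved.
#'
#' @param ps a [peak_set()].
#' @return data.frame with columns `chrom` and `position` (one row per peak).
#' @export
peak_centers <- function(ps) {
  stopifnot(inherits(ps, "PeakSet"))
  df <- ps$peaks
  data.frame(chrom = df$chrom,
             position = (df$start + df$end) %/% 2L,
             stringsAsFactors = FALSE)
}
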