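# Shared internal helpers.

#' Natural ordering of chromosome names
#'
#' Orders chromosome names the way genome browsers do: `chr1 < chr2 < ... <
#' chr10 < ... < chrX < chrY`, i.e. numeric cores sort numerically and
#' non-numeric cores sort alphabetically after all numeric ones. A leading
#' `chr`/`Chr` prefix is ignored for ranking but preserved in the names.
#'
#' @param chroms character vector of chromosome names.
#' @return integer permutation such that `chroms[natural_chrom_order(chroms)]`
#'   is in natural order.
#' @examples
#' natural_chrom_order(c("chr10", "chr2", "chrX", "chr1"))
#' @export
natural_chrom_order <- function(chroms) {
  core <- sub("^[Cc]hr", "", chroms)
  num <- suppressWarnings(as.numeric(core))
  order(is.na(num), num, core)
}

#' @rdname natural_chrom_order
#' @return `natural_chrom_rank` returns, for each element, its rank in the
#'   natural order of the distinct names (ties share a rank).
#' @export
natural_chrom_rank <- function(chroms) {
  u <- unique(chroms)
  ranked <- u[natural_chrom_order(u)]
  match(chroms, ranked)
}

# stop() with a consistent prefix, no call in the condition
abort <- function(...) stop(..., call. = FALSE)

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    abort(sprintf("'%s' must be positive", name))
  invisible(x)
}
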