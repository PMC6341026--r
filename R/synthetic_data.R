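# Synthetic point-process generator: inhomogeneous Poisson patterns from
# known intensity archetypes (Gaussian-bump mixtures) plus toy BED
# fixtures, so inference and clustering are testable end-to-end with no
# external data.

#' Gaussian-bump mixture intensity
#'
#' Builds a closed-form non-negative intensity on `[0, L]`:
#' `lambda(s) = baseline + sum_k heights[k] * exp(-(s - centers[k])^2 /
#' (2 * widths[k]^2))`. The supremum is bounded by
#' `baseline + sum(heights)`, which the thinning sampler uses.
#'
#' @param centers,widths,heights equal-length numeric vectors; widths and
#'   heights must be positive and non-negative respectively.
#' @param baseline constant floor (default 0).
#' @return function(s) -> intensity; attributes `"lambda_max"` (upper
#'   bound) and `"mass"` (untruncated integral
#'   `baseline * L + sum(heights * widths * sqrt(2 * pi))` is *not*
#'   attached — integrate numerically when the exact mass on `[0, L]`
#'   matters).
#' @export
bump_intensity <- function(centers, widths, heights, baseline = 0) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(heights))
  if (any(widths <= 0)) abort("bump widths must be positive")
  if (any(heights < 0)) abort("bump heights must be non-negative")
  if (baseline < 0) abort("baseline must be non-negative")
  force(centers); force(widths); force(heights); force(baseline)
  f <- function(s) {
    out <- rep(baseline, length(s))
    for (k in seq_along(centers))
      out <- out + heights[k] * exp(-(s - centers[k])^2 / (2 * widths[k]^2))
    out
  }
  attr(f, "lambda_max") <- baseline + sum(heights)
  f
}

#' Sample an inhomogeneous Poisson pattern by Lewis–Shedler thinning
#'
#' Draws `Poisson(lambda_max * L)` homogeneous candidates on `[0, L]` and
#' keeps each with probability `lambda(s) / lambda_max`. Uses R's global
#' RNG unless `seed` is given.
#'
#' @param intensity non-negative function on `[0, L]`.
#' @param L interval length.
#' @param lambda_max finite upper bound on the intensity; defaults to the
#'   function's `"lambda_max"` attribute, else a numeric maximum over a
#'   fine grid (with 10% headroom).
#' @param seed optional integer seed.
#' @param protein,state names recorded on the pattern.
#' @return a [point_pattern()].
#' @export
sample_ipp <- function(intensity, L = 50, lambda_max = NULL, seed = NULL,
                       protein = NA_character_, state = NA_character_) {
  stopifnot(is.function(intensity))
  stopifnot_scalar_number(L, "L", positive = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(lambda_max)) {
    lambda_max <- attr(intensity, "lambda_max")
    if (is.null(lambda_max))
      lambda_max <- 1.1 * max(intensity(seq(0, L, length.out = 4096L)))
  }
  if (!is.finite(lambda_max))
    abort("lambda_max must be finite")
  if (lambda_max <= 0)
    return(point_pattern(numeric(0), protein = protein, state = state, L = L))
  n_cand <- stats::rpois(1L, lambda_max * L)
  s <- stats::runif(n_cand, 0, L)
  keep <- stats::runif(n_cand) < intensity(s) / lambda_max
  point_pattern(sort(s[keep]), protein = protein, state = state, L = L)
}

#' Default three-archetype recovery scenario configuration
#'
#' Three unimodal Gaussian bumps centered at 10, 25 and 40 on `[0, 50]`,
#' each of width 3 and total mass about 150 expected events per process —
#' localized shapes of the kind estimated from real binding data, well
#' separated so that cluster recovery is identifiable.
#'
#' @param L interval length.
#' @param mass expected events per process (bump integral).
#' @return list of archetype specs (`centers`, `widths`, `heights`).
#' @export
default_archetypes <- function(L = 50, mass = 150) {
  lapply(c(10, 25, 40), function(ctr) {
    w <- 3
    list(centers = ctr, widths = w, heights = mass / (w * sqrt(2 * pi)))
  })
}

#' Generate a labeled multi-process scenario
#'
#' Assigns `N` processes to the archetypes round-robin and samples each
#' independently with [sample_ipp()]; fully reproducible from `seed`.
#'
#' @param archetypes list of archetype specs as in [default_archetypes()]
#'   (each a list with `centers`, `widths`, `heights`, optional
#'   `baseline`).
#' @param N number of processes (>= number of archetypes).
#' @param L interval length.
#' @param seed integer seed.
#' @param state state label stamped on the patterns.
#' @return list with `scenario` (class `SyntheticScenario`: `K_true`,
#'   `intensities`, `labels`, `N`, `L`, `seed`) and `patterns` (list of
#'   [point_pattern()]s named proc01, proc02, ...).
#' @export
make_scenario <- function(archetypes = default_archetypes(), N = 12L,
                          L = 50, seed = 1L, state = "synthetic") {
  N <- as.integer(N)
  K <- length(archetypes)
  if (N < K) abort("N must be >= the number of archetypes")
  intensities <- lapply(archetypes, function(a)
    bump_intensity(a$centers, a$widths, a$heights, a$baseline %||% 0))
  labels <- rep_len(seq_len(K), N)
  set.seed(as.integer(seed))
  patterns <- lapply(seq_len(N), function(i)
    sample_ipp(intensities[[labels[i]]], L = L,
               protein = sprintf("proc%02d", i), state = state))
  scenario <- structure(list(K_true = K, intensities = intensities,
                             labels = labels, N = N, L = L,
                             seed = as.integer(seed)),
                        class = "SyntheticScenario")
  list(scenario = scenario, patterns = patterns)
}

# Deterministic toy genome used by make_fixtures(): 3 proteins, 2 states.
# Numbers are fixed in code (no RNG) so fixture files are byte-stable.
toy_fixture_spec <- function() {
  seg <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(0L, 6000L, 0L, 5000L),
    end   = c(6000L, 10000L, 5000L, 9000L),
    label = c("D1", "D5", "D5", "D1"),
    stringsAsFactors = FALSE)
  peaks <- list(
    TFA = data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                     start = c(100L, 2500L, 7000L, 1200L, 6200L),
                     end   = c(500L, 2900L, 7400L, 1600L, 6600L)),
    TFB = data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                     start = c(4000L, 8200L, 2000L, 4400L),
                     end   = c(4600L, 8800L, 2400L, 4800L)),
    TFC = data.frame(chrom = c("chr1", "chr2", "chr2"),
                     start = c(9000L, 500L, 7000L),
                     end   = c(9800L, 900L, 7800L)))
  list(segmentation = seg, peaks = peaks)
}

#' Write toy BED fixtures
#'
#' Writes one BED file per toy protein plus a two-state BED4 segmentation
#' under `outdir`. Deterministic: repeated runs produce identical files.
#' Projecting the fixture peaks through state "D5" reproduces the golden
#' pattern set shipped in `inst/extdata/golden_patterns.json` (itself
#' synthetic).
#'
#' @param outdir writable directory (created if missing).
#' @return named character vector of written paths.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- toy_fixture_spec()
  seg_path <- file.path(outdir, "segmentation.bed")
  write_segmentation(state_segmentation(spec$segmentation), seg_path)
  peak_paths <- vapply(names(spec$peaks), function(nm) {
    ps <- peak_set(spec$peaks[[nm]], protein = nm)
    write_peaks(ps, file.path(outdir, paste0(nm, ".bed")))
    file.path(outdir, paste0(nm, ".bed"))
  }, character(1))
  c(segmentation = seg_path, peak_paths)
}
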