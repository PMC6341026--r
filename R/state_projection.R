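# Projection of genome-coordinate binding events onto the common interval
# [0, L]. All genome windows of one domain-level chromatin state are
# concatenated (natural chromosome order, then start) and rescaled so the
# concatenated axis has total length L; peak centers falling inside the
# state's windows become point events on [0, L].

#' Build the genome-to-interval coordinate map for one state
#'
#' Concatenates every window of `state` into a single axis (windows ordered
#' by natural chromosome order then start) and records the running offset of
#' each window, so that genome positions can be mapped to the common
#' interval `[0, L]` by a single affine rescale of factor `L / total_bp`.
#'
#' @param seg a [state_segmentation()].
#' @param state state label present in `seg$states`.
#' @param L length of the common interval (default 50, dimensionless).
#' @return object of class `StateCoordinateMap`: list with `state`,
#'   `windows` (ordered data.frame), `cumulative_offsets` (bp running starts
#'   on the concatenated axis), `total_bp` and `L`.
#' @export
build_coordinate_map <- function(seg, state, L = 50) {
  stopifnot(inherits(seg, "StateSegmentation"))
  stopifnot_scalar_number(L, "L", positive = TRUE)
  if (!state %in% seg$states)
    abort(sprintf("unknown state '%s' (available: %s)", state,
                  paste(seg$states, collapse = ", ")))
  w <- seg$windows[seg$windows$label == state, , drop = FALSE]
  ord <- order(natural_chrom_rank(w$chrom), w$start)
  w <- w[ord, , drop = FALSE]
  rownames(w) <- NULL
  len <- w$end - w$start
  total_bp <- sum(as.numeric(len))
  if (total_bp <= 0) abort(sprintf("state '%s' covers zero bp", state))
  offsets <- cumsum(c(0, as.numeric(len)[-length(len)]))
  structure(list(state = state, windows = w, cumulative_offsets = offsets,
                 total_bp = total_bp, L = L),
            class = "StateCoordinateMap")
}

#' Construct a PointPattern
#'
#' One protein's binding events on the common interval: a sorted vector of
#' locations in `[0, L]`.
#'
#' @param events numeric vector of event locations.
#' @param protein protein name.
#' @param state chromatin-state label the events were projected from.
#' @param L interval length.
#' @return object of class `PointPattern`: list with `protein`, `state`,
#'   `events` (sorted), `L` and `n`.
#' @export
point_pattern <- function(events, protein = NA_character_,
                          state = NA_character_, L = 50) {
  events <- as.numeric(events)
  stopifnot_scalar_number(L, "L", positive = TRUE)
  if (anyNA(events) || any(!is.finite(events)))
    abort("events must be finite numbers")
  if (length(events) && (min(events) < 0 || max(events) > L))
    abort(sprintf("events outside [0, %g]", L))
  structure(list(protein = as.character(protein), state = as.character(state),
                 events = sort(events), L = L, n = length(events)),
            class = "PointPattern")
}

#' @export
print.PointPattern <- function(x, ...) {
  cat(sprintf("PointPattern '%s' (state %s): %d events on [0, %g]\n",
              x$protein, x$state, x$n, x$L))
  invisible(x)
}

# Nudge duplicated values in a sorted vector apart by the smallest workable
# increment so events remain simple points; clamps to [0, L].
make_events_distinct <- function(x, L) {
  if (!anyDuplicated(x)) return(x)
  eps <- max(.Machine$double.eps * max(1, L), .Machine$double.xmin)
  while (anyDuplicated(x)) {
    d <- duplicated(x)
    x[d] <- x[d] + eps * seq_len(sum(d))
    x <- sort(pmin(pmax(x, 0), L))
    eps <- eps * 2
  }
  x
}

#' Project peak centers onto the common interval of a state
#'
#' A center at genomic position `p` inside window `w` (half-open
#' `[start, end)`) maps to `(offset(w) + p - start(w)) * L / total_bp`.
#' Centers not covered by any window of the state are dropped. Duplicate
#' mapped positions are separated by a minimal jitter so the result is a
#' simple point pattern.
#'
#' @param centers data.frame with columns `chrom` and `position`
#'   (as returned by [peak_centers()]).
#' @param cmap a [build_coordinate_map()].
#' @param protein protein name recorded on the result.
#' @return a [point_pattern()] on `[0, cmap$L]`.
#' @export
project_peaks <- function(centers, cmap, protein = NA_character_) {
  stopifnot(inherits(cmap, "StateCoordinateMap"))
  stopifnot(is.data.frame(centers),
            all(c("chrom", "position") %in% names(centers)))
  w <- cmap$windows
  scale <- cmap$L / cmap$total_bp
  mapped <- numeric(0)
  if (nrow(centers)) {
    for (k in seq_len(nrow(w))) {
      hit <- centers$chrom == w$chrom[k] &
        centers$position >= w$start[k] & centers$position < w$end[k]
      if (any(hit)) {
        p <- centers$position[hit]
        mapped <- c(mapped,
                    (cmap$cumulative_offsets[k] + p - w$start[k]) * scale)
      }
    }
  }
  mapped <- make_events_distinct(sort(mapped), cmap$L)
  point_pattern(mapped, protein = protein, state = cmap$state, L = cmap$L)
}

#' Serialize / deserialize a list of PointPatterns as JSON
#'
#' The on-disk form is a JSON array of objects with fields `protein`,
#' `state`, `L` and `events`, the documented interchange format of the
#' `project` CLI subcommand.
#'
#' @param patterns list of [point_pattern()] objects.
#' @param path file path.
#' @return `write_patterns` returns `path` invisibly; `read_patterns`
#'   returns a list of `PointPattern`s.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(all(vapply(patterns, inherits, logical(1), "PointPattern")))
  payload <- lapply(patterns, function(p)
    list(protein = p$protein, state = p$state, L = p$L, events = p$events))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(p)
    point_pattern(as.numeric(unlist(p$events)), protein = p$protein,
                  state = p$state, L = as.numeric(p$L)))
}
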