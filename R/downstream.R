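# Post-clustering analyses: peak-in-state enrichment, proximal-gene
# assignment around the TSS, and expression summaries per protein or
# module.

#' Read a gene annotation/expression table (TSV)
#'
#' Expected columns: `gene`, `chrom`, `tss` (bp), `strand`, `tpm`.
#'
#' @param path TSV path with a header row.
#' @return validated data.frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_gene_table(df)
}

validate_gene_table <- function(df) {
  need <- c("gene", "chrom", "tss", "strand", "tpm")
  if (!all(need %in% names(df)))
    abort(sprintf("gene table needs columns: %s", paste(need, collapse = ", ")))
  if (any(df$tss < 0)) abort("TSS positions must be >= 0")
  if (any(df$tpm < 0)) abort("TPM values must be >= 0")
  df
}

#' Peak-center enrichment per chromatin state
#'
#' For each state, compares the share of peak centers falling in the
#' state's windows with the state's share of the genome:
#' `log2( ((n_state + 1) / (n_total + S)) / (state_bp / genome_bp) )`,
#' where S is the number of states — one pseudo-center per state keeps the
#' ratio finite and the smoothed shares normalized. Centers outside every
#' window count toward the total only.
#'
#' @param peaks a [peak_set()].
#' @param seg a [state_segmentation()].
#' @param genome_bp total genome size in bp (>= segmented bp).
#' @return data.frame with columns `state`, `n_centers`, `state_bp`,
#'   `log2_enrichment`, covering every state in `seg`.
#' @export
state_enrichment <- function(peaks, seg, genome_bp) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(seg, "StateSegmentation"))
  stopifnot_scalar_number(genome_bp, "genome_bp", positive = TRUE)
  seg_bp <- sum(as.numeric(seg$windows$end - seg$windows$start))
  if (genome_bp < seg_bp)
    abort("genome_bp is smaller than the total segmented bp")
  centers <- peak_centers(peaks)
  n_total <- nrow(centers)
  if (n_total == 0L) abort("PeakSet has no peaks")
  states <- seg$states
  S <- length(states)
  rows <- lapply(states, function(st) {
    w <- seg$windows[seg$windows$label == st, , drop = FALSE]
    inside <- vapply(seq_len(n_total), function(i)
      any(centers$chrom[i] == w$chrom & centers$position[i] >= w$start &
            centers$position[i] < w$end), logical(1))
    n_s <- sum(inside)
    bp_s <- sum(as.numeric(w$end - w$start))
    obs <- (n_s + 1) / (n_total + S)
    exp_share <- bp_s / genome_bp
    data.frame(state = st, n_centers = n_s, state_bp = bp_s,
               log2_enrichment = log2(obs / exp_share),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map genes to proteins bound proximally to their TSS
#'
#' A gene is bound by a protein iff any of that protein's peak centers
#' lies within `[TSS - window_bp, TSS + window_bp]`, boundaries inclusive;
#' strand is ignored.
#'
#' @param genes a gene table (see [read_gene_table()]).
#' @param centers either a data.frame with columns `chrom`, `position`,
#'   `protein`, or a named list of per-protein center data.frames
#'   (`chrom`, `position`) as from [peak_centers()].
#' @param window_bp half-width of the proximal window (default 2000).
#' @return named list: gene id -> character vector of bound proteins
#'   (possibly empty), one entry per gene.
#' @export
proximal_genes <- function(genes, centers, window_bp = 2000L) {
  genes <- validate_gene_table(genes)
  stopifnot_scalar_number(window_bp, "window_bp", positive = TRUE)
  if (is.data.frame(centers)) {
    stopifnot(all(c("chrom", "position", "protein") %in% names(centers)))
  } else {
    stopifnot(is.list(centers), !is.null(names(centers)))
    centers <- do.call(rbind, lapply(names(centers), function(nm)
      cbind(centers[[nm]][, c("chrom", "position")], protein = nm)))
  }
  out <- lapply(seq_len(nrow(genes)), function(g) {
    hit <- centers$chrom == genes$chrom[g] &
      abs(centers$position - genes$tss[g]) <= window_bp
    sort(unique(centers$protein[hit]))
  })
  stats::setNames(out, genes$gene)
}

#' Expression summaries per gene group
#'
#' Deterministic descriptive summaries — no hypothesis test is attached.
#' The log summary uses a pseudocount of 1: `mean(log2(TPM + 1))`.
#'
#' @param genes a gene table (see [read_gene_table()]).
#' @param groups named list: group label -> character vector of gene ids.
#' @return data.frame with columns `group`, `n`, `median_tpm`,
#'   `mean_log2_tpm1`, `empty` (TRUE when no group gene is in the table;
#'   medians are then NA).
#' @export
expression_by_group <- function(genes, groups) {
  genes <- validate_gene_table(genes)
  if (!length(groups)) abort("groups must be non-empty")
  if (is.null(names(groups))) abort("groups must be named")
  rows <- lapply(names(groups), function(g) {
    tpm <- genes$tpm[genes$gene %in% groups[[g]]]
    n <- length(tpm)
    data.frame(group = g, n = n,
               median_tpm = if (n) stats::median(tpm) else NA_real_,
               mean_log2_tpm1 = if (n) mean(log2(tpm + 1)) else NA_real_,
               empty = n == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
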