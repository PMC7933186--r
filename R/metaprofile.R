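#' Bin a transcript coverage vector into equal spans
#'
#' Splits the transcript into `n_bins` contiguous, maximally equal nucleotide
#' spans (when the length is not divisible the longer spans come first) and
#' returns the per-bin mean of per-base values. Transcripts shorter than
#' `n_bins` are not supported.
#'
#' @param values Numeric per-base vector (or a [coverage_track()]).
#' @param n_bins Number of bins (>= 1).
#' @return Numeric vector of length `n_bins`.
#' @export
gene_to_binned <- function(values, n_bins) {
  if (inherits(values, "coverage_track")) values <- values$values
  L <- length(values)
  stopifnot(n_bins >= 1)
  if (n_bins > L)
    stop("n_bins (", n_bins, ") exceeds transcript length (", L,
         "): unsupported")
  base <- L %/% n_bins
  rem <- L %% n_bins
  sizes <- c(rep(base + 1L, rem), rep(base, n_bins - rem))
  idx <- rep.int(seq_len(n_bins), sizes)
  as.numeric(tapply(values, idx, mean))
}

#' Scaled TSS-to-TTS metaprofile over a gene set
#'
#' Each gene's spliced, strand-oriented coverage is scaled into `n_bins` bins
#' ([gene_to_binned()]) and the profile is the unweighted per-bin mean across
#' genes, so each gene contributes equally regardless of length or abundance.
#' Replicate tracks should be averaged first (see [average_track_sets()]).
#' The TSS/TTS are the transcript 5'/3' ends in transcript orientation.
#'
#' @param tracks List of [coverage_track()]s (one per gene).
#' @param n_bins Gene-body bin count (default 100).
#' @param flank_bins Flank bins each side; only 0 is supported (coverage is
#'   represented on spliced transcripts, which have no genomic flanks).
#' @param label Free-text label for the profile.
#' @param weighted If TRUE, genes are weighted by their mean coverage
#'   (coverage-weighted mode); default FALSE.
#' @return Object of class `metaprofile`: list with `values` (mean RPM per
#'   bin), `n_bins`, `flank_bins`, `n_genes`, `label`.
#' @export
metaprofile <- function(tracks, n_bins = 100, flank_bins = 0, label = "",
                        weighted = FALSE) {
  if (length(tracks) < 1) stop("metaprofile requires at least one gene")
  if (flank_bins != 0)
    stop("flank_bins != 0 is not supported on spliced-transcript coverage")
  binned <- vapply(tracks, gene_to_binned, numeric(n_bins), n_bins = n_bins)
  binned <- matrix(binned, nrow = n_bins)
  if (weighted) {
    w <- colMeans(binned)
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / ncol(binned), ncol(binned))
    vals <- as.numeric(binned %*% w)
  } else {
    vals <- rowMeans(binned)
  }
  structure(list(values = vals, n_bins = n_bins, flank_bins = flank_bins,
                 n_genes = length(tracks), label = label),
            class = "metaprofile")
}

#' @export
print.metaprofile <- function(x, ...) {
  cat(sprintf("<metaprofile> '%s': %d bins over %d genes, mean %.3g RPM\n",
              x$label, x$n_bins, x$n_genes, mean(x$values)))
  invisible(x)
}

#' Average replicate track sets per gene
#'
#' Given several named lists of [coverage_track()]s (one list per replicate,
#' keyed by gene id), returns one list with the per-base mean per gene.
#'
#' @param track_sets List of named track lists.
#' @return Named list of averaged [coverage_track()]s.
#' @export
average_track_sets <- function(track_sets) {
  stopifnot(length(track_sets) >= 1)
  ids <- names(track_sets[[1]])
  lapply(stats::setNames(ids, ids), function(id) {
    mats <- lapply(track_sets, function(s) {
      if (is.null(s[[id]])) stop("gene ", id, " missing from a replicate set")
      s[[id]]$values
    })
    coverage_track(id, Reduce(`+`, mats) / length(mats),
                   track_sets[[1]][[id]]$orientation)
  })
}
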