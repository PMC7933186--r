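#' Per-gene coverage tracks
#'
#' A coverage track stores per-nucleotide normalized coverage (RPM) over the
#' spliced transcript, 5' to 3' in transcript orientation. Antisense tracks
#' (e.g. 22G-RNA coverage) are built from the genomic strand opposite the
#' gene and attributed to the target transcript's coordinates.
#'
#' @param gene_id Gene identifier.
#' @param values Numeric vector of non-negative per-base values, length equal
#'   to the gene's spliced length.
#' @param orientation `"sense"` or `"antisense"` relative to the gene.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(gene_id, values, orientation = c("antisense", "sense")) {
  orientation <- match.arg(orientation)
  values <- as.numeric(values)
  if (length(values) < 1 || anyNA(values) || any(values < 0))
    stop("track values must be non-negative and non-empty for gene ", gene_id)
  structure(list(gene_id = gene_id, orientation = orientation,
                 values = values),
            class = "coverage_track")
}

## window of an Rle coverage vector, zero-padded past its end (1-based coords)
rle_window <- function(rle, start1, end1) {
  n <- length(rle)
  if (start1 > n) return(numeric(end1 - start1 + 1))
  got <- as.numeric(S4Vectors::window(rle, start1, min(end1, n)))
  c(got, numeric(max(0, end1 - n)))
}

import_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!GenomicRanges::isDisjoint(gr))
    stop("overlapping intervals in bedGraph '", path, "'")
  gr
}

#' Extract spliced per-gene coverage from bedGraph files
#'
#' Builds one strand-oriented spliced coverage track per gene from a pair of
#' strand-specific bedGraph files, scaled to reads per million by
#' `1e6 / total_mapped`. Positions without coverage are 0. For `orientation =
#' "antisense"` a `+` gene reads the minus-strand file and vice versa.
#' Intervals on chromosomes not used by any gene are skipped with a warning;
#' overlapping intervals within a file are an error.
#'
#' @param path_plus,path_minus bedGraph files holding plus- and minus-strand
#'   coverage. Passing the same file to both treats coverage as unstranded.
#' @param genes Named list of [gene_model()] objects.
#' @param total_mapped Total mapped reads used for RPM scaling (> 0).
#' @param orientation `"antisense"` (default) or `"sense"`.
#' @return Named list of [coverage_track()] objects, one per gene.
#' @export
read_bedgraph_to_tracks <- function(path_plus, path_minus, genes, total_mapped,
                                    orientation = c("antisense", "sense")) {
  orientation <- match.arg(orientation)
  stopifnot(total_mapped > 0)
  known <- unique(vapply(genes, `[[`, "", "chrom"))
  covs <- lapply(list(plus = path_plus, minus = path_minus), function(p) {
    gr <- import_bedgraph(p)
    extra <- setdiff(as.character(unique(GenomicRanges::seqnames(gr))), known)
    if (length(extra)) {
      warning("skipping bedGraph intervals on unknown chromosome(s): ",
              paste(extra, collapse = ", "))
      gr <- gr[!(as.character(GenomicRanges::seqnames(gr)) %in% extra)]
    }
    if (length(gr) == 0) GenomicRanges::coverage(gr)
    else GenomicRanges::coverage(gr, weight = gr$score)
  })
  scale <- 1e6 / total_mapped
  out <- lapply(genes, function(gm) {
    src <- if (orientation == "antisense") {
      if (gm$strand == "+") "minus" else "plus"
    } else {
      if (gm$strand == "+") "plus" else "minus"
    }
    cov <- covs[[src]]
    if (gm$chrom %in% names(cov)) {
      vals <- unlist(lapply(seq_along(gm$exon_starts), function(i) {
        rle_window(cov[[gm$chrom]], gm$exon_starts[i] + 1L, gm$exon_ends[i])
      }), use.names = FALSE)
    } else {
      vals <- numeric(spliced_length(gm))
    }
    if (gm$strand == "-") vals <- rev(vals)
    coverage_track(gm$gene_id, vals * scale, orientation)
  })
  names(out) <- vapply(genes, `[[`, "", "gene_id")
  out
}

#' Project per-gene tracks back to genomic bedGraph files
#'
#' Inverse of [read_bedgraph_to_tracks()] for disjoint genes: transcript-space
#' values are mapped to exonic genomic intervals (run-length compressed) and
#' written to the strand file the track's orientation dictates. Zero runs are
#' omitted.
#'
#' @param tracks Named list of [coverage_track()] objects.
#' @param genes Named list of [gene_model()] objects covering the tracks.
#' @param path_plus,path_minus Output bedGraph paths.
#' @export
tracks_to_bedgraph <- function(tracks, genes, path_plus, path_minus) {
  rows <- list(plus = list(), minus = list())
  for (tr in tracks) {
    gm <- genes[[tr$gene_id]]
    if (is.null(gm)) stop("no gene model for track ", tr$gene_id)
    vals <- tr$values
    if (length(vals) != spliced_length(gm))
      stop("track length mismatch for gene ", tr$gene_id)
    if (gm$strand == "-") vals <- rev(vals)  # back to genomic orientation
    dest <- if (tr$orientation == "antisense") {
      if (gm$strand == "+") "minus" else "plus"
    } else {
      if (gm$strand == "+") "plus" else "minus"
    }
    off <- 0
    for (i in seq_along(gm$exon_starts)) {
      w <- gm$exon_ends[i] - gm$exon_starts[i]
      ev <- vals[(off + 1):(off + w)]
      r <- rle(ev)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        rows[[dest]][[length(rows[[dest]]) + 1L]] <- data.frame(
          chrom = gm$chrom,
          start = gm$exon_starts[i] + starts[keep],
          end = gm$exon_starts[i] + ends[keep],
          value = r$values[keep])
      }
      off <- off + w
    }
  }
  for (side in c("plus", "minus")) {
    path <- if (side == "plus") path_plus else path_minus
    if (length(rows[[side]])) {
      df <- do.call(rbind, rows[[side]])
      df <- df[order(df$chrom, df$start), , drop = FALSE]
      writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                         as.integer(df$end),
                         format(df$value, trim = TRUE, scientific = FALSE)),
                 path)
    } else {
      writeLines(character(0), path)
    }
  }
  invisible(c(path_plus, path_minus))
}
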