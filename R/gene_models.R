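#' Gene models
#'
#' A gene model holds the genomic structure over which all per-gene statistics
#' are computed: the transcript span, its exon union, and the CDS/3'UTR
#' partition. Coordinates are 0-based, half-open (BED convention) everywhere
#' inside the package; the transcript coordinate system runs 5' to 3' in
#' transcript orientation over the spliced (intron-free) sequence.
#'
#' @param gene_id character scalar, unique gene identifier.
#' @param chrom character scalar, chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open genomic span of the transcript.
#' @param exon_starts,exon_ends integer vectors of 0-based half-open exon
#'   intervals, sorted and disjoint, all within `[start, end)`.
#' @param thick_start,thick_end 0-based half-open genomic CDS ("thick")
#'   interval; `thick_start == thick_end` means no annotated CDS.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       exon_starts, exon_ends,
                       thick_start = start, thick_end = start) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for gene ", gene_id)
  exon_starts <- as.numeric(exon_starts)
  exon_ends <- as.numeric(exon_ends)
  if (length(exon_starts) == 0L || length(exon_starts) != length(exon_ends))
    stop("gene ", gene_id, ": exon starts/ends empty or of unequal length")
  if (any(exon_ends <= exon_starts))
    stop("gene ", gene_id, ": empty or inverted exon interval")
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      any(exon_starts[-1] < exon_ends[-length(exon_ends)]))
    stop("gene ", gene_id, ": exons must be sorted and non-overlapping")
  if (exon_starts[1] < start || exon_ends[length(exon_ends)] > end)
    stop("gene ", gene_id, ": exon outside the transcript span")
  if (thick_end < thick_start)
    stop("gene ", gene_id, ": thick_end < thick_start")
  gm <- structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = as.numeric(start), end = as.numeric(end),
    exon_starts = exon_starts, exon_ends = exon_ends,
    thick_start = as.numeric(thick_start), thick_end = as.numeric(thick_end)
  ), class = "gene_model")
  if (spliced_length(gm) < 1)
    stop("gene ", gene_id, ": spliced length must be >= 1")
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  reg <- tx_regions(x)
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d exon(s), spliced %d nt, CDS %s\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              length(x$exon_starts), spliced_length(x),
              if (is.null(reg$cds)) "none"
              else sprintf("%d nt", reg$cds[2] - reg$cds[1])))
  invisible(x)
}

#' Spliced transcript length
#'
#' @param gm A [gene_model()].
#' @return Sum of exon lengths, in nucleotides.
#' @export
spliced_length <- function(gm) {
  sum(gm$exon_ends - gm$exon_starts)
}

## exonic bases overlapping a genomic interval [gstart, gend)
exonic_overlap <- function(gm, gstart, gend) {
  sum(pmax(0, pmin(gm$exon_ends, gend) - pmax(gm$exon_starts, gstart)))
}

#' Transcript-space regions of a gene model
#'
#' Projects the CDS ("thick") interval onto the spliced transcript and derives
#' the 5'UTR, CDS and 3'UTR as intervals in transcript coordinates (0-based,
#' half-open, 5' to 3' in transcript orientation). The 3'UTR is the exonic
#' region strictly 3' of the CDS and abuts it; genes without an annotated CDS
#' (zero-width thick interval, or a thick interval with no exonic overlap)
#' return `NULL` for `cds` and `utr3`.
#'
#' @param gm A [gene_model()].
#' @return A list with elements `utr5`, `cds`, `utr3`, each `c(start, end)` in
#'   transcript coordinates or `NULL` when empty.
#' @export
tx_regions <- function(gm) {
  L <- spliced_length(gm)
  cds_len <- exonic_overlap(gm, gm$thick_start, gm$thick_end)
  if (gm$thick_end == gm$thick_start || cds_len == 0)
    return(list(utr5 = if (L > 0) c(0, L) else NULL, cds = NULL, utr3 = NULL))
  if (gm$strand == "+") {
    before <- exonic_overlap(gm, gm$start, gm$thick_start)
  } else {
    before <- exonic_overlap(gm, gm$thick_end, gm$end)
  }
  cds <- c(before, before + cds_len)
  list(
    utr5 = if (before > 0) c(0, before) else NULL,
    cds = cds,
    utr3 = if (cds[2] < L) c(cds[2], L) else NULL
  )
}

## minimal structural pre-scan so malformed lines are reported by number
prescan_bed12 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L)
      stop("BED12 parse error at line ", i, ": expected 12 fields, got ",
           length(f))
    nblocks <- suppressWarnings(as.integer(f[10]))
    if (is.na(nblocks) || nblocks < 1L)
      stop("BED12 parse error at line ", i,
           ": blockCount must be a positive integer")
    sizes <- suppressWarnings(as.numeric(
      strsplit(sub(",$", "", f[11]), ",", fixed = TRUE)[[1]]))
    offs <- suppressWarnings(as.numeric(
      strsplit(sub(",$", "", f[12]), ",", fixed = TRUE)[[1]]))
    if (length(sizes) != nblocks || length(offs) != nblocks ||
        anyNA(sizes) || anyNA(offs))
      stop("BED12 parse error at line ", i,
           ": blockSizes/blockStarts inconsistent with blockCount")
  }
  invisible(TRUE)
}

#' Read gene models from a BED12 file
#'
#' One [gene_model()] per record. The thick interval encodes the CDS; the
#' 3'UTR is derived as the exonic region 3' of the CDS in transcript
#' orientation. Records with `thickStart == thickEnd` get an empty CDS and
#' empty 3'UTR.
#'
#' @param path Path to a BED12 file.
#' @return A named list of `gene_model` objects (names are gene ids), in file
#'   order.
#' @export
read_bed12 <- function(path) {
  prescan_bed12(path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("BED12 parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(gr$thick) || is.null(gr$blocks))
    stop("'", path, "' is not BED12 (missing thick/block columns)")
  n <- length(gr)
  ids <- gr$name
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("BED12 records must carry a name (gene id)")
  if (anyDuplicated(ids))
    stop("duplicate gene id in '", path, "': ",
         ids[duplicated(ids)][1])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    bl <- gr$blocks[[i]]  # block coords are relative to the record start
    off <- GenomicRanges::start(gr)[i] - 1L
    th <- gr$thick[i]
    out[[i]] <- tryCatch(gene_model(
      gene_id = ids[i],
      chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      strand = as.character(GenomicRanges::strand(gr)[i]),
      start = off,
      end = GenomicRanges::end(gr)[i],
      exon_starts = off + IRanges::start(bl) - 1L,
      exon_ends = off + IRanges::end(bl),
      thick_start = IRanges::start(th) - 1L,
      thick_end = IRanges::end(th)
    ), error = function(e) stop("BED12 validation error at record ", i,
                                " ('", ids[i], "'): ", conditionMessage(e),
                                call. = FALSE))
  }
  names(out) <- ids
  out
}

#' Write gene models to a BED12 file
#'
#' Inverse of [read_bed12()]: a write-then-read round trip reproduces the
#' models exactly.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @export
write_bed12 <- function(genes, path) {
  lines <- vapply(genes, function(gm) {
    sizes <- gm$exon_ends - gm$exon_starts
    offs <- gm$exon_starts - gm$start
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            gm$chrom, as.integer(gm$start), as.integer(gm$end), gm$gene_id,
            gm$strand, as.integer(gm$thick_start), as.integer(gm$thick_end),
            length(sizes),
            paste0(paste(as.integer(sizes), collapse = ","), ","),
            paste0(paste(as.integer(offs), collapse = ","), ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
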