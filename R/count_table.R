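#' Sample metadata and count tables
#'
#' A count table couples a genes x samples matrix of raw, non-negative integer
#' counts with a sample sheet describing each library (assay, embryonic stage,
#' condition, replicate). The pipeline starts from such tables; alignment and
#' read counting happen upstream.
#'
#' @name count_table
NULL

ASSAYS <- c("rna", "srna_input", "srna_ip", "degradome", "ribo", "gro")
STAGES <- c("one_cell", "early", "late", "mixed")
CONDITIONS <- c("control", "csr1_depleted", "rescue_DDH", "rescue_ADH")

validate_sample_meta <- function(meta) {
  need <- c("sample_id", "assay", "stage", "condition", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sample metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(meta$assay), ASSAYS)
  if (length(bad)) stop("unknown assay: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(meta$stage), STAGES)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(meta$condition), CONDITIONS)
  if (length(bad)) stop("unknown condition: ", paste(bad, collapse = ", "))
  if (any(meta$replicate < 1 | meta$replicate != round(meta$replicate)))
    stop("replicate must be a positive integer")
  key <- paste(meta$assay, meta$stage, meta$condition, meta$replicate)
  if (anyDuplicated(key))
    stop("duplicate (assay, stage, condition, replicate) combination: ",
         key[duplicated(key)][1])
  meta$replicate <- as.integer(meta$replicate)
  meta
}

#' Construct a count table
#'
#' @param counts Integer matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames.
#' @param samples data.frame with columns `sample_id`, `assay`, `stage`,
#'   `condition`, `replicate`; one row per column of `counts`, matched by
#'   `sample_id`.
#' @return An object of class `count_table` with elements `counts` and
#'   `samples`.
#' @export
count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene_id in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample id in counts")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  samples <- validate_sample_meta(as.data.frame(samples))
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss))
    stop("sample(s) in counts absent from metadata: ",
         paste(miss, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  storage.mode(counts) <- "double"
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$assay), collapse = ", ")))
  invisible(x)
}

#' Read a count table and its sample sheet
#'
#' The counts file is a TSV with a `gene_id` column plus one column per
#' sample; the metadata TSV maps those columns to assay/stage/condition/
#' replicate descriptors. All counts must be non-negative integers.
#'
#' @param path Counts TSV.
#' @param meta Sample-sheet TSV.
#' @return A [count_table()].
#' @export
read_counts <- function(path, meta) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = ".")
  if (!"gene_id" %in% names(tab))
    stop("counts file '", path, "' has no gene_id column")
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id row in '", path, "': ",
         tab$gene_id[duplicated(tab$gene_id)][1])
  m <- as.matrix(tab[setdiff(names(tab), "gene_id")])
  if (!is.numeric(m))
    stop("non-numeric count entry in '", path, "'")
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("counts in '", path, "' must be non-negative integers")
  rownames(m) <- tab$gene_id
  smeta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  count_table(m, smeta)
}

#' Write a count table and (optionally) its sample sheet
#'
#' @param ct A [count_table()].
#' @param path Counts TSV output path.
#' @param meta Optional sample-sheet TSV output path.
#' @export
write_counts <- function(ct, path, meta = NULL) {
  df <- data.frame(gene_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta))
    utils::write.table(ct$samples, meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
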