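#' Normalized abundance tables
#'
#' An abundance table is a genes x samples matrix of normalized values with
#' an explicit unit: RPM (reads per million mapped reads), RPK (reads per
#' kilobase of spliced transcript), or TPM (transcripts per million: RPK
#' rescaled so each sample sums to one million).
#'
#' @param values Non-negative numeric matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param samples Sample sheet (see [count_table()]); condition-level means
#'   carry `replicate = NA`.
#' @param unit `"RPM"`, `"RPK"` or `"TPM"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, samples, unit = c("TPM", "RPM", "RPK")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (anyNA(values) || any(values < 0))
    stop("abundance values must be non-negative")
  structure(list(values = values, samples = as.data.frame(samples),
                 unit = unit),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Counts to transcripts per million
#'
#' Normalizes first by transcript union exon length in kilobases (reads per
#' kilobase, RPK), then by million total RPK per sample (transcripts per
#' million, TPM). A sample with no counted reads yields an all-zero TPM
#' column.
#'
#' @param table A [count_table()].
#' @param genes Named list of [gene_model()] objects covering every gene in
#'   `table`.
#' @return An [abundance_table()] in TPM.
#' @export
counts_to_tpm <- function(table, genes) {
  ids <- rownames(table$counts)
  miss <- setdiff(ids, names(genes))
  if (length(miss))
    stop("missing gene model for: ", paste(utils::head(miss, 5), collapse = ", "))
  len_kb <- vapply(genes[ids], spliced_length, numeric(1)) / 1000
  rpk <- table$counts / len_kb
  tot <- colSums(rpk)
  tpm <- sweep(rpk, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm[, tot == 0] <- 0
  abundance_table(tpm, table$samples, "TPM")
}

#' Counts to reads per million
#'
#' `RPM = count * 1e6 / library_size`. The default library size is the
#' per-sample column sum, i.e. total counted reads in that library.
#'
#' @param table A [count_table()].
#' @param library_sizes Optional named numeric vector of per-sample library
#'   sizes (must be > 0); defaults to column sums of the table.
#' @return An [abundance_table()] in RPM.
#' @export
counts_to_rpm <- function(table, library_sizes = NULL) {
  if (is.null(library_sizes)) {
    library_sizes <- colSums(table$counts)
  } else {
    if (!is.null(names(library_sizes)))
      library_sizes <- library_sizes[colnames(table$counts)]
    if (length(library_sizes) != ncol(table$counts) || anyNA(library_sizes))
      stop("library_sizes must cover every sample")
  }
  if (any(library_sizes <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(table$counts)[library_sizes <= 0], collapse = ", "))
  abundance_table(sweep(table$counts, 2, library_sizes / 1e6, "/"),
                  table$samples, "RPM")
}

#' Average replicates within conditions
#'
#' Arithmetic mean of normalized values across replicates sharing the same
#' grouping keys (by default assay, stage and condition). Averaging happens in
#' normalized space (e.g. mean TPM), never on raw counts.
#'
#' @param table An [abundance_table()].
#' @param group_keys Character vector of sample-sheet columns defining the
#'   groups.
#' @return An [abundance_table()] with one column per group; group columns are
#'   named `assay.stage.condition` and carry `replicate = NA`.
#' @export
mean_by_condition <- function(table, group_keys = c("assay", "stage", "condition")) {
  miss <- setdiff(group_keys, names(table$samples))
  if (length(miss))
    stop("unknown grouping key(s): ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(table$samples[group_keys], sep = "."))
  if (any(!nzchar(key) | is.na(key))) stop("empty group key")
  groups <- unique(key)
  vals <- vapply(groups, function(g) {
    rowMeans(table$values[, key == g, drop = FALSE])
  }, numeric(nrow(table$values)))
  vals <- matrix(vals, nrow = nrow(table$values),
                 dimnames = list(rownames(table$values), groups))
  meta <- table$samples[match(groups, key), group_keys, drop = FALSE]
  meta$sample_id <- groups
  meta$replicate <- NA_integer_
  rownames(meta) <- NULL
  abundance_table(vals, meta, table$unit)
}

#' Select the single column of a condition from an abundance table
#'
#' Convenience accessor: returns the named numeric vector for one
#' (assay, stage, condition) group, averaging replicates if several columns
#' match.
#'
#' @param table An [abundance_table()].
#' @param assay,stage,condition Values to match in the sample sheet (NULL
#'   matches anything).
#' @return Named numeric vector over genes.
#' @export
abundance_vector <- function(table, assay = NULL, stage = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(table$samples))
  if (!is.null(assay)) keep <- keep & table$samples$assay == assay
  if (!is.null(stage)) keep <- keep & table$samples$stage == stage
  if (!is.null(condition)) keep <- keep & table$samples$condition == condition
  if (!any(keep))
    stop("no sample matches (", paste(c(assay, stage, condition), collapse = ", "), ")")
  rowMeans(table$values[, keep, drop = FALSE])
}

#' Write / read an abundance table as TSV with a unit header
#'
#' The file carries a `# unit=` comment line so the unit survives a round
#' trip.
#'
#' @param table An [abundance_table()].
#' @param path TSV path.
#' @param meta Sample-sheet TSV (written/read alongside).
#' @export
write_abundance <- function(table, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit=", table$unit), con)
  df <- data.frame(gene_id = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta))
    utils::write.table(table$samples, meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path, meta) {
  first <- readLines(path, n = 1)
  unit <- sub("^# unit=", "", first)
  if (identical(unit, first)) stop("'", path, "' lacks a '# unit=' header")
  tab <- utils::read.delim(path, skip = 1, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[setdiff(names(tab), "gene_id")])
  rownames(m) <- tab$gene_id
  smeta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  abundance_table(m, smeta[match(colnames(m), smeta$sample_id), , drop = FALSE],
                  unit)
}
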