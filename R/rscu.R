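#' Codon counting over a coding-sequence set
#'
#' Aggregates in-frame codon counts across a set of coding sequences
#' (standard nuclear genetic code). Each sequence must be a whole number of
#' codons over the ACGT alphabet; a terminal stop codon is dropped and an
#' internal stop is an error naming the offending record.
#'
#' @param cds Either a path to a FASTA file or a
#'   [Biostrings::DNAStringSet-class] of coding sequences.
#' @return Object of class `codon_counts`: named integer vector over the 61
#'   sense codons, with attribute `total_codons`.
#' @export
count_codons <- function(cds) {
  if (is.character(cds)) cds <- Biostrings::readDNAStringSet(cds)
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  sense <- names(code)[code != "*"]
  counts <- stats::setNames(integer(length(sense)), sense)
  if (length(cds) > 0) {
    w <- Biostrings::width(cds)
    if (any(w %% 3 != 0))
      stop("sequence length not divisible by 3: ",
           names(cds)[w %% 3 != 0][1])
    if (any(w < 3))
      stop("sequence shorter than one codon: ", names(cds)[w < 3][1])
    freq <- Biostrings::oligonucleotideFrequency(cds, width = 3, step = 3)
    if (any(rowSums(freq) != w %/% 3))
      stop("ambiguity codes are not allowed: ",
           names(cds)[rowSums(freq) != w %/% 3][1])
    # drop one terminal stop per sequence that ends in a stop
    last <- as.character(Biostrings::subseq(cds, start = w - 2, width = 3))
    term_stop <- last %in% stops
    freq[cbind(which(term_stop), match(last[term_stop], colnames(freq)))] <-
      freq[cbind(which(term_stop), match(last[term_stop], colnames(freq)))] - 1L
    internal <- rowSums(freq[, stops, drop = FALSE]) > 0
    if (any(internal))
      stop("internal stop codon in record: ", names(cds)[internal][1])
    counts <- colSums(freq)[sense]
  }
  structure(as.integer(counts), names = sense,
            total_codons = sum(counts), class = "codon_counts")
}

#' Relative synonymous codon usage
#'
#' For codon j of amino acid i with synonymous family size n_i,
#' `RSCU_ij = x_ij / ((1/n_i) * sum_j x_ij)`: the observed count divided by
#' the family mean. Values within a used family sum to the family size;
#' families with zero total usage are undefined (NA, with a message).
#' Computed over the aggregate counts of a gene set (pooled, not per-gene
#' averaged).
#'
#' @param counts A [count_codons()] result (or named count vector over the 61
#'   sense codons).
#' @return data.frame with columns `codon`, `aa`, `count`, `rscu`.
#' @export
rscu <- function(counts) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  if (is.null(names(counts)) || !all(sense %in% names(counts)))
    stop("counts must be named over the 61 sense codons")
  x <- as.numeric(counts[sense])
  aa <- unname(code[sense])
  fam_tot <- tapply(x, aa, sum)[aa]
  fam_n <- tapply(rep(1, length(aa)), aa, sum)[aa]
  vals <- ifelse(fam_tot > 0, x / (fam_tot / fam_n), NA_real_)
  if (any(fam_tot == 0))
    message("rscu: ", length(unique(aa[fam_tot == 0])),
            " unused famil(ies) left undefined")
  data.frame(codon = sense, aa = aa, count = x, rscu = unname(vals),
             stringsAsFactors = FALSE)
}
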