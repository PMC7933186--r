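#' Per-gene decay and translation statistics
#'
#' Vectorized statistics used throughout the analysis. All inputs are mean
#' TPM (or mean RPM for small-RNA quantities) unless stated otherwise.
#'
#' @name decay_metrics
NULL

#' Degradation rate
#'
#' Ratio of a transcript's abundance in sorted early embryos over 1-cell
#' embryos; lower values mean faster clearance. Genes with zero 1-cell
#' abundance are excluded (NA) with a message.
#'
#' @param tpm_early,tpm_1cell Numeric vectors of mean TPM.
#' @return Numeric vector of ratios (NA where excluded).
#' @export
degradation_rate <- function(tpm_early, tpm_1cell) {
  out <- ifelse(tpm_1cell > 0, tpm_early / tpm_1cell, NA_real_)
  n0 <- sum(tpm_1cell == 0)
  if (n0 > 0)
    message("degradation_rate: excluded ", n0, " gene(s) with zero 1-cell TPM")
  out
}

#' Degradation efficiency
#'
#' log2 ratio of degradome-seq over RNA-seq mean TPM. Genes with zero RNA-seq
#' signal are excluded; genes with zero degradome signal are reported as
#' missing (NA, with a message) rather than -Inf so downstream medians stay
#' well-defined.
#'
#' @param tpm_degradome,tpm_rna Numeric vectors of mean TPM.
#' @return Numeric vector of log2 ratios (NA where excluded/missing).
#' @export
degradation_efficiency <- function(tpm_degradome, tpm_rna) {
  out <- rep(NA_real_, length(tpm_rna))
  ok <- tpm_rna > 0 & tpm_degradome > 0
  out[ok] <- log2(tpm_degradome[ok] / tpm_rna[ok])
  nz <- sum(tpm_rna > 0 & tpm_degradome == 0)
  if (nz > 0)
    message("degradation_efficiency: ", nz,
            " gene(s) with zero degradome signal reported as missing")
  out
}

#' Translational efficiency
#'
#' log2 ratio of ribosome-protected-fragment over RNA-seq mean TPM, with a
#' pseudocount of 1 added to both terms so genes undetected in either assay
#' are retained with a finite value.
#'
#' @param tpm_rpf,tpm_rna Numeric vectors of mean TPM.
#' @param pseudo Pseudocount (TPM) added to both terms.
#' @return Numeric vector of log2 ratios (always finite).
#' @export
translational_efficiency <- function(tpm_rpf, tpm_rna, pseudo = 1) {
  log2((tpm_rpf + pseudo) / (tpm_rna + pseudo))
}

#' log2 fold change between two conditions
#'
#' `log2((a + pseudo) / (b + pseudo))`. The default pseudocount of 1 TPM
#' keeps the ratio finite for zero-count genes and matches the
#' translational-efficiency convention.
#'
#' @param tpm_a,tpm_b Numeric vectors of mean abundance (a vs b).
#' @param pseudo Pseudocount added to both terms.
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(tpm_a, tpm_b, pseudo = 1) {
  log2((tpm_a + pseudo) / (tpm_b + pseudo))
}

#' Enrichment factor of targets in a gene-expression category
#'
#' The predicted number of targets in a category of size `C` is
#' `T * C / G` under independence, with `G` the number of protein-coding
#' genes (20,447 for C. elegans); the enrichment is observed/predicted.
#'
#' @param n_targets Total number of embryonic targets (T).
#' @param n_category Number of genes in the category (C).
#' @param observed Observed number of targets in the category.
#' @param n_genes Total protein-coding genes (G), default 20447.
#' @return List with `observed`, `predicted`, `enrichment`, `n_targets`,
#'   `n_category`, `n_genes`.
#' @export
enrichment_factor <- function(n_targets, n_category, observed, n_genes = 20447) {
  stopifnot(n_genes > 0, n_targets <= n_genes, n_category <= n_genes)
  predicted <- n_targets * n_category / n_genes
  enrichment <- if (predicted > 0) observed / predicted
  else if (observed > 0) {
    message("enrichment_factor: predicted 0 with observed > 0 -> Inf")
    Inf
  } else NA_real_
  list(observed = observed, predicted = predicted, enrichment = enrichment,
       n_targets = n_targets, n_category = n_category, n_genes = n_genes)
}

#' Flag upregulated targets
#'
#' Targets whose log2 fold change is positive with a Benjamini-Hochberg
#' adjusted p-value below `alpha`.
#'
#' @param gene_id Character vector of gene ids.
#' @param log2fc,adj_p Numeric vectors aligned with `gene_id`.
#' @param targets Character vector of target gene ids.
#' @param alpha Adjusted p-value cutoff.
#' @return Character vector of flagged gene ids.
#' @export
flag_upregulated_targets <- function(gene_id, log2fc, adj_p, targets,
                                     alpha = 0.05) {
  keep <- gene_id %in% targets & log2fc > 0 & !is.na(adj_p) & adj_p < alpha
  gene_id[keep]
}
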