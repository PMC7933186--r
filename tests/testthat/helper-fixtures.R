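# small constructed fixtures shared across test files

# single-exon plus-strand gene: span [100, 400), CDS [150, 350)
gm_plus <- function() {
  gene_model("gplus", "chr1", "+", 100, 400,
             exon_starts = 100, exon_ends = 400,
             thick_start = 150, thick_end = 350)
}

# two-exon minus-strand gene: exons [500,600) + [700,800), CDS [550, 760)
gm_minus <- function() {
  gene_model("gminus", "chr1", "-", 500, 800,
             exon_starts = c(500, 700), exon_ends = c(600, 800),
             thick_start = 550, thick_end = 760)
}

tiny_meta <- function(ids, assay = "rna", stage = "early",
                      condition = "control") {
  data.frame(sample_id = ids, assay = assay, stage = stage,
             condition = condition, replicate = seq_along(ids))
}

tiny_counts <- function(m, assay = "rna", stage = "early",
                        condition = "control") {
  count_table(m, tiny_meta(colnames(m), assay, stage, condition))
}

# profile data.frame helper
prof <- function(p1, pe, pl, id = "g") {
  data.frame(gene_id = id, tpm_1cell = p1, tpm_early = pe, tpm_late = pl,
             stringsAsFactors = FALSE)
}

# planted-spot image: Gaussian spots on flat background plus optional noise
spot_image <- function(size, centers, amplitude, sigma = 1.5, noise_sd = 0,
                       background = 0) {
  img <- matrix(background, size, size)
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(size * size, 0, noise_sd), size, size)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    ys <- max(1, centers[i, 1] - r):min(size, centers[i, 1] + r)
    xs <- max(1, centers[i, 2] - r):min(size, centers[i, 2] + r)
    g <- outer((ys - centers[i, 1])^2, (xs - centers[i, 2])^2, "+")
    img[ys, xs] <- img[ys, xs] + amplitude * exp(-g / (2 * sigma^2))
  }
  img
}
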