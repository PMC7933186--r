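two_gene_models <- function(lengths, ids = paste0("g", seq_along(lengths))) {
  pos <- 0
  out <- lapply(seq_along(lengths), function(i) {
    gm <- gene_model(ids[i], "chr1", "+", pos, pos + lengths[i],
                     exon_starts = pos, exon_ends = pos + lengths[i])
    pos <<- pos + lengths[i] + 100
    gm
  })
  names(out) <- ids
  out
}

test_that("TPM normalizes by spliced kilobase then by million total RPK", {
  genes <- two_gene_models(c(1000, 9000))
  ct <- tiny_counts(matrix(c(10L, 90L), 2, 1,
                           dimnames = list(names(genes), "s1")))
  tpm <- counts_to_tpm(ct, genes)
  expect_equal(unname(tpm$values[, 1]), c(5e5, 5e5))  # equal RPK split
  expect_equal(tpm$unit, "TPM")

  # single gene: any positive count is the whole transcriptome
  g1 <- two_gene_models(500)
  t1 <- counts_to_tpm(tiny_counts(matrix(7L, 1, 1,
                                         dimnames = list("g1", "s1"))), g1)
  expect_equal(unname(t1$values[1, 1]), 1e6)

  # hand-computed: counts (1,2,3) over (100,200,300) nt are all RPK 10
  genes3 <- two_gene_models(c(100, 200, 300))
  t3 <- counts_to_tpm(tiny_counts(matrix(1:3, 3, 1,
                                         dimnames = list(names(genes3), "s1"))),
                      genes3)
  expect_equal(unname(t3$values[, 1]), rep(1e6 / 3, 3))

  # all-zero sample stays all-zero
  t0 <- counts_to_tpm(tiny_counts(matrix(0L, 2, 1,
                                         dimnames = list(names(genes), "s1"))),
                      genes)
  expect_equal(unname(t0$values[, 1]), c(0, 0))

  expect_error(counts_to_tpm(tiny_counts(matrix(1L, 1, 1,
                                                dimnames = list("nope", "s1"))),
                             genes), "nope")
})

test_that("RPM is counts per million library reads", {
  ct <- tiny_counts(matrix(c(22L, 150L), 1, 2,
                           dimnames = list("g1", c("s1", "s2"))))
  rpm <- counts_to_rpm(ct, library_sizes = c(s1 = 1e6, s2 = 2e6))
  expect_equal(unname(rpm$values[1, ]), c(22, 75))
  expect_error(counts_to_rpm(ct, library_sizes = c(s1 = 0, s2 = 1)), "zero")
  # default library size is the column sum
  def <- counts_to_rpm(tiny_counts(matrix(c(1L, 3L), 2, 1,
                                          dimnames = list(c("a", "b"), "s1"))))
  expect_equal(unname(def$values[, 1]), c(0.25, 0.75) * 1e6)
})

test_that("TPM column sums are conserved and scale-invariant (fuzzed)", {
  set.seed(42)
  for (i in 1:25) {
    ng <- sample(3:30, 1); ns <- sample(1:4, 1)
    genes <- two_gene_models(sample(200:5000, ng))
    m <- matrix(stats::rpois(ng * ns, 50), ng, ns,
                dimnames = list(names(genes), paste0("s", 1:ns)))
    tpm <- counts_to_tpm(tiny_counts(m), genes)
    expect_equal(colSums(tpm$values), rep(1e6, ns), tolerance = 1e-6,
                 ignore_attr = TRUE)
    # uniform scaling of a sample's counts leaves TPM unchanged
    tpm4 <- counts_to_tpm(tiny_counts(m * 4L), genes)
    expect_equal(tpm4$values, tpm$values, tolerance = 1e-12)
    # RPM scale invariance: doubling counts and library size cancels
    rpm1 <- counts_to_rpm(tiny_counts(m), library_sizes = colSums(m) + 1000)
    rpm2 <- counts_to_rpm(tiny_counts(m * 2L),
                          library_sizes = 2 * (colSums(m) + 1000))
    expect_equal(rpm1$values, rpm2$values)
  }
})

test_that("normalized abundances are monotone in the underlying count", {
  genes <- two_gene_models(c(1000, 1000, 2000))
  m <- matrix(c(5L, 9L, 14L), 3, 1, dimnames = list(names(genes), "s1"))
  m2 <- m; m2[1, 1] <- 8L
  tpm1 <- counts_to_tpm(tiny_counts(m), genes)
  tpm2 <- counts_to_tpm(tiny_counts(m2), genes)
  expect_gt(tpm2$values[1, 1], tpm1$values[1, 1])
  rpm1 <- counts_to_rpm(tiny_counts(m), library_sizes = c(s1 = 1e6))
  rpm2 <- counts_to_rpm(tiny_counts(m2), library_sizes = c(s1 = 1e6))
  expect_gt(rpm2$values[1, 1], rpm1$values[1, 1])
})

test_that("replicate averaging is the arithmetic mean within conditions", {
  samples <- data.frame(sample_id = c("a1", "a2", "b1", "b2", "b3"),
                        assay = "rna", stage = "early",
                        condition = c("control", "control", "csr1_depleted",
                                      "csr1_depleted", "csr1_depleted"),
                        replicate = c(1, 2, 1, 2, 3))
  vals <- matrix(c(2, 4, 1, 1, 7,
                   5, 5, 0, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), samples$sample_id))
  ab <- abundance_table(vals, samples, "TPM")
  mu <- mean_by_condition(ab)
  expect_equal(unname(mu$values["g1", ]), c(3, 3))
  expect_equal(unname(mu$values["g2", ]), c(5, 0))
  # single replicate is its own mean
  one <- abundance_table(vals[, 1, drop = FALSE], samples[1, ], "TPM")
  expect_equal(unname(mean_by_condition(one)$values[, 1]), vals[, 1],
               ignore_attr = TRUE)
  expect_error(mean_by_condition(ab, group_keys = "nope"), "unknown")
})

test_that("abundance tables round trip through TSV with their unit", {
  samples <- tiny_meta(c("s1", "s2"))
  ab <- abundance_table(matrix(c(1.5, 0, 2.25, 10), 2, 2,
                               dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                        samples, "RPM")
  path <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(ab, path, meta)
  back <- read_abundance(path, meta)
  expect_equal(back$unit, "RPM")
  expect_equal(back$values, ab$values)
})
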