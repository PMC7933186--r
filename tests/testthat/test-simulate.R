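small_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, n_genes = 200, n_targets = 30, n_images = 2,
             replicates = 2, ...)
}

test_that("gene generation is deterministic and structurally valid", {
  cfg <- small_cfg()
  g1 <- generate_genes(cfg)
  g2 <- generate_genes(cfg)
  expect_identical(g1, g2)
  expect_length(g1$genes, 200)
  lens <- vapply(g1$genes, spliced_length, numeric(1))
  expect_true(all(lens >= 450 & lens <= 10500))
  for (gm in g1$genes[1:30]) {
    reg <- tx_regions(gm)
    expect_false(is.null(reg$cds))
    expect_false(is.null(reg$utr3))
    expect_equal((reg$cds[2] - reg$cds[1]) %% 3, 0)
    expect_equal(reg$cds[2] - reg$cds[1],
                 Biostrings::width(g1$cds[gm$gene_id]))
  }
  expect_error(sim_config(seed = 1, n_genes = 5), "n_genes")
  expect_error(sim_config(n_genes = 100), "seed")
})

test_that("unbiased codon sampling yields RSCU near one for every family", {
  cfg <- sim_config(seed = 3, n_genes = 150, n_targets = 10, codon_bias = 0)
  gg <- generate_genes(cfg)
  r <- suppressMessages(rscu(count_codons(gg$cds)))
  # ~60k codons: multinomial noise on family shares is a few percent
  expect_true(all(abs(r$rscu[!is.na(r$rscu)] - 1) < 0.25))
  # a strong bias pushes preferred codons well above one
  cfgb <- sim_config(seed = 3, n_genes = 150, n_targets = 10, codon_bias = 0.8)
  rb <- suppressMessages(rscu(count_codons(generate_genes(cfgb)$cds)))
  expect_gt(max(rb$rscu, na.rm = TRUE), 1.5)
})

test_that("planted truth is self-consistent with the classifier rules", {
  cfg <- small_cfg()
  truth <- simulate_truth(cfg, generate_genes(cfg)$genes)
  relab <- classify_genes(data.frame(gene_id = truth$gene_id,
                                     tpm_1cell = truth$e1,
                                     tpm_early = truth$ee_active,
                                     tpm_late = truth$el_active))
  expect_equal(as.character(relab$mzt_class), truth$mzt_class)
  expect_equal(as.character(relab$decay_timing), truth$decay_timing)
  # slicing boost exceeds one only for targets; placement mirrors timing
  expect_true(all(truth$boost[!truth$is_target] == 1))
  expect_true(all(truth$boost[truth$is_target] > 1))
  expect_true(all(truth$placement[!truth$is_target] == "none"))
  tg <- truth[truth$is_target, ]
  expect_true(all(tg$placement[tg$decay_timing == "early_degraded"] ==
                    "cds_and_utr3"))
  expect_true(all(tg$placement[tg$decay_timing != "early_degraded"] ==
                    "utr3_only"))
  # per-stage planted totals are mass-balanced on the TPM scale
  expect_equal(sum(truth$e1), 1e6, tolerance = 1e-9)
  expect_equal(sum(truth$ee_active), 1e6, tolerance = 1e-9)
  expect_equal(sum(truth$el_active), 1e6, tolerance = 1e-9)
})

test_that("expected stage ratios encode class decay and the slicing boost", {
  cfg <- small_cfg()
  truth <- simulate_truth(cfg, generate_genes(cfg)$genes)
  # targets' active/inactive expected early ratio differs by the boost, up
  # to the uniform compositional factor both columns share (estimated from
  # non-targets, whose raw expectation is condition-independent)
  tg <- truth$is_target
  comp <- stats::median(truth$ee_inactive[!tg] / truth$ee_active[!tg])
  expect_equal(truth$ee_inactive[tg] / truth$ee_active[tg] / comp,
               unname(truth$boost[tg]), tolerance = 1e-9)
  # removing the slicing effect equalizes target and non-target kinetics:
  # within the cleared class, inactive-condition early ratios share one
  # distribution (compare medians of the planted values)
  cleared <- truth$mzt_class == "maternal_cleared"
  r_in <- truth$ee_inactive / truth$e1
  expect_lt(abs(stats::median(r_in[cleared & tg]) -
                  stats::median(r_in[cleared & !tg])), 0.15)
})

test_that("simulated mean TPM converges to the planted expectation", {
  cfg <- sim_config(seed = 21, n_genes = 200, n_targets = 30,
                    replicates = 50, nb_dispersion = 1e-4)
  gg <- generate_genes(cfg)
  truth <- simulate_truth(cfg, gg$genes)
  expr <- simulate_expression(truth, cfg, gg$genes)
  tpm <- mean_by_condition(counts_to_tpm(expr$rna, gg$genes))
  prof <- stage_profiles(tpm, condition = "control")
  for (stage in c("tpm_1cell", "tpm_early", "tpm_late")) {
    planted <- switch(stage, tpm_1cell = truth$e1,
                      tpm_early = truth$ee_active,
                      tpm_late = truth$el_active)
    keep <- planted > 1
    expect_lt(max(abs(prof[[stage]][keep] / planted[keep] - 1)), 0.05)
  }
})

test_that("22G tables and tracks encode enrichment and placement", {
  cfg <- small_cfg()
  gg <- generate_genes(cfg)
  truth <- simulate_truth(cfg, gg$genes)
  srna <- simulate_22g(truth, cfg, gg$genes)
  # non-target genes: expected IP/input ratio one (planted RPMs equal)
  expect_equal(truth$ip_rpm[!truth$is_target],
               truth$input_rpm[!truth$is_target])
  expect_true(all(truth$ip_rpm[truth$is_target] /
                    truth$input_rpm[truth$is_target] >= 4))
  # planted IP RPMs live on the RPM scale
  expect_equal(sum(truth$ip_rpm), 1e6, tolerance = 1e-6)
  # 3'UTR-only targets have near-zero CDS coverage
  tracks <- scale_tracks(average_track_sets(srna$track_reps),
                         1e6 / srna$total_mapped)
  ra <- suppressMessages(partition_cds_utr3(tracks, gg$genes))
  idx <- match(ra$gene_id, truth$gene_id)
  u3 <- truth$placement[idx] == "utr3_only"
  cds_len <- vapply(gg$genes[ra$gene_id], function(g) {
    r <- tx_regions(g); r$cds[2] - r$cds[1]
  }, numeric(1))
  expect_lt(max(ra$cds_rpm[u3] / cds_len[u3]), 0.2)
  expect_gt(min(ra$cds_rpm[!u3] / cds_len[!u3]), 0.5)
})

test_that("image simulation plants separated spots and errors when impossible", {
  cfg <- small_cfg()
  sim <- simulate_images(cfg)
  expect_length(sim$images, 4)  # 2 conditions x 2 images
  for (im in sim$images) {
    d <- as.matrix(stats::dist(cbind(im$truth$y, im$truth$x)))
    diag(d) <- Inf
    expect_gte(min(d), cfg$min_spot_sep)
    expect_true(all(sim$roi[cbind(im$truth$y, im$truth$x)] == im$truth$in_roi))
  }
  toomany <- sim_config(seed = 1, n_genes = 20, n_targets = 2, n_images = 1,
                        img_size = 32, n_spots = c(control = 400,
                                                   csr1_depleted = 1),
                        min_spot_sep = 8)
  expect_error(simulate_images(toomany), "density")
})

test_that("a full dataset is written byte-identically under one seed", {
  cfg <- small_cfg(seed = 31)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  expect_true(length(f1) > 10)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(small_cfg(seed = 32), d3)
  same <- tools::md5sum(file.path(d1, "counts_rna.tsv")) ==
    tools::md5sum(file.path(d3, "counts_rna.tsv"))
  expect_false(unname(same))
})
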