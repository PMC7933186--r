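test_that("target calling applies the ratio and abundance gates as printed", {
  ip <- c(a = 4, b = 0.5, c = 160, d = 50, e = 3, f = 0)
  input <- c(a = 2, b = 0.1, c = 10, d = 1, e = 0, f = 0)
  tc <- call_targets(ip, input)
  rownames(tc) <- tc$gene_id
  # boundary inclusive: a ratio of exactly 2 is a target
  expect_true(tc["a", "is_target"])
  expect_equal(tc["a", "enrichment_ratio"], 2)
  # ratio 5 but ip below the 1-RPM gate: not a target
  expect_false(tc["b", "is_target"])
  # density tiers tile (1,50], (50,150], (150,Inf)
  expect_equal(as.character(tc["c", "tier"]), "T3")
  expect_equal(as.character(tc["d", "tier"]), "T1")  # 50 closes T1
  # absent from input with ip above gate: ratio +Inf, still a target
  expect_true(is.infinite(tc["e", "enrichment_ratio"]))
  expect_true(tc["e", "is_target"])
  expect_false(tc["f", "is_target"])
  # deterministic gene_id ordering
  expect_equal(tc$gene_id, sort(names(ip)))
})

test_that("tier assignment partitions targets and is monotone in ip_rpm", {
  set.seed(5)
  ip <- stats::runif(300, 0, 400)
  input <- ip / sample(c(1, 4), 300, replace = TRUE)
  names(ip) <- names(input) <- sprintf("g%03d", 1:300)
  tc <- call_targets(ip, input)
  expect_true(all((tc$tier == "none") == !tc$is_target))
  expect_true(all(table(tc$gene_id) == 1))
  tgt <- tc[tc$is_target, ]
  expect_true(all(tgt$tier %in% c("T1", "T2", "T3")))
  # raising ip never lowers the tier
  ord <- order(tgt$ip_rpm)
  expect_true(!is.unsorted(as.integer(tgt$tier)[ord]))
  # unit guard
  bad <- abundance_table(matrix(ip, ncol = 1,
                                dimnames = list(names(ip), "s1")),
                         tiny_meta("s1"), "TPM")
  expect_error(call_targets(bad, input), "RPM")
})

test_that("CDS/3'UTR partition sums per-base RPM over the annotated regions", {
  genes <- list(gplus = gm_plus())
  # coverage only within the 3'UTR (transcript positions 251..300)
  v <- rep(0, 300); v[251:300] <- 2
  ra <- partition_cds_utr3(list(coverage_track("gplus", v)), genes)
  expect_equal(ra$cds_rpm, 0)
  expect_equal(ra$utr3_rpm, 100)
  # uniform 1 RPM/base: rectangle sums equal region lengths
  ra1 <- partition_cds_utr3(list(coverage_track("gplus", rep(1, 300))), genes)
  expect_equal(ra1$cds_rpm, 200)
  expect_equal(ra1$utr3_rpm, 50)
  # random track agrees with brute-force per-base summation
  set.seed(9)
  v <- stats::runif(300)
  ra2 <- partition_cds_utr3(list(coverage_track("gplus", v)), genes)
  reg <- tx_regions(genes$gplus)
  expect_equal(ra2$cds_rpm, sum(v[(reg$cds[1] + 1):reg$cds[2]]))
  expect_equal(ra2$utr3_rpm, sum(v[(reg$utr3[1] + 1):reg$utr3[2]]))
})

test_that("genes without CDS annotation are skipped with a message", {
  nocds <- gene_model("nocds", "chr1", "+", 0, 100, 0, 100)
  expect_message(
    ra <- partition_cds_utr3(list(coverage_track("nocds", rep(1, 100))),
                             list(nocds = nocds)),
    "skipping")
  expect_equal(nrow(ra), 0)
})

test_that("target-set overlaps report counts and declared-denominator fractions", {
  expect_equal(overlap_target_sets(letters[1:5], letters[1:5])$fraction, 1)
  expect_equal(overlap_target_sets(letters[1:5], letters[6:10])$fraction, 0)
  ov <- overlap_target_sets(as.character(1:10), as.character(6:15))
  expect_equal(ov$n_overlap, 5)
  expect_equal(ov$fraction, 5 / 15)
  expect_equal(overlap_target_sets(as.character(1:10), as.character(6:15),
                                   denominator = "a")$fraction, 0.5)
})
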