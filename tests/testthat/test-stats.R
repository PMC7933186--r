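test_that("exact Mann-Whitney matches the enumeration oracle exhaustively", {
  # p depends only on (n_x, n_y, U); cover every achievable U for a grid of
  # group sizes, constructing a tie-free sample with that exact U
  for (nx in c(2, 3, 5, 8)) for (ny in c(2, 4, 8)) {
    for (u in 0:(nx * ny)) {
      s <- sample_with_u(nx, ny, u)
      got <- mann_whitney(s$x, s$y, mode = "exact")
      oracle <- mwu_enum_oracle(s$x, s$y)
      expect_equal(got$U, oracle$U)
      expect_equal(got$p, oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("the canonical separated triples give U = 0 and exact p = 0.1", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")
})

test_that("identical samples give p = 1 under the normal approximation", {
  mw <- mann_whitney(c(1, 2, 3), c(1, 2, 3), mode = "normal_approx")
  expect_equal(mw$p, 1)
  # auto mode falls back to the approximation when ties are present
  expect_equal(mann_whitney(c(1, 1, 2), c(1, 2, 3))$method, "normal_approx")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney(c(1, 1), c(1, 2), mode = "exact"), "ties")
})

test_that("bootstrap median CI is seeded, ordered and degenerate-safe", {
  set.seed(101)
  x <- stats::rnorm(50)
  a <- median_ci(x, seed = 7)
  b <- median_ci(x, seed = 7)
  expect_identical(a, b)
  expect_lte(a$lo, a$median)
  expect_gte(a$hi, a$median)
  # constant sample collapses to the constant
  cc <- median_ci(rep(3.5, 20), seed = 1)
  expect_equal(c(cc$lo, cc$median, cc$hi), c(3.5, 3.5, 3.5))
  # symmetric sample: median 5 inside the interval
  s <- median_ci(1:9, seed = 2)
  expect_equal(s$median, 5)
  expect_lte(s$lo, 5); expect_gte(s$hi, 5)
  # n < 2: median only
  one <- median_ci(4)
  expect_true(is.na(one$lo) && is.na(one$hi))
  # seeding restores the caller's RNG stream
  set.seed(99); r1 <- stats::runif(1)
  set.seed(99); invisible(median_ci(x, seed = 3)); r2 <- stats::runif(1)
  expect_equal(r1, r2)
})

test_that("box summaries use type-7 quantiles", {
  expect_equal(unname(box_summary(0:100)), c(25, 50, 75, 5, 95))
  expect_equal(unname(box_summary(42)), rep(42, 5))
  set.seed(5)
  x <- stats::rnorm(83)
  expect_equal(unname(box_summary(x)),
               unname(stats::quantile(x, c(.25, .5, .75, .05, .95), type = 7)))
})

test_that("per-gene rate-ratio test matches hand-enumerated binomials and BH", {
  # identical proportions: p near 1
  same <- per_gene_count_test(c(g = 50), c(g = 50), 1e4, 1e4)
  expect_gt(same$p, 0.9)
  # 100 vs 0 at equal totals: overwhelming
  big <- per_gene_count_test(c(g = 100), c(g = 0), 1e4, 1e4)
  expect_lt(big$p, 1e-6)
  # hand enumeration: counts 3 vs 1 at equal totals, n = 4, p0 = 1/2;
  # two-sided p = P(k in {0,1,3,4}) = 10/16
  hand <- per_gene_count_test(c(g = 3), c(g = 1), 500, 500)
  expect_equal(hand$p, 10 / 16)
  # BH definition, hand-applied: [.01,.02,.03,1] -> [.04,.04,.04,1]
  pt <- per_gene_count_test(c(a = 0, b = 0, c = 0, d = 0),
                            c(a = 0, b = 0, c = 0, d = 0), 10, 10)
  expect_equal(pt$adj_p, rep(1, 4))  # empty genes are null
  bh_hand <- function(p) {
    n <- length(p); o <- order(p)
    adj <- rev(cummin(rev(p[o] * n / seq_len(n))))
    out <- numeric(n); out[o] <- pmin(adj, 1); out
  }
  expect_equal(bh_hand(c(0.01, 0.02, 0.03, 1)), c(0.04, 0.04, 0.04, 1))
  set.seed(77)
  ca <- stats::rpois(40, 30); cb <- stats::rpois(40, 30)
  names(ca) <- names(cb) <- sprintf("g%02d", 1:40)
  res <- per_gene_count_test(ca, cb, 5e4, 5e4)
  expect_equal(res$adj_p, bh_hand(res$p))
  expect_true(all(res$adj_p >= res$p - 1e-12 & res$adj_p <= 1))
  expect_error(per_gene_count_test(ca, cb, 0, 10), "> 0")
})
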