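pair_df <- function(bs_mod, bs_unmod, ox_mod, ox_unmod) {
  data.frame(chrom = "chr1", pos = seq_along(bs_mod) * 10L,
             bs_count_mod = bs_mod, bs_count_unmod = bs_unmod,
             ox_count_mod = ox_mod, ox_count_unmod = ox_unmod,
             stringsAsFactors = FALSE)
}

test_that("pairing matches brute-force intersection with coverage filter", {
  bs <- random_coverage(400, seed = 1)
  ox <- random_coverage(400, seed = 2)
  paired <- pair_sites(bs, ox, min_coverage = 10)
  # brute-force oracle via merge()
  bs_f <- bs[bs$count_mod + bs$count_unmod >= 10, ]
  ox_f <- ox[ox$count_mod + ox$count_unmod >= 10, ]
  oracle <- merge(bs_f, ox_f, by = c("chrom", "pos"))
  oracle <- oracle[order(oracle$chrom, oracle$pos, method = "radix"), ]
  expect_equal(nrow(paired), nrow(oracle))
  expect_equal(paired$pos, oracle$pos)
  expect_equal(paired$bs_count_mod, oracle$count_mod.x)
  expect_equal(paired$ox_count_mod, oracle$count_mod.y)

  # disjoint position sets pair to nothing
  ox_shift <- ox
  ox_shift$pos <- ox_shift$pos + 1L
  ox_shift <- ox_shift[order(ox_shift$chrom, ox_shift$pos, method = "radix"), ]
  expect_equal(nrow(pair_sites(bs, ox_shift, 1)), 0L)
})

test_that("pairing enforces the per-library coverage threshold and sortedness", {
  bs <- data.frame(chrom = "chr1", pos = 100L, pct_mod = 100 * 5 / 9,
                   count_mod = 5L, count_unmod = 4L) # coverage 9
  ox <- data.frame(chrom = "chr1", pos = 100L, pct_mod = 50,
                   count_mod = 10L, count_unmod = 10L)
  expect_equal(nrow(pair_sites(bs, ox, min_coverage = 10)), 0L)
  expect_equal(nrow(pair_sites(bs, ox, min_coverage = 9)), 1L)

  srt <- random_coverage(50, seed = 3)
  unsorted <- srt[c(2L, 1L, seq_len(nrow(srt))[-(1:2)]), ]
  expect_error(pair_sites(unsorted, unsorted, 1), "not sorted")
})

test_that("subtraction equations reconstruct counts as specified", {
  # worked case: BS 8/2 vs oxBS 5/5
  call <- infer_5hmc(pair_df(8, 2, 5, 5))
  expect_equal(call$count_5hmC, 3L)
  expect_equal(call$pct_5hmC, 30)
  expect_equal(call$count_no5hmC, 7L) # round(3 * 70 / 30)
  expect_equal(call$pct_5mC, 50)
  expect_equal(call$count_5mC_mod, 5)
  expect_false(call$fringe)

  # identical libraries: no 5hmC anywhere, 5mC carried through
  call2 <- infer_5hmc(pair_df(10, 0, 10, 0))
  expect_equal(call2$count_5hmC, 0L)
  expect_equal(call2$pct_5hmC, 0)
  expect_equal(call2$pct_5mC, 100)
})

test_that("fringe rule zeroes negative 5hmC and keeps BS unmethylated count", {
  call <- infer_5hmc(pair_df(4, 6, 5, 5))
  expect_true(call$fringe)
  expect_equal(call$count_5hmC, 0L)
  expect_equal(call$pct_5hmC, 0)
  expect_equal(call$count_no5hmC, 6L)

  # sign-inconsistent case from unequal depths: count diff > 0, pct diff <= 0
  call2 <- infer_5hmc(pair_df(10, 10, 5, 5))
  expect_true(call2$fringe)
  expect_equal(call2$count_5hmC, 0L)
  expect_equal(call2$count_no5hmC, 10L)
})

test_that("reconstructed counts reproduce the subtracted percent within rounding", {
  set.seed(21)
  n <- 5000
  bs_tot <- sample(10:80, n, replace = TRUE)
  ox_tot <- sample(10:80, n, replace = TRUE)
  bs_mod <- rbinom(n, bs_tot, 0.7)
  ox_mod <- rbinom(n, ox_tot, 0.5)
  calls <- infer_5hmc(pair_df(bs_mod, bs_tot - bs_mod, ox_mod, ox_tot - ox_mod))
  nf <- calls[!calls$fringe & calls$pct_5hmC > 0, ]
  expect_gt(nrow(nf), 1000)
  rederived <- 100 * nf$count_5hmC / (nf$count_5hmC + nf$count_no5hmC)
  bound <- 50 / (nf$count_5hmC + nf$count_no5hmC)
  expect_true(all(abs(rederived - nf$pct_5hmC) <= bound + 1e-9))
  # non-negativity across every call, fringe included
  expect_true(all(calls$count_5hmC >= 0))
  expect_true(all(calls$pct_5hmC >= 0))
  expect_true(all(calls$count_no5hmC >= 0))
})

test_that("increasing BS modified count never decreases the 5hmC count", {
  grid <- pair_df(0:20, 20:0, rep(8, 21), rep(12, 21))
  calls <- infer_5hmc(grid)
  expect_true(all(diff(calls$count_5hmC) >= 0))
})

test_that("infer_sample emits paired 5mC/5hmC coverage files", {
  rec <- random_coverage(300, seed = 8)
  f <- tempfile(fileext = ".cov")
  write_coverage(rec, f)
  out <- infer_sample(f, f, min_coverage = 1)
  expect_true(all(out$hmc$pct_mod == 0)) # identical libraries: zero 5hmC
  expect_equal(out$mc$count_mod, rec$count_mod)

  # empty intersection -> two empty outputs
  rec2 <- rec
  rec2$pos <- rec2$pos + 2000000L
  rec2 <- rec2[order(rec2$chrom, rec2$pos, method = "radix"), ]
  f2 <- tempfile(fileext = ".cov")
  write_coverage(rec2, f2)
  out2 <- infer_sample(f, f2, min_coverage = 1)
  expect_equal(nrow(out2$mc), 0L)
  expect_equal(nrow(out2$hmc), 0L)
})

test_that("inferred 5hmC recovers h scaled by oxidation efficiency", {
  # depth-matched near-Poisson libraries at mean 50: the regime where the
  # analytic expectation h * e applies. With independent overdispersed
  # depths the fringe rule fires on depth asymmetry and biases the mean
  # (documented estimator property; see the vignette).
  for (e in c(1, 0.9)) {
    cfg <- flat_config(m = 0.5, h = 0.2, n_sites = 4000, coverage_mean = 50,
                       coverage_dispersion = 1000, ox_efficiency = e,
                       depth_matched = TRUE, seed = 31)
    land <- build_landscape(cfg)
    d <- tempdir()
    bs_p <- file.path(d, sprintf("rec_bs_%s.cov", e))
    ox_p <- file.path(d, sprintf("rec_ox_%s.cov", e))
    write_coverage(simulate_library(land$truth, "A", "BS", 1, cfg), bs_p)
    write_coverage(simulate_library(land$truth, "A", "oxBS", 1, cfg), ox_p)
    out <- infer_sample(bs_p, ox_p, min_coverage = 10)
    expect_lt(abs(mean(out$calls$pct_5hmC) / 100 - 0.2 * e), 0.01)
  }
})

test_that("global summary is the coverage-weighted modified fraction", {
  full <- data.frame(chrom = "chr1", pos = 1:2, pct_mod = c(100, 100),
                     count_mod = c(5L, 9L), count_unmod = c(0L, 0L))
  expect_equal(global_summary(full), 100)
  half <- data.frame(chrom = "chr1", pos = 1:2, pct_mod = c(100, 0),
                     count_mod = c(10L, 0L), count_unmod = c(0L, 10L))
  expect_equal(global_summary(half), 50)
  rec <- random_coverage(500, seed = 12)
  oracle <- 100 * sum(rec$count_mod) / sum(rec$count_mod + rec$count_unmod)
  expect_equal(global_summary(rec), oracle)
  expect_error(global_summary(rec[0, ]), "at least one")
})
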