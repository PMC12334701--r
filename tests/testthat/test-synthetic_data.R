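test_that("landscape applies class baselines and additive effects", {
  cfg <- flat_config(m = 0.5, h = 0, n_sites = 200)
  land <- build_landscape(cfg)
  expect_true(all(land$truth$m == 0.5))
  expect_true(all(land$truth$h == 0))
  expect_false(any(duplicated(paste(land$truth$chrom, land$truth$pos))))

  # additive effect on one class in one condition only
  cfg2 <- sim_config(
    n_sites = 500, n_chrom = 1L, chrom_length = 1e6,
    annotation_fractions = c(ERVK = 0.3, LINE = 0.3),
    baseline_m = c(ERVK = 0.8, LINE = 0.5, background = 0.2),
    baseline_h = c(ERVK = 0, LINE = 0, background = 0),
    conditions = c("WT", "DKO"),
    effects = data.frame(condition = "DKO", class = "ERVK",
                         target = "m", delta = -0.3),
    seed = 3)
  land2 <- build_landscape(cfg2)
  tr <- land2$truth
  expect_equal(unique(tr$m[tr$condition == "DKO" & tr$class == "ERVK"]), 0.5)
  expect_equal(unique(tr$m[tr$condition == "WT" & tr$class == "ERVK"]), 0.8)
  expect_equal(unique(tr$m[tr$condition == "DKO" & tr$class == "LINE"]), 0.5)
})

test_that("m + h > 1 is resolved by proportional rescaling", {
  # baselines are valid; effects push past the simplex and trigger rescaling
  cfg <- flat_config(m = 0.8, h = 0.2, n_sites = 50,
                     effects = data.frame(condition = "A", class = "all",
                                          target = "m", delta = 0.1))
  land <- build_landscape(cfg)
  # m = 0.9, h = 0.3 is impossible; rescaled at ratio 3:1
  cfg2 <- flat_config(m = 0.7, h = 0.3, n_sites = 50,
                      effects = data.frame(condition = "A", class = "all",
                                           target = "m", delta = 0.2))
  land2 <- build_landscape(cfg2)
  expect_equal(unique(land2$truth$m), 0.75)
  expect_equal(unique(land2$truth$h), 0.25)
  expect_true(all(land$truth$m + land$truth$h <= 1 + 1e-12))
})

test_that("invalid configurations are rejected", {
  expect_error(flat_config(m = 0.5, h = 0.6), "baseline_m \\+ baseline_h")
  expect_error(
    sim_config(n_sites = 10, annotation_fractions = c(a = 0.7, b = 0.6),
               baseline_m = c(a = 0.1, b = 0.1, background = 0.1),
               baseline_h = c(a = 0, b = 0, background = 0),
               conditions = "A"),
    "sum")
  expect_error(flat_config(m = 0.5, h = 0.1, conv_failure = 1.5),
               "probability")
  cfg <- flat_config(m = 0.5, h = 0.1)
  land <- build_landscape(cfg)
  expect_error(simulate_library(land$truth, "nope", "BS", 1, cfg),
               "unknown condition")
})

test_that("error-free extremes give fully modified / unmodified reads", {
  cfg <- flat_config(m = 1, h = 0, n_sites = 300)
  land <- build_landscape(cfg)
  for (kind in c("BS", "oxBS")) {
    lib <- simulate_library(land$truth, "A", kind, 1, cfg)
    expect_true(all(lib$count_unmod == 0))
    expect_true(all(lib$pct_mod == 100))
  }
  cfg2 <- flat_config(m = 0, h = 1, n_sites = 300)
  land2 <- build_landscape(cfg2)
  bs <- simulate_library(land2$truth, "A", "BS", 1, cfg2)
  ox <- simulate_library(land2$truth, "A", "oxBS", 1, cfg2)
  expect_true(all(bs$count_unmod == 0))  # BS reads 5hmC as modified
  expect_true(all(ox$count_mod == 0))    # full oxidation strips 5hmC
})

test_that("library fractions converge to m + h (BS) and m (oxBS)", {
  cfg <- flat_config(m = 0.5, h = 0.2, n_sites = 400, coverage_mean = 10000,
                     coverage_dispersion = 1e6, seed = 11)
  land <- build_landscape(cfg)
  bs <- simulate_library(land$truth, "A", "BS", 1, cfg)
  ox <- simulate_library(land$truth, "A", "oxBS", 1, cfg)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  bs_n <- bs$count_mod + bs$count_unmod
  ox_n <- ox$count_mod + ox$count_unmod
  # per-site deviations are binomial: ~99.7% of sites inside 3 s.e.
  expect_gte(mean(abs(bs$pct_mod / 100 - 0.7) <= 3 * se(0.7, bs_n)), 0.985)
  expect_gte(mean(abs(ox$pct_mod / 100 - 0.5) <= 3 * se(0.5, ox_n)), 0.985)
  expect_lt(abs(mean(bs$pct_mod) / 100 - 0.7), 0.005)
  expect_lt(abs(mean(ox$pct_mod) / 100 - 0.5), 0.005)
})

test_that("partial oxidation leaves the expected 5hmC carry-through in oxBS", {
  # p_mod(oxBS) = m + h * (1 - e) = 0.5 + 0.2 * 0.1 = 0.52
  cfg <- flat_config(m = 0.5, h = 0.2, n_sites = 10000, coverage_mean = 50,
                     ox_efficiency = 0.9, seed = 5)
  land <- build_landscape(cfg)
  ox <- simulate_library(land$truth, "A", "oxBS", 1, cfg)
  n_reads <- sum(ox$count_mod + ox$count_unmod)
  se <- sqrt(0.52 * 0.48 / n_reads)
  expect_lt(abs(weighted.mean(ox$pct_mod / 100,
                              ox$count_mod + ox$count_unmod) - 0.52), 3 * se)
})

test_that("depth-matched mode shares one coverage draw between BS and oxBS", {
  cfg <- flat_config(m = 0.5, h = 0.2, n_sites = 500, depth_matched = TRUE)
  land <- build_landscape(cfg)
  bs <- simulate_library(land$truth, "A", "BS", 1, cfg)
  ox <- simulate_library(land$truth, "A", "oxBS", 1, cfg)
  expect_identical(bs$pos, ox$pos)
  expect_identical(bs$count_mod + bs$count_unmod,
                   ox$count_mod + ox$count_unmod)
  # independent mode: separate preps, depths differ
  cfg2 <- flat_config(m = 0.5, h = 0.2, n_sites = 500)
  land2 <- build_landscape(cfg2)
  bs2 <- simulate_library(land2$truth, "A", "BS", 1, cfg2)
  ox2 <- simulate_library(land2$truth, "A", "oxBS", 1, cfg2)
  k <- intersect(paste(bs2$pos), paste(ox2$pos))
  tot <- function(df) (df$count_mod + df$count_unmod)[match(k, paste(df$pos))]
  expect_gt(sum(tot(bs2) != tot(ox2)), 0)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- default_sim_config(seed = 9, n_sites = 500, n_replicates = 1)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_experiment(cfg, d1)
  simulate_experiment(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("truth table round-trips losslessly", {
  cfg <- default_sim_config(seed = 2, n_sites = 100, n_replicates = 1)
  land <- build_landscape(cfg)
  f <- tempfile(fileext = ".tsv")
  write_truth(land$truth, f)
  back <- read_truth(f)
  expect_equal(back, land$truth)
  # empty truth -> header-only file
  f0 <- tempfile(fileext = ".tsv")
  write_truth(land$truth[0, ], f0)
  expect_equal(length(readLines(f0)), 1L)
})

test_that("default configuration is calibrated near 35% global modification", {
  cfg <- default_sim_config(seed = 19)
  land <- build_landscape(cfg)
  libs <- lapply(1:3, function(r)
    simulate_library(land$truth, "WT_young", "BS", r, cfg))
  g <- vapply(libs, global_summary, numeric(1))
  expect_true(all(g >= 30 & g <= 40))
})
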