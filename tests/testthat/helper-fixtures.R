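# Shared fixture builders: all fixtures are generated in code.

random_coverage <- function(n, seed = 1, chroms = c("chr1", "chr2"),
                            max_cov = 60) {
  set.seed(seed)
  cm <- rbinom(n, max_cov, 0.4)
  cu <- pmax(1L - cm, rbinom(n, max_cov, 0.4)) # guarantee sum >= 1
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   pos = sample.int(1e6, n),
                   count_mod = cm, count_unmod = cu,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$chrom, df$pos)), ]
  df$pct_mod <- 100 * df$count_mod / (df$count_mod + df$count_unmod)
  df <- df[order(df$chrom, df$pos, method = "radix"),
           c("chrom", "pos", "pct_mod", "count_mod", "count_unmod")]
  rownames(df) <- NULL
  df
}

write_cov_lines <- function(lines) {
  f <- tempfile(fileext = ".cov")
  writeLines(lines, f)
  f
}

# single-class, single-condition config for focused simulations
flat_config <- function(m, h, n_sites = 1000, coverage_mean = 50,
                        conv_failure = 0, bs_nonconv_of_mod = 0,
                        ox_efficiency = 1, seed = 1, n_replicates = 1,
                        conditions = "A", ...) {
  sim_config(n_sites = n_sites, n_chrom = 1L, chrom_length = 1e7,
             annotation_fractions = c(all = 1),
             baseline_m = c(all = m, background = 0),
             baseline_h = c(all = h, background = 0),
             conditions = conditions, n_replicates = n_replicates,
             coverage_mean = coverage_mean, conv_failure = conv_failure,
             bs_nonconv_of_mod = bs_nonconv_of_mod,
             ox_efficiency = ox_efficiency, seed = seed, ...)
}

# brute-force hypergeometric upper tail via exact binomial coefficients
hyper_upper_oracle <- function(k, K, C, D) {
  if (k == 0) return(1)
  xs <- k:min(D, K)
  sum(choose(K, xs) * choose(C - K, D - xs)) / choose(C, D)
}
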