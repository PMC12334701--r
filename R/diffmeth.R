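# Per-cytosine two-group differential methylation testing, applied
# separately to the 5mC and 5hmC channels.
#
# Two per-site tests are provided. When either group has a single
# replicate, a two-sided exact conditional test on the 2x2 table of pooled
# (modified, unmodified) counts is used: the p-value sums the
# hypergeometric probabilities, at fixed margins, of every table no more
# probable than the observed one. With replicates in both groups, a
# binomial likelihood-ratio test compares group-wise MLE proportions
# (= pooled group fractions) against the common pooled proportion, with
# G ~ chi-square(1) under the null. Candidate sites are then filtered on
# the pooled percent difference and the Benjamini-Hochberg q-value, the
# study's "change more than 25% and pass q" rule.

#' Two-sided exact conditional test on pooled counts
#'
#' Tests equality of modification proportions between two groups from their
#' pooled (modified, unmodified) counts, conditioning on both margins of
#' the 2x2 table. The two-sided p-value sums hypergeometric probabilities
#' of all tables with the observed margins whose probability does not
#' exceed that of the observed table (with a 1e-7 relative tolerance on
#' the comparison to absorb floating-point ties).
#'
#' @param a,b Length-2 numeric vectors `c(count_mod, count_unmod)` for
#'   groups A and B; each must total at least 1 read.
#' @return A p-value in `[0, 1]`.
#' @export
#' @examples
#' test_site_pooled(c(5, 5), c(5, 5)) # identical proportions: p = 1
test_site_pooled <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, all(a >= 0), all(b >= 0),
            sum(a) >= 1, sum(b) >= 1)
  n_a <- sum(a); n_b <- sum(b); k <- a[1] + b[1]
  support <- max(0, k - n_b):min(n_a, k)
  probs <- stats::dhyper(support, n_a, n_b, k)
  obs <- stats::dhyper(a[1], n_a, n_b, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# binomial log-likelihood, 0*log(0) treated as 0
.binom_ll <- function(x, y, p) {
  t1 <- ifelse(x > 0, x * log(p), 0)
  t2 <- ifelse(y > 0, y * log(1 - p), 0)
  t1 + t2
}

# vectorised LRT over pooled group counts; returns list(G, p)
.lrt_pooled <- function(xa, ya, xb, yb) {
  na <- xa + ya; nb <- xb + yb
  if (any(na == 0) || any(nb == 0))
    stop("likelihood-ratio test needs non-zero total coverage in both groups")
  pa <- xa / na; pb <- xb / nb; pp <- (xa + xb) / (na + nb)
  G <- 2 * (.binom_ll(xa, ya, pa) + .binom_ll(xb, yb, pb) -
              .binom_ll(xa, ya, pp) - .binom_ll(xb, yb, pp))
  G <- pmax(G, 0)
  list(G = G, p = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

#' Binomial likelihood-ratio test across replicates
#'
#' Replicate-aware two-group test under a binomial likelihood with a shared
#' proportion per group. The group MLEs are the pooled group fractions, so
#' the statistic has the closed form
#' `G = 2 * (ll(p_A) + ll(p_B) - ll(p_pooled))` evaluated on pooled counts;
#' p-values come from the chi-square distribution with 1 df. `G = 0` when
#' the group fractions are equal.
#'
#' @param a,b Replicate counts for groups A and B: a matrix or data.frame
#'   with columns (count_mod, count_unmod) and one row per replicate, or a
#'   length-2 vector for a single replicate. At least one group should have
#'   two or more replicates (otherwise use [test_site_pooled()]).
#' @return A list with the statistic `G` and p-value `p`.
#' @export
test_site_lrt <- function(a, b) {
  as_mat <- function(x) {
    if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 2, byrow = TRUE)
    as.matrix(x)
  }
  a <- as_mat(a); b <- as_mat(b)
  stopifnot(ncol(a) == 2L, ncol(b) == 2L, all(a >= 0), all(b >= 0))
  res <- .lrt_pooled(sum(a[, 1]), sum(a[, 2]), sum(b[, 1]), sum(b[, 2]))
  list(G = unname(res$G), p = unname(res$p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a p-value vector; input
#' order is preserved in the output.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# Assemble the per-site replicate count arrays for sites covered at
# >= min_coverage in every replicate of both groups.
.assemble_sites <- function(group_a, group_b, min_coverage) {
  groups <- c(group_a, group_b)
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  keys <- NULL
  for (df in groups) {
    validate_coverage(df)
    k <- .site_key(df$chrom, df$pos)[df$count_mod + df$count_unmod >= min_coverage]
    keys <- if (is.null(keys)) k else intersect(keys, k)
  }
  if (length(keys) == 0L) {
    return(list(sites = data.frame(chrom = character(), pos = integer()),
                a_mod = NULL, a_unmod = NULL, b_mod = NULL, b_unmod = NULL))
  }
  ref <- groups[[1]]
  i <- match(keys, .site_key(ref$chrom, ref$pos))
  sites <- data.frame(chrom = ref$chrom[i], pos = ref$pos[i],
                      stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos, method = "radix")
  sites <- sites[o, , drop = FALSE]
  keys <- keys[o]
  rownames(sites) <- NULL
  pull <- function(dfs) {
    mod <- vapply(dfs, function(df) {
      df$count_mod[match(keys, .site_key(df$chrom, df$pos))]
    }, numeric(length(keys)))
    unmod <- vapply(dfs, function(df) {
      df$count_unmod[match(keys, .site_key(df$chrom, df$pos))]
    }, numeric(length(keys)))
    list(mod = matrix(mod, nrow = length(keys)),
         unmod = matrix(unmod, nrow = length(keys)))
  }
  a <- pull(group_a); b <- pull(group_b)
  list(sites = sites, a_mod = a$mod, a_unmod = a$unmod,
       b_mod = b$mod, b_unmod = b$unmod)
}

#' Test every common site for differential methylation
#'
#' Tests all sites covered at `min_coverage` or more in every replicate of
#' both groups. The methylation difference is computed from
#' replicate-pooled (coverage-weighted) fractions as
#' `percent(B) - percent(A)`, so "hyper" means higher in group B (the
#' mutant/aged group by convention). The per-site test is the pooled exact
#' conditional test when either group has a single replicate and the
#' binomial likelihood-ratio test otherwise; q-values are BH-adjusted
#' across all tested sites of the channel.
#'
#' @param group_a,group_b Lists of coverage `data.frame`s (one per
#'   replicate), e.g. the `mc` or `hmc` outputs of [infer_sample()].
#' @param min_coverage Minimum reads per replicate for a site to be tested
#'   (default 10).
#' @param channel Label for the tested channel, `"5mC"` or `"5hmC"`.
#' @return A `data.frame` sorted by `(chrom, pos)` with columns `chrom`,
#'   `pos`, `meth_diff` (percentage points, B minus A), `p`, `q`,
#'   `direction` (`"hyper"`/`"hypo"`), `channel`.
#' @export
test_dm_sites <- function(group_a, group_b, min_coverage = 10L,
                          channel = c("5mC", "5hmC")) {
  channel <- match.arg(channel)
  asm <- .assemble_sites(group_a, group_b, min_coverage)
  n <- nrow(asm$sites)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      meth_diff = numeric(), p = numeric(), q = numeric(),
                      direction = character(), channel = character(),
                      stringsAsFactors = FALSE))
  }
  xa <- rowSums(asm$a_mod); ya <- rowSums(asm$a_unmod)
  xb <- rowSums(asm$b_mod); yb <- rowSums(asm$b_unmod)
  meth_diff <- 100 * (xb / (xb + yb) - xa / (xa + ya))
  if (length(group_a) == 1L || length(group_b) == 1L) {
    p <- vapply(seq_len(n), function(i) {
      test_site_pooled(c(xa[i], ya[i]), c(xb[i], yb[i]))
    }, numeric(1))
  } else {
    p <- .lrt_pooled(xa, ya, xb, yb)$p
  }
  data.frame(chrom = asm$sites$chrom, pos = asm$sites$pos,
             meth_diff = meth_diff, p = p, q = bh_adjust(p),
             direction = ifelse(meth_diff > 0, "hyper", "hypo"),
             channel = channel, stringsAsFactors = FALSE)
}

#' Call differentially methylated cytosines
#'
#' Runs [test_dm_sites()] and keeps the sites passing the joint filter
#' `|meth_diff| >= min_diff_pct` and `q < q_threshold` — the study design
#' of requiring at least a 25-percentage-point change alongside a
#' corrected significance threshold.
#'
#' @inheritParams test_dm_sites
#' @param min_diff_pct Minimum absolute pooled methylation difference in
#'   percentage points (default 25).
#' @param q_threshold BH q-value cutoff, in (0, 1).
#' @return A `data.frame` of significant sites (possibly zero rows), same
#'   columns as [test_dm_sites()].
#' @export
call_dm_sites <- function(group_a, group_b, min_diff_pct = 25,
                          q_threshold = 0.05, min_coverage = 10L,
                          channel = c("5mC", "5hmC")) {
  stopifnot(q_threshold > 0, q_threshold < 1, min_diff_pct >= 0)
  res <- test_dm_sites(group_a, group_b, min_coverage = min_coverage,
                       channel = channel)
  out <- res[abs(res$meth_diff) >= min_diff_pct & res$q < q_threshold, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
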