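# Per-CpG 5hmC/5mC deconvolution from paired BS and oxBS libraries.
#
# Bisulfite sequencing reads 5mC + 5hmC as "methylated"; prior oxidation
# converts 5hmC to 5fC, which converts like unmodified C, so the oxBS
# library reports 5mC alone. True 5mC is therefore taken directly from the
# oxBS record, and 5hmC is inferred by subtraction:
#
#   Count_5hmC = Count_BSmethylated - Count_oxBSmethylated
#   %5hmC      = %BSmethylated - %oxBSmethylated
#   Count_No5hmC from  %5hmC = 100 * Count_5hmC / (Count_5hmC + Count_No5hmC),
#   rounded to the closest integer (half away from zero).
#
# Fringe rule: when the oxBS signal exceeds the BS signal (negative 5hmC),
# 5hmC is set to zero and Count_No5hmC to Count_BSunmethylated. Percentages
# are recomputed from raw counts at full precision before subtraction, so
# file-level percent rounding never leaks into the inferred signal.

#' Pair BS and oxBS coverage records by position
#'
#' Intersects two coverage tables from the same sample on `(chrom, pos)`,
#' keeping only positions covered by at least `min_coverage` reads in each
#' library. Both inputs must be sorted by `(chrom, pos)` (as
#' [read_coverage()] returns them).
#'
#' @param bs,oxbs Coverage `data.frame`s for the bisulfite and oxidative
#'   bisulfite libraries.
#' @param min_coverage Minimum total reads required in each library
#'   (default 10).
#' @return A `data.frame` sorted by `(chrom, pos)` with columns `chrom`,
#'   `pos`, `bs_count_mod`, `bs_count_unmod`, `ox_count_mod`,
#'   `ox_count_unmod`.
#' @export
pair_sites <- function(bs, oxbs, min_coverage = 10L) {
  validate_coverage(bs)
  validate_coverage(oxbs)
  if (!.is_sorted_sites(bs$chrom, bs$pos))
    stop("BS records are not sorted by (chrom, pos)")
  if (!.is_sorted_sites(oxbs$chrom, oxbs$pos))
    stop("oxBS records are not sorted by (chrom, pos)")
  stopifnot(min_coverage >= 1)
  bs <- bs[bs$count_mod + bs$count_unmod >= min_coverage, , drop = FALSE]
  oxbs <- oxbs[oxbs$count_mod + oxbs$count_unmod >= min_coverage, , drop = FALSE]
  i <- match(.site_key(bs$chrom, bs$pos), .site_key(oxbs$chrom, oxbs$pos))
  keep <- !is.na(i)
  out <- data.frame(chrom = bs$chrom[keep], pos = bs$pos[keep],
                    bs_count_mod = bs$count_mod[keep],
                    bs_count_unmod = bs$count_unmod[keep],
                    ox_count_mod = oxbs$count_mod[i[keep]],
                    ox_count_unmod = oxbs$count_unmod[i[keep]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer per-site 5mC and 5hmC from paired records
#'
#' Applies the subtraction equations to every paired site, reconstructing
#' integer 5hmC counts. 5mC fields are carried from the oxBS record with
#' the percentage recomputed from counts at full precision. The `fringe`
#' flag marks sites where the negative/inconsistent-signal rule fired
#' (oxBS signal above BS, or a count and percent difference of opposite
#' sign, the latter possible only with unequal library depths); fringe
#' sites report zero 5hmC with `count_no5hmC = bs_count_unmod`.
#'
#' @param pairs Paired-site `data.frame` from [pair_sites()] (one or more
#'   rows).
#' @return A `data.frame` with one row per input pair: `chrom`, `pos`,
#'   `pct_5mC`, `count_5mC_mod`, `count_5mC_unmod`, `pct_5hmC`,
#'   `count_5hmC`, `count_no5hmC`, `fringe`.
#' @export
#' @examples
#' p <- data.frame(chrom = "chr1", pos = 100L, bs_count_mod = 8L,
#'                 bs_count_unmod = 2L, ox_count_mod = 5L, ox_count_unmod = 5L)
#' infer_5hmc(p) # Count_5hmC = 3, %5hmC = 30, Count_No5hmC = 7
infer_5hmc <- function(pairs) {
  need <- c("chrom", "pos", "bs_count_mod", "bs_count_unmod",
            "ox_count_mod", "ox_count_unmod")
  stopifnot(is.data.frame(pairs), all(need %in% names(pairs)))
  bs_tot <- pairs$bs_count_mod + pairs$bs_count_unmod
  ox_tot <- pairs$ox_count_mod + pairs$ox_count_unmod
  stopifnot(all(bs_tot >= 1), all(ox_tot >= 1))
  bs_pct <- 100 * pairs$bs_count_mod / bs_tot
  ox_pct <- 100 * pairs$ox_count_mod / ox_tot
  count_5hmC <- pairs$bs_count_mod - pairs$ox_count_mod
  pct_5hmC <- bs_pct - ox_pct
  ok <- pct_5hmC > 0 & count_5hmC > 0
  fringe <- (count_5hmC < 0 | pct_5hmC < 0) |
    (count_5hmC > 0 & pct_5hmC <= 0) | (count_5hmC <= 0 & pct_5hmC > 0)
  count_no5hmC <- integer(nrow(pairs))
  count_no5hmC[!ok] <- pairs$bs_count_unmod[!ok]
  count_no5hmC[ok] <- as.integer(round_half_away(
    count_5hmC[ok] * (100 - pct_5hmC[ok]) / pct_5hmC[ok]))
  count_5hmC[!ok] <- 0L
  pct_5hmC[!ok] <- 0
  data.frame(chrom = pairs$chrom, pos = pairs$pos,
             pct_5mC = ox_pct,
             count_5mC_mod = pairs$ox_count_mod,
             count_5mC_unmod = pairs$ox_count_unmod,
             pct_5hmC = pct_5hmC,
             count_5hmC = as.integer(count_5hmC),
             count_no5hmC = count_no5hmC,
             fringe = fringe,
             stringsAsFactors = FALSE)
}

#' Infer 5mC and 5hmC coverage tables for one sample
#'
#' Reads one BS and one oxBS coverage file, pairs positions at the given
#' coverage threshold, and emits two standard coverage tables: 5mC (the
#' oxBS counts at paired positions) and 5hmC (reconstructed counts, with
#' zero modified reads at fringe sites), both consumable by downstream
#' stages or third-party tools.
#'
#' @param bs_path,oxbs_path Paths to the paired coverage files.
#' @param min_coverage Minimum per-library coverage at pairing (default 10).
#' @return A list with coverage `data.frame`s `mc` and `hmc`, plus `calls`
#'   (the full [infer_5hmc()] table).
#' @export
infer_sample <- function(bs_path, oxbs_path, min_coverage = 10L) {
  pairs <- pair_sites(read_coverage(bs_path), read_coverage(oxbs_path),
                      min_coverage = min_coverage)
  calls <- infer_5hmc(pairs)
  mc <- data.frame(chrom = calls$chrom, pos = calls$pos,
                   pct_mod = calls$pct_5mC,
                   count_mod = calls$count_5mC_mod,
                   count_unmod = calls$count_5mC_unmod,
                   stringsAsFactors = FALSE)
  hmc <- data.frame(chrom = calls$chrom, pos = calls$pos,
                    pct_mod = calls$pct_5hmC,
                    count_mod = calls$count_5hmC,
                    count_unmod = calls$count_no5hmC,
                    stringsAsFactors = FALSE)
  # a fringe site with no unmethylated BS reads would carry zero total
  # reconstructed reads; coverage records require >= 1 read
  empty <- hmc$count_mod + hmc$count_unmod < 1
  hmc <- hmc[!empty, , drop = FALSE]
  rownames(hmc) <- NULL
  list(mc = mc, hmc = hmc, calls = calls)
}

#' Coverage-weighted global percent modified
#'
#' Global modification level of a set of coverage records, weighted by
#' read depth: `100 * sum(count_mod) / sum(count_mod + count_unmod)`.
#' Used for per-replicate global 5mC/5hmC summaries.
#'
#' @param records A non-empty coverage `data.frame`.
#' @return A single percentage in `[0, 100]`.
#' @export
global_summary <- function(records) {
  validate_coverage(records)
  if (nrow(records) == 0L) stop("global_summary needs at least one record")
  100 * sum(as.numeric(records$count_mod)) /
    sum(as.numeric(records$count_mod) + as.numeric(records$count_unmod))
}
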