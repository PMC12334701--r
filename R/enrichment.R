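# Annotation-class enrichment of differentially methylated (DM) cytosines.
#
# Given D total DM sites among C tested cytosines, with D_overlaps DM and
# N_overlaps non-DM sites overlapping an annotation class:
#
#   Odds Ratio = (D_overlaps / (D - D_overlaps)) /
#                (N_overlaps / (C - D - N_overlaps))
#
# and the one-sided enrichment p-value is the hypergeometric upper tail
# P(X >= D_overlaps) when drawing D sites without replacement from C, of
# which D_overlaps + N_overlaps are annotation-overlapping; p-values are
# BH-adjusted across the annotation classes tested in one run.

.sites_gr <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(start = sites$pos, width = 1L))
}

.ann_gr <- function(ann) {
  if (nrow(ann$intervals) == 0L) return(GenomicRanges::GRanges())
  # BED 0-based half-open -> 1-based inclusive GRanges
  GenomicRanges::GRanges(ann$intervals$chrom,
                         IRanges::IRanges(start = ann$intervals$start + 1L,
                                          end = ann$intervals$end))
}

#' Count DM / non-DM overlaps with one annotation class
#'
#' A site overlaps the class when its 1-bp interval (1-based position `p`,
#' i.e. `[p - 1, p)` half-open) intersects any interval of the class;
#' membership is counted once regardless of how many intervals contain the
#' site.
#'
#' @param dm_sites `data.frame` with columns `chrom`, `pos` (1-based): the
#'   DM sites. Must be a subset of `tested_sites`.
#' @param tested_sites `data.frame` with columns `chrom`, `pos`: all sites
#'   that entered the DM test.
#' @param annotation An [annotation_set()].
#' @return An object of class `overlap_table`: list with `annotation`,
#'   `D_overlaps`, `N_overlaps`, `D`, `C`.
#' @export
overlap_counts <- function(dm_sites, tested_sites, annotation) {
  stopifnot(inherits(annotation, "annotation_set"),
            all(c("chrom", "pos") %in% names(dm_sites)),
            all(c("chrom", "pos") %in% names(tested_sites)))
  tested_keys <- .site_key(tested_sites$chrom, tested_sites$pos)
  dm_keys <- .site_key(dm_sites$chrom, dm_sites$pos)
  miss <- setdiff(dm_keys, tested_keys)
  if (length(miss) > 0L)
    stop("DM site(s) absent from the tested set: ",
         paste(utils::head(miss, 5), collapse = ", "))
  hit <- GenomicRanges::countOverlaps(.sites_gr(tested_sites),
                                      .ann_gr(annotation)) > 0
  is_dm <- tested_keys %in% dm_keys
  structure(list(annotation = annotation$name,
                 D_overlaps = sum(hit & is_dm),
                 N_overlaps = sum(hit & !is_dm),
                 D = nrow(dm_sites), C = nrow(tested_sites)),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("<overlap_table> %s: D_overlaps=%d N_overlaps=%d D=%d C=%d\n",
              x$annotation, x$D_overlaps, x$N_overlaps, x$D, x$C))
  invisible(x)
}

.check_overlap_table <- function(t) {
  stopifnot(is.list(t),
            all(c("D_overlaps", "N_overlaps", "D", "C") %in% names(t)))
  with(t, stopifnot(D_overlaps >= 0, N_overlaps >= 0, D >= 0, C >= 0,
                    D_overlaps <= D, D_overlaps + N_overlaps <= C, D <= C))
  invisible(t)
}

#' Enrichment odds ratio
#'
#' Computes the odds ratio of annotation overlap among DM sites relative
#' to non-DM tested sites, exactly as the displayed formula above. A zero
#' numerator (`D_overlaps = 0` with `N_overlaps > 0`) yields 0; degenerate
#' denominators (`D_overlaps = D`, `N_overlaps = 0`, or
#' `C - D - N_overlaps = 0`) yield `Inf` — the raw table is kept alongside
#' the ratio in reports so users may apply their own continuity correction.
#'
#' @param t An [overlap_counts()] table (or any list with fields
#'   `D_overlaps`, `N_overlaps`, `D`, `C`).
#' @return A non-negative number, possibly `Inf` (`NaN` when both odds are
#'   zero).
#' @export
#' @examples
#' odds_ratio(list(D_overlaps = 5, N_overlaps = 10, D = 10, C = 110)) # 9
odds_ratio <- function(t) {
  .check_overlap_table(t)
  Do <- t$D_overlaps; No <- t$N_overlaps; D <- t$D; C <- t$C
  if (Do == 0) return(if (No > 0) 0 else NaN)
  if (Do == D || No == 0 || C - D - No == 0) return(Inf)
  (Do / (D - Do)) / (No / (C - D - No))
}

#' One-sided hypergeometric enrichment p-value
#'
#' Probability of drawing `D_overlaps` or more annotation-overlapping
#' sites by chance when drawing `D` DM sites from `C` tested cytosines of
#' which `D_overlaps + N_overlaps` overlap the annotation — the upper
#' tail, inclusive of the observed count, of the hypergeometric
#' distribution. Computed by direct summation of log-gamma
#' (log-binomial-coefficient) terms.
#'
#' @param t An [overlap_counts()] table.
#' @return A p-value in `[0, 1]`; `P = 1` when `D_overlaps = 0`.
#' @export
hypergeom_enrichment_p <- function(t) {
  .check_overlap_table(t)
  k <- t$D_overlaps; K <- t$D_overlaps + t$N_overlaps; C <- t$C; D <- t$D
  if (k == 0) return(1)
  xs <- k:min(D, K)
  lp <- lchoose(K, xs) + lchoose(C - K, D - xs) - lchoose(C, D)
  min(1, sum(exp(lp)))
}

#' Enrichment of DM sites across annotation classes
#'
#' Builds the overlap table for every annotation class, computes the odds
#' ratio and hypergeometric enrichment p per class, and BH-adjusts the
#' p-values across the classes tested in this call. Nested or overlapping
#' classes (e.g. ERVK within all LTRs) are tested independently. Run this
#' separately per channel (5mC/5hmC) and per direction (hyper/hypo) to
#' mirror per-contrast enrichment panels.
#'
#' @inheritParams overlap_counts
#' @param annotations List of [annotation_set()] objects with unique names.
#' @return A `data.frame` ordered by class name with columns `annotation`,
#'   `D_overlaps`, `N_overlaps`, `D`, `C`, `odds_ratio`, `p`, `q`.
#' @export
enrich_all <- function(dm_sites, tested_sites, annotations) {
  stopifnot(length(annotations) >= 1L,
            all(vapply(annotations, inherits, logical(1), "annotation_set")))
  nms <- vapply(annotations, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate annotation class names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  annotations <- annotations[order(nms)]
  rows <- lapply(annotations, function(ann) {
    t <- overlap_counts(dm_sites, tested_sites, ann)
    data.frame(annotation = t$annotation, D_overlaps = t$D_overlaps,
               N_overlaps = t$N_overlaps, D = t$D, C = t$C,
               odds_ratio = odds_ratio(t), p = hypergeom_enrichment_p(t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
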