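# Simulator of paired BS/oxBS RRBS coverage with known per-site 5mC/5hmC
# ground truth. The generative model, per CpG site and library:
#
#   coverage ~ NegBin(mu = coverage_mean, size = coverage_dispersion)
#     (RRBS depth is overdispersed; BS and oxBS are separate library preps
#      and draw coverage independently; sites drawing 0 are omitted)
#   count_mod ~ Binomial(coverage, p_mod), where for true fractions (m, h):
#     BS:   p_mod = (m + h) (1 - bs_nonconv_of_mod) + (1 - m - h) conv_failure
#     oxBS: p_mod = (m + h (1 - ox_efficiency)) (1 - bs_nonconv_of_mod)
#                   + (1 - m - h) conv_failure
#
# conv_failure: unmodified C escaping bisulfite conversion (reads modified);
# bs_nonconv_of_mod: modified C erroneously read unmodified;
# ox_efficiency: fraction of 5hmC successfully oxidised in the oxBS library.

.SIM_TARGETS <- c("m", "h")
.LIB_KINDS <- c("BS", "oxBS")

#' Build a simulation configuration
#'
#' Defines the genomic landscape (site count, chromosome layout, annotation
#' class fractions), the true per-class 5mC/5hmC baselines, the sequencing
#' model (negative-binomial coverage; conversion/oxidation error rates) and
#' condition-specific effects for a paired BS/oxBS RRBS simulation.
#'
#' @param n_sites Number of CpG sites.
#' @param n_chrom,chrom_length Number of chromosomes and length of each.
#' @param annotation_fractions Named numeric vector: fraction of sites
#'   assigned to each annotation class; must sum to at most 1, the remainder
#'   is unannotated background.
#' @param baseline_m,baseline_h Named numeric vectors of true 5mC / 5hmC
#'   fractions per class; must contain every class in
#'   `annotation_fractions` plus a `"background"` entry; `m + h <= 1`
#'   per class.
#' @param conditions Character vector of condition labels.
#' @param effects `data.frame` with columns `condition`, `class`, `target`
#'   (`"m"` or `"h"`) and `delta`: additive shifts on the fraction scale,
#'   applied to the named class in the named condition.
#' @param n_replicates Biological replicates per condition.
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage mean
#'   and size (dispersion) per library.
#' @param conv_failure Probability an unmodified C escapes conversion and
#'   reads as modified.
#' @param bs_nonconv_of_mod Probability a modified base is read unmodified.
#' @param ox_efficiency Probability a 5hmC base is oxidised in the oxBS
#'   library.
#' @param depth_matched Logical; when `TRUE` the BS and oxBS libraries of a
#'   replicate share one per-site coverage draw, emulating depth-matched
#'   (downsampled) library pairs. Default `FALSE`: separate preps draw
#'   coverage independently. Matched depth is the regime in which the
#'   subtraction estimator's analytic expectation holds; see the vignette.
#' @param seed Integer seed governing every random draw.
#' @return An object of class `sim_config`.
#' @seealso [default_sim_config()] for the shipped HP1-study-style defaults.
#' @export
sim_config <- function(n_sites,
                       n_chrom = 4L,
                       chrom_length = 5e6,
                       annotation_fractions,
                       baseline_m,
                       baseline_h,
                       conditions,
                       effects = data.frame(condition = character(),
                                            class = character(),
                                            target = character(),
                                            delta = numeric()),
                       n_replicates = 3L,
                       coverage_mean = 30,
                       coverage_dispersion = 5,
                       conv_failure = 0.005,
                       bs_nonconv_of_mod = 0.01,
                       ox_efficiency = 0.95,
                       depth_matched = FALSE,
                       seed = 1L) {
  classes <- names(annotation_fractions)
  errs <- character()
  add <- function(...) errs <<- c(errs, sprintf(...))
  if (is.null(classes) || any(!nzchar(classes)) || anyDuplicated(classes))
    add("annotation_fractions must be a uniquely named vector")
  if (any(annotation_fractions < 0)) add("annotation fractions must be >= 0")
  if (sum(annotation_fractions) > 1 + 1e-12)
    add("annotation fractions sum to %.4f > 1", sum(annotation_fractions))
  want <- c(classes, "background")
  for (nm in c("baseline_m", "baseline_h")) {
    v <- get(nm)
    if (!all(want %in% names(v)))
      add("%s must name every annotation class plus 'background'", nm)
  }
  if (all(want %in% names(baseline_m)) && all(want %in% names(baseline_h))) {
    bm <- baseline_m[want]; bh <- baseline_h[want]
    if (any(bm < 0 | bm > 1 | bh < 0 | bh > 1)) add("baselines must lie in [0, 1]")
    if (any(bm + bh > 1 + 1e-12)) add("baseline_m + baseline_h must be <= 1 per class")
  }
  for (p in c("conv_failure", "bs_nonconv_of_mod", "ox_efficiency")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      add("%s must be a probability in [0, 1]", p)
  }
  if (coverage_mean <= 0) add("coverage_mean must be > 0")
  if (coverage_dispersion <= 0) add("coverage_dispersion must be > 0")
  if (n_sites < 1) add("n_sites must be >= 1")
  if (n_replicates < 1) add("n_replicates must be >= 1")
  if (length(conditions) < 1 || anyDuplicated(conditions))
    add("conditions must be a non-empty set of unique labels")
  if (nrow(effects) > 0) {
    if (!all(c("condition", "class", "target", "delta") %in% names(effects)))
      add("effects needs columns condition, class, target, delta")
    else {
      if (!all(effects$target %in% .SIM_TARGETS))
        add("effect target must be 'm' or 'h'")
      if (!all(effects$class %in% classes))
        add("effect classes must be annotation classes: unknown %s",
            paste(setdiff(effects$class, classes), collapse = ", "))
      if (!all(effects$condition %in% conditions))
        add("effect conditions must be declared conditions: unknown %s",
            paste(setdiff(effects$condition, conditions), collapse = ", "))
    }
  }
  if (!is.logical(depth_matched) || length(depth_matched) != 1L)
    add("depth_matched must be TRUE or FALSE")
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  structure(list(
    n_sites = as.integer(n_sites), n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(chrom_length),
    annotation_fractions = annotation_fractions,
    baseline_m = baseline_m[want], baseline_h = baseline_h[want],
    conditions = as.character(conditions), effects = effects,
    n_replicates = as.integer(n_replicates),
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    conv_failure = conv_failure, bs_nonconv_of_mod = bs_nonconv_of_mod,
    ox_efficiency = ox_efficiency, depth_matched = depth_matched,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default simulation configuration emulating the HP1-mutant hippocampus study
#'
#' Eight conditions (WT, HP1bKO, HP1gKO, DKO, each young and aged) with
#' effects mirroring the study's qualitative findings: marked 5mC loss at
#' ERVK (and milder loss at other LTRs), clustered-protocadherin and
#' ICR-like hypomethylation in the double knockout; de novo CpG-island
#' hypermethylation in HP1bKO; and a broad 5hmC gain over introns, LINEs,
#' SINEs and LTRs in single knockouts and in normal aging. Per-class
#' baseline fractions are synthetic choices calibrated so the
#' coverage-weighted global modified-cytosine fraction is ~35%.
#'
#' @param seed Integer seed.
#' @param n_sites Number of CpG sites (default 10000).
#' @param n_replicates Replicates per condition (default 3).
#' @param effects Optional replacement for the default effect table
#'   (`data.frame` with columns condition, class, target, delta).
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed = 1L, n_sites = 10000L, n_replicates = 3L,
                               effects = NULL, ...) {
  fr <- c(CpG = 0.12, exon = 0.10, intron = 0.14, LINE = 0.10, SINE = 0.12,
          ERV1 = 0.04, ERVL_MaLR = 0.05, ERVK = 0.04, LTR_other = 0.04,
          ICR = 0.01, cPcdh = 0.02)
  bm <- c(CpG = 0.10, exon = 0.48, intron = 0.35, LINE = 0.45, SINE = 0.38,
          ERV1 = 0.50, ERVL_MaLR = 0.50, ERVK = 0.75, LTR_other = 0.50,
          ICR = 0.45, cPcdh = 0.40, background = 0.08)
  bh <- c(CpG = 0.01, exon = 0.04, intron = 0.06, LINE = 0.05, SINE = 0.04,
          ERV1 = 0.04, ERVL_MaLR = 0.04, ERVK = 0.03, LTR_other = 0.04,
          ICR = 0.03, cPcdh = 0.03, background = 0.02)
  conds <- c("WT_young", "WT_aged", "HP1bKO_young", "HP1bKO_aged",
             "HP1gKO_young", "HP1gKO_aged", "DKO_young", "DKO_aged")
  dko <- c("DKO_young", "DKO_aged")
  drift <- c("WT_aged", "HP1bKO_young", "HP1bKO_aged",
             "HP1gKO_young", "HP1gKO_aged")
  eff <- rbind(
    expand.grid(condition = dko, class = "ERVK", target = "m", delta = -0.30,
                stringsAsFactors = FALSE),
    expand.grid(condition = dko, class = "LTR_other", target = "m", delta = -0.15,
                stringsAsFactors = FALSE),
    expand.grid(condition = dko, class = "cPcdh", target = "m", delta = -0.35,
                stringsAsFactors = FALSE),
    expand.grid(condition = dko, class = "ICR", target = "m", delta = -0.20,
                stringsAsFactors = FALSE),
    expand.grid(condition = dko, class = "ERVK", target = "h", delta = 0.05,
                stringsAsFactors = FALSE),
    expand.grid(condition = c("HP1bKO_young", "HP1bKO_aged"), class = "CpG",
                target = "m", delta = 0.20, stringsAsFactors = FALSE),
    expand.grid(condition = drift, class = c("intron", "LINE", "SINE", "LTR_other"),
                target = "h", delta = 0.05, stringsAsFactors = FALSE)
  )
  if (!is.null(effects)) eff <- effects
  sim_config(n_sites = n_sites, annotation_fractions = fr, baseline_m = bm,
             baseline_h = bh, conditions = conds, effects = eff,
             n_replicates = n_replicates, seed = seed, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d sites on %d chromosome(s), %d condition(s) x %d replicate(s)\n",
    "  classes: %s\n  coverage NB(mu=%.3g, size=%.3g); conv_failure=%.3g, ",
    "bs_nonconv_of_mod=%.3g, ox_efficiency=%.3g; seed=%d\n"),
    x$n_sites, x$n_chrom, length(x$conditions), x$n_replicates,
    paste(names(x$annotation_fractions), collapse = ", "),
    x$coverage_mean, x$coverage_dispersion, x$conv_failure,
    x$bs_nonconv_of_mod, x$ox_efficiency, x$seed))
  invisible(x)
}

# clamp to [0,1] then enforce m + h <= 1 by proportional rescaling
.clamp_mh <- function(m, h) {
  m <- pmin(pmax(m, 0), 1)
  h <- pmin(pmax(h, 0), 1)
  s <- m + h
  over <- s > 1
  if (any(over)) {
    m[over] <- m[over] / s[over]
    h[over] <- h[over] / s[over]
  }
  list(m = m, h = h)
}

#' Build the simulated genomic landscape and per-site truth
#'
#' Places `n_sites` CpG sites at distinct positions across the configured
#' chromosomes, assigns each site to an annotation class (or background)
#' according to `annotation_fractions`, and derives the true per-condition
#' (5mC, 5hmC) fractions: class baseline plus the sum of applicable effect
#' deltas, clamped to `[0, 1]` with `m + h <= 1` enforced by proportional
#' rescaling. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `annotations` (list of [annotation_set()], one per
#'   class, 1-bp intervals merged when adjacent) and `truth`: a long
#'   `data.frame` with columns `chrom`, `pos`, `class`, `condition`, `m`,
#'   `h`.
#' @export
build_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "landscape"))
  per <- diff(round(seq(0, config$n_sites, length.out = config$n_chrom + 1L)))
  chrom <- character(0); pos <- integer(0)
  for (i in seq_len(config$n_chrom)) {
    if (per[i] == 0L) next
    p <- sort(sample.int(config$chrom_length, per[i]))
    chrom <- c(chrom, rep(sprintf("chr%d", i), per[i]))
    pos <- c(pos, p)
  }
  classes <- names(config$annotation_fractions)
  probs <- c(config$annotation_fractions, 1 - sum(config$annotation_fractions))
  cls <- sample(c(classes, "background"), config$n_sites, replace = TRUE,
                prob = probs)
  annotations <- lapply(classes, function(cl) {
    idx <- which(cls == cl)
    if (length(idx) == 0L) return(annotation_set(cl, data.frame()))
    by_chr <- split(pos[idx], chrom[idx])
    iv <- do.call(rbind, lapply(names(by_chr), function(ch) {
      r <- IRanges::reduce(IRanges::IRanges(start = by_chr[[ch]] - 1L, width = 1L))
      data.frame(chrom = ch, start = IRanges::start(r), end = IRanges::end(r) + 1L,
                 stringsAsFactors = FALSE)
    }))
    annotation_set(cl, iv)
  })
  names(annotations) <- classes
  truth <- do.call(rbind, lapply(config$conditions, function(cond) {
    m <- unname(config$baseline_m[ifelse(cls %in% classes, cls, "background")])
    h <- unname(config$baseline_h[ifelse(cls %in% classes, cls, "background")])
    eff <- config$effects
    if (nrow(eff) > 0) {
      for (k in which(eff$condition == cond)) {
        sel <- cls == eff$class[k]
        if (eff$target[k] == "m") m[sel] <- m[sel] + eff$delta[k]
        else h[sel] <- h[sel] + eff$delta[k]
      }
    }
    mh <- .clamp_mh(m, h)
    data.frame(chrom = chrom, pos = pos, class = cls, condition = cond,
               m = mh$m, h = mh$h, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(annotations = annotations, truth = truth)
}

#' Simulate one BS or oxBS coverage library
#'
#' Draws per-site coverage and modified-read counts for one replicate
#' library of one condition under the generative model described above.
#' Sites drawing zero coverage are omitted (matching the reader invariant
#' that every record carries at least one read). Fully reproducible given
#' the config seed, condition, replicate index and library kind.
#'
#' @param truth Truth table from [build_landscape()].
#' @param condition Condition label (must be one of the config's conditions).
#' @param library_kind `"BS"` or `"oxBS"`.
#' @param replicate Replicate index (1-based integer).
#' @param config The [sim_config()] the truth was built from.
#' @return A coverage `data.frame` (see [read_coverage()] for columns).
#' @export
simulate_library <- function(truth, condition, library_kind, replicate, config) {
  stopifnot(inherits(config, "sim_config"))
  library_kind <- match.arg(library_kind, .LIB_KINDS)
  if (!condition %in% config$conditions)
    stop("unknown condition '", condition, "'; configured: ",
         paste(config$conditions, collapse = ", "))
  tr <- truth[truth$condition == condition, , drop = FALSE]
  if (nrow(tr) == 0L) stop("truth table has no rows for condition '", condition, "'")
  n <- nrow(tr)
  cov_stream <- if (isTRUE(config$depth_matched)) "paired" else library_kind
  set.seed(derive_seed(config$seed, "cov", condition, replicate, cov_stream))
  coverage <- stats::rnbinom(n, size = config$coverage_dispersion,
                             mu = config$coverage_mean)
  set.seed(derive_seed(config$seed, "lib", condition, replicate, library_kind))
  m <- tr$m; h <- tr$h
  eff_mod <- if (library_kind == "BS") m + h else m + h * (1 - config$ox_efficiency)
  p_mod <- eff_mod * (1 - config$bs_nonconv_of_mod) +
    (1 - m - h) * config$conv_failure
  count_mod <- stats::rbinom(n, coverage, p_mod)
  keep <- coverage > 0L
  data.frame(chrom = tr$chrom[keep], pos = tr$pos[keep],
             pct_mod = 100 * count_mod[keep] / coverage[keep],
             count_mod = count_mod[keep],
             count_unmod = coverage[keep] - count_mod[keep],
             stringsAsFactors = FALSE)
}

#' Write / read the ground-truth table
#'
#' Serialises the per-site, per-condition truth (true 5mC and 5hmC
#' fractions) as a TSV that round-trips losslessly.
#'
#' @param truth Truth `data.frame` from [build_landscape()].
#' @param path Output path.
#' @return `path` invisibly for the writer; the truth `data.frame` for the
#'   reader.
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(c("chrom", "pos", "class", "condition", "m", "h") %in% names(truth)))
  write_report_tsv(truth[, c("chrom", "pos", "class", "condition", "m", "h")], path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  df
}

#' Simulate a full paired BS/oxBS experiment to disk
#'
#' Builds the landscape and writes, under `outdir`: one coverage file per
#' condition, replicate and library kind (named
#' `{condition}_{replicate}_{BS|oxBS}.cov`), one BED file per annotation
#' class, and the ground-truth TSV. Byte-identical across reruns with the
#' same config.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the landscape and all written paths.
#' @export
simulate_experiment <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  land <- build_landscape(config)
  cov_paths <- character(0)
  for (cond in config$conditions) {
    for (rep_i in seq_len(config$n_replicates)) {
      for (kind in .LIB_KINDS) {
        rec <- simulate_library(land$truth, cond, kind, rep_i, config)
        p <- file.path(outdir, sprintf("%s_%d_%s.cov", cond, rep_i, kind))
        write_coverage(rec, p)
        cov_paths <- c(cov_paths, p)
      }
    }
  }
  bed_paths <- vapply(land$annotations, function(ann) {
    p <- file.path(outdir, paste0(ann$name, ".bed"))
    write_bed(ann, p)
    p
  }, character(1))
  truth_path <- file.path(outdir, "truth.tsv")
  write_truth(land$truth, truth_path)
  invisible(list(landscape = land, coverage = cov_paths, beds = bed_paths,
                 truth = truth_path))
}
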