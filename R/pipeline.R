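# End-to-end driver: simulate (or ingest) paired BS/oxBS coverage, infer
# 5mC/5hmC per sample, test each configured contrast per channel, and
# quantify annotation enrichment per direction, writing TSV reports and a
# machine-readable run manifest. All stages draw their seeds from the
# single config seed, so a rerun with the same config is byte-identical.

.default_thresholds <- function() {
  list(min_coverage = 10L, min_diff_pct = 25, q_threshold = 0.05)
}

#' Assemble a pipeline configuration
#'
#' @param simulation A [sim_config()]; ignored when `coverage_files` is
#'   supplied.
#' @param contrasts List of contrasts; each a list with `name`, `group_a`,
#'   `group_b` (condition labels) and `channels` (subset of
#'   `c("5mC", "5hmC")`). Group B is the mutant/aged group: "hyper" means
#'   higher in B.
#' @param thresholds List with `min_coverage`, `min_diff_pct`,
#'   `q_threshold`; missing entries are filled with defaults (10, 25, 0.05).
#' @param outdir Output directory.
#' @param seed Integer seed; overrides the simulation seed so one value
#'   governs the whole run.
#' @param coverage_files Optional real-data mode: named list mapping
#'   `condition` to a list of per-replicate lists with elements `bs` and
#'   `oxbs` (paths to existing Bismark coverage files). No simulation is
#'   performed; annotation BED files must then be given in `annotations`.
#' @param annotations Optional named character vector of BED paths
#'   (real-data mode).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = default_sim_config(),
                            contrasts = list(list(name = "DKO_aged_vs_WT_aged",
                                                  group_a = "WT_aged",
                                                  group_b = "DKO_aged",
                                                  channels = c("5mC", "5hmC"))),
                            thresholds = list(), outdir = "hmcall_run",
                            seed = 1L, coverage_files = NULL,
                            annotations = NULL) {
  th <- utils::modifyList(.default_thresholds(), thresholds)
  cfg <- structure(list(simulation = simulation, contrasts = contrasts,
                        thresholds = th, outdir = outdir,
                        seed = as.integer(seed),
                        coverage_files = coverage_files,
                        annotations = annotations),
                   class = "pipeline_config")
  errs <- .config_violations(cfg)
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  cfg
}

.config_violations <- function(cfg) {
  errs <- character()
  add <- function(...) errs <<- c(errs, sprintf(...))
  th <- cfg$thresholds
  if (!is.numeric(th$min_coverage) || th$min_coverage < 1)
    add("thresholds: min_coverage must be >= 1 (got %s)", format(th$min_coverage))
  if (!is.numeric(th$min_diff_pct) || th$min_diff_pct < 0 || th$min_diff_pct > 100)
    add("thresholds: min_diff_pct must lie in [0, 100] (got %s)",
        format(th$min_diff_pct))
  if (!is.numeric(th$q_threshold) || th$q_threshold <= 0 || th$q_threshold >= 1)
    add("thresholds: q_threshold must lie in (0, 1) (got %s)",
        format(th$q_threshold))
  sim_mode <- is.null(cfg$coverage_files)
  if (sim_mode && !inherits(cfg$simulation, "sim_config"))
    add("simulation must be a sim_config (or supply coverage_files)")
  known <- if (sim_mode && inherits(cfg$simulation, "sim_config"))
    cfg$simulation$conditions else names(cfg$coverage_files)
  if (length(cfg$contrasts) == 0L) add("at least one contrast is required")
  for (i in seq_along(cfg$contrasts)) {
    ct <- cfg$contrasts[[i]]
    for (f in c("name", "group_a", "group_b"))
      if (is.null(ct[[f]])) add("contrast %d: missing field '%s'", i, f)
    for (g in c("group_a", "group_b"))
      if (!is.null(ct[[g]]) && !is.null(known) && !ct[[g]] %in% known)
        add("contrast %d: %s '%s' is not a defined condition", i, g, ct[[g]])
    if (!is.null(ct$channels) && !all(ct$channels %in% c("5mC", "5hmC")))
      add("contrast %d: channels must be among 5mC, 5hmC", i)
  }
  if (!sim_mode) {
    for (cond in names(cfg$coverage_files)) {
      for (r in seq_along(cfg$coverage_files[[cond]])) {
        pair <- cfg$coverage_files[[cond]][[r]]
        if (is.null(pair$bs) || is.null(pair$oxbs))
          add("coverage_files: %s replicate %d needs 'bs' and 'oxbs' paths",
              cond, r)
      }
    }
    if (is.null(cfg$annotations) || length(cfg$annotations) == 0L)
      add("real-data mode needs annotation BED paths")
  }
  errs
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults (min_coverage 10,
#' min_diff_pct 25, q_threshold 0.05, the shipped simulation config) and
#' either returns the fully-resolved [pipeline_config()] or stops with
#' every violation found, not just the first.
#'
#' @param path Path to a YAML file. Recognised top-level keys:
#'   `simulation` (overrides for [default_sim_config()]), `contrasts`,
#'   `thresholds`, `outdir`, `seed`, `coverage_files`, `annotations`.
#' @return A `pipeline_config`.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file is not a YAML mapping: ", path)
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  sim <- tryCatch({
    sim_args <- raw$simulation
    if (is.null(sim_args)) sim_args <- list()
    if (!is.null(sim_args$effects))
      sim_args$effects <- do.call(rbind, lapply(sim_args$effects, as.data.frame))
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    do.call(default_sim_config, sim_args)
  }, error = function(e) e)
  contrasts <- raw$contrasts
  if (is.null(contrasts))
    contrasts <- list(list(name = "DKO_aged_vs_WT_aged", group_a = "WT_aged",
                           group_b = "DKO_aged", channels = c("5mC", "5hmC")))
  contrasts <- lapply(contrasts, function(ct) {
    if (is.null(ct$channels)) ct$channels <- c("5mC", "5hmC")
    ct$channels <- unlist(ct$channels)
    ct
  })
  cfg <- structure(list(
    simulation = if (inherits(sim, "error")) NULL else sim,
    contrasts = contrasts,
    thresholds = utils::modifyList(.default_thresholds(),
                                   if (is.null(raw$thresholds)) list()
                                   else raw$thresholds),
    outdir = if (is.null(raw$outdir)) "hmcall_run" else raw$outdir,
    seed = seed,
    coverage_files = raw$coverage_files,
    annotations = if (is.null(raw$annotations)) NULL
                  else unlist(raw$annotations)
  ), class = "pipeline_config")
  errs <- character()
  if (inherits(sim, "error") && is.null(cfg$coverage_files))
    errs <- c(errs, paste("simulation:", conditionMessage(sim)))
  errs <- c(errs, .config_violations(cfg))
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  cfg
}

.log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, sprintf(...)))
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest) -> infer -> differential methylation ->
#' enrichment for every configured contrast and channel. Writes, under the
#' output directory: simulated coverage/BED/truth files (simulation mode),
#' inferred 5mC/5hmC coverage files per sample, a global-summary TSV (one
#' row per replicate and channel), per-contrast DM-site TSVs, per-direction
#' enrichment TSVs, and `manifest.json` recording the seed, thresholds,
#' package version and every output file. Identical config and seed yield
#' byte-identical outputs. Any stage failure aborts with the stage name;
#' the manifest of a failed run is left marked incomplete.
#'
#' @param config A [pipeline_config()] (or path to a YAML config, which is
#'   passed through [validate_config()]).
#' @param outdir Optional override of the configured output directory.
#' @return Invisibly, a list with `dm` (named list of DM-call tables),
#'   `enrichment` (named list of enrichment tables), `global` (the global
#'   summary table) and `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(outdir)) outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  manifest <- list(status = "incomplete", seed = config$seed,
                   thresholds = th, package = "hmcall",
                   version = as.character(utils::packageVersion("hmcall")),
                   outputs = character(0))
  manifest_path <- file.path(outdir, "manifest.json")
  .write_manifest(manifest, manifest_path)
  record <- function(p) manifest$outputs <<- c(manifest$outputs,
                                               basename(p))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      .write_manifest(manifest, manifest_path)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sim_mode <- is.null(config$coverage_files)
  if (sim_mode) {
    sim <- run_stage("simulate", {
      cfg <- config$simulation
      cfg$seed <- config$seed
      simulate_experiment(cfg, outdir)
    })
    annotations <- sim$landscape$annotations
    conditions <- config$simulation$conditions
    n_rep <- config$simulation$n_replicates
    sample_files <- list()
    for (cond in conditions) {
      sample_files[[cond]] <- lapply(seq_len(n_rep), function(r) {
        list(bs = file.path(outdir, sprintf("%s_%d_BS.cov", cond, r)),
             oxbs = file.path(outdir, sprintf("%s_%d_oxBS.cov", cond, r)))
      })
    }
    for (p in c(sim$coverage, sim$beds, sim$truth)) record(p)
  } else {
    annotations <- run_stage("annotations", {
      anns <- lapply(names(config$annotations), function(nm)
        read_bed(config$annotations[[nm]], name = nm))
      names(anns) <- names(config$annotations)
      anns
    })
    sample_files <- config$coverage_files
  }

  # inference: per condition and replicate
  inferred <- list()
  global_rows <- list()
  run_stage("infer", {
    for (cond in names(sample_files)) {
      inferred[[cond]] <- lapply(seq_along(sample_files[[cond]]), function(r) {
        pair <- sample_files[[cond]][[r]]
        res <- infer_sample(pair$bs, pair$oxbs,
                            min_coverage = th$min_coverage)
        mc_path <- file.path(outdir, sprintf("%s_%d_5mC.cov", cond, r))
        hmc_path <- file.path(outdir, sprintf("%s_%d_5hmC.cov", cond, r))
        write_coverage(res$mc, mc_path)
        write_coverage(res$hmc, hmc_path)
        res
      })
      for (r in seq_along(inferred[[cond]])) {
        record(sprintf("%s_%d_5mC.cov", cond, r))
        record(sprintf("%s_%d_5hmC.cov", cond, r))
        for (ch in c("5mC", "5hmC")) {
          rec <- if (ch == "5mC") inferred[[cond]][[r]]$mc
                 else inferred[[cond]][[r]]$hmc
          global_rows[[length(global_rows) + 1L]] <- data.frame(
            condition = cond, replicate = r, channel = ch,
            global_pct = if (nrow(rec)) global_summary(rec) else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  global <- do.call(rbind, global_rows)
  gs_path <- file.path(outdir, "global_summary.tsv")
  write_report_tsv(global, gs_path)
  record(gs_path)

  # differential methylation + enrichment per contrast and channel
  dm_out <- list(); enr_out <- list()
  for (ct in config$contrasts) {
    for (ch in ct$channels) {
      tag <- sprintf("%s_%s", ct$name, ch)
      res <- run_stage(paste0("diffmeth:", tag), {
        pick <- function(cond) lapply(inferred[[cond]], function(x)
          if (ch == "5mC") x$mc else x$hmc)
        tested <- test_dm_sites(pick(ct$group_a), pick(ct$group_b),
                                min_coverage = th$min_coverage, channel = ch)
        dm <- tested[abs(tested$meth_diff) >= th$min_diff_pct &
                       tested$q < th$q_threshold, , drop = FALSE]
        rownames(dm) <- NULL
        list(tested = tested, dm = dm)
      })
      dm_path <- file.path(outdir, sprintf("dm_%s.tsv", tag))
      write_report_tsv(res$dm, dm_path)
      record(dm_path)
      dm_out[[tag]] <- res$dm
      for (dir_lab in c("hyper", "hypo")) {
        sub <- res$dm[res$dm$direction == dir_lab, , drop = FALSE]
        enr <- run_stage(paste0("enrich:", tag, ":", dir_lab), {
          if (nrow(res$tested) == 0L) NULL
          else enrich_all(sub[, c("chrom", "pos")],
                          res$tested[, c("chrom", "pos")], annotations)
        })
        if (!is.null(enr)) {
          enr_path <- file.path(outdir,
                                sprintf("enrichment_%s_%s.tsv", tag, dir_lab))
          write_report_tsv(enr, enr_path)
          record(enr_path)
          enr_out[[paste(tag, dir_lab, sep = "_")]] <- enr
        }
      }
    }
  }

  manifest$status <- "complete"
  .write_manifest(manifest, manifest_path)
  .log_msg("INFO", "pipeline complete: %d contrast-channel result set(s) in %s",
           length(dm_out), outdir)
  invisible(list(dm = dm_out, enrichment = enr_out, global = global,
                 manifest = manifest))
}

.write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
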