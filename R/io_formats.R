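# Readers and writers for the standard formats the pipeline touches:
# Bismark coverage files, BED annotation sets and TSV reports.
#
# Coordinate conventions, used consistently everywhere downstream:
#   * Bismark coverage positions are 1-based inclusive (start == end == pos).
#   * BED intervals are 0-based half-open.
#   * All internal interval arithmetic is 0-based half-open; a cytosine at
#     1-based position p occupies [p - 1, p).
# Chromosome names are matched by exact string equality; no "chr" prefix
# normalisation is attempted.

#' Read a Bismark coverage file
#'
#' Parses a whitespace- or tab-delimited Bismark coverage file
#' (chrom, start, end, percent methylated, count methylated,
#' count unmethylated; 1-based positions) into a per-cytosine table.
#' Each reported position is treated independently; CpG dyads are never
#' merged across strands.
#'
#' @param path Path to a coverage file.
#' @return A `data.frame` with columns `chrom` (character), `pos` (integer,
#'   1-based), `pct_mod` (numeric, 0-100), `count_mod`, `count_unmod`
#'   (non-negative integers, summing to at least 1 per row), sorted by
#'   `(chrom, pos)`. An empty file yields a zero-row table.
#' @export
#' @examples
#' f <- tempfile(fileext = ".cov")
#' writeLines("chr1\t100\t100\t80\t8\t2", f)
#' read_coverage(f)
read_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), pct_mod = numeric(),
                      count_mod = integer(), count_unmod = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- line_no[which(nf < 6L)[1]]
    stop(sprintf("malformed coverage line %d in '%s': fewer than 6 fields", bad, path))
  }
  mat <- vapply(fields, function(x) x[1:6], character(6))
  chrom <- mat[1L, ]
  pos <- suppressWarnings(as.numeric(mat[2L, ]))
  pct <- suppressWarnings(as.numeric(mat[4L, ]))
  cm  <- suppressWarnings(as.numeric(mat[5L, ]))
  cu  <- suppressWarnings(as.numeric(mat[6L, ]))
  bad <- !is.finite(pos) | pos != round(pos) | pos < 1 |
         !is.finite(pct) | pct < 0 | pct > 100 |
         !is.finite(cm) | cm != round(cm) | cm < 0 |
         !is.finite(cu) | cu != round(cu) | cu < 0 |
         (cm + cu) < 1
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "malformed coverage line %d in '%s': need integer pos >= 1, pct in [0,100], non-negative integer counts summing >= 1 (got '%s')",
      line_no[i], path, lines[i]))
  }
  out <- data.frame(chrom = chrom, pos = as.integer(pos), pct_mod = pct,
                    count_mod = as.integer(cm), count_unmod = as.integer(cu),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a Bismark coverage file
#'
#' Writes a per-cytosine table in 6-column Bismark coverage format
#' (tab-delimited, no header, start == end == pos, UTF-8, Unix newlines).
#' Percentages are written with six decimals so that a round trip through
#' [read_coverage()] reproduces counts exactly and percentages to well
#' under 0.01.
#'
#' @param records Coverage `data.frame` as returned by [read_coverage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(records, path) {
  validate_coverage(records)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(records) > 0L) {
    txt <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   records$chrom, records$pos, records$pos,
                   formatC(records$pct_mod, format = "f", digits = 6),
                   records$count_mod, records$count_unmod)
    writeLines(txt, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Validate a per-cytosine coverage table
#'
#' Checks the structural invariants of a coverage table: required columns,
#' non-negative integer counts summing to at least one read per site, and a
#' stored percentage consistent with the count-derived percentage. The
#' allowed deviation is `max(0.5, 50 / coverage)` per record: 0.5 covers
#' percents stored rounded in coverage files, and `50 / coverage` is the
#' bound induced by integer-count reconstruction of 5hmC records, whose
#' stored percent is the subtracted percent rather than the count ratio.
#'
#' @param records A coverage `data.frame`.
#' @return `records`, invisibly; stops with a message on violation.
#' @export
validate_coverage <- function(records) {
  need <- c("chrom", "pos", "pct_mod", "count_mod", "count_unmod")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("coverage table must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  if (nrow(records) == 0L) return(invisible(records))
  cm <- records$count_mod; cu <- records$count_unmod
  if (any(cm < 0 | cu < 0 | cm != round(cm) | cu != round(cu)))
    stop("coverage counts must be non-negative integers")
  if (any(cm + cu < 1)) stop("every coverage record needs count_mod + count_unmod >= 1")
  if (any(records$pct_mod < 0 | records$pct_mod > 100))
    stop("pct_mod must lie in [0, 100]")
  exact <- 100 * cm / (cm + cu)
  tol <- pmax(0.5, 50 / (cm + cu))
  if (any(abs(records$pct_mod - exact) > tol + 1e-9))
    stop("pct_mod inconsistent with count-derived percentage")
  invisible(records)
}

#' Construct an annotation set
#'
#' An annotation set is a named collection of genomic intervals in 0-based
#' half-open coordinates (one class, e.g. "CpG", "ERVK", "LINE"). Intervals
#' within a class may overlap; sites are scored by membership, not
#' multiplicity.
#'
#' @param name Class label.
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open, `start < end`).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(name, intervals) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (nrow(intervals) > 0L) {
    stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
    if (any(intervals$start < 0) || any(intervals$start >= intervals$end))
      stop("annotation intervals need 0 <= start < end")
  } else {
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
  }
  structure(list(name = name,
                 intervals = data.frame(chrom = as.character(intervals$chrom),
                                        start = as.integer(intervals$start),
                                        end = as.integer(intervals$end),
                                        stringsAsFactors = FALSE)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d interval(s)\n", x$name, nrow(x$intervals)))
  invisible(x)
}

#' Read a BED annotation file
#'
#' Reads a BED3+ file (0-based half-open intervals) into an
#' [annotation_set()]. The class label is supplied by the caller, not taken
#' from the file.
#'
#' @param path Path to a BED file.
#' @param name Annotation class label for the set.
#' @return An `annotation_set`.
#' @export
read_bed <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#") &
    !startsWith(trimws(lines), "track")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(annotation_set(name, data.frame()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d in '%s': fewer than 3 fields",
                 line_no[which(nf < 3L)[1]], path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- !is.finite(start) | !is.finite(end) | start != round(start) |
    end != round(end) | start < 0 | start >= end
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("malformed BED line %d in '%s': need integer 0 <= start < end (got '%s')",
                 line_no[i], path, lines[i]))
  }
  annotation_set(name, data.frame(chrom = chrom, start = as.integer(start),
                                  end = as.integer(end), stringsAsFactors = FALSE))
}

#' Write an annotation set as BED3
#'
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(ann$intervals) > 0L) {
    writeLines(sprintf("%s\t%d\t%d", ann$intervals$chrom, ann$intervals$start,
                       ann$intervals$end), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

# Write a TSV report with header, UTF-8, Unix newlines; numbers at full
# precision so reports round-trip.
write_report_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cols <- lapply(df, function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  })
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}
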