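# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a base seed and a label
#'
#' Combines a base integer seed with an arbitrary set of string/numeric
#' labels (condition, replicate index, library kind, stage name, ...) into a
#' deterministic 32-bit seed, so that independent simulation streams do not
#' collide and every stream is reproducible from the single top-level seed.
#'
#' @param seed Base integer seed.
#' @param ... Labels identifying the stream; coerced to character.
#' @return A single integer in `[1, 2^31 - 20]`.
#' @export
#' @examples
#' derive_seed(1, "lib", "WT_young", 2, "BS")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  label <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                        character(1)), collapse = "/")
  m <- 2147483629 # prime < 2^31
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m + h) %% m + 1)
}

# round half away from zero ("closest integer" with fixed half-way behaviour;
# base round() rounds half to even, which is not what we want here)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# TRUE when a coverage table is sorted by (chrom, pos)
.is_sorted_sites <- function(chrom, pos) {
  if (length(pos) <= 1L) return(TRUE)
  o <- order(chrom, pos, method = "radix")
  all(o == seq_along(o))
}

.site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

.stop_mod <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}
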