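## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference genome lengths
#'
#' GRCh38 chromosome lengths (bp). Used as the default genome both for the
#' clustering chance model (whose null considers genome-wide breakend
#' density, so `G` should be the whole genome) and for the cohort
#' simulator (background copy-number events land on non-chr21
#' chromosomes).
#'
#' @return Named numeric vector of chromosome lengths.
#' @export
default_genome <- function() {
  c(chr1 = 248956422, chr2 = 242193529, chr3 = 198295559,
    chr4 = 190214555, chr5 = 181538259, chr6 = 170805979,
    chr7 = 159345973, chr8 = 145138636, chr9 = 138394717,
    chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
    chr13 = 114364328, chr14 = 107043718, chr15 = 101991189,
    chr16 = 90338345, chr17 = 83257441, chr18 = 80373285,
    chr19 = 58617616, chr20 = 64444167, chr21 = 46709983,
    chr22 = 50818468, chrX = 156040895, chrY = 57227415)
}

#' Canonical simulated chromothripsis event region
#'
#' The default shatter region used by worked examples and the
#' simulator-to-caller round trip: a focal 200-kb window at the 21q22
#' amplified core. The focal scale keeps the breakend density of a
#' 20-breakpoint event compatible with the simplified proximity null used
#' for clustering (breakend gaps well below `G * alpha`).
#'
#' @return Numeric `c(start, end)` on chr21.
#' @export
default_event_region <- function() c(37500000, 37700000)

## Validate a seed: single finite integer-valued scalar below 2^31.
check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) ||
      seed != round(seed) || abs(seed) >= 2^31)
    stop("'seed' must be a single integer with |seed| < 2^31", call. = FALSE)
  as.integer(seed)
}

## Derive k child seeds from a parent seed deterministically, all < 2^31.
derive_seeds <- function(seed, k) {
  set.seed(check_seed(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  x
}

## Classed error for degenerate simulation draws.
stop_degenerate <- function(msg) {
  cnd <- structure(
    class = c("chromoshard_degenerate_draw", "error", "condition"),
    list(message = msg, call = sys.call(-1)))
  stop(cnd)
}

## Classed error when single-cell data cannot support ordering.
stop_insufficient_data <- function(msg) {
  cnd <- structure(
    class = c("chromoshard_insufficient_data", "error", "condition"),
    list(message = msg, call = sys.call(-1)))
  stop(cnd)
}

## Largest-remainder apportionment: integer counts summing to n with
## counts/n as close to 'fractions' as possible. Used so that printed
## prevalences are hit exactly rather than in expectation.
apportion <- function(fractions, n) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
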