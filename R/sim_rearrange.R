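## Derivative-chromosome simulator.
##
## A derivative arrangement describes the rearranged content of one region
## of one chromosome on ONE haplotype (amplification events of this kind
## occur on a single allele). Fragments are 0-based half-open source
## intervals, in derivative order, each with an orientation and a
## copy_index distinguishing repeated uses of the same source interval.
## The flanks of the region ([0, region_start) and [region_end, chrom_len))
## are implicit, always retained, forward, on both alleles.

new_arrangement <- function(chrom, chrom_length, region, fragments,
                            mechanism) {
  stopifnot(region[1] < region[2], region[1] >= 0,
            region[2] <= chrom_length)
  structure(list(chrom = chrom, chrom_length = chrom_length,
                 region = as.numeric(region), fragments = fragments,
                 mechanism = mechanism, affected_allele = "allele1"),
            class = "derivative_arrangement")
}

#' Construct a derivative arrangement explicitly
#'
#' Low-level constructor for a derivative chromosome given its ordered
#' fragment list. Mostly useful for tests and worked examples (e.g. the
#' identity arrangement, which must imply zero junctions and a flat
#' copy-number profile).
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param region Numeric `c(start, end)`, 0-based half-open.
#' @param source_start,source_end,orientation Parallel vectors describing
#'   the fragments in derivative order.
#' @param mechanism Label, e.g. `"chromothripsis"`, `"bfb"`, `"simple_sv"`
#'   or `"background"`.
#' @return A `derivative_arrangement`.
#' @export
derivative_arrangement <- function(chrom, chrom_length, region,
                                   source_start, source_end, orientation,
                                   mechanism = "background") {
  if (any(source_start >= source_end))
    stop("fragment source_start must be < source_end", call. = FALSE)
  if (any(source_start < region[1]) || any(source_end > region[2]))
    stop("fragments must lie within the declared region", call. = FALSE)
  new_arrangement(chrom, chrom_length, region,
                  frag_table(source_start, source_end, orientation),
                  mechanism)
}

#' @export
print.derivative_arrangement <- function(x, ...) {
  cat(sprintf("<derivative_arrangement> %s on %s:%s-%s (%d fragment(s), one allele)\n",
              x$mechanism, x$chrom, format_pos(x$region[1]),
              format_pos(x$region[2]), nrow(x$fragments)))
  invisible(x)
}

frag_table <- function(source_start, source_end, orientation) {
  dt <- data.table(source_start = as.numeric(source_start),
                   source_end = as.numeric(source_end),
                   orientation = as.character(orientation))
  ## copy_index: 0,1,2,... per repeated use of an identical source interval
  dt[, copy_index := seq_len(.N) - 1L, by = .(source_start, source_end)]
  dt
}

#' Simulate a chromothriptic derivative chromosome
#'
#' Models catastrophic shattering followed by haphazard religation: the
#' region is cut at `n_breakpoints` uniformly drawn positions into
#' `n_breakpoints + 1` fragments; each fragment is independently retained
#' with probability `retention_prob`; retained fragments are shuffled
#' uniformly, each inverted with probability 1/2, and the result is
#' reattached between the flanking (unshattered) sequence. Lost fragments
#' leave single-allele copy-number losses, so the copy number downstream
#' oscillates between two states along the region.
#'
#' With `amp_multiplicity > 1` an amplified sub-block is planted: fragments
#' within `amp_interval` (which is forced onto the breakpoint grid) are
#' each emitted `amp_multiplicity` times, modelling chromothripsis with
#' fragment amplification.
#'
#' @param chrom Chromosome name.
#' @param region Numeric `c(start, end)`, 0-based half-open.
#' @param n_breakpoints Number of cuts (>= 2).
#' @param retention_prob Per-fragment retention probability.
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @param chrom_length Chromosome length; defaults to the region end.
#' @param amp_multiplicity Copies for fragments inside `amp_interval`.
#' @param amp_interval Interval to amplify when `amp_multiplicity > 1`.
#' @return A `derivative_arrangement`.
#' @export
simulate_chromothripsis <- function(chrom, region, n_breakpoints = 20,
                                    retention_prob = 0.5, seed,
                                    chrom_length = NULL,
                                    amp_multiplicity = 1,
                                    amp_interval = NULL) {
  set.seed(check_seed(seed))
  check_prob(retention_prob, "retention_prob")
  region <- as.numeric(region)
  chrom_length <- chrom_length %||% region[2]
  if (n_breakpoints < 2) stop("n_breakpoints must be >= 2", call. = FALSE)
  if (region[2] - region[1] <= n_breakpoints)
    stop("region length must exceed n_breakpoints", call. = FALSE)
  bp <- sort(region[1] + sample.int(region[2] - region[1] - 1,
                                    n_breakpoints))
  if (amp_multiplicity > 1) {
    if (is.null(amp_interval))
      stop("amp_interval required when amp_multiplicity > 1", call. = FALSE)
    bp <- sort(unique(c(bp, amp_interval)))
    bp <- bp[bp > region[1] & bp < region[2]]
  }
  starts <- c(region[1], bp)
  ends <- c(bp, region[2])
  n_frag <- length(starts)
  mult <- rbinom(n_frag, 1, retention_prob)
  if (amp_multiplicity > 1) {
    in_amp <- starts >= amp_interval[1] & ends <= amp_interval[2]
    mult[in_amp] <- amp_multiplicity
  }
  if (sum(mult) == 0)
    stop_degenerate("degenerate chromothripsis draw: no fragment retained")
  idx <- rep(seq_len(n_frag), mult)
  idx <- idx[sample.int(length(idx))]          # haphazard religation order
  ori <- ifelse(runif(length(idx)) < 0.5, "-", "+")
  arr <- new_arrangement(chrom, chrom_length, region,
                         frag_table(starts[idx], ends[idx], ori),
                         "chromothripsis")
  arr
}

#' Simulate breakage-fusion-bridge cycles
#'
#' Iterated break-invert-duplicate: each cycle picks a uniform break
#' position along the current derivative, keeps the proximal prefix, and
#' fuses a mirror image of that prefix onto the break (sister-chromatid
#' fusion), creating a head-to-head or tail-to-tail fold-back junction
#' with co-located breakends and doubling copy counts distal of successive
#' breaks. After `n_cycles` the product is re-anchored to the distal flank
#' (the final stabilising rejoin is abstracted, not modelled).
#'
#' @param chrom Chromosome name.
#' @param region Numeric `c(start, end)`, 0-based half-open (>= 2 bp).
#' @param n_cycles Number of cycles (>= 1).
#' @param seed Integer seed.
#' @param chrom_length Chromosome length; defaults to the region end.
#' @return A `derivative_arrangement`.
#' @export
simulate_bfb <- function(chrom, region, n_cycles, seed,
                         chrom_length = NULL) {
  set.seed(check_seed(seed))
  region <- as.numeric(region)
  chrom_length <- chrom_length %||% region[2]
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  if (region[2] - region[1] < 2)
    stop("region must be at least 2 bp", call. = FALSE)
  frags <- data.table(source_start = region[1], source_end = region[2],
                      orientation = "+")
  for (cycle in seq_len(n_cycles)) {
    len <- sum(frags$source_end - frags$source_start)
    ## the dicentric bridge breaks between its two centromeres, distal of
    ## the fold: draw the break in the distal half so each daughter keeps
    ## a full copy of the prior arrangement (copy counts double, max CN
    ## non-decreasing in cycle count)
    half <- floor(len / 2)
    cut <- half + sample.int(max(len - half - 1, 1), 1) - 1
    cut <- max(cut, 1)
    prefix <- truncate_fragments(frags, cut)
    mirror <- prefix[rev(seq_len(nrow(prefix)))]
    mirror[, orientation := ifelse(orientation == "+", "-", "+")]
    frags <- rbind(prefix, mirror)
  }
  new_arrangement(chrom, chrom_length, region,
                  frag_table(frags$source_start, frags$source_end,
                             frags$orientation), "bfb")
}

## Keep the first 'offset' derivative bases of a fragment list, splitting
## the fragment that straddles the cut (in source coordinates, respecting
## orientation).
truncate_fragments <- function(frags, offset) {
  lens <- frags$source_end - frags$source_start
  cum <- cumsum(lens)
  i <- which(cum >= offset)[1]
  keep <- frags[seq_len(i)]
  excess <- cum[i] - offset
  if (excess > 0) {
    if (keep$orientation[i] == "+")
      keep[i, source_end := source_end - excess]
    else
      keep[i, source_start := source_start + excess]
  }
  keep
}

#' Simulate a simple structural variant
#'
#' Single-junction (or two-junction, for inversions) events used as
#' negative controls for complex-event classification and as the
#' non-chromothriptic route to regional amplification.
#'
#' @param chrom Chromosome name.
#' @param region The affected interval, `c(start, end)` 0-based half-open.
#' @param type `"tandem_duplication"`, `"deletion"` or `"inversion"`.
#' @param seed Integer seed (kept for interface uniformity; the
#'   construction is deterministic given its arguments).
#' @param chrom_length Chromosome length; defaults to the region end plus
#'   the region length (so the event is interstitial).
#' @param n_copies Total copies of the region for tandem duplications.
#' @return A `derivative_arrangement`.
#' @export
simulate_simple_sv <- function(chrom, region,
                               type = c("tandem_duplication", "deletion",
                                        "inversion"),
                               seed = 1, chrom_length = NULL, n_copies = 2) {
  type <- match.arg(type)
  check_seed(seed)
  region <- as.numeric(region)
  chrom_length <- chrom_length %||% (region[2] + (region[2] - region[1]))
  frags <- switch(type,
    tandem_duplication = frag_table(rep(region[1], n_copies),
                                    rep(region[2], n_copies),
                                    rep("+", n_copies)),
    deletion = frag_table(numeric(0), numeric(0), character(0)),
    inversion = frag_table(region[1], region[2], "-"))
  new_arrangement(chrom, chrom_length, region, frags, "simple_sv")
}

#' Derive the copy-number profile implied by an arrangement
#'
#' Total copy number at a base is `(ploidy - 1)` (the unaffected alleles)
#' plus the number of fragment copies covering it on the affected allele.
#' Returned segments are maximal constant-CN intervals covering the whole
#' chromosome, sorted and non-overlapping.
#'
#' @param arr A `derivative_arrangement`.
#' @param ploidy Baseline ploidy (default 2).
#' @param sample_id Sample id stamped on the segments.
#' @return A `cn_segments` table.
#' @export
derive_cn_profile <- function(arr, ploidy = 2, sample_id = "sample1") {
  L <- arr$chrom_length
  ivs <- rbind(
    data.table(start = c(0, arr$region[2]),
               end = c(arr$region[1], L))[start < end],
    arr$fragments[, .(start = source_start, end = source_end)])
  if (nrow(ivs) == 0) {                        # whole chromosome shattered, all lost
    return(cn_segments(arr$chrom, 0, L, ploidy - 1, sample_id = sample_id))
  }
  cov <- IRanges::coverage(IRanges(ivs$start + 1, ivs$end), width = L)
  rl <- S4Vectors::runLength(cov)
  rv <- S4Vectors::runValue(cov) + (ploidy - 1)
  ends <- cumsum(rl)
  starts <- c(0, head(ends, -1))
  cn_segments(arr$chrom, starts, ends, rv, sample_id = sample_id)
}

#' Derive breakpoint junctions implied by an arrangement
#'
#' One junction is emitted for every adjacent fragment pair (including the
#' implicit flanks) whose source coordinates are not contiguous in
#' orientation. Breakend strands follow the flanking fragment
#' orientations, so a skipped fragment yields a deletion-type junction and
#' a mirrored fragment a fold-back (HH/TT) junction. Each junction gets an
#' insertion length drawn uniformly from `insertion_len_range`, the short
#' non-templated scar characteristic of non-homologous end joining; no
#' templated insertions are emitted.
#'
#' @param arr A `derivative_arrangement`.
#' @param insertion_len_range Integer `c(lo, hi)`, default `c(0, 6)` bp.
#' @param seed Integer seed for the insertion-length draws.
#' @param sample_id Sample id stamped on the junctions.
#' @return A `junction_set`.
#' @export
derive_junctions <- function(arr, insertion_len_range = c(0, 6), seed = 1,
                             sample_id = "sample1") {
  set.seed(check_seed(seed))
  fr <- arr$fragments
  walk <- rbind(
    if (arr$region[1] > 0)
      data.table(source_start = 0, source_end = arr$region[1],
                 orientation = "+")
    else NULL,
    fr[, .(source_start, source_end, orientation)],
    if (arr$region[2] < arr$chrom_length)
      data.table(source_start = arr$region[2],
                 source_end = arr$chrom_length, orientation = "+")
    else NULL)
  n <- nrow(walk)
  if (n < 2)
    return(junctions(character(0), numeric(0), character(0), character(0),
                     numeric(0), character(0), sample_id = sample_id))
  left <- walk[-n]; right <- walk[-1]
  contiguous <-
    (left$orientation == "+" & right$orientation == "+" &
       left$source_end == right$source_start) |
    (left$orientation == "-" & right$orientation == "-" &
       left$source_start == right$source_end)
  keep <- which(!contiguous)
  if (length(keep) == 0)
    return(junctions(character(0), numeric(0), character(0), character(0),
                     numeric(0), character(0), sample_id = sample_id))
  pos1 <- ifelse(left$orientation[keep] == "+", left$source_end[keep],
                 left$source_start[keep])
  str1 <- ifelse(left$orientation[keep] == "+", "+", "-")
  pos2 <- ifelse(right$orientation[keep] == "+", right$source_start[keep],
                 right$source_end[keep])
  str2 <- ifelse(right$orientation[keep] == "+", "-", "+")
  ins <- sample(seq(insertion_len_range[1], insertion_len_range[2]),
                length(keep), replace = TRUE)
  junctions(arr$chrom, pos1, str1, arr$chrom, pos2, str2,
            insertion_len = ins, sample_id = sample_id)
}
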