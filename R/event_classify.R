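## Simple/complex and chromothripsis-like classification of SV clusters.

#' Default chromothripsis-like classification thresholds
#'
#' The four criteria: cluster size at least 5 grouped SVs; fragment-join
#' goodness-of-fit p at least 0.05 (random joining); at least 4
#' interleaved events; and copy-number oscillations of at least 4 segments
#' between 2 states or at least 5 segments between 3 states. An event is
#' chromothripsis-like when at least 3 of the 4 criteria are met (and the
#' cluster is complex).
#'
#' @return Named list of thresholds.
#' @export
chromothripsis_thresholds <- function() {
  list(min_sv = 5L, min_fragment_join_p = 0.05, min_interleaved = 4L,
       min_run2 = 4L, min_run3 = 5L, min_criteria = 3L, min_seg_len = 1e4)
}

#' Classify cluster complexity
#'
#' A cluster is `"complex"` when it contains at least 3 interconnected
#' SVs; clusters of 1-2 junctions (e.g. a simple tandem duplication) are
#' `"simple"`.
#'
#' @param cluster An `sv_cluster` or an integer junction count.
#' @return `"simple"` or `"complex"`.
#' @export
classify_complexity <- function(cluster) {
  n <- if (inherits(cluster, "sv_cluster")) cluster$n_junctions
       else as.integer(cluster)
  if (n >= 3L) "complex" else "simple"
}

#' Chromothripsis-like classification of one cluster
#'
#' Evaluates the four criteria against `thresholds` and returns a
#' `chromothripsis_call`. When no copy-number data overlap the cluster
#' footprint the oscillation criterion is unknown and drops out of the
#' denominator rather than counting as failed (conservative): the verdict
#' then requires all 3 remaining criteria. The verdict is
#' `"chromothripsis_like"` only for complex clusters meeting at least
#' `min_criteria` known criteria; otherwise `"complex"` or `"simple"`.
#'
#' @param cluster An `sv_cluster`.
#' @param segs Optional `cn_segments` for the same sample (restricted to
#'   the cluster footprint internally).
#' @param thresholds See [chromothripsis_thresholds()].
#' @return A `chromothripsis_call` (list with criterion flags, counts,
#'   verdict, fold-back presence and the small-insertion fraction).
#' @export
classify_chromothripsis <- function(cluster, segs = NULL,
                                    thresholds = chromothripsis_thresholds()) {
  th <- utils::modifyList(chromothripsis_thresholds(), thresholds)
  size_ok <- cluster$n_junctions >= th$min_sv
  p <- cluster$fragment_join_p
  fragment_join_ok <- if (is.na(p)) NA else p >= th$min_fragment_join_p
  interleaved_ok <- as.integer(cluster$n_interleaved) >= th$min_interleaved
  run2 <- run3 <- NA_integer_
  oscillation_ok <- NA
  if (!is.null(segs)) {
    states <- cn_states_in_footprint(segs, cluster$footprint,
                                     min_seg_len = th$min_seg_len)
    if (length(states) > 0) {
      run2 <- max_oscillation_run(states, k = 2)
      run3 <- max_oscillation_run(states, k = 3)
      oscillation_ok <- run2 >= th$min_run2 || run3 >= th$min_run3
    }
  }
  flags <- c(size_ok = size_ok, fragment_join_ok = fragment_join_ok,
             interleaved_ok = interleaved_ok, oscillation_ok = oscillation_ok)
  n_met <- sum(flags, na.rm = TRUE)
  complexity <- classify_complexity(cluster)
  verdict <- if (complexity == "complex" && n_met >= th$min_criteria)
    "chromothripsis_like" else complexity
  sig <- repair_signature(cluster$junctions)
  structure(list(
    cluster_id = cluster$cluster_id,
    flags = flags,
    n_criteria_met = n_met,
    n_criteria_known = sum(!is.na(flags)),
    oscillation_run2 = run2,
    oscillation_run3 = run3,
    verdict = verdict,
    foldback_present = any(detect_foldback(cluster$junctions)),
    frac_small_insertions = sig$fraction),
    class = "chromothripsis_call")
}

#' @export
print.chromothripsis_call <- function(x, ...) {
  f <- ifelse(is.na(x$flags), "?", ifelse(x$flags, "+", "-"))
  cat(sprintf("<chromothripsis_call %s> %s (%d/%d criteria: size%s join%s interleave%s oscillate%s)%s\n",
              x$cluster_id, x$verdict, x$n_criteria_met, x$n_criteria_known,
              f[1], f[2], f[3], f[4],
              if (isTRUE(x$foldback_present)) " foldback" else ""))
  invisible(x)
}

#' Detect fold-back inversion junctions
#'
#' A fold-back is an intrachromosomal head-to-head or tail-to-tail
#' inverted junction whose breakends lie close together (within
#' `max_gap`), the hallmark of a breakage-fusion-bridge cycle.
#'
#' @param junc A `junction_set`.
#' @param max_gap Maximum breakend separation in bp (default 5000).
#' @return Logical vector, one element per junction.
#' @export
detect_foldback <- function(junc, max_gap = 5000) {
  cls <- classify_orientation(junc)
  junc <- as.data.table(junc)
  cls %in% c("HH", "TT") & abs(junc$pos2 - junc$pos1) <= max_gap
}

#' Breakpoint repair signature summary
#'
#' Fraction of junctions whose insertion length falls in `nhej_range`
#' (short non-templated insertions, the non-homologous end joining scar),
#' plus the insertion-length histogram. Junctions without an insertion
#' length are excluded and reported.
#'
#' @param junc A `junction_set`.
#' @param nhej_range Inclusive bp range, default `c(0, 6)`.
#' @param consistency_threshold Fraction at or above which the set is
#'   flagged NHEJ-consistent (default 0.8).
#' @return List with `fraction`, `histogram`, `nhej_consistent`,
#'   `n_assessed`, `n_missing`.
#' @export
repair_signature <- function(junc, nhej_range = c(0, 6),
                             consistency_threshold = 0.8) {
  junc <- as.data.table(junc)
  ins <- junc$insertion_len
  missing <- is.na(ins)
  ins <- ins[!missing]
  frac <- if (length(ins) == 0) NA_real_
          else mean(ins >= nhej_range[1] & ins <= nhej_range[2])
  list(fraction = frac,
       histogram = table(factor(ins, levels = seq(min(c(ins, nhej_range[1])),
                                                  max(c(ins, nhej_range[2]))))),
       nhej_consistent = !is.na(frac) && frac >= consistency_threshold,
       n_assessed = length(ins),
       n_missing = sum(missing))
}

#' Cluster, classify and summarise one sample's junctions
#'
#' Convenience wrapper running [cluster_junctions()] and
#' [classify_chromothripsis()] over every cluster, returning a per-cluster
#' call table.
#'
#' @param junc A `junction_set` (one sample).
#' @param segs Optional `cn_segments` for the sample.
#' @param genome_lengths,alpha Passed to [cluster_junctions()].
#' @param thresholds Passed to [classify_chromothripsis()].
#' @return `data.table` with one row per cluster: verdict, criteria flags,
#'   fold-back presence, small-insertion fraction.
#' @export
classify_sample <- function(junc, segs = NULL,
                            genome_lengths = default_genome(),
                            alpha = 1e-3,
                            thresholds = chromothripsis_thresholds()) {
  clusters <- cluster_junctions(junc, genome_lengths, alpha)
  rbindlist(lapply(clusters, function(cl) {
    call <- classify_chromothripsis(cl, segs, thresholds)
    data.table(cluster_id = cl$cluster_id,
               n_junctions = cl$n_junctions,
               verdict = call$verdict,
               n_criteria_met = call$n_criteria_met,
               n_criteria_known = call$n_criteria_known,
               size_ok = call$flags[["size_ok"]],
               fragment_join_ok = call$flags[["fragment_join_ok"]],
               interleaved_ok = call$flags[["interleaved_ok"]],
               oscillation_ok = call$flags[["oscillation_ok"]],
               oscillation_run2 = call$oscillation_run2,
               oscillation_run3 = call$oscillation_run3,
               foldback_present = call$foldback_present,
               frac_small_insertions = call$frac_small_insertions)
  }))
}
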