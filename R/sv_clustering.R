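## Proximity clustering of breakpoint junctions and the per-cluster
## statistics feeding chromothripsis-like classification.

#' Cluster junctions by breakend proximity
#'
#' Groups junctions that fall closer together than expected by chance.
#' With `N` breakends scattered over a genome of total length `G`, the
#' probability that two independent breakends land within distance `d` of
#' each other is approximated by `p = 1 - exp(-2 N d / G)` (Poisson/
#' exponential nearest-neighbour approximation). Clusters are merged
#' agglomeratively: at each step the pair of clusters with the smallest
#' inter-cluster minimum breakend distance (same chromosome only) is
#' merged if its `p` is below `alpha`; translocation junctions carry
#' breakends on both partner chromosomes and therefore connect clusters
#' across them. Because `p` is monotone in `d`, this is single-linkage
#' merging and the fixpoint equals the connected components at the
#' distance threshold `d* = -G log(1 - alpha) / (2 N)`. Ties are broken
#' deterministically (leftmost coordinate, then id).
#'
#' @param junc A `junction_set`.
#' @param genome_lengths Named vector of chromosome lengths covering every
#'   chromosome used (see [default_genome()]).
#' @param alpha Chance threshold in (0, 1); default `1e-3`.
#' @return A list of `sv_cluster` objects (see [cluster_stats()]), one per
#'   cluster; every junction belongs to exactly one cluster.
#' @export
cluster_junctions <- function(junc, genome_lengths = default_genome(),
                              alpha = 1e-3) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  junc <- as.data.table(junc)
  if (nrow(junc) == 0) stop("no junctions to cluster", call. = FALSE)
  chroms <- unique(c(junc$chrom1, junc$chrom2))
  if (!all(chroms %in% names(genome_lengths)))
    stop("genome_lengths missing: ",
         paste(setdiff(chroms, names(genome_lengths)), collapse = ", "),
         call. = FALSE)
  n <- nrow(junc)
  N <- 2 * n
  G <- sum(genome_lengths)
  d_star <- -G * log(1 - alpha) / (2 * N)

  ## breakends as points
  be <- data.table(
    j = rep(seq_len(n), 2L),
    chrom = c(junc$chrom1, junc$chrom2),
    pos = c(junc$pos1, junc$pos2))
  ## union-find over junctions; link junctions with any same-chromosome
  ## breakend pair within d_star
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  setorder(be, chrom, pos, j)
  for (ch in unique(be$chrom)) {
    sub <- be[chrom == ch]
    if (nrow(sub) < 2) next
    close_next <- diff(sub$pos) <= d_star
    for (k in which(close_next)) {
      a <- find(sub$j[k]); b <- find(sub$j[k + 1])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  ## deterministic cluster ids: ordered by leftmost breakend then id
  ord <- junc[, .(j = seq_len(n), chrom1, pos1, id)][order(chrom1, pos1, id)]
  seen <- unique(comp[ord$j])
  relabel <- setNames(seq_along(seen), seen)
  comp <- relabel[as.character(comp)]
  lapply(seq_along(seen), function(k) {
    cluster_stats(junc[comp == k], cluster_id = sprintf("C%03d", k),
                  d_pad = d_star)
  })
}

#' Compute cluster statistics
#'
#' Builds an `sv_cluster`: member junction ids, per-chromosome footprint
#' intervals (union of breakend neighbourhoods), orientation class counts,
#' the number of interleaved members and the fragment-join p-value.
#'
#' @param junc Junctions of one cluster.
#' @param cluster_id Identifier.
#' @param d_pad Padding added around breakends when forming footprints.
#' @return An `sv_cluster` object.
#' @export
cluster_stats <- function(junc, cluster_id = "C001", d_pad = 0) {
  junc <- as.data.table(junc)
  cls <- classify_orientation(junc)
  counts <- vapply(c("D", "TD", "HH", "TT", "TRA"),
                   function(k) sum(cls == k), 1L)
  be <- data.table(chrom = c(junc$chrom1, junc$chrom2),
                   pos = c(junc$pos1, junc$pos2))
  fp <- be[, .(start = max(0, min(pos) - d_pad), end = max(pos) + d_pad + 1),
           by = chrom]
  structure(list(
    cluster_id = cluster_id,
    junctions = junc,
    junction_ids = junc$id,
    n_junctions = nrow(junc),
    footprint = fp,
    orientation_counts = counts,
    n_interleaved = count_interleaved(junc),
    fragment_join_p = fragment_join_pvalue(counts[c("D", "TD", "HH", "TT")])),
    class = "sv_cluster")
}

#' @export
print.sv_cluster <- function(x, ...) {
  cat(sprintf("<sv_cluster %s> %d junction(s) [%s] interleaved=%d fragment_join_p=%s\n",
              x$cluster_id, x$n_junctions,
              paste(names(x$orientation_counts), x$orientation_counts,
                    sep = ":", collapse = " "),
              x$n_interleaved,
              format(x$fragment_join_p, digits = 3)))
  invisible(x)
}

#' Count interleaved junctions
#'
#' Two intrachromosomal junctions interleave when their spans cross:
#' exactly one breakend of one lies strictly inside the other's span
#' (nested or disjoint pairs do not count). Returns the number of
#' junctions that interleave with at least one other cluster member; the
#' pairwise crossing count is attached as attribute `"n_pairs"`.
#'
#' @param junc Junctions of one cluster.
#' @return Integer count.
#' @export
count_interleaved <- function(junc) {
  junc <- as.data.table(junc)
  intra <- junc[chrom1 == chrom2]
  n <- nrow(intra)
  if (n < 2) {
    out <- 0L; attr(out, "n_pairs") <- 0L; return(out)
  }
  lo <- pmin(intra$pos1, intra$pos2)
  hi <- pmax(intra$pos1, intra$pos2)
  hit <- logical(n); pairs <- 0L
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    if (intra$chrom1[i] != intra$chrom1[k]) next
    ## crossing: exactly one endpoint of k strictly inside (lo_i, hi_i)
    in1 <- lo[k] > lo[i] && lo[k] < hi[i]
    in2 <- hi[k] > lo[i] && hi[k] < hi[i]
    if (xor(in1, in2)) {
      hit[i] <- hit[k] <- TRUE
      pairs <- pairs + 1L
    }
  }
  out <- sum(hit)
  attr(out, "n_pairs") <- pairs
  out
}

#' Fragment-join goodness-of-fit p-value
#'
#' Tests whether the four intrachromosomal orientation classes (D, TD, HH,
#' TT) are equally represented, as expected when shattered fragments are
#' rejoined at random. A high p-value indicates random joining, consistent
#' with chromothripsis. For `n <= exact_max` an exact multinomial test is
#' used (the sum of probabilities of all outcomes no more probable than
#' the observed one); beyond that, a chi-square test with 3 df.
#' Translocations are excluded upstream.
#'
#' @param counts Integer vector `c(D, TD, HH, TT)` (any order; the test is
#'   exchangeable in its four arguments).
#' @param exact_max Largest total count for which the exact test is used.
#' @return p-value in `[0, 1]`, or `NA` for all-zero counts.
#' @export
fragment_join_pvalue <- function(counts, exact_max = 40) {
  counts <- as.integer(counts)
  if (length(counts) != 4) stop("counts must have length 4", call. = FALSE)
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  if (n <= exact_max) {
    outcomes <- multinomial_outcomes(n)
    lp <- lgamma(n + 1) - rowSums(lgamma(outcomes + 1)) + n * log(0.25)
    lp_obs <- lgamma(n + 1) - sum(lgamma(counts + 1)) + n * log(0.25)
    sum(exp(lp[lp <= lp_obs + 1e-9]))
  } else {
    expect <- n / 4
    stat <- sum((counts - expect)^2 / expect)
    pchisq(stat, df = 3, lower.tail = FALSE)
  }
}

## All compositions of n into 4 non-negative parts.
multinomial_outcomes <- function(n) {
  g <- as.data.table(expand.grid(a = 0:n, b = 0:n, c = 0:n))
  g <- g[a + b + c <= n]
  as.matrix(g[, .(a, b, c, d = n - a - b - c)])
}

#' Longest copy-number oscillation run
#'
#' Given the ordered (integer-discretised) copy-number states of
#' consecutive segments inside a cluster footprint, returns the length (in
#' segments) of the longest contiguous run in which every adjacent pair of
#' states differs and at most `k` distinct states appear. Chromothriptic
#' regions oscillate, e.g. `2,3,2,3,...` between two states.
#'
#' @param states Integer (or roundable numeric) vector of segment CN states.
#' @param k Maximum number of distinct states in a run (2 or 3).
#' @return Integer run length; 0 for empty input.
#' @export
max_oscillation_run <- function(states, k = 2) {
  states <- round(as.numeric(states))
  n <- length(states)
  if (n == 0) return(0L)
  best <- 1L
  i <- 1L
  while (i <= n) {
    seen <- states[i]
    len <- 1L
    j <- i
    while (j < n && states[j + 1] != states[j]) {
      cand <- unique(c(seen, states[j + 1]))
      if (length(cand) > k) break
      seen <- cand
      len <- len + 1L
      j <- j + 1L
    }
    best <- max(best, len)
    i <- i + 1L
  }
  best
}

#' Extract ordered CN states within a cluster footprint
#'
#' Restricts a sample's CN segments to the cluster footprint, drops
#' segments shorter than `min_seg_len` (short fragments are unreliable on
#' arrays), rounds the copy number to the nearest integer and returns the
#' ordered state sequence.
#'
#' @param segs A `cn_segments` table (one sample).
#' @param footprint `data.table(chrom, start, end)` as in an `sv_cluster`.
#' @param min_seg_len Minimum segment length retained (default 10 kb).
#' @return Integer vector of states (possibly empty).
#' @export
cn_states_in_footprint <- function(segs, footprint, min_seg_len = 1e4) {
  segs <- as.data.table(segs)
  out <- integer(0)
  for (i in seq_len(nrow(footprint))) {
    fp <- footprint[i]
    sub <- segs[chrom == fp$chrom & end > fp$start & start < fp$end]
    sub <- sub[(pmin(end, fp$end) - pmax(start, fp$start)) >= min_seg_len]
    setorder(sub, start)
    out <- c(out, as.integer(round(sub$total_cn)))
  }
  out
}

#' Summarise clusters as a report table
#'
#' @param clusters List of `sv_cluster` objects.
#' @return One row per cluster with member count, orientation counts,
#'   interleaving and fragment-join statistics.
#' @export
cluster_report <- function(clusters) {
  rbindlist(lapply(clusters, function(cl) {
    data.table(cluster_id = cl$cluster_id,
               n_junctions = cl$n_junctions,
               n_D = cl$orientation_counts[["D"]],
               n_TD = cl$orientation_counts[["TD"]],
               n_HH = cl$orientation_counts[["HH"]],
               n_TT = cl$orientation_counts[["TT"]],
               n_TRA = cl$orientation_counts[["TRA"]],
               n_interleaved = as.integer(cl$n_interleaved),
               fragment_join_p = cl$fragment_join_p,
               footprint = paste(sprintf("%s:%s-%s", cl$footprint$chrom,
                                         format_pos(cl$footprint$start),
                                         format_pos(cl$footprint$end)),
                                 collapse = ","))
  }))
}
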