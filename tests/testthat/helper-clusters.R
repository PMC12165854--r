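## Construct a synthetic sv_cluster with prescribed statistics. The
## junction table only needs to support repair_signature/detect_foldback.
fake_cluster <- function(n_junctions, fragment_join_p, n_interleaved,
                         cluster_id = "C001") {
  jx <- junctions(rep("chr21", n_junctions),
                  seq(1e6, by = 1e4, length.out = n_junctions), "+",
                  rep("chr21", n_junctions),
                  seq(2e6, by = 1e4, length.out = n_junctions), "-",
                  insertion_len = rep(2, n_junctions))
  structure(list(cluster_id = cluster_id, junctions = jx,
                 junction_ids = jx$id, n_junctions = n_junctions,
                 footprint = data.table(chrom = "chr21", start = 1e6,
                                        end = 3e6),
                 orientation_counts = c(D = n_junctions, TD = 0L, HH = 0L,
                                        TT = 0L, TRA = 0L),
                 n_interleaved = n_interleaved,
                 fragment_join_p = fragment_join_p),
            class = "sv_cluster")
}

## Segments giving an oscillation run of the requested length inside the
## 1-3 Mb footprint.
osc_segments <- function(run_len) {
  states <- if (run_len <= 1) rep(2, 3) else rep(c(2, 3), length.out = run_len)
  n <- length(states)
  edges <- seq(1e6, 3e6, length.out = n + 1)
  cn_segments(rep("chr21", n), head(edges, -1), tail(edges, -1), states)
}

## Independent interval-intersection oracle: intersect per-sample interval
## unions by pairwise sweep (single chromosome).
oracle_intersection <- function(interval_sets) {
  isect <- function(a, b) {
    out <- list()
    for (i in seq_len(nrow(a))) for (k in seq_len(nrow(b))) {
      lo <- max(a$start[i], b$start[k]); hi <- min(a$end[i], b$end[k])
      if (lo < hi) out[[length(out) + 1L]] <- data.table(start = lo, end = hi)
    }
    if (length(out) == 0) data.table(start = numeric(0), end = numeric(0))
    else rbindlist(out)[order(start)]
  }
  Reduce(isect, interval_sets)
}
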