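## Cohort-level copy-number analysis: lesion typing, regional
## amplification calling, minimally amplified region (MAR) derivation, a
## simplified GISTIC-like recurrence scan, and lesion co-occurrence and
## burden statistics.

#' Classify a copy-number segment
#'
#' `gain` at or above `baseline + margin`, `loss` at or below
#' `baseline - margin`, `cnn_loh` within the margin with a positive LOH
#' flag (copy-neutral loss of heterozygosity), otherwise `neutral`. An
#' unknown LOH flag (`NA`) can never produce `cnn_loh`. The margin is
#' symmetric about the baseline, so every segment falls in exactly one
#' class.
#'
#' @param total_cn Numeric copy number(s).
#' @param loh Logical LOH flag(s), `NA` when not assayed.
#' @param baseline_ploidy Baseline (default 2).
#' @param margin Half-width of the neutral band (default 0.5).
#' @return Character vector: `gain`, `loss`, `cnn_loh` or `neutral`.
#' @export
classify_cna <- function(total_cn, loh = NA, baseline_ploidy = 2,
                         margin = 0.5) {
  loh <- rep_len(as.logical(loh), length(total_cn))
  out <- rep("neutral", length(total_cn))
  out[total_cn >= baseline_ploidy + margin] <- "gain"
  out[total_cn <= baseline_ploidy - margin] <- "loss"
  mid <- abs(total_cn - baseline_ploidy) < margin
  out[mid & !is.na(loh) & loh] <- "cnn_loh"
  out
}

#' Call a regional chromosome-21 amplification
#'
#' A sample is a carrier when at least one gain segment (CN at or above
#' `cn_threshold`) overlaps the target region. The amplified intervals are
#' the union of all such segments genome-wide on the target chromosome
#' (oscillating profiles exclude the intervening normal-CN gaps).
#'
#' @param segs A `cn_segments` table for one sample.
#' @param target_region `list(chrom=, start=, end=)` or
#'   `data.table(chrom, start, end)`; defaults to the simulator's planted
#'   21q22 core.
#' @param cn_threshold Gain threshold (default 2.5).
#' @return List with `flag` (logical) and `amplified_intervals`
#'   (`data.table(chrom, start, end)`).
#' @export
call_chr21amp <- function(segs, target_region = mar_core_region(),
                          cn_threshold = 2.5) {
  segs <- as.data.table(segs)
  tr <- as.data.table(target_region)
  on_chrom <- segs[chrom == tr$chrom[1]]
  if (nrow(on_chrom) == 0) {
    warning("no segments on ", tr$chrom[1], "; carrier flag set FALSE",
            call. = FALSE)
    return(list(flag = FALSE,
                amplified_intervals = data.table(chrom = character(0),
                                                 start = numeric(0),
                                                 end = numeric(0))))
  }
  amp <- on_chrom[total_cn >= cn_threshold]
  if (nrow(amp) == 0)
    return(list(flag = FALSE,
                amplified_intervals = data.table(chrom = character(0),
                                                 start = numeric(0),
                                                 end = numeric(0))))
  iv <- IRanges::reduce(IRanges(amp$start + 1, amp$end))
  ivs <- data.table(chrom = tr$chrom[1],
                    start = IRanges::start(iv) - 1,
                    end = IRanges::end(iv))
  hit <- any(ivs$start < tr$end[1] & ivs$end > tr$start[1])
  list(flag = hit, amplified_intervals = ivs)
}

#' The planted amplification core of the synthetic genome
#'
#' A 2.7-Mb interval within the 21q22 analogue of the synthetic genome,
#' used as the ground-truth core that every simulated carrier amplifies.
#'
#' @return `data.table(chrom, start, end)`.
#' @export
mar_core_region <- function() {
  data.table(chrom = "chr21", start = 37300000, end = 40000000)
}

#' Derive the minimally amplified region (MAR)
#'
#' The MAR is the strict intersection, over all supporting samples, of
#' each sample's amplified interval union; it may consist of several
#' intervals. With `min_support = k < n`, the region amplified in at least
#' `k` samples is reported instead (the union of intersections over all
#' size-`k` subsets), the escape hatch when the strict intersection is
#' empty. Genes are assigned by full containment within the MAR by
#' default, matching "genes contained in the region" semantics; use
#' `gene_mode = "any"` for overlap.
#'
#' @param amplified_by_sample Named list: per sample a
#'   `data.table(chrom, start, end)` of amplified intervals.
#' @param genes Optional `data.table(chrom, start, end, gene)`.
#' @param min_support Minimum number of supporting samples (default all).
#' @param gene_mode `"within"` or `"any"`.
#' @param segments Optional cohort `cn_segments` used to report per-sample
#'   mean CN over the MAR.
#' @return A `mar_result`: intervals, supporting sample count, gene list,
#'   per-sample CN.
#' @export
compute_mar <- function(amplified_by_sample, genes = NULL,
                        min_support = NULL, gene_mode = c("within", "any"),
                        segments = NULL) {
  gene_mode <- match.arg(gene_mode)
  n <- length(amplified_by_sample)
  if (n == 0) stop("need at least one supporting sample", call. = FALSE)
  min_support <- min_support %||% n
  gr <- lapply(amplified_by_sample, function(iv) {
    iv <- as.data.table(iv)
    GenomicRanges::reduce(GRanges(iv$chrom, IRanges(iv$start + 1, iv$end)))
  })
  cov <- GenomicRanges::coverage(do.call(c, unname(gr)))
  hit <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
  mar <- GRanges(hit)
  if (length(mar) == 0) {
    stop(sprintf(paste0(
      "empty intersection across %d samples; rerun with a smaller ",
      "min_support (e.g. compute_mar(..., min_support = k)) to report ",
      "regions shared by at least k samples"), n), call. = FALSE)
  }
  intervals <- data.table(chrom = as.character(GenomicRanges::seqnames(mar)),
                          start = GenomicRanges::start(mar) - 1,
                          end = GenomicRanges::end(mar))
  gene_list <- character(0)
  if (!is.null(genes)) {
    genes <- as.data.table(genes)
    ggr <- GRanges(genes$chrom, IRanges(genes$start + 1, genes$end))
    ov <- GenomicRanges::findOverlaps(
      ggr, mar, type = if (gene_mode == "within") "within" else "any")
    gene_list <- sort(unique(genes$gene[S4Vectors::queryHits(ov)]))
  }
  cn_by_sample <- NULL
  if (!is.null(segments)) {
    segments <- as.data.table(segments)
    cn_by_sample <- segments[, {
      tot <- 0; w <- 0
      for (i in seq_len(nrow(intervals))) {
        sub <- .SD[chrom == intervals$chrom[i] &
                     end > intervals$start[i] & start < intervals$end[i]]
        if (nrow(sub)) {
          ww <- pmin(sub$end, intervals$end[i]) -
            pmax(sub$start, intervals$start[i])
          tot <- tot + sum(ww * sub$total_cn); w <- w + sum(ww)
        }
      }
      .(mean_cn = if (w > 0) tot / w else NA_real_)
    }, by = sample_id]
  }
  structure(list(intervals = intervals,
                 n_supporting_samples = min_support,
                 n_samples = n,
                 genes = gene_list,
                 cn_by_sample = cn_by_sample),
            class = "mar_result")
}

#' @export
print.mar_result <- function(x, ...) {
  cat(sprintf("<mar_result> %d interval(s), %.3g Mb total, %d/%d samples, %d gene(s)\n",
              nrow(x$intervals),
              sum(x$intervals$end - x$intervals$start) / 1e6,
              x$n_supporting_samples, x$n_samples, length(x$genes)))
  invisible(x)
}

#' GISTIC-like recurrence scan (simplified)
#'
#' A deliberately simplified stand-in for semi-parametric recurrence
#' callers: the genome is binned, each sample contributes
#' `max(0, log2(CN/2))` (amplification G-score) weighted by its overlap
#' fraction of the bin, and significance is assessed against an empirical
#' null built by circularly shifting each sample's per-chromosome score
#' track by an independent uniform offset (in bins) per permutation --
#' preserving each sample's within-chromosome segment structure.
#' Benjamini-Hochberg q-values are computed across bins. A deletion score
#' (`max(0, -log2(CN/2))`) is reported alongside.
#'
#' @param segs Cohort `cn_segments`.
#' @param genome_lengths Named chromosome lengths.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @param n_perm Number of permutations (default 1000; fewer than 100
#'   triggers a warning about unstable q-values).
#' @param seed Integer seed.
#' @return `data.table(chrom, bin_start, bin_end, amp_score, del_score,
#'   amp_p, amp_q)`.
#' @export
recurrence_scan <- function(segs, genome_lengths = default_genome(),
                            bin_size = 1e6, n_perm = 1000, seed = 1) {
  if (n_perm < 100)
    warning("n_perm < 100: empirical q-values will be unstable",
            call. = FALSE)
  set.seed(check_seed(seed))
  segs <- as.data.table(segs)
  samples <- sort(unique(segs$sample_id))
  chroms <- names(genome_lengths)
  nbin <- setNames(as.integer(ceiling(genome_lengths / bin_size)), chroms)

  ## per sample per chromosome: score vector over bins
  score_of <- function(cn) pmax(0, log2(pmax(cn, 1e-6) / 2))
  del_of <- function(cn) pmax(0, -log2(pmax(cn, 1e-6) / 2))
  tracks <- list()
  for (s in samples) for (ch in chroms) {
    v <- numeric(nbin[[ch]]); vd <- numeric(nbin[[ch]])
    sub <- segs[sample_id == s & chrom == ch]
    for (i in seq_len(nrow(sub))) {
      b0 <- floor(sub$start[i] / bin_size); b1 <- ceiling(sub$end[i] / bin_size) - 1
      for (b in b0:b1) {
        lo <- max(sub$start[i], b * bin_size)
        hi <- min(sub$end[i], (b + 1) * bin_size)
        frac <- (hi - lo) / bin_size
        v[b + 1] <- v[b + 1] + frac * score_of(sub$total_cn[i])
        vd[b + 1] <- vd[b + 1] + frac * del_of(sub$total_cn[i])
      }
    }
    tracks[[paste(s, ch)]] <- list(amp = v, del = vd)
  }
  obs <- rbindlist(lapply(chroms, function(ch) {
    amp <- Reduce(`+`, lapply(samples, function(s) tracks[[paste(s, ch)]]$amp))
    del <- Reduce(`+`, lapply(samples, function(s) tracks[[paste(s, ch)]]$del))
    data.table(chrom = ch,
               bin_start = (seq_len(nbin[[ch]]) - 1) * bin_size,
               bin_end = pmin(seq_len(nbin[[ch]]) * bin_size,
                              genome_lengths[[ch]]),
               amp_score = amp, del_score = del)
  }))
  ## permutation null: circular shift per sample per chromosome (bin
  ## units); all-zero tracks are shift-invariant and skipped
  nonzero <- lapply(chroms, function(ch) {
    vs <- lapply(samples, function(s) tracks[[paste(s, ch)]]$amp)
    vs[vapply(vs, function(v) any(v > 0), TRUE)]
  })
  names(nonzero) <- chroms
  exceed <- numeric(nrow(obs))
  row_off <- c(0, cumsum(vapply(chroms, function(ch) nbin[[ch]], 1L)))
  names(row_off) <- c(chroms, "end")
  for (p in seq_len(n_perm)) {
    perm <- numeric(nrow(obs))
    for (ch in chroms) {
      vs <- nonzero[[ch]]
      if (length(vs) == 0) next
      B <- nbin[[ch]]
      tot <- numeric(B)
      for (v in vs) {
        off <- sample.int(B, 1) - 1L
        if (off > 0) v <- v[c((B - off + 1):B, 1:(B - off))]
        tot <- tot + v
      }
      perm[(row_off[[ch]] + 1):(row_off[[ch]] + B)] <- tot
    }
    exceed <- exceed + (perm >= obs$amp_score - 1e-12)
  }
  obs[, amp_p := (1 + exceed) / (n_perm + 1)]
  obs[amp_score == 0, amp_p := 1]
  obs[, amp_q := p.adjust(amp_p, method = "BH")]
  obs[]
}

#' Exact Fisher test on a 2x2 table
#'
#' Two-sided Fisher exact test (sum of hypergeometric probabilities of
#' tables no more probable than the observed one, at fixed margins),
#' vectorised over the support. Returns the conditional odds ratio as the
#' sample odds ratio `ad/bc` for reporting (undefined with a zero margin).
#'
#' @param tab 2x2 integer matrix, or `c(a, b, c, d)` row-wise.
#' @return List `p`, `odds_ratio`.
#' @export
fisher_exact <- function(tab) {
  x <- as.integer(tab)
  if (length(x) != 4 || any(x < 0)) stop("need a 2x2 table", call. = FALSE)
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m <- a + cc; nn <- b + d; k <- a + b
  if (m == 0 || nn == 0 || k == 0 || cc + d == 0)
    return(list(p = 1, odds_ratio = NA_real_))
  lo <- max(0L, k - nn); hi <- min(k, m)
  supp <- lo:hi
  probs <- stats::dhyper(supp, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b == 0 || cc == 0) {
    if (a == 0 || d == 0) NA_real_ else Inf
  } else (a * d) / (b * cc)
  list(p = p, odds_ratio = or)
}

#' Pairwise lesion association
#'
#' For every pair of lesions in a samples x lesions 0/1/NA matrix:
#' two-sided Fisher exact p (rows with `NA` in either lesion dropped
#' pairwise), sample odds ratio and the Pearson phi correlation, with
#' Benjamini-Hochberg adjustment across pairs.
#'
#' @param lesion_matrix Matrix or data.frame of 0/1/NA, columns = lesions.
#' @return `data.table(lesion1, lesion2, n, p, p_adj, odds_ratio, phi)`.
#' @export
lesion_association <- function(lesion_matrix) {
  m <- as.matrix(lesion_matrix)
  if (ncol(m) < 2) stop("need at least 2 lesions", call. = FALSE)
  lesions <- colnames(m) %||% paste0("lesion", seq_len(ncol(m)))
  combos <- utils::combn(seq_len(ncol(m)), 2)
  out <- rbindlist(apply(combos, 2, function(ix) {
    x <- m[, ix[1]]; y <- m[, ix[2]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    tab <- c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
             sum(x == 0 & y == 1), sum(x == 0 & y == 0))
    ft <- fisher_exact(tab)
    phi <- if (length(unique(x)) < 2 || length(unique(y)) < 2) NA_real_
           else suppressWarnings(cor(x, y))
    data.table(lesion1 = lesions[ix[1]], lesion2 = lesions[ix[2]],
               n = length(x), p = ft$p, odds_ratio = ft$odds_ratio,
               phi = phi)
  }, simplify = FALSE))
  out[, p_adj := p.adjust(p, method = "BH")]
  setcolorder(out, c("lesion1", "lesion2", "n", "p", "p_adj",
                     "odds_ratio", "phi"))
  out[]
}

#' Count non-chr21 CNA burden per sample
#'
#' Counts one CNA per non-neutral classified segment after merging
#' adjacent same-class segments (gap <= 1 bp), excluding the target
#' chromosome (whose amplification defines the carrier groups).
#'
#' @param segs Cohort `cn_segments`.
#' @param baseline_ploidy,margin Passed to [classify_cna()].
#' @param exclude_chrom Chromosome excluded from the count.
#' @return `data.table(sample_id, n_cna)` covering every sample in `segs`.
#' @export
count_cna_burden <- function(segs, baseline_ploidy = 2, margin = 0.5,
                             exclude_chrom = "chr21") {
  segs <- as.data.table(segs)
  segs[, cn_class := classify_cna(total_cn, loh, baseline_ploidy, margin)]
  sub <- segs[chrom != exclude_chrom & cn_class != "neutral"]
  counts <- if (nrow(sub) == 0) {
    data.table(sample_id = character(0), n_cna = integer(0))
  } else {
    setorder(sub, sample_id, chrom, start)
    sub[, run_id := cumsum(
      c(1L, (chrom[-1] != chrom[-.N]) | (cn_class[-1] != cn_class[-.N]) |
          (start[-1] > end[-.N] + 1))), by = sample_id]
    sub[, .(n_cna = uniqueN(run_id)), by = sample_id]
  }
  all_samples <- data.table(sample_id = sort(unique(segs$sample_id)))
  out <- counts[all_samples, on = "sample_id"]
  out[is.na(n_cna), n_cna := 0L]
  out[]
}

#' Compare CNA burden between carriers and non-carriers
#'
#' Reports the group medians and a two-sided Wilcoxon rank-sum p-value
#' (exact when both groups have at most 25 observations and no ties;
#' normal approximation with tie correction otherwise).
#'
#' @param burden_carriers,burden_noncarriers Integer CNA counts.
#' @return List `median_carriers`, `median_noncarriers`, `p`.
#' @export
cna_burden_test <- function(burden_carriers, burden_noncarriers) {
  if (length(burden_carriers) == 0 || length(burden_noncarriers) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  exact <- length(burden_carriers) <= 25 && length(burden_noncarriers) <= 25 &&
    !anyDuplicated(c(burden_carriers, burden_noncarriers))
  wt <- suppressWarnings(
    wilcox.test(burden_carriers, burden_noncarriers, exact = exact,
                correct = TRUE))
  list(median_carriers = median(burden_carriers),
       median_noncarriers = median(burden_noncarriers),
       p = wt$p.value)
}
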