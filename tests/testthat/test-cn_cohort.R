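test_that("CNA classification partitions segments with symmetric margins", {
  expect_equal(classify_cna(3.5), "gain")
  expect_equal(classify_cna(2.5), "gain")
  expect_equal(classify_cna(1.5), "loss")
  expect_equal(classify_cna(2.0, loh = TRUE), "cnn_loh")
  expect_equal(classify_cna(2.2, loh = NA), "neutral")
  expect_equal(classify_cna(2.2, loh = TRUE), "cnn_loh")
  expect_equal(classify_cna(2.49), "neutral")
  ## vectorised, one class each
  cls <- classify_cna(seq(0, 4, by = 0.1))
  expect_true(all(cls %in% c("gain", "loss", "neutral")))
  expect_equal(sum(cls == "gain") + sum(cls == "loss") +
                 sum(cls == "neutral"), 41L)
})

test_that("chr21amp calling unions gain segments over the target", {
  tr <- mar_core_region()
  ## oscillating profile: amplified intervals exclude the CN-2 gaps
  edges <- seq(tr$start - 1e6, tr$end + 1e6, length.out = 6)
  segs <- cn_segments(rep("chr21", 5), head(edges, -1), tail(edges, -1),
                      c(3, 2, 4, 2, 3))
  res <- call_chr21amp(segs, tr)
  expect_true(res$flag)
  expect_equal(nrow(res$amplified_intervals), 3L)
  widths <- res$amplified_intervals$end - res$amplified_intervals$start
  expect_equal(sum(widths), 3 * (edges[2] - edges[1]))
  ## all CN 2 -> not a carrier
  flat <- cn_segments("chr21", 0, 46709983, 2)
  expect_false(call_chr21amp(flat, tr)$flag)
  ## no chr21 segments -> warning, flag FALSE
  off <- cn_segments("chr1", 0, 1e6, 3)
  expect_warning(res2 <- call_chr21amp(off, tr), "no segments")
  expect_false(res2$flag)
  ## gain threshold respected
  sub <- cn_segments("chr21", tr$start, tr$end, 2.4)
  expect_false(call_chr21amp(sub, tr)$flag)
})

test_that("MAR is the strict interval intersection across samples", {
  amp <- list(S1 = data.table(chrom = "chr21", start = 10, end = 20),
              S2 = data.table(chrom = "chr21", start = 15, end = 30),
              S3 = data.table(chrom = "chr21", start = 12, end = 25))
  mar <- compute_mar(amp)
  expect_equal(mar$intervals$start, 15)
  expect_equal(mar$intervals$end, 20)
  ## single sample: its own union
  one <- compute_mar(amp["S2"])
  expect_equal(one$intervals$start, 15)
  expect_equal(one$intervals$end, 30)
  ## empty intersection errors with the min_support hint, which works
  amp$S4 <- data.table(chrom = "chr21", start = 100, end = 200)
  expect_error(compute_mar(amp), "min_support")
  relaxed <- compute_mar(amp, min_support = 3)
  expect_equal(relaxed$intervals$start, 15)
  expect_equal(relaxed$intervals$end, 20)
})

test_that("MAR gene membership distinguishes containment from overlap", {
  amp <- list(S1 = data.table(chrom = "chr21", start = 1000, end = 9000),
              S2 = data.table(chrom = "chr21", start = 2000, end = 8000))
  genes <- data.table(chrom = "chr21",
                      start = c(2500, 1500, 7500),
                      end = c(3500, 2500, 8500),
                      gene = c("inside", "straddle_left", "straddle_right"))
  mar_within <- compute_mar(amp, genes = genes)
  expect_equal(mar_within$genes, "inside")
  mar_any <- compute_mar(amp, genes = genes, gene_mode = "any")
  expect_setequal(mar_any$genes,
                  c("inside", "straddle_left", "straddle_right"))
})

test_that("simulated cohorts recover the planted core (MAR round trip)", {
  for (s in c(2, 9)) {
    params <- sim_params(cohort_size = 16, seed = s)
    bundle <- simulate_cohort(params)
    segs <- as.data.table(bundle$segments)
    amp <- lapply(split(segs, by = "sample_id"), call_chr21amp)
    carriers <- names(Filter(function(x) x$flag, amp))
    expect_setequal(carriers,
                    bundle$truth$sample_id[bundle$truth$carrier])
    mar <- compute_mar(lapply(amp[carriers],
                              function(x) x$amplified_intervals))
    core <- mar_core_region()
    ## MAR contains the planted core
    expect_true(any(mar$intervals$start <= core$start &
                      mar$intervals$end >= core$end))
    ## MAR contained in every supporting sample's amplified union
    for (cs in carriers) {
      iv <- amp[[cs]]$amplified_intervals
      for (k in seq_len(nrow(mar$intervals))) {
        covered <- any(iv$start <= mar$intervals$start[k] &
                         iv$end >= mar$intervals$end[k])
        expect_true(covered, label = paste(cs, "interval", k))
      }
    }
  }
})

test_that("recurrence scan scores and calibrates as documented", {
  ## no deviation from CN 2 -> all scores 0, all q = 1
  flat <- cn_segments(rep("chr21", 2), c(0, 2e7), c(2e7, 46709983),
                      c(2, 2), sample_id = "S1")
  rs <- suppressWarnings(
    recurrence_scan(flat, c(chr21 = 46709983), n_perm = 50, seed = 1))
  expect_true(all(rs$amp_score == 0))
  expect_true(all(rs$amp_q == 1))
  ## single sample, single gain: covered bins score log2(CN/2) exactly
  gain <- cn_segments(rep("chr21", 3), c(0, 1e6, 3e6),
                      c(1e6, 3e6, 46709983), c(2, 3, 2),
                      sample_id = "S1")
  rs2 <- suppressWarnings(
    recurrence_scan(gain, c(chr21 = 46709983), n_perm = 50, seed = 1))
  covered <- rs2[bin_start >= 1e6 & bin_end <= 3e6]
  expect_equal(covered$amp_score, rep(log2(3 / 2), nrow(covered)))
  expect_warning(recurrence_scan(gain, c(chr21 = 46709983), n_perm = 50,
                                 seed = 1), "unstable")
})

test_that("planted amplification is the top recurrence bin", {
  bundle <- simulate_cohort(sim_params(cohort_size = 24, seed = 4))
  rs <- recurrence_scan(bundle$segments, bin_size = 1e6, n_perm = 200,
                        seed = 5)
  setorder(rs, amp_p, -amp_score)
  core <- mar_core_region()
  top <- rs[1]
  expect_equal(top$chrom, "chr21")
  expect_true(top$bin_start < core$end && top$bin_end > core$start)
})

test_that("fisher_exact matches enumeration, fisher.test and the paper case", {
  ## chromothripsis x mTP53: [[10,19],[1,34]] -> printed P = 0.002
  ft <- fisher_exact(c(10, 19, 1, 34))
  expect_equal(round(ft$p, 3), 0.002)
  expect_equal(ft$p, oracle_fisher_p(10, 19, 1, 34), tolerance = 1e-12)
  expect_equal(ft$p, fisher.test(matrix(c(10, 1, 19, 34), 2))$p.value,
               tolerance = 1e-9)
  ## zero-margin tables: p = 1, odds undefined
  expect_equal(fisher_exact(c(0, 0, 3, 4)), list(p = 1, odds_ratio = NA_real_))
  expect_equal(fisher_exact(c(2, 0, 5, 0))$p, 1)
  ## sweep against stats::fisher.test on random tables
  set.seed(33)
  for (i in 1:50) {
    tab <- as.integer(sample(0:12, 4, replace = TRUE))
    expect_equal(fisher_exact(tab)$p,
                 fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
  }
})

test_that("lesion association reports phi, odds ratios and BH p-values", {
  m <- cbind(A = c(1, 1, 1, 0, 0, 0, NA, 1),
             B = c(1, 1, 1, 0, 0, 0, 1, NA),
             C = c(0, 1, 0, 1, 0, 1, 0, 1))
  res <- lesion_association(m)
  expect_equal(nrow(res), 3L)
  ab <- res[lesion1 == "A" & lesion2 == "B"]
  expect_equal(ab$n, 6L)            # NA rows dropped pairwise
  expect_equal(ab$phi, 1)           # perfectly concordant
  expect_true(all(res$p_adj >= res$p))
  expect_error(lesion_association(m[, 1, drop = FALSE]), "2 lesions")
})

test_that("burden counting merges adjacent same-class segments", {
  segs <- cn_segments(
    chrom = c("chr1", "chr1", "chr1", "chr5", "chr21", "chr1"),
    start = c(0, 1e6, 5e6, 0, 0, 0),
    end = c(1e6, 2e6, 6e6, 1e6, 1e7, 1e6),
    total_cn = c(3, 3, 1, 3, 5, 2),
    sample_id = c("S1", "S1", "S1", "S1", "S1", "S2"))
  burden <- count_cna_burden(segs)
  ## S1: adjacent chr1 gains merge (gap 0), plus chr1 loss and chr5 gain;
  ## chr21 excluded; S2 neutral
  expect_equal(burden[sample_id == "S1", n_cna], 3L)
  expect_equal(burden[sample_id == "S2", n_cna], 0L)
})

test_that("burden rank-sum test matches exact enumeration", {
  ## all carriers above all non-carriers, 5 vs 5: exact p = 2/choose(10,5)
  res <- cna_burden_test(6:10, 1:5)
  expect_equal(res$p, 2 / choose(10, 5))
  expect_equal(res$median_carriers, 8)
  ## identical groups: p = 1 (up to method granularity)
  res2 <- cna_burden_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(res2$p, 0.99)
  expect_error(cna_burden_test(numeric(0), 1:3), "non-empty")
})

test_that("simulated carriers bear a heavier background CNA burden", {
  bundle <- simulate_cohort(sim_params(seed = 6))
  burden <- count_cna_burden(bundle$segments)
  burden[, carrier := sample_id %in%
           bundle$truth$sample_id[bundle$truth$carrier]]
  bt <- cna_burden_test(burden[carrier == TRUE, n_cna],
                        burden[carrier == FALSE, n_cna])
  expect_gt(bt$median_carriers, bt$median_noncarriers)
  expect_lt(bt$p, 0.01)
})

test_that("prevalence zero leaves chr21 untouched and carrier count exact", {
  b0 <- simulate_cohort(sim_params(cohort_size = 8, chr21amp_prevalence = 0,
                                   seed = 11))
  segs <- as.data.table(b0$segments)
  expect_true(all(segs[chrom == "chr21", total_cn] == 2))
  b25 <- simulate_cohort(sim_params(cohort_size = 64,
                                    chr21amp_prevalence = 0.25, seed = 12))
  expect_equal(b25$truth$n_carriers, 16L)
  expect_equal(sum(b25$truth$carrier), 16L)
})
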