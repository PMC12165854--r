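test_that("complexity threshold is exactly 3 junctions", {
  expect_equal(classify_complexity(2), "simple")
  expect_equal(classify_complexity(3), "complex")
  expect_equal(classify_complexity(fake_cluster(2, 1, 0)), "simple")
  expect_equal(classify_complexity(fake_cluster(3, 1, 0)), "complex")
})

test_that("chromothripsis verdict follows 3-of-4 over the full flag grid", {
  ## values on either side of each threshold
  vals <- list(
    size = list(pass = 5L, fail = 4L),
    join = list(pass = 0.05, fail = 0.049),
    inter = list(pass = 4L, fail = 3L),
    osc = list(pass = 4L, fail = 3L))
  for (bits in 0:15) {
    f <- as.logical(bitwAnd(bits, c(8L, 4L, 2L, 1L)) > 0)  # size,join,inter,osc
    n_j <- if (f[1]) vals$size$pass else vals$size$fail
    cl <- fake_cluster(n_j,
                       if (f[2]) vals$join$pass else vals$join$fail,
                       if (f[3]) vals$inter$pass else vals$inter$fail)
    segs <- osc_segments(if (f[4]) vals$osc$pass else vals$osc$fail)
    call <- classify_chromothripsis(cl, segs)
    expect_equal(unname(call$flags), f, label = paste("bits", bits))
    expect_equal(call$n_criteria_met, sum(f))
    want <- if (sum(f) >= 3) "chromothripsis_like" else "complex"
    expect_equal(call$verdict, want, label = paste("bits", bits))
  }
})

test_that("run3 >= 5 satisfies the oscillation criterion on its own", {
  cl <- fake_cluster(5, 0.6, 4)
  states <- c(2, 3, 4, 3, 2)  # 3-state run of 5, 2-state run of 3
  edges <- seq(1e6, 3e6, length.out = 6)
  segs <- cn_segments(rep("chr21", 5), head(edges, -1), tail(edges, -1),
                      states)
  call <- classify_chromothripsis(cl, segs)
  expect_equal(call$oscillation_run2, 3L)
  expect_equal(call$oscillation_run3, 5L)
  expect_true(call$flags[["oscillation_ok"]])
})

test_that("missing CN data drops the oscillation criterion conservatively", {
  ## 3 known criteria met, oscillation unknown -> chromothripsis-like
  cl <- fake_cluster(5, 0.6, 4)
  call <- classify_chromothripsis(cl, segs = NULL)
  expect_true(is.na(call$flags[["oscillation_ok"]]))
  expect_equal(call$n_criteria_known, 3L)
  expect_equal(call$verdict, "chromothripsis_like")
  ## only 2 of the 3 known met -> complex, not chromothripsis-like
  call2 <- classify_chromothripsis(fake_cluster(5, 0.01, 4), segs = NULL)
  expect_equal(call2$n_criteria_met, 2L)
  expect_equal(call2$verdict, "complex")
})

test_that("adding a satisfied criterion never demotes the verdict", {
  ## monotonicity: flip each failing statistic to passing, one at a time
  base <- list(n = 5L, p = 0.01, inter = 4L, run = 4L)
  call0 <- classify_chromothripsis(
    fake_cluster(base$n, base$p, base$inter), osc_segments(base$run))
  expect_equal(call0$verdict, "chromothripsis_like")
  call1 <- classify_chromothripsis(
    fake_cluster(base$n, 0.6, base$inter), osc_segments(base$run))
  expect_equal(call1$verdict, "chromothripsis_like")
  expect_gte(call1$n_criteria_met, call0$n_criteria_met)
})

test_that("fold-back detection needs inverted orientation and a small gap", {
  hh_near <- junctions("chr21", 1e6, "+", "chr21", 1e6 + 1000, "+")
  hh_far <- junctions("chr21", 1e6, "+", "chr21", 2e6, "+")
  tt_near <- junctions("chr21", 1e6, "-", "chr21", 1e6 + 4999, "-")
  d_near <- junctions("chr21", 1e6, "+", "chr21", 1e6 + 1000, "-")
  tra <- junctions("chr21", 1e6, "+", "chr19", 1e6 + 10, "+")
  expect_true(detect_foldback(hh_near))
  expect_false(detect_foldback(hh_far))
  expect_true(detect_foldback(tt_near))
  expect_false(detect_foldback(d_near))
  expect_false(detect_foldback(tra))
  expect_true(detect_foldback(hh_far, max_gap = 2e6))
})

test_that("repair signature summarises the NHEJ insertion scar", {
  all_small <- junctions(rep("chr21", 4), 1:4 * 1e5, "+",
                         rep("chr21", 4), 1:4 * 1e5 + 5e4, "-",
                         insertion_len = c(0, 2, 4, 6))
  sig <- repair_signature(all_small)
  expect_equal(sig$fraction, 1.0)
  expect_true(sig$nhej_consistent)
  half_big <- junctions(rep("chr21", 4), 1:4 * 1e5, "+",
                        rep("chr21", 4), 1:4 * 1e5 + 5e4, "-",
                        insertion_len = c(0, 2, 20, 20))
  sig2 <- repair_signature(half_big)
  expect_equal(sig2$fraction, 0.5)
  expect_false(sig2$nhej_consistent)
  with_na <- junctions(rep("chr21", 3), 1:3 * 1e5, "+",
                       rep("chr21", 3), 1:3 * 1e5 + 5e4, "-",
                       insertion_len = c(0, NA, 3))
  sig3 <- repair_signature(with_na)
  expect_equal(sig3$n_missing, 1L)
  expect_equal(sig3$n_assessed, 2L)
})

test_that("simulated events classify by mechanism (scaled round trip)", {
  L <- 46709983
  reg <- default_event_region()
  verdicts <- vapply(1:25, function(s) {
    arr <- simulate_chromothripsis("chr21", reg, 20, 0.5, seed = s,
                                   chrom_length = L)
    calls <- classify_sample(derive_junctions(arr, seed = s + 1000),
                             derive_cn_profile(arr))
    any(calls$verdict == "chromothripsis_like")
  }, TRUE)
  expect_gte(mean(verdicts), 0.9)
  td_calls <- classify_sample(
    derive_junctions(simulate_simple_sv("chr21", c(37e6, 38e6),
                                        "tandem_duplication", seed = 1,
                                        chrom_length = L), seed = 2),
    NULL)
  expect_equal(td_calls$verdict, "simple")
  ## BFB: complex-with-foldback, mixed-orientation chromothripsis not implied
  bfb_fb <- vapply(1:25, function(s) {
    arr <- simulate_bfb("chr21", c(40e6, L), 2, seed = s)
    any(detect_foldback(derive_junctions(arr, seed = s + 2000)))
  }, TRUE)
  expect_true(all(bfb_fb))
})

test_that("default chromothripsis events mix all four orientation classes", {
  pooled <- character(0)
  per_event <- integer(0)
  for (s in 1:50) {
    arr <- simulate_chromothripsis("chr21", default_event_region(), 20, 0.5,
                                   seed = s, chrom_length = 46709983)
    cls <- classify_orientation(derive_junctions(arr, seed = s + 400))
    pooled <- c(pooled, cls)
    per_event <- c(per_event, length(unique(cls)))
  }
  expect_setequal(unique(pooled), c("D", "TD", "HH", "TT"))
  expect_gte(mean(per_event >= 3), 0.9)
})

test_that("default simulator output is fully NHEJ-consistent", {
  arr <- simulate_chromothripsis("chr21", default_event_region(), 20, 0.5,
                                 seed = 17, chrom_length = 46709983)
  sig <- repair_signature(derive_junctions(arr, seed = 18))
  expect_equal(sig$fraction, 1.0)
  expect_true(sig$nhej_consistent)
})
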