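test_that("identity arrangement implies zero junctions and flat CN", {
  arr <- derivative_arrangement("toy", 10000, c(2000, 9000),
                                source_start = 2000, source_end = 9000,
                                orientation = "+")
  expect_equal(nrow(derive_junctions(arr, seed = 1)), 0L)
  segs <- as.data.table(derive_cn_profile(arr))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$total_cn, 2)
  expect_equal(c(segs$start, segs$end), c(0, 10000))
})

test_that("single lost fragment yields one-allele loss and a D junction", {
  arr <- derivative_arrangement("toy", 10000, c(2000, 9000),
                                source_start = c(2000, 6000),
                                source_end = c(4000, 9000),
                                orientation = c("+", "+"))
  segs <- as.data.table(derive_cn_profile(arr))
  expect_equal(segs$total_cn, c(2, 1, 2))
  expect_equal(segs[total_cn == 1, c(start, end)], c(4000, 6000))
  jx <- derive_junctions(arr, seed = 1)
  expect_equal(nrow(jx), 1L)
  expect_equal(classify_orientation(jx), "D")
  expect_equal(c(jx$pos1, jx$pos2), c(4000, 6000))
})

test_that("mirrored fragment at its own boundary is a fold-back HH", {
  arr <- derivative_arrangement("toy", 10000, c(2000, 9000),
                                source_start = c(2000, 2000),
                                source_end = c(5000, 5000),
                                orientation = c("+", "-"))
  jx <- derive_junctions(arr, seed = 1)
  expect_equal(classify_orientation(jx)[1], "HH")
  expect_true(detect_foldback(jx)[1])
})

test_that("triple-retained fragment gives CN 4 and conserves copy mass", {
  arr <- derivative_arrangement("toy", 10000, c(2000, 9000),
                                source_start = rep(3000, 3),
                                source_end = rep(5000, 3),
                                orientation = c("+", "+", "+"))
  segs <- as.data.table(derive_cn_profile(arr))
  expect_equal(segs[start == 3000 & end == 5000, total_cn], 4)
  gained_minus_lost <- sum((segs$total_cn - 2) * (segs$end - segs$start))
  expect_equal(gained_minus_lost, oracle_copy_mass(arr))
  ## copy_index distinguishes repeated uses
  expect_equal(arr$fragments$copy_index, 0:2)
})

test_that("retained-fragment count is Binomial(n_breakpoints + 1, p)", {
  ## 1000 seeds at n_breakpoints = 9, retention 0.5: mean ~5, var ~2.5
  n_ret <- vapply(1:1000, function(s) {
    arr <- tryCatch(toy_chromothripsis(s), error = function(e) NULL)
    if (is.null(arr)) return(NA_integer_)  # degenerate draws rejected
    nrow(arr$fragments)
  }, 1L)
  n_ret <- n_ret[!is.na(n_ret)]
  expect_gt(length(n_ret), 990)            # P(all 10 lost) ~ 1e-3
  expect_equal(mean(n_ret), 5, tolerance = 0.05)
  expect_equal(var(n_ret), 2.5, tolerance = 0.15)
})

test_that("degenerate chromothripsis draws signal a classed condition", {
  ## retention 0 forces zero retained fragments
  expect_error(
    simulate_chromothripsis("toy", c(2000, 9000), 9, 0, seed = 1,
                            chrom_length = 10000),
    class = "chromoshard_degenerate_draw")
  expect_error(simulate_chromothripsis("toy", c(0, 10), 2, 1, seed = 1),
               NA)
  expect_error(simulate_chromothripsis("toy", c(0, 10), 20, 1, seed = 1),
               "exceed")
  expect_error(simulate_chromothripsis("toy", c(0, 1e4), 1, 1, seed = 1),
               ">= 2")
})

test_that("copy-mass conservation holds for every simulated arrangement", {
  for (s in 1:40) {
    arr <- tryCatch(toy_chromothripsis(s), error = function(e) NULL)
    if (is.null(arr)) next
    segs <- as.data.table(derive_cn_profile(arr))
    lhs <- sum((segs$total_cn - 2) * (segs$end - segs$start))
    expect_equal(lhs, oracle_copy_mass(arr), label = paste("seed", s))
    ## per-base oracle agreement
    expect_equal(rep(segs$total_cn, segs$end - segs$start),
                 oracle_cn_per_base(arr), label = paste("seed", s))
  }
  for (s in 1:20) {
    arr <- simulate_bfb("toy", c(4000, 10000), n_cycles = 3, seed = s,
                        chrom_length = 10000)
    segs <- as.data.table(derive_cn_profile(arr))
    lhs <- sum((segs$total_cn - 2) * (segs$end - segs$start))
    expect_equal(lhs, oracle_copy_mass(arr), label = paste("bfb seed", s))
  }
})

test_that("BFB cycles bound multiplicity by 2^n and create fold-backs", {
  for (s in c(7, 11, 23)) {
    for (n_cycles in 1:4) {
      arr <- simulate_bfb("toy", c(4000, 10000), n_cycles, seed = s,
                          chrom_length = 10000)
      segs <- as.data.table(derive_cn_profile(arr))
      expect_lte(max(segs$total_cn), 2^n_cycles + 1)
      jx <- derive_junctions(arr, seed = s)
      expect_gte(sum(detect_foldback(jx)), 1)
    }
  }
  ## single cycle: exactly one fold-back junction with co-located breakends
  arr <- simulate_bfb("toy", c(4000, 10000), 1, seed = 5,
                      chrom_length = 10000)
  jx <- derive_junctions(arr, seed = 5)
  fb <- jx[detect_foldback(jx)]
  expect_equal(nrow(fb), 1L)
  expect_equal(fb$pos1, fb$pos2)
  expect_error(simulate_bfb("toy", c(100, 101), 1, seed = 1), "2 bp")
})

test_that("max CN is non-decreasing in BFB cycle count at fixed seed", {
  for (s in 1:10) {
    maxcn <- vapply(1:4, function(nc) {
      max(as.data.table(derive_cn_profile(
        simulate_bfb("toy", c(4000, 10000), nc, seed = s,
                     chrom_length = 10000)))$total_cn)
    }, 1)
    expect_true(all(diff(maxcn) >= 0), label = paste("seed", s))
  }
})

test_that("junction insertion lengths are uniform on [0, 6]", {
  ins <- unlist(lapply(1:400, function(s) {
    arr <- tryCatch(toy_chromothripsis(s, n_breakpoints = 15),
                    error = function(e) NULL)
    if (is.null(arr)) return(NULL)
    derive_junctions(arr, seed = s + 5000)$insertion_len
  }))
  expect_gt(length(ins), 3000)
  expect_true(all(ins %in% 0:6))
  expect_equal(mean(ins), 3, tolerance = 0.05)
})

test_that("same seed gives identical simulated output", {
  a1 <- simulate_chromothripsis("chr21", default_event_region(), 20, 0.5,
                                seed = 99, chrom_length = 46709983)
  a2 <- simulate_chromothripsis("chr21", default_event_region(), 20, 0.5,
                                seed = 99, chrom_length = 46709983)
  expect_identical(a1, a2)
  j1 <- derive_junctions(a1, seed = 5)
  j2 <- derive_junctions(a2, seed = 5)
  expect_identical(as.data.table(j1), as.data.table(j2))
})

test_that("chromothripsis CN oscillates along the affected allele", {
  ## default-scale event: longest 2-state oscillation run >= 4 segments
  arr <- simulate_chromothripsis("chr21", default_event_region(), 20, 0.5,
                                 seed = 42, chrom_length = 46709983)
  segs <- as.data.table(derive_cn_profile(arr))
  expect_gte(max_oscillation_run(segs$total_cn, k = 2), 4)
})
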