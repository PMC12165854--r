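## Independent oracles used across the suite. These deliberately avoid the
## code paths they check: per-base coverage instead of interval algebra,
## pairwise enumeration instead of the production counters, log-factorial
## enumeration instead of dhyper, dmultinom instead of the lgamma
## composition sum.

## Per-base total CN of an arrangement (toy chromosomes only).
oracle_cn_per_base <- function(arr, ploidy = 2) {
  L <- arr$chrom_length
  cn <- rep(ploidy - 1, L)
  bump <- function(s, e) if (e > s) cn[(s + 1):e] <<- cn[(s + 1):e] + 1
  bump(0, arr$region[1])
  bump(arr$region[2], L)
  fr <- arr$fragments
  for (i in seq_len(nrow(fr))) bump(fr$source_start[i], fr$source_end[i])
  cn
}

## Bases gained minus bases lost, from fragment multiplicities.
oracle_copy_mass <- function(arr) {
  fr <- arr$fragments
  mult <- rep(0L, arr$region[2] - arr$region[1])
  for (i in seq_len(nrow(fr))) {
    ix <- (fr$source_start[i] - arr$region[1] + 1):(fr$source_end[i] - arr$region[1])
    mult[ix] <- mult[ix] + 1L
  }
  sum(pmax(mult - 1L, 0L)) - sum(mult == 0L)
}

## Pairwise crossing enumeration (interleaving).
oracle_interleaved <- function(junc) {
  junc <- data.table::as.data.table(junc)
  intra <- junc[chrom1 == chrom2]
  n <- nrow(intra)
  if (n < 2) return(0L)
  a1 <- pmin(intra$pos1, intra$pos2); a2 <- pmax(intra$pos1, intra$pos2)
  hit <- logical(n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k || intra$chrom1[i] != intra$chrom1[k]) next
    cross <- (a1[i] < a1[k] & a1[k] < a2[i] & a2[i] < a2[k]) |
             (a1[k] < a1[i] & a1[i] < a2[k] & a2[k] < a2[i])
    if (cross) hit[i] <- TRUE
  }
  sum(hit)
}

## Brute-force longest oscillation run over all subwindows.
oracle_oscillation <- function(states, k) {
  states <- round(states)
  n <- length(states)
  if (n == 0) return(0L)
  best <- 1L
  for (i in seq_len(n)) for (j in i:n) {
    w <- states[i:j]
    if (length(w) > 1 && any(diff(w) == 0)) next
    if (length(unique(w)) <= k) best <- max(best, length(w))
  }
  best
}

## Exact multinomial p by full enumeration with dmultinom.
oracle_multinomial_p <- function(counts) {
  n <- sum(counts)
  p_obs <- dmultinom(counts, prob = rep(0.25, 4))
  total <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    pr <- dmultinom(c(a, b, cc, d), prob = rep(0.25, 4))
    if (pr <= p_obs * (1 + 1e-9)) total <- total + pr
  }
  total
}

## Fisher two-sided p by log-factorial enumeration at fixed margins.
oracle_fisher_p <- function(a, b, cc, d) {
  lfac <- lgamma(seq_len(a + b + cc + d + 1))  # lfac[k+1] = log(k!)
  lf <- function(k) lgamma(k + 1)
  m <- a + cc; nn <- b + d; K <- a + b; N <- m + nn
  logp <- function(x) lf(m) - lf(x) - lf(m - x) +
    lf(nn) - lf(K - x) - lf(nn - K + x) - (lf(N) - lf(K) - lf(N - K))
  supp <- max(0, K - nn):min(K, m)
  lp <- vapply(supp, logp, 1)
  lobs <- logp(a)
  min(1, sum(exp(lp[lp <= lobs + 1e-7])))
}

## Small random junction sets for property tests.
random_junctions <- function(n, chrom = "chr21", span = 1e6, seed = 1) {
  set.seed(seed)
  pos1 <- sample.int(span, n)
  pos2 <- pos1 + sample.int(span / 2, n)
  junctions(rep(chrom, n), pos1, sample(c("+", "-"), n, TRUE),
            rep(chrom, n), pos2, sample(c("+", "-"), n, TRUE),
            insertion_len = sample(0:6, n, TRUE))
}

## Canonical toy: a 10-kb chromosome for per-base oracles.
toy_chromothripsis <- function(seed, n_breakpoints = 9,
                               retention_prob = 0.5) {
  simulate_chromothripsis("toy", c(2000, 9000), n_breakpoints,
                          retention_prob, seed = seed, chrom_length = 10000)
}
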