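## Cohort-, single-cell- and expression-level simulation. The generator's
## defaults emulate the statistical structure of a 64-patient BP-MPN
## cohort: a quarter of samples carry a regional chr21q22 gain sharing a
## common 2.7-Mb amplified core (a third of carriers via chromothripsis),
## carriers bear a heavier non-chr21 CNA burden, the single-cell clone
## structure is the linear hierarchy WT -> JAK2 -> JAK2+TP53 ->
## +chr21amp, and expression follows gene dosage with allelic skew toward
## the amplified allele.

#' Simulation parameters
#'
#' Bundles every tunable of the synthetic-data generator with defaults
#' chosen to emulate the published cohort structure: 64 samples with 25%
#' carriers (16/64), non-chr21 CNA burden medians near 6.5 (carriers)
#' versus 1 (non-carriers), single-cell clone sizes 107/179/162/1455 of
#' 1903 cells, and amplified copy number around 3-4 driving a pure dosage
#' effect (`dosage_factor = 1`).
#'
#' @param cohort_size Number of samples.
#' @param chr21amp_prevalence Carrier fraction; carriers =
#'   `round(prevalence * cohort_size)` so printed prevalences are hit
#'   exactly.
#' @param chromothripsis_fraction Fraction of carriers whose amplification
#'   arises by chromothripsis (the rest are simple tandem duplications).
#' @param n_breakpoints,retention_prob Chromothripsis event parameters.
#' @param bfb_cycles BFB cycles for [simulate_bfb()]-based events.
#' @param insertion_len_range Junction insertion length range in bp.
#' @param burden_mean_carriers,burden_mean_noncarriers Poisson means of
#'   background (non-chr21) CNA counts.
#' @param p_jak2,p_tp53_carrier,p_tp53_noncarrier Lesion frequencies for
#'   the lesion table (TP53 alteration co-occurs with the amplification).
#' @param clone_fractions Fractions for the WT, JAK2, JAK2+TP53 and triple
#'   (JAK2+TP53+chr21amp) clones; must sum to 1.
#' @param n_cells Number of single cells.
#' @param ado_rate Allele dropout rate: each per-cell genotype call is
#'   independently set to missing with this probability.
#' @param cn_amp Total copy number of the amplified region in amplified
#'   cells (drives dosage and allelic skew).
#' @param dosage_factor Expression log2 fold change per log2 CN ratio
#'   (1 = pure dosage).
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param ase_depth Read depth per heterozygous SNP in the ASE simulation.
#' @param ase_snps_per_gene Informative SNPs per gene.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(cohort_size = 64,
                       chr21amp_prevalence = 0.25,
                       chromothripsis_fraction = 1 / 3,
                       n_breakpoints = 20,
                       retention_prob = 0.5,
                       bfb_cycles = 3,
                       insertion_len_range = c(0, 6),
                       burden_mean_carriers = 6.5,
                       burden_mean_noncarriers = 1.3,
                       p_jak2 = 0.6,
                       p_tp53_carrier = 0.75,
                       p_tp53_noncarrier = 0.35,
                       clone_fractions = c(wt = 107, jak2 = 179,
                                           jak2_tp53 = 162,
                                           triple = 1455) / 1903,
                       n_cells = 1903,
                       ado_rate = 0.05,
                       cn_amp = 4,
                       dosage_factor = 1,
                       nb_dispersion = 0.5,
                       ase_depth = 30,
                       ase_snps_per_gene = 3,
                       seed = 1) {
  check_prob(chr21amp_prevalence, "chr21amp_prevalence")
  check_prob(retention_prob, "retention_prob")
  check_prob(ado_rate, "ado_rate")
  check_prob(p_jak2, "p_jak2")
  if (abs(sum(clone_fractions) - 1) > 1e-8)
    stop("clone_fractions must sum to 1", call. = FALSE)
  if (cohort_size < 2) stop("cohort_size must be >= 2", call. = FALSE)
  if (nb_dispersion < 0 || cn_amp < 2)
    stop("negative rates not allowed", call. = FALSE)
  p <- as.list(environment())
  p$seed <- check_seed(seed)
  structure(p, class = "sim_params")
}

#' The 24-gene panel of the synthetic amplified core
#'
#' Gene coordinates (synthetic, evenly spaced across the planted 2.7-Mb
#' core) for a 24-gene panel named after genes of the 21q22 region; the
#' five dosage-responsive genes of the default simulation are DYRK1A,
#' DSCR3, MORC3, PIGP and TTC3.
#'
#' @return `data.table(chrom, start, end, gene, dosage_responsive)`.
#' @export
mar_gene_panel <- function() {
  genes <- c("DYRK1A", "DSCR3", "MORC3", "PIGP", "TTC3",
             "ETS2", "ERG", "TMPRSS2", "HMGN1", "BRWD1", "PSMG1",
             "B3GALT5", "IGSF5", "PCP4", "DSCAM", "BACE2", "KCNJ6",
             "KCNJ15", "RIPK4", "PRDM15", "C2CD2", "ZBTB21", "UMODL1",
             "ABCG1")
  core <- mar_core_region()
  n <- length(genes)
  pitch <- (core$end - core$start) / n
  dt <- data.table(chrom = core$chrom,
                   start = floor(core$start + (seq_len(n) - 1) * pitch + pitch * 0.1),
                   end = floor(core$start + (seq_len(n) - 1) * pitch + pitch * 0.7),
                   gene = genes,
                   dosage_responsive = genes %in% c("DYRK1A", "DSCR3",
                                                    "MORC3", "PIGP", "TTC3"))
  setorder(dt, start)
  dt[]
}

#' Simulate a cohort
#'
#' `round(prevalence * n)` samples become carriers of a chr21q22
#' amplification whose amplified intervals all contain the planted core
#' ([mar_core_region()]); a third (by default) acquire it through a
#' chromothripsis event with an amplified sub-block, the rest through a
#' simple tandem duplication. Carriers draw more background (non-chr21)
#' CNAs than non-carriers, and the lesion table couples TP53 alteration to
#' carrier status. Junction calls are emitted for the chr21 events.
#'
#' @param params A [sim_params()] object.
#' @return A `cohort_bundle` list: `segments` (all samples), `junctions`,
#'   `lesions` (samples x lesions 0/1 table), `truth` (per-sample carrier
#'   flag, mechanism, planted core).
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$cohort_size
  n_carriers <- round(params$chr21amp_prevalence * n)
  seeds <- derive_seeds(params$seed, 6 * n + 10)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  set.seed(next_seed())
  carrier <- rep(FALSE, n)
  carrier[sample.int(n, n_carriers)] <- TRUE
  n_chromo <- round(params$chromothripsis_fraction * n_carriers)
  mech <- character(n)
  mech[which(carrier)[seq_len(n_carriers) <= n_chromo]] <- "chromothripsis"
  mech[carrier & mech == ""] <- "tandem_duplication"
  mech[!carrier] <- "none"

  genome <- default_genome()
  core <- mar_core_region()
  sample_ids <- sprintf("S%03d", seq_len(n))
  seg_list <- list(); junc_list <- list()

  for (i in seq_len(n)) {
    sid <- sample_ids[i]
    set.seed(next_seed())
    if (carrier[i]) {
      pad_l <- runif(1, 5e5, 3e6); pad_r <- runif(1, 5e5, 3e6)
      region <- c(max(0, core$start - pad_l),
                  min(genome[["chr21"]], core$end + pad_r))
      if (mech[i] == "chromothripsis") {
        mult <- sample(2:7, 1)
        arr <- simulate_chromothripsis(
          "chr21", region, n_breakpoints = params$n_breakpoints,
          retention_prob = params$retention_prob, seed = next_seed(),
          chrom_length = genome[["chr21"]], amp_multiplicity = mult,
          amp_interval = c(core$start, core$end))
      } else {
        arr <- simulate_simple_sv(
          "chr21", region, type = "tandem_duplication", seed = next_seed(),
          chrom_length = genome[["chr21"]],
          n_copies = sample(2:4, 1))
      }
      segs <- derive_cn_profile(arr, ploidy = 2, sample_id = sid)
      jx <- derive_junctions(arr, params$insertion_len_range,
                             seed = next_seed(), sample_id = sid)
      junc_list[[sid]] <- jx
      chr21_segs <- as.data.table(segs)
    } else {
      next_seed(); next_seed()                 # keep the seed stream aligned
      chr21_segs <- data.table(chrom = "chr21", start = 0,
                               end = genome[["chr21"]], total_cn = 2,
                               loh = NA, sample_id = sid)
    }
    ## background CNAs on non-chr21 chromosomes
    set.seed(next_seed())
    lambda <- if (carrier[i]) params$burden_mean_carriers
              else params$burden_mean_noncarriers
    n_bg <- rpois(1, lambda)
    bg <- background_cnas(n_bg, genome, sid)
    other <- data.table(chrom = setdiff(names(genome), c("chr21", unique(bg$chrom))))
    neutral <- if (nrow(other)) data.table(chrom = other$chrom, start = 0,
                                           end = genome[other$chrom],
                                           total_cn = 2, loh = NA,
                                           sample_id = sid) else NULL
    seg_list[[sid]] <- rbind(chr21_segs, bg, neutral, fill = TRUE)
  }

  segments <- validate_segments(rbindlist(seg_list))
  junctions_all <- if (length(junc_list)) rbindlist(junc_list)
                   else junctions(character(0), numeric(0), character(0),
                                  character(0), numeric(0), character(0))[0]

  set.seed(next_seed())
  jak2 <- rbinom(n, 1, params$p_jak2)
  tp53 <- rbinom(n, 1, ifelse(carrier, params$p_tp53_carrier,
                              params$p_tp53_noncarrier))
  lesions <- data.table(
    sample_id = sample_ids,
    chr21amp = as.integer(carrier),
    JAK2_mut = jak2,
    TP53_alt = tp53,
    del5q = rbinom(n, 1, 0.27),
    monosomy7 = rbinom(n, 1, 0.09),
    del17p = rbinom(n, 1, 0.16),
    gain1q = rbinom(n, 1, 0.16))

  structure(list(
    segments = segments,
    junctions = normalize_junctions(junctions_all),
    lesions = lesions,
    truth = list(sample_id = sample_ids, carrier = carrier,
                 mechanism = mech, core = core,
                 n_carriers = n_carriers)),
    class = "cohort_bundle")
}

## Random non-overlapping background gains/losses/CNN-LOH events on the
## non-chr21 chromosomes; class mix follows the cohort-wide CNA spectrum
## (~30% gains, ~63% losses, ~7% CNN-LOH).
background_cnas <- function(n_bg, genome, sid, max_tries = 50) {
  if (n_bg == 0)
    return(data.table(chrom = character(0), start = numeric(0),
                      end = numeric(0), total_cn = numeric(0), loh = logical(0),
                      sample_id = character(0)))
  chroms <- setdiff(names(genome), "chr21")
  placed <- data.table(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  rows <- list()
  for (e in seq_len(n_bg)) {
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1)
      len <- runif(1, 1e6, 3e7)
      st <- floor(runif(1, 0, genome[[ch]] - len))
      en <- floor(st + len)
      clash <- placed[chrom == ch & end > st & start < en]
      if (nrow(clash) == 0) {
        placed <- rbind(placed, data.table(chrom = ch, start = st, end = en))
        cls <- sample(c("gain", "loss", "cnn_loh"), 1,
                      prob = c(0.30, 0.63, 0.07))
        rows[[e]] <- data.table(
          chrom = ch, start = st, end = en,
          total_cn = switch(cls, gain = 3, loss = 1, cnn_loh = 2),
          loh = cls == "cnn_loh", sample_id = sid)
        break
      }
    }
  }
  out <- rbindlist(rows)
  ## fill the gaps with neutral CN so each touched chromosome is covered
  fill <- rbindlist(lapply(unique(out$chrom), function(ch) {
    ivs <- out[chrom == ch][order(start)]
    edges <- c(0, as.vector(rbind(ivs$start, ivs$end)), genome[[ch]])
    gaps <- matrix(edges, ncol = 2, byrow = TRUE)
    gaps <- gaps[c(TRUE, rep(c(FALSE, TRUE), nrow(ivs)))[seq_len(nrow(gaps))], ,
                 drop = FALSE]
    gaps <- gaps[gaps[, 1] < gaps[, 2], , drop = FALSE]
    if (nrow(gaps) == 0) return(NULL)
    data.table(chrom = ch, start = gaps[, 1], end = gaps[, 2],
               total_cn = 2, loh = NA, sample_id = sid)
  }))
  rbind(out, fill, fill = TRUE)
}

#' Simulate single cells with genotypes, counts and allelic reads
#'
#' Cells are apportioned to the linear clonal hierarchy WT -> JAK2 ->
#' JAK2+TP53 -> triple (JAK2+TP53+chr21amp) by largest-remainder rounding
#' of `clone_fractions` (so the printed clone sizes are recovered exactly
#' at zero dropout), then shuffled. Each genotype call is independently
#' set to missing with probability `ado_rate`. Gene counts follow a
#' negative-binomial model whose mean, for dosage-responsive genes in
#' amplified cells, is scaled by `(CN/2)^dosage_factor`. Allelic read
#' counts for amplified-gene SNPs are Binomial(depth, (CN-1)/CN) toward
#' the amplified allele in amplified cells and balanced otherwise.
#'
#' @param params A [sim_params()] object.
#' @return List `cells` (per-cell genotype calls and truth),
#'   `counts` (genes x cells integer matrix), `ase` (per-SNP pooled allelic
#'   read counts per gene and cell group).
#' @export
simulate_single_cells <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  seeds <- derive_seeds(params$seed + 1L, 4)
  n <- params$n_cells
  counts_per_clone <- apportion(params$clone_fractions, n)
  clones <- rep(c("wt", "jak2", "jak2_tp53", "triple"), counts_per_clone)
  set.seed(seeds[1])
  clones <- clones[sample.int(n)]

  truth <- data.table(
    cell_id = sprintf("cell%05d", seq_len(n)),
    clone = clones,
    JAK2_true = ifelse(clones == "wt", "wt", "mutant"),
    TP53_true = ifelse(clones %in% c("jak2_tp53", "triple"), "mutant", "wt"),
    chr21_true = ifelse(clones == "triple", "amp", "normal"))

  set.seed(seeds[2])
  drop <- matrix(runif(3 * n) < params$ado_rate, ncol = 3)
  cells <- truth[, .(cell_id, clone,
                     JAK2 = ifelse(drop[, 1], "missing", JAK2_true),
                     TP53 = ifelse(drop[, 2], "missing", TP53_true),
                     chr21 = ifelse(drop[, 3], "missing", chr21_true))]

  ## expression: 24-gene panel, NB counts, dosage shift in amplified cells
  panel <- mar_gene_panel()
  set.seed(seeds[3])
  base_mu <- stats::rgamma(nrow(panel), shape = 2, rate = 0.4)  # mean ~5
  names(base_mu) <- panel$gene
  amp_cells <- truth$chr21_true == "amp"
  scale_amp <- (params$cn_amp / 2)^params$dosage_factor
  size <- 1 / params$nb_dispersion
  counts <- matrix(0L, nrow = nrow(panel), ncol = n,
                   dimnames = list(panel$gene, truth$cell_id))
  for (g in seq_len(nrow(panel))) {
    mu <- rep(base_mu[g], n)
    if (panel$dosage_responsive[g]) mu[amp_cells] <- mu[amp_cells] * scale_amp
    counts[g, ] <- rnbinom(n, mu = mu, size = size)
  }

  ## allelic reads: pooled per SNP over amplified vs control cells
  set.seed(seeds[4])
  f_amp <- (params$cn_amp - 1) / params$cn_amp
  ase <- rbindlist(lapply(panel$gene, function(g) {
    rbindlist(lapply(seq_len(params$ase_snps_per_gene), function(s) {
      data.table(
        gene = g, snp_id = sprintf("%s_snp%d", g, s),
        group = c("chr21amp", "control"),
        amp_reads = c(rbinom(1, params$ase_depth, f_amp),
                      rbinom(1, params$ase_depth, 0.5)),
        total_reads = params$ase_depth,
        total_cn = c(params$cn_amp, 2))
    }))
  }))
  list(cells = cells, counts = counts, ase = ase)
}

#' Simulate bulk DE and DA result tables
#'
#' Emits precomputed-style differential-expression and
#' differential-accessibility tables of the kind consumed by
#' [integrate_de_da()]: the dosage-responsive MAR genes are up-regulated,
#' one of them (DYRK1A by default) additionally carries a significant
#' promoter DA peak; non-MAR filler genes provide the null background.
#'
#' @param params A [sim_params()] object.
#' @param promoter_gene Gene given the significant promoter peak.
#' @return List `de` (gene, log2_fc, p, p_adj), `da` (peak coordinates,
#'   assigned gene, is_promoter, log2_fc, p_adj).
#' @export
simulate_bulk_tables <- function(params = sim_params(),
                                 promoter_gene = "DYRK1A") {
  set.seed(derive_seeds(params$seed + 2L, 1))
  panel <- mar_gene_panel()
  filler <- sprintf("GENE%03d", 1:120)
  de_genes <- c(panel$gene, filler)
  is_up <- de_genes %in% panel$gene[panel$dosage_responsive]
  log2_fc <- ifelse(is_up, log2(params$cn_amp / 2) + stats::rnorm(length(de_genes), 0, 0.15),
                    stats::rnorm(length(de_genes), 0, 0.3))
  p <- ifelse(is_up, stats::runif(length(de_genes), 1e-6, 1e-3),
              stats::runif(length(de_genes), 0.05, 1))
  de <- data.table(gene = de_genes, log2_fc = log2_fc, p = p,
                   p_adj = p.adjust(p, method = "BH"))
  da <- rbindlist(list(
    data.table(chrom = "chr21",
               start = panel[gene == promoter_gene, start] - 1500,
               end = panel[gene == promoter_gene, start] + 200,
               gene = promoter_gene, is_promoter = TRUE,
               log2_fc = 2.36, p_adj = 0.015),
    data.table(chrom = "chr21",
               start = panel[gene == promoter_gene, start] + 5000 + (0:5) * 3000,
               end = panel[gene == promoter_gene, start] + 6500 + (0:5) * 3000,
               gene = promoter_gene, is_promoter = FALSE,
               log2_fc = stats::rnorm(6, 1.5, 0.4),
               p_adj = stats::runif(6, 0.001, 0.049)),
    data.table(chrom = "chr21",
               start = panel[gene != promoter_gene, start],
               end = panel[gene != promoter_gene, start] + 1000,
               gene = panel[gene != promoter_gene, gene],
               is_promoter = FALSE,
               log2_fc = stats::rnorm(23, 0, 0.3),
               p_adj = stats::runif(23, 0.1, 1))))
  list(de = de, da = da)
}
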