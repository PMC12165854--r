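## Candidate-gene prioritisation over the minimally amplified region:
## a single-cell differential-expression screen, the DE x DA-promoter
## integration rule, and allele-specific expression skew testing.
## Differential-expression/accessibility model fitting itself (DESeq2-class
## negative binomial machinery) is consumed as precomputed tables; the
## integration rule is what this module owns.

#' Log-normalise a count matrix
#'
#' Library-size normalisation to a fixed scale followed by `log2(1 + x)`,
#' the usual single-cell normalisation preceding rank-based tests.
#'
#' @param counts genes x cells integer matrix.
#' @param scale Target library size (default 1e4).
#' @return Numeric matrix of the same shape.
#' @export
lognorm_counts <- function(counts, scale = 1e4) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  log2(1 + t(t(counts) / lib) * scale)
}

#' Single-cell differential expression screen
#'
#' Per-gene two-sided Wilcoxon rank-sum test on normalised expression
#' between two cell groups, with Benjamini-Hochberg adjustment across the
#' tested gene subset. A gene is called up-regulated when `p_adj < 0.05`
#' and its mean expression is higher in the amplified group. Genes absent
#' from the matrix are reported missing, not an error.
#'
#' @param expr genes x cells matrix of log-normalised expression (see
#'   [lognorm_counts()]).
#' @param group Factor/character of length `ncol(expr)` with exactly two
#'   levels; the first level (or `amp_level`) is the amplified group.
#' @param gene_subset Genes to screen (e.g. the MAR panel).
#' @param amp_level Which group label is the amplified one; defaults to
#'   the first level.
#' @param alpha Significance threshold on `p_adj`.
#' @return `data.table(gene, present, log2_fc, p, p_adj, up,
#'   expressing_frac_amp, expressing_frac_ctrl)`.
#' @export
sc_de_screen <- function(expr, group, gene_subset = rownames(expr),
                         amp_level = NULL, alpha = 0.05) {
  group <- as.factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly two levels", call. = FALSE)
  amp_level <- amp_level %||% levels(group)[1]
  amp <- group == amp_level
  out <- rbindlist(lapply(gene_subset, function(g) {
    if (!g %in% rownames(expr))
      return(data.table(gene = g, present = FALSE, log2_fc = NA_real_,
                        p = NA_real_,
                        expressing_frac_amp = NA_real_,
                        expressing_frac_ctrl = NA_real_))
    x <- expr[g, amp]; y <- expr[g, !amp]
    p <- if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) 1
         else suppressWarnings(wilcox.test(x, y)$p.value)
    data.table(gene = g, present = TRUE,
               log2_fc = mean(x) - mean(y), p = p,
               expressing_frac_amp = mean(x > 0),
               expressing_frac_ctrl = mean(y > 0))
  }))
  out[present == TRUE, p_adj := p.adjust(p, method = "BH")]
  out[, up := present & !is.na(p_adj) & p_adj < alpha & log2_fc > 0]
  setcolorder(out, c("gene", "present", "log2_fc", "p", "p_adj", "up",
                     "expressing_frac_amp", "expressing_frac_ctrl"))
  out[]
}

#' Integrate DE and DA evidence over the MAR gene list
#'
#' The integration rule: a candidate must (i) lie in the MAR, (ii) be
#' significantly up-regulated in the bulk DE table (`p_adj < de_alpha`,
#' `log2_fc > 0`), and (iii) carry at least one significant differentially
#' accessible promoter peak (`is_promoter`, `p_adj < da_alpha`).
#' Candidates are ranked by promoter-peak log2 fold change, then DE log2
#' fold change. The function is a pure filter: its output is always a
#' subset of `mar_genes`, and loosening either threshold never removes a
#' candidate.
#'
#' When the DA table has no `is_promoter` column, promoter status is
#' derived from a TSS window (`promoter_window` around the gene start,
#' strand-agnostic, default -2000/+500 bp).
#'
#' @param de `data.table(gene, log2_fc, p_adj, ...)`.
#' @param da `data.table(gene, log2_fc, p_adj, is_promoter
#'   | chrom+start+end)`.
#' @param mar_genes Character vector of MAR genes (non-empty).
#' @param genes Gene coordinates, required only to derive promoter flags.
#' @param de_alpha,da_alpha Significance thresholds.
#' @param promoter_window `c(upstream, downstream)` bp around the TSS.
#' @return `data.table(gene, in_mar, bulk_de_up, has_da_promoter,
#'   candidate, promoter_log2_fc, de_log2_fc, priority_rank)` with one row
#'   per MAR gene.
#' @export
integrate_de_da <- function(de, da, mar_genes, genes = NULL,
                            de_alpha = 0.05, da_alpha = 0.05,
                            promoter_window = c(2000, 500)) {
  if (length(mar_genes) == 0)
    stop("empty MAR gene list", call. = FALSE)
  de <- as.data.table(de); da <- as.data.table(da)
  if (!"is_promoter" %in% names(da)) {
    if (is.null(genes))
      stop("DA table lacks is_promoter; supply gene coordinates",
           call. = FALSE)
    genes <- as.data.table(genes)
    da <- merge(da, genes[, .(gene, tss = start)], by = "gene",
                all.x = TRUE)
    da[, is_promoter := !is.na(tss) &
         end > tss - promoter_window[1] & start < tss + promoter_window[2]]
  }
  out <- rbindlist(lapply(mar_genes, function(g) {
    de_row <- de[gene == g]
    de_up <- nrow(de_row) > 0 && any(de_row$p_adj < de_alpha &
                                       de_row$log2_fc > 0)
    prom <- da[gene == g & is_promoter == TRUE & p_adj < da_alpha]
    data.table(gene = g, in_mar = TRUE, bulk_de_up = de_up,
               has_da_promoter = nrow(prom) > 0,
               promoter_log2_fc = if (nrow(prom)) max(prom$log2_fc)
                                  else NA_real_,
               de_log2_fc = if (nrow(de_row)) de_row$log2_fc[1]
                            else NA_real_)
  }))
  out[, candidate := bulk_de_up & has_da_promoter]
  setorder(out, -candidate, -promoter_log2_fc, -de_log2_fc, gene,
           na.last = TRUE)
  out[, priority_rank := NA_integer_]
  out[candidate == TRUE, priority_rank := seq_len(.N)]
  out[]
}

#' Allele-specific expression skew test
#'
#' With a single amplified haplotype at total copy number CN, the expected
#' amplified-allele read fraction is `f = (CN - 1) / CN`. Each SNP gets an
#' exact two-sided binomial test against 0.5 (skew detection) and against
#' `f` (dosage consistency); SNP-level evidence is combined per gene by
#' Stouffer's method on direction-signed z-scores (equal weights;
#' single-SNP genes keep the SNP p directly). A gene is skewed when the
#' combined test against 0.5 rejects at `alpha` with the bias toward the
#' amplified allele; it is dosage-consistent when the combined test
#' against `f` does not reject.
#'
#' @param ase `data.table(gene, amp_reads, total_reads, total_cn)`, one
#'   row per SNP; SNPs with zero total reads are excluded.
#' @param alpha Significance threshold (default 0.05).
#' @return `data.table(gene, n_snps, amp_fraction, expected_fraction,
#'   p_skew, p_dosage, skew_direction, skewed, consistent_with_cn)`.
#' @export
ase_test <- function(ase, alpha = 0.05) {
  ase <- as.data.table(ase)
  ase <- ase[total_reads > 0]
  if (nrow(ase) == 0)
    stop("no SNPs with reads", call. = FALSE)
  if (any(ase$total_cn < 2)) stop("total_cn must be >= 2", call. = FALSE)
  ase[, {
    f_exp <- (total_cn[1] - 1) / total_cn[1]
    p_half <- mapply(function(k, n) binom.test(k, n, p = 0.5)$p.value,
                     amp_reads, total_reads)
    p_f <- mapply(function(k, n) binom.test(k, n, p = f_exp)$p.value,
                  amp_reads, total_reads)
    dir <- sign(amp_reads / total_reads - 0.5)
    comb_half <- stouffer_combine(p_half, dir)
    comb_f <- stouffer_combine(p_f, sign(amp_reads / total_reads - f_exp))
    frac <- sum(amp_reads) / sum(total_reads)
    .(n_snps = .N,
      amp_fraction = frac,
      expected_fraction = f_exp,
      p_skew = comb_half$p,
      p_dosage = comb_f$p,
      skew_direction = if (comb_half$z > 0) "amplified"
                       else if (comb_half$z < 0) "other" else "none",
      skewed = comb_half$p < alpha && comb_half$z > 0,
      consistent_with_cn = comb_f$p >= alpha)
  }, by = gene]
}

## Stouffer combination of two-sided p-values with direction signs.
## Singleton input keeps the original p (and its direction).
stouffer_combine <- function(p, direction) {
  p <- pmin(pmax(p, 1e-300), 1)
  z <- direction * qnorm(1 - p / 2)
  z[direction == 0] <- 0
  zc <- sum(z) / sqrt(length(z))
  list(z = zc, p = if (length(p) == 1) p[1] else 2 * pnorm(-abs(zc)))
}
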