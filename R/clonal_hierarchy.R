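## Single-cell clonal state tabulation and event-order inference.
##
## Cell tables carry one row per cell with per-lesion calls:
## JAK2/TP53 in {mutant, wt, missing} and chr21 in {amp, normal, missing}.
## A cell is "usable" when no tracked call is missing; unusable cells are
## reported separately (allele dropout and failed genotyping are real, and
## silently dropping them would bias clone sizes).

LESION_COLS <- c("JAK2", "TP53", "chr21")

lesion_positive <- function(cells, lesion) {
  v <- cells[[lesion]]
  if (lesion == "chr21") v == "amp" else v == "mutant"
}

lesion_missing <- function(cells, lesion) cells[[lesion]] == "missing"

#' Tabulate single-cell clonal states
#'
#' Exact contingency over the 2x2x2 lesion space (JAK2 x TP53 x chr21amp)
#' for cells with no missing tracked call; cells with any missing call are
#' counted in a separate `n_unusable` bucket. The four states of the
#' linear hierarchy get canonical names (`WT`, `JAK2`, `JAK2_TP53`,
#' `JAK2_TP53_chr21amp`).
#'
#' @param cells Cell table with columns `JAK2`, `TP53`, `chr21`.
#' @return A `clonal_states` list: `counts` (named, all 8 combinations),
#'   `n_usable`, `n_unusable`.
#' @export
tabulate_states <- function(cells) {
  cells <- as.data.table(cells)
  miss <- Reduce(`|`, lapply(LESION_COLS, lesion_missing, cells = cells))
  usable <- cells[!miss]
  if (nrow(usable) == 0)
    stop_insufficient_data("no usable cells: all have missing calls")
  combo <- paste0(ifelse(lesion_positive(usable, "JAK2"), "JAK2+", "JAK2-"),
                  ifelse(lesion_positive(usable, "TP53"), "TP53+", "TP53-"),
                  ifelse(lesion_positive(usable, "chr21"), "amp+", "amp-"))
  levels <- apply(expand.grid(c("JAK2-", "JAK2+"), c("TP53-", "TP53+"),
                              c("amp-", "amp+")), 1, paste0, collapse = "")
  counts <- table(factor(combo, levels = levels))
  pretty <- c("JAK2-TP53-amp-" = "WT", "JAK2+TP53-amp-" = "JAK2",
              "JAK2+TP53+amp-" = "JAK2_TP53",
              "JAK2+TP53+amp+" = "JAK2_TP53_chr21amp")
  names(counts) <- ifelse(names(counts) %in% names(pretty),
                          pretty[names(counts)], names(counts))
  structure(list(counts = counts, n_usable = nrow(usable),
                 n_unusable = sum(miss)),
            class = "clonal_states")
}

#' @export
print.clonal_states <- function(x, ...) {
  cat(sprintf("<clonal_states> %d usable cell(s), %d unusable\n",
              x$n_usable, x$n_unusable))
  nz <- x$counts[x$counts > 0]
  for (k in names(nz)) cat(sprintf("  %-22s %d\n", k, nz[[k]]))
  invisible(x)
}

#' Infer the order of lesion acquisition
#'
#' For each ordered lesion pair (A, B), A is taken to precede B when the
#' B-mutant cells are a subset of the A-mutant cells up to a tolerance:
#' the fraction of B-mutant cells lacking A (assessed on cells non-missing
#' for both) must not exceed `contradiction_tolerance` (default 1%,
#' absorbing allele dropout). A strict precedence additionally requires
#' that the reverse containment fails. A consistent set of precedences
#' yields a total order; contradictory or cyclic containment beyond
#' tolerance yields an ambiguous result with flagged pairs -- not an
#' exception.
#'
#' @param cells Cell table with columns `JAK2`, `TP53`, `chr21`.
#' @param contradiction_tolerance Allowed violation fraction per pair.
#' @return A `hierarchy_result`: `order` (character vector of lesions,
#'   earliest first, or `NA` when ambiguous), `pairs` (per-pair
#'   statistics), `n_contradictory_cells`, `ambiguous`, `note`.
#' @export
infer_event_order <- function(cells, contradiction_tolerance = 0.01) {
  cells <- as.data.table(cells)
  pos <- lapply(LESION_COLS, lesion_positive, cells = cells)
  mis <- lapply(LESION_COLS, lesion_missing, cells = cells)
  names(pos) <- names(mis) <- LESION_COLS
  with_mutants <- LESION_COLS[vapply(pos, any, TRUE)]
  if (length(with_mutants) < 2)
    stop_insufficient_data(
      "need mutant cells for at least 2 lesions to order events")

  pairs <- list(); contradictions <- 0L
  precedes <- matrix(FALSE, 3, 3, dimnames = list(LESION_COLS, LESION_COLS))
  frac <- matrix(NA_real_, 3, 3, dimnames = list(LESION_COLS, LESION_COLS))
  for (a in LESION_COLS) for (b in LESION_COLS) {
    if (a == b) next
    ok <- !mis[[a]] & !mis[[b]]
    nb <- sum(pos[[b]] & ok)
    viol <- sum(pos[[b]] & !pos[[a]] & ok)
    f <- if (nb > 0) viol / nb else NA_real_
    frac[a, b] <- f
    precedes[a, b] <- !is.na(f) && f <= contradiction_tolerance
    pairs[[paste(a, b)]] <- data.table(
      earlier = a, later = b, n_later_mutant = nb, n_violations = viol,
      violation_fraction = f,
      contains = precedes[a, b])
  }
  pair_dt <- rbindlist(pairs)
  ## strict precedence: A contains B's mutants but not vice versa
  strict <- precedes & !t(precedes)
  score <- rowSums(strict[with_mutants, with_mutants, drop = FALSE])
  ord <- with_mutants[order(-score, with_mutants)]
  ## a total order requires a strict chain among lesions with mutants
  total <- TRUE
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (i < j && !strict[ord[i], ord[j]]) total <- FALSE
  }
  contradictory <- pair_dt[contains == FALSE & earlier %in% with_mutants &
                             later %in% with_mutants]
  n_contra <- 0L
  if (!total)
    n_contra <- sum(pair_dt[contains == FALSE]$n_violations, na.rm = TRUE)
  structure(list(
    order = if (total) canonical_lesion_names(ord) else NA_character_,
    lesions_ordered = if (total) ord else NA_character_,
    pairs = pair_dt,
    n_contradictory_cells = n_contra,
    ambiguous = !total,
    note = if (total)
      sprintf("total order over %d lesion(s) at tolerance %.3g",
              length(ord), contradiction_tolerance)
    else "containment contradictory or tied; returning partial order"),
    class = "hierarchy_result")
}

canonical_lesion_names <- function(x) {
  map <- c(JAK2 = "JAK2", TP53 = "TP53", chr21 = "chr21amp")
  unname(map[x])
}

#' @export
print.hierarchy_result <- function(x, ...) {
  if (!x$ambiguous)
    cat("<hierarchy_result> ", paste(x$order, collapse = " -> "), "\n",
        sep = "")
  else
    cat("<hierarchy_result> ambiguous (", x$n_contradictory_cells,
        " contradictory cell-calls)\n", sep = "")
  invisible(x)
}
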