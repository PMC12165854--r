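## Junction and copy-number segment I/O.
##
## Internal coordinate convention: 0-based breakpoint positions and 0-based
## half-open segment intervals. BEDPE is read/written 0-based, VCF breakends
## 1-based; conversion happens at the file boundary only.
##
## BEDPE strand semantics (documented in README because tools disagree): a
## junction breakend with strand "+" retains the sequence to the LEFT of the
## breakpoint (the join faces right); "-" retains the sequence to the right.
## Hence, after normalisation (breakend 1 before breakend 2 in genome order),
## a deletion is (+,-), a tandem duplication (-,+), head-to-head inversion
## (+,+) and tail-to-tail inversion (-,-).

#' Construct a normalized breakpoint junction table
#'
#' A junction is one structural variant expressed as two oriented breakends
#' plus the length of any non-templated sequence inserted at the join (the
#' NHEJ scar). Breakends are normalized so that `(chrom1, pos1)` sorts
#' before `(chrom2, pos2)` in genome order.
#'
#' @param chrom1,chrom2 Chromosome names.
#' @param pos1,pos2 0-based breakpoint coordinates.
#' @param strand1,strand2 `"+"` or `"-"`; `"+"` means the junction retains
#'   sequence left of the breakpoint.
#' @param insertion_len Non-negative insertion length in bp (`NA` if unknown).
#' @param sample_id Sample identifier.
#' @param id Junction identifier; autogenerated when missing.
#' @return A `data.table` with class `junction_set`.
#' @export
junctions <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                      insertion_len = NA_integer_, sample_id = "sample1",
                      id = NULL) {
  n <- length(pos1)
  if (is.null(id)) id <- sprintf("J%04d", seq_len(n))
  dt <- data.table(
    chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
    strand1 = as.character(strand1),
    chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
    strand2 = as.character(strand2),
    insertion_len = as.numeric(insertion_len),
    sample_id = as.character(sample_id), id = as.character(id))
  if (!all(dt$strand1 %in% c("+", "-")) || !all(dt$strand2 %in% c("+", "-")))
    stop("strands must be '+' or '-'", call. = FALSE)
  if (any(!is.na(dt$insertion_len) & dt$insertion_len < 0))
    stop("insertion_len must be >= 0", call. = FALSE)
  normalize_junctions(dt)
}

## Swap breakends where (chrom1,pos1) sorts after (chrom2,pos2).
normalize_junctions <- function(dt) {
  swap <- (dt$chrom1 > dt$chrom2) |
    (dt$chrom1 == dt$chrom2 & dt$pos1 > dt$pos2)
  if (any(swap)) {
    tmp <- dt[swap, .(chrom1, pos1, strand1)]
    dt[swap, `:=`(chrom1 = chrom2, pos1 = pos2, strand1 = strand2)]
    dt[swap, `:=`(chrom2 = tmp$chrom1, pos2 = tmp$pos1, strand2 = tmp$strand1)]
  }
  setattr(dt, "class", c("junction_set", class(dt)))
  dt[]
}

#' Classify junction orientation
#'
#' Maps each junction to the five orientation classes used in integrated
#' copy-number/SV plots: `TRA` for interchromosomal junctions, otherwise
#' `D` (deletion-type, `+/-`), `TD` (tandem-duplication-type, `-/+`),
#' `HH` (head-to-head inverted, `+/+`) or `TT` (tail-to-tail inverted,
#' `-/-`).
#'
#' @param junc A `junction_set` (see [junctions()]).
#' @return Character vector of classes.
#' @export
classify_orientation <- function(junc) {
  out <- rep(NA_character_, nrow(junc))
  tra <- junc$chrom1 != junc$chrom2
  out[tra] <- "TRA"
  key <- paste0(junc$strand1, junc$strand2)
  map <- c("+-" = "D", "-+" = "TD", "++" = "HH", "--" = "TT")
  out[!tra] <- map[key[!tra]]
  out
}

#' Read SV junctions from BEDPE or VCF breakend records
#'
#' BEDPE requires at least 10 columns (chrom1 start1 end1 chrom2 start2
#' end2 name score strand1 strand2); column 11, when numeric, is taken as
#' the junction insertion length and column 12 as the sample id. VCF input
#' supports the 4.2 breakend (BND) subset: bracket ALT notation is decoded
#' to strand pairs, inserted bases in the ALT give the insertion length,
#' and mate records are deduplicated. Unmated BNDs are skipped with a
#' warning.
#'
#' @param path File path.
#' @param format `"bedpe"` or `"vcf_bnd"`.
#' @param sample_id Sample id to assign when absent from the file.
#' @return A `junction_set`.
#' @export
read_junctions <- function(path, format = c("bedpe", "vcf_bnd"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "bedpe") read_bedpe(path, sample_id)
  else read_vcf_bnd(path, sample_id)
}

read_bedpe <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(junctions(character(), numeric(), character(),
                     character(), numeric(), character())[0])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 10L))
    stop(sprintf("malformed BEDPE line %d: fewer than 10 columns",
                 which(ncol < 10L)[1]), call. = FALSE)
  get <- function(i) vapply(fields, `[[`, "", i)
  pos1 <- suppressWarnings(as.numeric(get(2)))
  pos2 <- suppressWarnings(as.numeric(get(5)))
  bad <- which(is.na(pos1) | is.na(pos2))
  if (length(bad))
    stop(sprintf("malformed BEDPE line %d: non-numeric coordinate", bad[1]),
         call. = FALSE)
  ins <- if (all(ncol >= 11L))
    suppressWarnings(as.numeric(get(11))) else NA_real_
  smp <- if (all(ncol >= 12L)) get(12) else sample_id %||% "sample1"
  junctions(get(1), pos1, get(9), get(4), pos2, get(10),
            insertion_len = ins, sample_id = smp, id = get(7))
}

#' Write junctions
#'
#' Writers emit deterministic column order and sorting (genome order of the
#' first breakend, then id). BEDPE gains columns 11 (insertion length) and
#' 12 (sample id); VCF output writes both mates of each breakend pair with
#' inserted bases spelled as `N`s in the ALT.
#'
#' @param junc A `junction_set`.
#' @param path Output path.
#' @param format `"bedpe"` or `"vcf_bnd"`.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junc, path, format = c("bedpe", "vcf_bnd")) {
  format <- match.arg(format)
  junc <- copy(as.data.table(junc))
  setorder(junc, chrom1, pos1, chrom2, pos2, id)
  if (format == "bedpe") {
    out <- junc[, .(
      chrom1, start1 = format_pos(pos1), end1 = format_pos(pos1 + 1),
      chrom2, start2 = format_pos(pos2), end2 = format_pos(pos2 + 1),
      name = id, score = ".", strand1, strand2,
      insertion_len = ifelse(is.na(insertion_len), ".",
                             format_pos(insertion_len)),
      sample_id)]
    fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  } else {
    write_vcf_bnd(junc, path)
  }
  invisible(path)
}

format_pos <- function(x) format(x, scientific = FALSE, trim = TRUE)

## VCF BND bracket notation, decoded against the BEDPE strand convention:
##   t[p[  -> (+,-)   piece left of here joined to piece right of mate
##   t]p]  -> (+,+)
##   ]p]t  -> (-,+)
##   [p[t  -> (-,-)
read_vcf_bnd <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  recs <- list(); skipped <- 0L
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("malformed VCF line %d: fewer than 8 columns", k),
           call. = FALSE)
    alt <- f[5]
    m <- regmatches(alt, regexec("^([A-Za-z.*]*)(\\[|\\])([^:]+):([0-9]+)(\\[|\\])([A-Za-z.*]*)$", alt))[[1]]
    if (length(m) == 0L) { skipped <- skipped + 1L; next }
    pre <- m[2]; br <- m[3]; mchrom <- m[4]; mpos1 <- as.numeric(m[5])
    post <- m[7]
    if (nzchar(pre) && nzchar(post))
      stop(sprintf("malformed BND ALT on VCF line %d: %s", k, alt),
           call. = FALSE)
    s1 <- if (nzchar(pre)) "+" else "-"
    s2 <- if (br == "[") "-" else "+"
    ins <- max(nchar(pre), nchar(post)) - 1L
    recs[[length(recs) + 1L]] <- data.table(
      chrom1 = f[1], pos1 = as.numeric(f[2]) - 1, strand1 = s1,
      chrom2 = mchrom, pos2 = mpos1 - 1, strand2 = s2,
      insertion_len = as.numeric(ins), id = f[3])
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d non-BND VCF record(s)", skipped),
            call. = FALSE)
  if (length(recs) == 0L)
    return(junctions(character(), numeric(), character(),
                     character(), numeric(), character())[0])
  dt <- rbindlist(recs)
  dt[, sample_id := sample_id %||% "sample1"]
  dt <- normalize_junctions(dt)
  ## deduplicate mate pairs: both mates describe the same normalized junction
  key <- dt[, paste(chrom1, pos1, strand1, chrom2, pos2, strand2)]
  singletons <- names(which(table(key) == 1L))
  if (length(singletons))
    warning(sprintf("%d unmated BND record(s) retained as-is",
                    length(singletons)), call. = FALSE)
  dt <- dt[!duplicated(key)]
  dt[, id := sub("_[12]$", "", id)]
  setcolorder(dt, c("chrom1", "pos1", "strand1", "chrom2", "pos2",
                    "strand2", "insertion_len", "sample_id", "id"))
  dt[]
}

write_vcf_bnd <- function(junc, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=BND,Description=\"Breakend\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  for (i in seq_len(nrow(junc))) {
    j <- junc[i]
    ins <- if (is.na(j$insertion_len)) 0L else as.integer(j$insertion_len)
    t1 <- paste0("N", strrep("N", ins))  # REF base + inserted bases
    alt1 <- bnd_alt(t1, j$strand1, j$chrom2, j$pos2 + 1, j$strand2)
    alt2 <- bnd_alt(t1, j$strand2, j$chrom1, j$pos1 + 1, j$strand1)
    info1 <- sprintf("SVTYPE=BND;MATEID=%s_2", j$id)
    info2 <- sprintf("SVTYPE=BND;MATEID=%s_1", j$id)
    rows <- c(rows,
      sprintf("%s\t%d\t%s_1\tN\t%s\t.\tPASS\t%s", j$chrom1,
              as.integer(j$pos1 + 1), j$id, alt1, info1),
      sprintf("%s\t%d\t%s_2\tN\t%s\t.\tPASS\t%s", j$chrom2,
              as.integer(j$pos2 + 1), j$id, alt2, info2))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

bnd_alt <- function(t, strand_here, mate_chrom, mate_pos1, mate_strand) {
  br <- if (mate_strand == "-") "[" else "]"
  loc <- paste0(br, mate_chrom, ":", format_pos(mate_pos1), br)
  if (strand_here == "+") paste0(t, loc) else paste0(loc, t)
}

#' Construct a copy-number segment table
#'
#' Segments are genomic intervals (0-based half-open) carrying a total copy
#' number and an optional loss-of-heterozygosity flag. Unknown LOH is
#' encoded as `NA`, never `FALSE`: copy-neutral LOH calling must be able to
#' distinguish "no LOH" from "not assayed".
#'
#' @param chrom,start,end Interval coordinates.
#' @param total_cn Non-negative total copy number (may be fractional).
#' @param loh Logical or `NA`.
#' @param sample_id Sample identifier.
#' @return A `data.table` with class `cn_segments`, sorted, with per-sample
#'   non-overlap enforced.
#' @export
cn_segments <- function(chrom, start, end, total_cn, loh = NA,
                        sample_id = "sample1") {
  dt <- data.table(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), total_cn = as.numeric(total_cn),
                   loh = as.logical(loh), sample_id = as.character(sample_id))
  validate_segments(dt)
}

validate_segments <- function(dt) {
  if (any(dt$start >= dt$end))
    stop("segment start must be < end (0-based half-open)", call. = FALSE)
  if (any(!is.na(dt$total_cn) & dt$total_cn < 0))
    stop("negative total_cn", call. = FALSE)
  setorder(dt, sample_id, chrom, start)
  ## half-open intervals: touching segments (end == next start) are fine
  ov <- dt[, .(bad = any(head(end, -1) > tail(start, -1)),
               at = which(head(end, -1) > tail(start, -1))[1]),
           by = .(sample_id, chrom)]
  ov <- ov[bad == TRUE]
  if (nrow(ov) > 0) {
    o <- ov[1]
    seg <- dt[sample_id == o$sample_id & chrom == o$chrom]
    stop(sprintf(
      "overlapping segments for sample %s on %s: [%s,%s) and [%s,%s)",
      o$sample_id, o$chrom, format_pos(seg$start[o$at]),
      format_pos(seg$end[o$at]), format_pos(seg$start[o$at + 1]),
      format_pos(seg$end[o$at + 1])), call. = FALSE)
  }
  setattr(dt, "class", c("cn_segments", class(dt)))
  dt[]
}

#' Read / write copy-number segments
#'
#' BED-like TSV with a header line: columns `chrom start end total_cn`
#' plus optional `loh` (0/1/NA) and `sample_id`. Coordinates are 0-based
#' half-open. Overlapping segments within one sample are rejected with the
#' offending pair named.
#'
#' @param path File path.
#' @param sample_id Sample id used when the file lacks a sample column.
#' @return A `cn_segments` table.
#' @export
read_segments <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "start", "end", "total_cn")
  if (!all(need %in% names(dt)))
    stop("segment file must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"loh" %in% names(dt)) dt[, loh := NA]
  if (!"sample_id" %in% names(dt))
    dt[, sample_id := sample_id %||% "sample1"]
  cn_segments(dt$chrom, dt$start, dt$end, dt$total_cn,
              loh = as.logical(dt$loh), sample_id = dt$sample_id)
}

#' @rdname read_segments
#' @param segs A `cn_segments` table.
#' @export
write_segments <- function(segs, path) {
  out <- copy(as.data.table(segs))
  setorder(out, sample_id, chrom, start)
  out[, loh := ifelse(is.na(loh), "NA", as.integer(loh))]
  fwrite(out[, .(chrom, start, end, total_cn, loh, sample_id)], path,
         sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
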