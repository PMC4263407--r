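# Readers and writers for the file dialects the pipeline touches.
# All coordinates are 0-based half-open internally; 1-based inputs are
# converted at the parser boundary. readLines(gzfile(...)) is transparent
# to gzip so every reader accepts plain or .gz files.

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

.split_fields <- function(lines, sep = "\t") strsplit(lines, sep, fixed = TRUE)

.as_int <- function(x, what, line_no) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0)
    stop(sprintf("parse error at line %d: %s '%s' is not an integer",
                 line_no[bad[1]], what, x[bad[1]]))
  out
}

#' Read a Bismark-style cytosine report
#'
#' Parses tab-separated lines `chrom, 1-based position, strand,
#' methylated count, unmethylated count, context` into a
#' [methylome_track()]. Positions are converted to 0-based. Cytosines
#' with zero coverage are retained (depth filters drop them later).
#'
#' @param path path to a plain or gzipped cytosine report.
#' @param sample_id,cell_type passed to [methylome_track()].
#' @return a `MethylomeTrack` with per-cytosine calls in all contexts.
#' @export
read_cx_report <- function(path, sample_id = basename(path),
                           cell_type = "other") {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(methylome_track(
      data.table(chrom = character(), pos = integer(), strand = character(),
                 context = character(), meth = integer(), total = integer()),
      sample_id = sample_id, cell_type = cell_type))
  fields <- .split_fields(lines)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop(sprintf("parse error at line %d: expected >=6 tab-separated fields, got %d",
                 which(nf < 6)[1], nf[which(nf < 6)[1]]))
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  line_no <- seq_along(lines)
  pos1 <- .as_int(m[, 2], "position", line_no)
  meth <- .as_int(m[, 4], "methylated count", line_no)
  unmeth <- .as_int(m[, 5], "unmethylated count", line_no)
  ctx <- m[, 6]
  bad_ctx <- which(!ctx %in% c("CG", "CHG", "CHH"))
  if (length(bad_ctx) > 0)
    stop(sprintf("parse error at line %d: unknown context token '%s'",
                 bad_ctx[1], ctx[bad_ctx[1]]))
  calls <- data.table(chrom = m[, 1], pos = pos1 - 1L, strand = m[, 3],
                      context = ctx, meth = meth, total = meth + unmeth)
  methylome_track(calls, sample_id = sample_id, cell_type = cell_type)
}

#' Read a Bismark coverage (bedGraph-with-counts) file
#'
#' Columns: `chrom, 0-based start, end, level%, meth_reads, unmeth_reads`.
#' The stored level is always recomputed from the counts; if the level
#' column disagrees with the counts by more than 0.5 percentage points a
#' warning is emitted and the counts win. Duplicate positions are an
#' error (they usually indicate concatenated files).
#'
#' @inheritParams read_cx_report
#' @return a `MethylomeTrack` of CG calls on the forward-C convention.
#' @export
read_bedgraph_counts <- function(path, sample_id = basename(path),
                                 cell_type = "other") {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(methylome_track(
      data.table(chrom = character(), pos = integer(), strand = character(),
                 context = character(), meth = integer(), total = integer()),
      sample_id = sample_id, cell_type = cell_type))
  fields <- .split_fields(lines)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop(sprintf("parse error at line %d: expected 6 fields, got %d",
                 which(nf < 6)[1], nf[which(nf < 6)[1]]))
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  line_no <- seq_along(lines)
  start <- .as_int(m[, 2], "start", line_no)
  meth <- .as_int(m[, 5], "meth_reads", line_no)
  unmeth <- .as_int(m[, 6], "unmeth_reads", line_no)
  stated <- suppressWarnings(as.numeric(m[, 4]))
  total <- meth + unmeth
  recomputed <- ifelse(total > 0, 100 * meth / total, 0)
  off <- which(!is.na(stated) & abs(stated - recomputed) > 0.5)
  if (length(off) > 0)
    warning(sprintf(
      "%d row(s) with level column inconsistent with counts by >0.5 points (first at line %d); counts used",
      length(off), off[1]))
  key <- paste(m[, 1], start)
  if (anyDuplicated(key) > 0)
    stop(sprintf("parse error: duplicate position %s (line %d)",
                 key[anyDuplicated(key)], which(duplicated(key))[1]))
  calls <- data.table(chrom = m[, 1], pos = start, strand = "+",
                      context = "CG", meth = meth, total = total)
  methylome_track(calls, sample_id = sample_id, cell_type = cell_type)
}

#' Write a track in the coverage (bedGraph-with-counts) dialect
#'
#' Inverse of [read_bedgraph_counts()]: `chrom, start, end, level%,
#' meth, unmeth` for CG calls. Round-tripping reproduces counts exactly.
#'
#' @param track a `MethylomeTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph_counts <- function(track, path) {
  cg <- track$calls[track$calls$context == "CG"]
  level <- ifelse(cg$total > 0, 100 * cg$meth / cg$total, 0)
  out <- data.table(cg$chrom, cg$pos, cg$pos + 1L,
                    formatC(level, format = "fg", digits = 6),
                    cg$meth, cg$total - cg$meth)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a track as a cytosine report
#'
#' Tab-separated `chrom, 1-based position, strand, meth, unmeth, context`,
#' the dialect [read_cx_report()] parses.
#'
#' @inheritParams write_bedgraph_counts
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(track, path) {
  calls <- track$calls
  out <- data.table(calls$chrom, calls$pos + 1L, calls$strand, calls$meth,
                    calls$total - calls$meth, calls$context)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Combine the two strands of each CpG dyad
#'
#' A CpG dyad is palindromic: the reverse-strand C sits one base after
#' the forward-strand C and reports the same methylation unit, so reads
#' from both strands are summed into one call at the forward-C position.
#' Calls not belonging to a supplied dyad pass through unchanged.
#' Reverse-strand CG calls with no matching dyad are kept as orphans and
#' counted in the `orphan_reverse_calls` attribute.
#'
#' @param track a `MethylomeTrack` with per-cytosine CG calls.
#' @param cpg_dyads `data.frame` with columns `chrom`, `pos` giving the
#'   forward-strand C position of each reference dyad.
#' @return a merged `MethylomeTrack`; total read counts are conserved.
#' @export
merge_cpg_strands <- function(track, cpg_dyads) {
  dyads <- as.data.table(cpg_dyads)[, .(chrom, pos)]
  calls <- copy(track$calls)
  cg <- calls[context == "CG"]
  other <- calls[context != "CG"]

  setkeyv(dyads, c("chrom", "pos"))
  fwd <- dyads[cg[, .(chrom, pos)], on = c("chrom", "pos"), which = TRUE]
  is_fwd <- !is.na(fwd)
  rev_key <- cg[, .(chrom, pos = pos - 1L)]
  rev_hit <- dyads[rev_key, on = c("chrom", "pos"), which = TRUE]
  is_rev <- !is.na(rev_hit) & !is_fwd   # forward match wins if both

  merged_fwd <- cg[is_fwd][, .(chrom, pos, meth, total)]
  merged_rev <- cg[is_rev][, .(chrom, pos = pos - 1L, meth, total)]
  merged <- rbindlist(list(merged_fwd, merged_rev))[
    , .(meth = sum(meth), total = sum(total)), by = .(chrom, pos)]
  merged[, `:=`(strand = "+", context = "CG")]

  orphans <- cg[!is_fwd & !is_rev]
  n_orphan <- sum(orphans$strand == "-")
  out_calls <- rbindlist(list(
    merged[, .(chrom, pos, strand, context, meth, total)],
    orphans[, .(chrom, pos, strand, context, meth, total)],
    other[, .(chrom, pos, strand, context, meth, total)]))
  out <- methylome_track(out_calls, sample_id = track$sample_id,
                         cell_type = track$cell_type,
                         min_depth_applied = track$min_depth_applied)
  attr(out, "orphan_reverse_calls") <- n_orphan
  out
}

#' Apply a minimum read-depth filter
#'
#' Retains only cytosines covered by at least `min_depth` reads and
#' records the threshold on the track. In the source study CpGs covered
#' with >=3 reads were analysed for oocytes and >=5 reads for all other
#' samples.
#'
#' @param track a `MethylomeTrack`.
#' @param min_depth minimum total read count (>= 1).
#' @return the filtered `MethylomeTrack` with `min_depth_applied` set.
#' @export
filter_depth <- function(track, min_depth) {
  stopifnot(length(min_depth) == 1, min_depth >= 1)
  min_depth <- as.integer(min_depth)
  prev <- track$min_depth_applied
  eff <- if (is.na(prev)) min_depth else max(prev, min_depth)
  methylome_track(track$calls[total >= min_depth],
                  sample_id = track$sample_id, cell_type = track$cell_type,
                  min_depth_applied = eff)
}

#' Pool biological replicates into one track
#'
#' Per-position read counts are summed across replicate tracks of the
#' same cell type. No depth filter is applied here: the caller filters
#' after pooling, so a CpG shallow in each replicate can still pass on
#' the pooled counts.
#'
#' @param tracks list of `MethylomeTrack`s, all with the same `cell_type`.
#' @param sample_id identifier for the pooled track.
#' @return the pooled `MethylomeTrack` (`min_depth_applied` unset).
#' @export
pool_tracks <- function(tracks, sample_id = "pooled") {
  stopifnot(length(tracks) >= 1)
  types <- unique(vapply(tracks, `[[`, "", "cell_type"))
  if (length(types) != 1)
    stop("cannot pool tracks of mixed cell types: ",
         paste(types, collapse = ", "))
  all_calls <- rbindlist(lapply(tracks, `[[`, "calls"))
  pooled <- all_calls[, .(strand = strand[1], meth = sum(meth),
                          total = sum(total)),
                      by = .(chrom, pos, context)]
  methylome_track(pooled[, .(chrom, pos, strand, context, meth, total)],
                  sample_id = sample_id, cell_type = types)
}

#' Estimate the bisulfite conversion rate from an unmethylated spike-in
#'
#' Every cytosine of the spike-in contig (for example lambda phage) is
#' unmethylated, so any methylated call there reflects failed
#' conversion. The rate is `1 - sum(meth) / sum(total)` over all
#' cytosines of the spike contig, in all contexts.
#'
#' @param spike_track a `MethylomeTrack` restricted to the spike contig.
#' @return conversion rate as a fraction in `[0, 1]`.
#' @export
estimate_conversion_rate <- function(spike_track) {
  total <- sum(spike_track$calls$total)
  if (total == 0) stop("no spike-in coverage")
  1 - sum(spike_track$calls$meth) / total
}

# ---- region annotation readers ------------------------------------------

.empty_regions <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             strand = character(), kind = character(), name = character())
}

.check_coords <- function(start, end, line_no) {
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0)
    stop(sprintf("parse error at line %d: invalid interval [%s, %s)",
                 line_no[bad[1]], start[bad[1]], end[bad[1]]))
}

#' Read genomic region annotations
#'
#' Parses one of five dialects into a region table (0-based half-open
#' intervals). The dialect is named explicitly; there is no sniffing.
#'
#' * `"bed3"` / `"bed6"` — plain BED intervals.
#' * `"bed12"` — transcript models; block fields yield exon structure in
#'   the `exon_starts` / `exon_sizes` list-columns (`kind = "transcript"`).
#' * `"repeatmasker"` — RepeatMasker `.out`; 1-based inclusive query
#'   coordinates are converted and the repeat name plus class/family
#'   are kept (`kind = "repeat_copy"`).
#' * `"trf"` — Tandem Repeats Finder `.dat`; standard 15-field data
#'   lines yield VNTR records with `period`, `copies`, `score` and
#'   `consensus` (`kind = "VNTR"`).
#'
#' @param path input file (plain or gzipped).
#' @param dialect one of `"bed3"`, `"bed6"`, `"bed12"`, `"repeatmasker"`,
#'   `"trf"`.
#' @param kind region kind label for BED dialects (default `"other"`;
#'   use e.g. `"CGI"` or `"DMR"`).
#' @return a `data.table` region set.
#' @export
read_regions <- function(path, dialect = c("bed3", "bed6", "bed12",
                                           "repeatmasker", "trf"),
                         kind = "other") {
  dialect <- match.arg(dialect)
  lines <- .read_lines(path)
  switch(dialect,
         bed3 = .parse_bed(lines, 3, kind),
         bed6 = .parse_bed(lines, 6, kind),
         bed12 = .parse_bed12(lines),
         repeatmasker = .parse_repeatmasker(lines),
         trf = .parse_trf(lines))
}

.parse_bed <- function(lines, ncol_min, kind) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) return(.empty_regions())
  fields <- .split_fields(lines)
  nf <- lengths(fields)
  if (any(nf < ncol_min))
    stop(sprintf("parse error at line %d: expected >=%d BED fields",
                 which(nf < ncol_min)[1], ncol_min))
  line_no <- seq_along(lines)
  g <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- .as_int(g(2), "start", line_no)
  end <- .as_int(g(3), "end", line_no)
  .check_coords(start, end, line_no)
  data.table(chrom = g(1), start = start, end = end,
             strand = if (ncol_min >= 6) g(6) else ".",
             kind = kind,
             name = if (ncol_min >= 6) g(4) else
               paste0(g(1), ":", start, "-", end))
}

.parse_bed12 <- function(lines) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- .empty_regions()
    out[, `:=`(gene_id = character(), exon_starts = list(),
               exon_sizes = list())]
    return(out)
  }
  fields <- .split_fields(lines)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop(sprintf("parse error at line %d: expected 12 BED12 fields",
                 which(nf < 12)[1]))
  line_no <- seq_along(lines)
  g <- function(i) vapply(fields, `[`, "", i)
  start <- .as_int(g(2), "start", line_no)
  end <- .as_int(g(3), "end", line_no)
  .check_coords(start, end, line_no)
  parse_csv_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  sizes <- lapply(g(11), parse_csv_ints)
  starts <- lapply(g(12), parse_csv_ints)
  nb <- .as_int(g(10), "blockCount", line_no)
  if (any(lengths(sizes) != nb | lengths(starts) != nb))
    stop("parse error: block count disagrees with block lists")
  data.table(chrom = g(1), start = start, end = end, strand = g(6),
             kind = "transcript", name = g(4), gene_id = g(4),
             exon_starts = starts, exon_sizes = sizes)
}

.parse_repeatmasker <- function(lines) {
  # skip the 2 header lines + blank line; data lines are whitespace-separated
  data_lines <- grep("^\\s*\\d+\\s", lines, value = TRUE)
  if (length(data_lines) == 0) {
    out <- .empty_regions()
    out[, `:=`(rep_class = character(), rep_family = character())]
    return(out)
  }
  fields <- strsplit(trimws(data_lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11))
    stop(sprintf("parse error at RepeatMasker data line %d: expected >=11 fields",
                 which(nf < 11)[1]))
  g <- function(i) vapply(fields, `[`, "", i)
  line_no <- seq_along(data_lines)
  begin1 <- .as_int(g(6), "query begin", line_no)
  end1 <- .as_int(g(7), "query end", line_no)
  cf <- g(11)                       # class/family, e.g. SINE/Alu or Satellite
  cls <- sub("/.*$", "", cf)
  fam <- ifelse(grepl("/", cf), sub("^[^/]*/", "", cf), cf)
  start <- begin1 - 1L              # 1-based inclusive -> 0-based half-open
  .check_coords(start, end1, line_no)
  data.table(chrom = g(5), start = start, end = end1,
             strand = ifelse(g(9) == "C", "-", "+"),
             kind = "repeat_copy", name = g(10),
             rep_class = cls, rep_family = fam)
}

.parse_trf <- function(lines) {
  chrom <- NA_character_
  rows <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "Sequence:")) {
      chrom <- strsplit(trimws(sub("^Sequence:", "", ln)), "\\s+")[[1]][1]
      next
    }
    if (!grepl("^\\d+ \\d+ ", ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 15)
      stop(sprintf("parse error at TRF data line %d: expected 15 fields, got %d",
                   i, length(f)))
    if (is.na(chrom))
      stop(sprintf("parse error at line %d: TRF data line before any 'Sequence:' header", i))
    start1 <- suppressWarnings(as.integer(f[1]))
    end1 <- suppressWarnings(as.integer(f[2]))
    if (is.na(start1) || is.na(end1) || start1 < 1 || start1 > end1)
      stop(sprintf("parse error at line %d: invalid TRF interval", i))
    n <- n + 1L
    rows[[n]] <- data.table(
      chrom = chrom, start = start1 - 1L, end = end1, strand = ".",
      kind = "VNTR", name = sprintf("%s:%d-%d", chrom, start1 - 1L, end1),
      period = as.integer(f[3]), copies = as.numeric(f[4]),
      score = as.integer(f[8]), consensus = f[14])
  }
  if (n == 0) {
    out <- .empty_regions()
    out[, `:=`(period = integer(), copies = numeric(), score = integer(),
               consensus = character())]
    return(out)
  }
  rbindlist(rows[seq_len(n)])
}

#' Admit tandem-repeat records as VNTRs
#'
#' Applies the detection thresholds used for VNTR identification:
#' minimum alignment score 150 and maximum period size 500 bp
#' (Tandem Repeats Finder alignment parameters 2, 5, 7).
#'
#' @param vntrs a VNTR region table (from `read_regions(..., "trf")` or
#'   [detect_tandem_repeats_naive()]).
#' @param min_score minimum alignment score (default 150).
#' @param max_period maximum period size in bp (default 500).
#' @return the admitted subset.
#' @export
admit_vntrs <- function(vntrs, min_score = 150, max_period = 500) {
  as.data.table(vntrs)[score >= min_score & period <= max_period]
}

# internal: region table -> GRanges for overlap machinery
.regions_gr <- function(regions) {
  regions <- as.data.table(regions)
  strand <- if ("strand" %in% names(regions)) regions$strand
  else rep("*", nrow(regions))
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = strand)
}

.points_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos + 1L, width = 1L))
}
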