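#' @importFrom data.table data.table as.data.table setkey setkeyv := rbindlist
#'   fread setorder copy setnames tstrsplit .N .SD setDT
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
NULL

# data.table NSE columns
utils::globalVariables(c(
  "chrom", "pos", "strand", "context", "meth", "total", "level", "start",
  "end", "kind", "name", "rep_class", "rep_family", "n_covered", "window_id",
  "mean_a", "mean_b", "delta", "p", "q", "call", "category", "n_copies",
  "n_protected", "proportion_protected", "gene_id", "sample_id", "density",
  "cpg_idx", "dyad_pos", "is_dyad", "score", "period", "copies", "consensus",
  "region_id", "bin", "..keep", "rel", "N", "J", "i.pos", "mean_level",
  "assigned_class", "placenta_maintained", "rpkm", "log2_rpkm", "body_length",
  "n_cpgs_used", "truth_p", "label", "i.end", "i.start", "i.name"
))

#' Construct a per-CpG methylome track
#'
#' A `MethylomeTrack` holds one sample's cytosine-level bisulfite calls:
#' for every (chromosome, position, context) the number of methylated and
#' total reads. Positions are 0-based and, after [merge_cpg_strands()],
#' CpG records are keyed by the forward-strand C of the dyad.
#'
#' @param calls a `data.frame`/`data.table` with columns `chrom`, `pos`
#'   (0-based integer), `strand` (`"+"`, `"-"` or `"."`), `context`
#'   (`"CG"`, `"CHG"` or `"CHH"`), `meth` and `total` (read counts).
#' @param sample_id sample identifier string.
#' @param cell_type one of `"oocyte"`, `"sperm"`, `"blastocyst"`,
#'   `"blood"`, `"ES"`, `"other"`.
#' @param min_depth_applied the minimum read depth already enforced on
#'   `calls`, or `NA` if no depth filter has been applied.
#' @return an object of class `MethylomeTrack`.
#' @export
methylome_track <- function(calls, sample_id = "sample",
                            cell_type = c("other", "oocyte", "sperm",
                                          "blastocyst", "blood", "ES"),
                            min_depth_applied = NA_integer_) {
  cell_type <- match.arg(cell_type)
  calls <- as.data.table(calls)
  required <- c("chrom", "pos", "strand", "context", "meth", "total")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0)
    stop("calls lacks columns: ", paste(missing_cols, collapse = ", "))
  calls <- calls[, required, with = FALSE]
  calls[, pos := as.integer(pos)]
  calls[, meth := as.integer(meth)]
  calls[, total := as.integer(total)]
  if (any(calls$meth > calls$total))
    stop("meth_reads exceeds total_reads at ",
         sum(calls$meth > calls$total), " position(s)")
  if (any(calls$pos < 0)) stop("negative positions in calls")
  if (!all(calls$context %in% c("CG", "CHG", "CHH")))
    stop("unknown context token: ",
         paste(unique(setdiff(calls$context, c("CG", "CHG", "CHH"))),
               collapse = ", "))
  if (anyDuplicated(calls, by = c("chrom", "pos", "context")) > 0)
    stop("duplicate (chrom, pos, context) keys in calls")
  setkeyv(calls, c("chrom", "pos"))
  structure(
    list(sample_id = sample_id, cell_type = cell_type, calls = calls,
         min_depth_applied = as.integer(min_depth_applied)),
    class = "MethylomeTrack")
}

#' @export
print.MethylomeTrack <- function(x, ...) {
  cat(sprintf("MethylomeTrack '%s' (%s): %d calls on %d sequence(s)",
              x$sample_id, x$cell_type, nrow(x$calls),
              length(unique(x$calls$chrom))))
  if (!is.na(x$min_depth_applied))
    cat(sprintf("; depth filter >=%d applied", x$min_depth_applied))
  cat("\n")
  invisible(x)
}

#' Number of cytosine calls in a track
#' @param track a `MethylomeTrack`.
#' @return integer call count.
#' @export
n_calls <- function(track) nrow(track$calls)

#' Per-CpG methylation levels of a track
#'
#' Returns the calls table augmented with `level`, the per-cytosine
#' methylation percentage `100 * meth / total` (`NaN` where `total == 0`).
#'
#' @param track a `MethylomeTrack`.
#' @param context restrict to one context (default `"CG"`); `NULL` keeps all.
#' @return a `data.table` with a `level` column in percent.
#' @export
track_levels <- function(track, context = "CG") {
  calls <- track$calls
  ctx_wanted <- context     # distinct name: column shadows in `[` scope
  if (!is.null(ctx_wanted)) calls <- calls[calls$context == ctx_wanted]
  out <- copy(calls)
  out[, level := 100 * meth / total]
  out[]
}

#' Mean methylation level per cytosine context
#'
#' Global unweighted mean of per-cytosine levels for CG and, split by the
#' base following the C, for CA/CT/CC non-CpG sites. Used to summarise
#' non-CpG methylation (oocytes show elevated CpA methylation).
#'
#' @param track a `MethylomeTrack` whose calls retain non-CpG contexts.
#' @return a `data.table` with columns `context` and `mean_level` (percent).
#' @export
context_mean_levels <- function(track) {
  calls <- track$calls[track$calls$total > 0]
  calls[, .(mean_level = mean(100 * meth / total)), by = context][order(context)]
}
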