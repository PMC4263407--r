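# Region-level methylation: promoter/gene-body derivation, per-region
# means with kind-specific CpG minima, gamete categories on regions, and
# the cross-sample correlation structure.

#' Derive promoter regions from transcript models
#'
#' Promoters are 1 kb upstream and downstream of the transcription start
#' site of each transcript (strand-aware TSS: `start` for `+`, `end - 1`
#' for `-`). Overlapping promoters are kept separate, one per
#' transcript. Promoters running off the start of a contig are clipped
#' at 0 rather than dropped.
#'
#' @param transcripts transcript region table (BED12 or BED6 derived)
#'   with `strand` and `name`.
#' @param flank half-width around the TSS in bp (default 1000).
#' @return a region table with `kind = "promoter"`.
#' @export
define_promoters <- function(transcripts, flank = 1000) {
  tr <- as.data.table(transcripts)
  tss <- ifelse(tr$strand == "-", tr$end - 1L, tr$start)
  data.table(chrom = tr$chrom,
             start = pmax(0L, as.integer(tss - flank)),
             end = as.integer(tss + flank),
             strand = tr$strand, kind = "promoter",
             name = paste0(tr$name, "_promoter"),
             gene_id = if ("gene_id" %in% names(tr)) tr$gene_id else tr$name)
}

#' Derive merged gene bodies from transcript models
#'
#' The gene body is the union of a gene's transcribed regions (introns
#' included) minus all of its promoter intervals; transcripts of the
#' same `gene_id` are merged into a single body. Genes whose merged
#' transcribed span is shorter than `min_gene_length` bp (mostly small
#' RNA genes) are excluded. The summed body length is recorded for
#' downstream length filters.
#'
#' @param transcripts transcript region table with `gene_id`.
#' @param flank promoter half-width subtracted around each TSS
#'   (default 1000).
#' @param min_gene_length minimum merged transcribed span in bp
#'   (default 300).
#' @return a region table (`kind = "gene_body"`, possibly several
#'   intervals per gene) with a `body_length` column giving the summed
#'   body length of the gene.
#' @export
define_gene_bodies <- function(transcripts, flank = 1000,
                               min_gene_length = 300) {
  tr <- as.data.table(transcripts)
  if (!"gene_id" %in% names(tr)) tr[, gene_id := name]
  prom <- define_promoters(tr, flank = flank)
  out <- rbindlist(lapply(split(seq_len(nrow(tr)), tr$gene_id), function(ix) {
    g <- tr[ix]
    span <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    if (sum(IRanges::width(span)) < min_gene_length) return(NULL)
    pg <- prom[ix]
    body <- IRanges::setdiff(span, IRanges::IRanges(pg$start + 1L, pg$end))
    if (length(body) == 0) return(NULL)
    data.table(chrom = g$chrom[1], start = IRanges::start(body) - 1L,
               end = IRanges::end(body), strand = g$strand[1],
               kind = "gene_body", name = g$gene_id[1],
               gene_id = g$gene_id[1],
               body_length = sum(IRanges::width(body)))
  }))
  if (is.null(out) || nrow(out) == 0) {
    out <- .empty_regions()
    out[, `:=`(gene_id = character(), body_length = integer())]
  }
  setorder(out, chrom, start)
  out[]
}

#' Mean methylation level of annotated regions
#'
#' A CpG belongs to a region when its forward-C position lies in
#' `[start, end)`. The region mean is the unweighted average of per-CpG
#' levels over the region's covered CpGs, and is `NA` when fewer than
#' `min_cpgs` CpGs are covered — the study used >=10 for CGIs and
#' promoters and >=5 for repeat copies.
#'
#' @param regions region table (`chrom`, `start`, `end`, `name`).
#' @param track a depth-filtered `MethylomeTrack`.
#' @param min_cpgs minimum covered CpGs for a defined mean (default 10).
#' @return the region table with `n_cpgs_used` and `mean_level` added
#'   (one row per input region, in input order).
#' @export
region_means <- function(regions, track, min_cpgs = 10) {
  reg <- as.data.table(regions)
  lev <- track_levels(track)[!is.na(level)]
  hits <- GenomicRanges::findOverlaps(.points_gr(lev$chrom, lev$pos),
                                      .regions_gr(reg))
  agg <- data.table(region_row = S4Vectors::subjectHits(hits),
                    level = lev$level[S4Vectors::queryHits(hits)])[
    , .(n_cpgs_used = .N, mean_level = mean(level)), by = region_row]
  out <- copy(reg)
  out[, `:=`(n_cpgs_used = 0L, mean_level = NA_real_)]
  out[agg$region_row, `:=`(n_cpgs_used = agg$n_cpgs_used,
                           mean_level = agg$mean_level)]
  out[n_cpgs_used < min_cpgs, mean_level := NA_real_]
  out[]
}
utils::globalVariables(c("region_row"))

#' Cross-sample Pearson correlation matrix on shared features
#'
#' Feature-level (window, CGI, promoter or repeat-copy) mean methylation
#' is computed per sample and features with a defined mean in every
#' sample are retained (listwise deletion); the matrix is the pairwise
#' Pearson correlation of those shared feature vectors.
#'
#' @param mean_tables named list of per-sample feature-mean tables, each
#'   with a feature key column (`window_id` or `name`) and `mean_level`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation_matrix <- function(mean_tables) {
  stopifnot(length(mean_tables) >= 2)
  key_of <- function(x) if ("window_id" %in% names(x)) "window_id" else "name"
  vecs <- lapply(mean_tables, function(x) {
    x <- as.data.table(x)
    setNames(x$mean_level, x[[key_of(x)]])
  })
  shared <- Reduce(intersect, lapply(vecs, names))
  mat <- vapply(vecs, function(v) v[shared], numeric(length(shared)))
  if (!is.matrix(mat))
    mat <- matrix(mat, nrow = length(shared), ncol = length(vecs),
                  dimnames = list(NULL, names(vecs)))
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 3)
    stop("fewer than 3 features with defined means in all samples")
  cor(mat, method = "pearson")
}

#' Categorise regions by gamete-specific methylation
#'
#' The window-level rule set ([categorize_gamete_windows()]) applied to
#' region means (CGIs, promoters): >=80% is hypermethylated, <=20%
#' hypomethylated; regions undefined in either gamete are dropped.
#'
#' @param oocyte_means,sperm_means [region_means()] outputs for the two
#'   gametes (same region table).
#' @param hyper,hypo inclusive thresholds (defaults 80 and 20).
#' @return `data.table` with `name`, `oocyte`, `sperm`, `category`.
#' @export
categorize_gamete_regions <- function(oocyte_means, sperm_means,
                                      hyper = 80, hypo = 20) {
  oo <- as.data.table(oocyte_means)[, .(name, oocyte = mean_level)]
  sp <- as.data.table(sperm_means)[, .(name, sperm = mean_level)]
  j <- oo[sp, on = "name", nomatch = NULL]
  j <- j[!is.na(oocyte) & !is.na(sperm)]
  j[, category := "other"]
  j[oocyte >= hyper & sperm <= hypo, category := "oocyte_specific"]
  j[sperm >= hyper & oocyte <= hypo, category := "sperm_specific"]
  j[oocyte >= hyper & sperm >= hyper, category := "both_hyper"]
  j[oocyte <= hypo & sperm <= hypo, category := "both_hypo"]
  j[]
}
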