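# Imprinted-DMR taxonomy: classify a known DMR catalogue from
# per-sample methylation means and quantify how the classes persist in
# blastocysts and ES cells.

.DMR_CLASSES <- c("M_gDMR", "P_gDMR", "placenta_specific_M_gDMR", "sDMR")

#' Classify imprinted DMRs into germline/secondary classes
#'
#' A catalogue DMR is a germline DMR (gDMR) when it is hypermethylated
#' (>= `hyper`) in one gamete and hypomethylated (<= `hypo`) in the
#' other; the hypermethylated gamete fixes maternal (oocyte) versus
#' paternal (sperm) origin. A gDMR whose blood-cell mean lies in the
#' closed maintenance interval `[35, 65]`% is a somatically maintained
#' M-gDMR / P-gDMR; a maternal gDMR outside that interval that the
#' catalogue flags as placenta-maintained is a placenta-specific
#' M-gDMR. Everything that is not a gDMR is a secondary DMR (sDMR).
#' The placenta flag is catalogue metadata, not computed — no placenta
#' methylome enters the classification.
#'
#' @param dmrs `data.frame` with columns `name`, `oocyte`, `sperm`,
#'   `blood` (mean methylation percentages) and logical
#'   `placenta_maintained`.
#' @param hyper,hypo gamete thresholds (defaults 80/20, the global
#'   definitions).
#' @param blood_interval closed maintenance interval in blood
#'   (default `c(35, 65)`).
#' @return the input with an `assigned_class` column; rows with an
#'   undefined oocyte, sperm or blood mean get `NA` and are reported via
#'   the `n_unclassifiable` attribute.
#' @export
classify_dmr <- function(dmrs, hyper = 80, hypo = 20,
                         blood_interval = c(35, 65)) {
  d <- as.data.table(dmrs)
  stopifnot(all(c("name", "oocyte", "sperm", "blood") %in% names(d)))
  if (!"placenta_maintained" %in% names(d)) d[, placenta_maintained := FALSE]
  ok <- !is.na(d$oocyte) & !is.na(d$sperm) & !is.na(d$blood)
  maternal_g <- ok & d$oocyte >= hyper & d$sperm <= hypo
  paternal_g <- ok & d$sperm >= hyper & d$oocyte <= hypo
  in_blood <- ok & d$blood >= blood_interval[1] & d$blood <= blood_interval[2]
  cls <- rep(NA_character_, nrow(d))
  cls[ok] <- "sDMR"
  cls[maternal_g] <- "M_gDMR"
  cls[paternal_g] <- "P_gDMR"
  cls[maternal_g & !in_blood & d$placenta_maintained %in% TRUE] <-
    "placenta_specific_M_gDMR"
  d[, assigned_class := cls]
  out <- d[]
  attr(out, "n_unclassifiable") <- sum(!ok)
  out
}

#' Count class assignments of a classified catalogue
#'
#' @param classified output of [classify_dmr()].
#' @return named integer vector over the four classes.
#' @export
dmr_class_counts <- function(classified) {
  cls <- factor(classified$assigned_class, levels = .DMR_CLASSES)
  table_counts <- table(cls)
  stats::setNames(as.integer(table_counts), names(table_counts))
}

#' Loss of intermediate gDMR methylation in ES cells
#'
#' Somatically maintained gDMRs sit near 50% methylation; in ES cells
#' this balance is often lost towards hypermethylation. Counts, per ES
#' line, the gDMRs (placenta-specific ones excluded) whose ES mean
#' strictly exceeds `threshold`.
#'
#' @param classified output of [classify_dmr()].
#' @param es_means named list (one element per ES line) of numeric
#'   vectors of ES mean levels aligned with `classified$name`, or a
#'   single numeric vector.
#' @param threshold strict hypermethylation threshold (default 75).
#' @return `data.table` with `es_line`, `n_gdmr`, `n_hyper`, `fraction`.
#' @export
es_stability_summary <- function(classified, es_means, threshold = 75) {
  if (is.numeric(es_means)) es_means <- list(ES = es_means)
  keep <- classified$assigned_class %in% c("M_gDMR", "P_gDMR")
  rbindlist(lapply(names(es_means), function(nm) {
    v <- es_means[[nm]][keep]
    v <- v[!is.na(v)]
    data.table(es_line = nm, n_gdmr = length(v),
               n_hyper = sum(v > threshold),
               fraction = if (length(v) > 0) mean(v > threshold) else NA_real_)
  }))
}

#' Compare blastocyst persistence of gDMRs and oocyte-specific CGIs
#'
#' If the maternal methylome is passively diluted after fertilization,
#' non-imprinted oocyte-specific CGIs should fall well below gDMRs
#' (which maintenance machinery protects) in blastocysts; if it is
#' largely retained, the two groups should sit at similar levels.
#' Reports group medians/quartiles, their difference, and a Mann-Whitney
#' p-value; optionally splits the CGI group into autosomal and X-linked
#' (X-linked oocyte-methylated CGIs run higher in pooled blastocysts
#' because the male X is maternal).
#'
#' @param gdmr_blast numeric vector of blastocyst means of gDMRs.
#' @param cgi_blast numeric vector of blastocyst means of
#'   oocyte-specific methylated CGIs.
#' @param cgi_chrom optional chromosome names aligned with `cgi_blast`
#'   for the autosome/X split (X recognised as `"chrX"` or `"X"`).
#' @return list with `gdmr`, `cgi` (group summaries), `median_diff`
#'   (CGI - gDMR), `test` (a `meth_test`), and when `cgi_chrom` is given
#'   `cgi_autosomal` / `cgi_x` summaries.
#' @export
persistence_comparison <- function(gdmr_blast, cgi_blast, cgi_chrom = NULL) {
  gdmr_blast <- gdmr_blast[!is.na(gdmr_blast)]
  cgi_blast_all <- cgi_blast
  if (!is.null(cgi_chrom)) {
    stopifnot(length(cgi_chrom) == length(cgi_blast))
    is_x <- cgi_chrom %in% c("chrX", "X")
  }
  cgi_blast <- cgi_blast[!is.na(cgi_blast)]
  if (length(gdmr_blast) == 0 || length(cgi_blast) == 0)
    stop("both groups must be non-empty with defined blastocyst means")
  out <- list(gdmr = group_summary(gdmr_blast),
              cgi = group_summary(cgi_blast),
              median_diff = median(cgi_blast) - median(gdmr_blast),
              test = mann_whitney_u(cgi_blast, gdmr_blast))
  if (!is.null(cgi_chrom)) {
    out$cgi_autosomal <- group_summary(cgi_blast_all[!is_x])
    out$cgi_x <- group_summary(cgi_blast_all[is_x])
  }
  out
}
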