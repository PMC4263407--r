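# Gene-body methylation versus transcription: RPKM loading with the
# 0.01 floor, the gene-body/expression join, the bimodal
# active/inactive boundary, and cross-species gene-body classes.

#' Load an RPKM expression table
#'
#' Two-column TSV (`gene`, `rpkm`, header optional). RPKM values below
#' 0.01 are floored to 0.01 before the log, so `log2_rpkm` is bounded
#' below by `log2(0.01) = -6.644`.
#'
#' @param path TSV path.
#' @param species species label recorded on the records.
#' @param floor RPKM floor (default 0.01).
#' @return `data.table` with `gene_id`, `rpkm`, `log2_rpkm`, `species`.
#' @export
load_expression <- function(path, species = "human", floor = 0.01) {
  tab <- fread(path, header = "auto", sep = "\t",
               col.names = c("gene_id", "rpkm"))
  tab[, rpkm := as.numeric(rpkm)]
  if (any(is.na(tab$rpkm))) stop("non-numeric RPKM values")
  if (any(tab$rpkm < 0)) stop("negative RPKM values")
  expression_records(tab$gene_id, tab$rpkm, species = species, floor = floor)
}

#' Build expression records from vectors
#'
#' @param gene_id character vector of gene identifiers.
#' @param rpkm non-negative numeric RPKM values.
#' @param species species label.
#' @param floor RPKM floor before the log (default 0.01).
#' @return `data.table` with `gene_id`, `rpkm`, `log2_rpkm`, `species`.
#' @export
expression_records <- function(gene_id, rpkm, species = "human",
                               floor = 0.01) {
  stopifnot(length(gene_id) == length(rpkm), all(rpkm >= 0))
  data.table(gene_id = gene_id, rpkm = rpkm,
             log2_rpkm = log2(pmax(rpkm, floor)), species = species)
}

#' Join gene-body methylation with expression
#'
#' Per gene: body mean methylation and log2 RPKM. Genes with a summed
#' body length below `min_length` (default 5 kb) or an undefined body
#' mean are dropped; drop counts are attached as attribute `dropped`.
#'
#' @param body_means [region_means()] output on gene bodies, carrying
#'   `gene_id`, `body_length`, `mean_level` (one or more intervals per
#'   gene; per-gene methylation is recomputed across a gene's intervals
#'   weighted by covered CpGs).
#' @param expression expression record table ([load_expression()]).
#' @param min_length strict minimum summed body length in bp
#'   (default 5000).
#' @return `data.table` with `gene_id`, `body_length`, `mean_level`,
#'   `rpkm`, `log2_rpkm`.
#' @export
genebody_expression_join <- function(body_means, expression,
                                     min_length = 5000) {
  bm <- as.data.table(body_means)
  per_gene <- bm[, .(
    body_length = sum(end - start),
    n_cpgs_used = sum(n_cpgs_used),
    mean_level = if (sum(n_cpgs_used) > 0)
      sum(mean_level * n_cpgs_used, na.rm = TRUE) /
        sum(n_cpgs_used[!is.na(mean_level)]) else NA_real_
  ), by = gene_id]
  n_short <- sum(per_gene$body_length <= min_length)
  n_undef <- sum(is.na(per_gene$mean_level) &
                   per_gene$body_length > min_length)
  per_gene <- per_gene[body_length > min_length & !is.na(mean_level)]
  ex <- as.data.table(expression)
  j <- per_gene[ex, on = "gene_id", nomatch = NULL]
  if (nrow(j) == 0) stop("empty join between gene bodies and expression")
  out <- j[, .(gene_id, body_length, mean_level, rpkm, log2_rpkm)]
  attr(out, "dropped") <- c(short = n_short, undefined_mean = n_undef,
                            no_expression = nrow(per_gene) - nrow(j))
  out
}

#' Label genes transcriptionally active or inactive
#'
#' Gene-body methylation in oocytes is bimodal with an expression-level
#' boundary near `log2(RPKM) = -5` for human and `0` for mouse; genes
#' strictly above the boundary are labelled active.
#'
#' @param records table with `log2_rpkm` (e.g. from
#'   [genebody_expression_join()]).
#' @param boundary_log2 boundary; default -5 (`species = "mouse"`
#'   switches to 0 when `boundary_log2` is `NULL`).
#' @param species used only to pick the default boundary.
#' @return the table with a `state` column (`"active"`/`"inactive"`).
#' @export
classify_transcriptional_state <- function(records, boundary_log2 = NULL,
                                           species = "human") {
  if (is.null(boundary_log2))
    boundary_log2 <- if (species == "mouse") 0 else -5
  out <- copy(as.data.table(records))
  out[, state := ifelse(log2_rpkm > boundary_log2, "active", "inactive")]
  out[]
}
utils::globalVariables(c("state"))

#' Cross-species gene-body methylation classes
#'
#' Homologous gene pairs are classified from their gene-body means in
#' the two species with the global hyper/hypo thresholds:
#' `human_specific_hyper` (human >= 80, mouse <= 20),
#' `mouse_specific_hyper` (mirror), `both_hyper`, `both_hypo`, `other`.
#' Duplicate homolog pairs are dropped (first kept, count logged via the
#' `n_duplicates_dropped` attribute).
#'
#' @param human_table,mouse_table joined tables with `gene_id` and
#'   `mean_level`.
#' @param homolog_pairs `data.frame` with columns `human`, `mouse` (and
#'   optionally `homologene_id`).
#' @param hyper,hypo thresholds (defaults 80/20).
#' @return `data.table` with the pair, both means and `class`.
#' @export
cross_species_genebody_classes <- function(human_table, mouse_table,
                                           homolog_pairs,
                                           hyper = 80, hypo = 20) {
  hp <- as.data.table(homolog_pairs)
  stopifnot(all(c("human", "mouse") %in% names(hp)))
  n0 <- nrow(hp)
  hp <- hp[!duplicated(human) & !duplicated(mouse)]
  n_dup <- n0 - nrow(hp)
  h <- as.data.table(human_table)[, .(human = gene_id, human_meth = mean_level)]
  m <- as.data.table(mouse_table)[, .(mouse = gene_id, mouse_meth = mean_level)]
  j <- hp[h, on = "human", nomatch = NULL][m, on = "mouse", nomatch = NULL]
  j <- j[!is.na(human_meth) & !is.na(mouse_meth)]
  j[, class := "other"]
  j[human_meth >= hyper & mouse_meth <= hypo, class := "human_specific_hyper"]
  j[mouse_meth >= hyper & human_meth <= hypo, class := "mouse_specific_hyper"]
  j[human_meth >= hyper & mouse_meth >= hyper, class := "both_hyper"]
  j[human_meth <= hypo & mouse_meth <= hypo, class := "both_hypo"]
  attr(j, "n_duplicates_dropped") <- n_dup
  j[]
}
utils::globalVariables(c("human", "mouse", "human_meth", "mouse_meth",
                         "class"))
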