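# Repeat-family methylation dynamics, the >70%-window
# demethylation-protection screen, and the VNTR analyses.

#' CpG-pooled methylation of repeat families
#'
#' For every repeat name (e.g. SVA_A, LTR12C, AluY) the mean methylation
#' over all CpGs falling in any copy of that family. CpGs are pooled
#' across copies — a copy with more CpGs contributes more — which is not
#' the same as averaging per-copy means.
#'
#' @param track a depth-filtered `MethylomeTrack`.
#' @param repeat_regions repeat-copy region table (`name`, `rep_class`).
#' @return `data.table` with `name`, `rep_class`, `n_cpgs`,
#'   `mean_level`.
#' @export
family_methylation <- function(track, repeat_regions) {
  reg <- as.data.table(repeat_regions)
  lev <- track_levels(track)[!is.na(level)]
  hits <- GenomicRanges::findOverlaps(.points_gr(lev$chrom, lev$pos),
                                      .regions_gr(reg))
  tab <- data.table(name = reg$name[S4Vectors::subjectHits(hits)],
                    rep_class = if ("rep_class" %in% names(reg))
                      reg$rep_class[S4Vectors::subjectHits(hits)] else NA_character_,
                    level = lev$level[S4Vectors::queryHits(hits)])
  # a CpG inside two overlapping copies of the same family counts once
  tab <- unique(data.table(tab,
                           cpg = S4Vectors::queryHits(hits)),
                by = c("name", "cpg"))
  out <- tab[, .(rep_class = rep_class[1], n_cpgs = .N,
                 mean_level = mean(level)), by = name]
  setorder(out, -mean_level)
  out[]
}
utils::globalVariables(c("cpg"))

#' Demethylation-protection screen over repeat families
#'
#' For each repeat name, the fraction of its genomic copies overlapping
#' (>= 1 bp) any protected window — windows whose blastocyst mean
#' exceeds 70%, from [screen_windows_above()]. Families with at most
#' `min_copies` copies are excluded from the ranking (kept in the table
#' with `ranked = FALSE`).
#'
#' @param repeat_regions repeat-copy region table.
#' @param protected_windows region table of protected windows (`chrom`,
#'   `start`, `end`).
#' @param min_copies strict minimum copy number for ranking
#'   (default 100).
#' @return `data.table` sorted by `proportion_protected` (ranked
#'   families first) with `name`, `rep_class`, `n_copies`,
#'   `n_protected`, `proportion_protected`, `ranked`.
#' @export
protection_screen <- function(repeat_regions, protected_windows,
                              min_copies = 100) {
  reg <- as.data.table(repeat_regions)
  if (nrow(protected_windows) == 0) {
    prot <- rep(FALSE, nrow(reg))
  } else {
    prot <- IRanges::overlapsAny(.regions_gr(reg),
                                 .regions_gr(as.data.table(protected_windows)),
                                 ignore.strand = TRUE)
  }
  out <- reg[, .(rep_class = if ("rep_class" %in% names(reg))
                   rep_class[1] else NA_character_,
                 n_copies = .N, n_protected = sum(prot[.I])),
             by = name]
  out[, proportion_protected := n_protected / n_copies]
  out[, ranked := n_copies > min_copies]
  setorder(out, -ranked, -proportion_protected, -n_copies)
  out[]
}
utils::globalVariables(c("ranked"))

#' Detect exact tandem arrays in a DNA sequence
#'
#' A simplified periodicity scan used for synthetic sequence: for each
#' period `p` it finds maximal runs where `s[i] == s[i - p]`, i.e.
#' perfect tandem arrays. Scoring follows the Tandem Repeats Finder
#' match weight of 2 per base of the array, so a perfect array of `c`
#' copies of a `p`-mer scores `2 * p * c`. Arrays detectable at several
#' periods are reported once at their smallest period; records below
#' `min_score` or above `max_period` are dropped. This detector is for
#' the self-contained synthetic pipeline; real genomes use parsed
#' Tandem Repeats Finder `.dat` output, which feeds the same record
#' type.
#'
#' @param sequence uppercase DNA string (A/C/G/T/N).
#' @param chrom chromosome name recorded on the output intervals.
#' @param min_period,max_period period-size range in bp (defaults 1 and
#'   500).
#' @param min_score minimum alignment score (default 150).
#' @return a VNTR region table (`chrom`, `start`, `end`, `period`,
#'   `copies`, `score`, `consensus`).
#' @export
detect_tandem_repeats_naive <- function(sequence, chrom = "seq",
                                        min_period = 1, max_period = 500,
                                        min_score = 150) {
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains non-ACGTN characters")
  n <- nchar(sequence)
  s <- utf8ToInt(sequence)
  recs <- list(); nr <- 0L
  max_p <- min(max_period, n %/% 2)
  # an array must reach score >= min_score, i.e. length >= min_score/2
  min_len <- max(ceiling(min_score / 2), 2L)
  for (p in seq.int(min_period, max_p)) {
    eq <- s[(p + 1):n] == s[1:(n - p)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= max(p, min_len - p))
    for (h in hit) {
      a_start <- starts[h]            # position (1-based) of first match in eq
      run <- r$lengths[h]
      arr_len <- run + p              # array spans the run plus one period
      if (arr_len < min_len) next
      score <- 2L * arr_len
      if (score < min_score) next
      start0 <- a_start - 1L          # 0-based array start in sequence
      nr <- nr + 1L
      recs[[nr]] <- data.table(
        chrom = chrom, start = start0, end = start0 + arr_len,
        strand = ".", kind = "VNTR",
        name = sprintf("%s:%d-%d", chrom, start0, start0 + arr_len),
        period = p, copies = round(arr_len / p, 1), score = score,
        consensus = substr(sequence, start0 + 1L, start0 + p))
    }
  }
  if (nr == 0)
    return(.parse_trf(character(0)))
  out <- rbindlist(recs)
  # keep, among mutually overlapping records, the best-scoring smallest
  # period (a perfect p-mer array also matches at 2p, 3p, ...)
  setorder(out, -score, period, start)
  gr <- .regions_gr(out)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    ov <- IRanges::overlapsAny(gr, gr[i])
    ov[i] <- FALSE
    keep[keep & ov & seq_len(nrow(out)) > i] <- FALSE
  }
  out <- out[keep]
  setorder(out, chrom, start)
  out[]
}

#' Pick the representative VNTR of a region
#'
#' When several VNTRs overlap one region (typically a CGI), the one with
#' the highest alignment score is analysed; ties go to the longer array,
#' then the leftmost.
#'
#' @param region one-row region table (`chrom`, `start`, `end`).
#' @param vntr_records VNTR region table.
#' @return the selected one-row record, or `NULL` when none overlaps.
#' @export
select_top_vntr <- function(region, vntr_records) {
  v <- as.data.table(vntr_records)
  if (nrow(v) == 0) return(NULL)
  ov <- IRanges::overlapsAny(.regions_gr(v),
                             .regions_gr(as.data.table(region)),
                             ignore.strand = TRUE)
  v <- v[ov]
  if (nrow(v) == 0) return(NULL)
  v[, len := end - start]
  setorder(v, -score, -len, start)
  v[1, !"len"]
}
utils::globalVariables(c("len"))

#' VNTR enrichment of a region group against a background
#'
#' A region "contains" a VNTR when it overlaps one by at least 1 bp.
#' Builds the 2x2 table (group vs background) x (VNTR yes/no) and tests
#' it with the Pearson chi-square (no continuity correction by default).
#'
#' @param group_regions,background_regions region tables; the group is
#'   not assumed to be a subset of the background.
#' @param vntr_records VNTR region table (already thresholded, see
#'   [admit_vntrs()]).
#' @param correction passed to [chi_square_2x2()].
#' @return list with `counts` (named: `group_with`, `group_total`,
#'   `background_with`, `background_total`) and `test` (a `meth_test`).
#' @export
vntr_enrichment <- function(group_regions, background_regions, vntr_records,
                            correction = "none") {
  grp <- as.data.table(group_regions)
  bkg <- as.data.table(background_regions)
  if (nrow(grp) == 0) stop("empty region group")
  vgr <- .regions_gr(as.data.table(vntr_records))
  g_with <- sum(IRanges::overlapsAny(.regions_gr(grp), vgr,
                                     ignore.strand = TRUE))
  b_with <- sum(IRanges::overlapsAny(.regions_gr(bkg), vgr,
                                     ignore.strand = TRUE))
  counts <- c(group_with = g_with, group_total = nrow(grp),
              background_with = b_with, background_total = nrow(bkg))
  test <- chi_square_2x2(g_with, nrow(grp) - g_with,
                         b_with, nrow(bkg) - b_with,
                         correction = correction)
  list(counts = counts, test = test)
}

#' Protection of gamete-hypermethylated CGIs by VNTR content
#'
#' Restricted to autosomal CGIs hypermethylated in both gametes, tests
#' whether CGIs containing a VNTR are preferentially protected from
#' demethylation in blastocysts: 2x2 of (VNTR yes/no) x (blastocyst
#' mean strictly > `threshold` yes/no).
#'
#' @param cgis region table of CGIs hypermethylated in both gametes
#'   (caller applies the gamete and autosome restrictions).
#' @param blastocyst_means numeric vector of blastocyst means aligned
#'   with `cgis` rows; `NA` rows are dropped.
#' @param vntr_records VNTR region table.
#' @param threshold strict protection threshold in percent (default 70).
#' @param correction passed to [chi_square_2x2()].
#' @return list with the 2x2 `counts` matrix and `test` (a `meth_test`,
#'   or `NULL` with a message when a marginal is zero).
#' @export
cgi_protection_by_vntr <- function(cgis, blastocyst_means, vntr_records,
                                   threshold = 70, correction = "none") {
  cg <- as.data.table(cgis)
  stopifnot(length(blastocyst_means) == nrow(cg))
  keep <- !is.na(blastocyst_means)
  cg <- cg[keep]
  bl <- blastocyst_means[keep]
  has_vntr <- IRanges::overlapsAny(.regions_gr(cg),
                                   .regions_gr(as.data.table(vntr_records)),
                                   ignore.strand = TRUE)
  protected <- bl > threshold
  counts <- matrix(c(sum(has_vntr & protected), sum(has_vntr & !protected),
                     sum(!has_vntr & protected), sum(!has_vntr & !protected)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("VNTR", "no_VNTR"),
                                   c("protected", "not_protected")))
  test <- tryCatch(
    chi_square_2x2(counts[1, 1], counts[1, 2], counts[2, 1], counts[2, 2],
                   correction = correction),
    error = function(e) {
      message("chi-square not computable: ", conditionMessage(e))
      NULL
    })
  list(counts = counts, test = test)
}

#' Compare VNTR features between protected and unprotected CGIs
#'
#' Mann-Whitney comparisons of consensus period size, tandem copy
#' number and alignment score between the representative VNTRs (one per
#' CGI, via [select_top_vntr()]) of two CGI groups.
#'
#' @param vntrs_protected,vntrs_unprotected VNTR tables with `period`,
#'   `copies`, `score` (one row per CGI).
#' @return `data.table` with one row per feature: group summaries and
#'   the Mann-Whitney p-value.
#' @export
compare_vntr_features <- function(vntrs_protected, vntrs_unprotected) {
  a <- as.data.table(vntrs_protected)
  b <- as.data.table(vntrs_unprotected)
  if (nrow(a) < 1 || nrow(b) < 1) stop("both VNTR groups must be non-empty")
  rbindlist(lapply(c("period", "copies", "score"), function(f) {
    x <- as.numeric(a[[f]]); y <- as.numeric(b[[f]])
    tt <- mann_whitney_u(x, y)
    data.table(feature = f,
               protected_median = median(x), unprotected_median = median(y),
               protected_n = length(x), unprotected_n = length(y),
               p = tt$p_value)
  }))
}
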