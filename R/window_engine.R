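# Fixed-CpG-count sliding windows and the window-level dynamics calls.
#
# Windows are anchored on a reference CpG map (all genomic dyads), not on
# per-sample covered CpGs, so window identity is comparable across
# samples. The default geometry is 20 CpGs per window with a step of 10
# CpGs; a window is testable in a sample when >=10 of its CpGs pass that
# sample's depth filter.

#' Build fixed-CpG-count sliding windows on a reference CpG map
#'
#' Each chromosome with at least `W` CpGs yields
#' `floor((N - W) / step) + 1` windows; trailing CpGs that do not fill a
#' complete window are dropped.
#'
#' @param cpg_map `data.frame` with columns `chrom`, `pos` listing every
#'   reference CpG dyad (forward-C position, 0-based).
#' @param W CpGs per window (default 20).
#' @param step CpGs between successive window starts (default 10).
#' @return a list with `windows` (a `data.table`: `window_id`, `chrom`,
#'   `start`, `end`, `first_idx`, `last_idx`) and `cpg_map` (the sorted
#'   map with a global `cpg_idx` column); windows reference CpGs by index
#'   range into this map.
#' @export
build_cpg_windows <- function(cpg_map, W = 20, step = 10) {
  stopifnot(W >= 1, step >= 1, step <= W)
  map <- as.data.table(cpg_map)[, .(chrom, pos)]
  setorder(map, chrom, pos)
  if (anyDuplicated(map) > 0) stop("duplicate CpG positions in reference map")
  map[, cpg_idx := .I]
  per_chrom <- map[, .(n = .N, off = min(cpg_idx) - 1L), by = chrom]
  win_list <- lapply(seq_len(nrow(per_chrom)), function(i) {
    n <- per_chrom$n[i]
    if (n < W) return(NULL)
    k <- seq.int(0L, (n - W) %/% step)
    first_local <- k * step + 1L
    data.table(chrom = per_chrom$chrom[i],
               first_idx = per_chrom$off[i] + first_local,
               last_idx = per_chrom$off[i] + first_local + W - 1L)
  })
  windows <- rbindlist(win_list)
  if (nrow(windows) == 0)
    stop("no chromosome has enough CpGs for a single window")
  windows[, `:=`(start = map$pos[first_idx],
                 end = map$pos[last_idx] + 2L)]   # dyad spans pos, pos+1
  windows[, window_id := sprintf("%s:%d-%d", chrom, start, end)]
  list(windows = windows[, .(window_id, chrom, start, end,
                             first_idx, last_idx)],
       cpg_map = map, W = as.integer(W), step = as.integer(step))
}

# internal: per-(window, CpG) table of a track's covered CpG levels.
# Each covered reference CpG is attributed to every window whose index
# range contains it (at most ceiling(W/step) windows).
.window_cpg_levels <- function(win, track) {
  cg <- track$calls[context == "CG" & total > 0]
  hit <- win$cpg_map[cg, on = c("chrom", "pos"), nomatch = NULL]
  hit[, level := 100 * meth / total]
  W <- win$W; step <- win$step
  # local (within-chromosome) index
  off <- win$cpg_map[, .(off = min(cpg_idx) - 1L), by = chrom]
  hit <- off[hit, on = "chrom"]
  hit[, local := cpg_idx - off]
  reps <- lapply(0:((W - 1L) %/% step), function(j) j)  # candidate k offsets
  # window with local start k*step+1 contains local index i iff
  # k in [ceil((i - W)/step), floor((i-1)/step)] and k >= 0
  out <- rbindlist(lapply(seq_len(length(reps)), function(jj) {
    h <- copy(hit)
    h[, k := (local - 1L) %/% step - (jj - 1L)]
    h <- h[k >= 0L & local - (k * step + 1L) < W & local >= k * step + 1L]
    h[, first_idx := off + k * step + 1L]
    h
  }))
  win$windows[out, on = c("chrom", "first_idx"), nomatch = NULL][
    , .(window_id, cpg_idx, level)]
}
utils::globalVariables(c("k", "local", "off", ".I", "va", "vb", "na_",
                         "nb_", "sp2", "tstat", "df", "n_a", "n_b"))

#' Per-window mean methylation for one sample
#'
#' The window mean is the unweighted average of per-CpG levels over the
#' window's covered CpGs; windows with fewer than `min_covered` covered
#' CpGs are untestable and get `NA`.
#'
#' @param win window set from [build_cpg_windows()].
#' @param track a depth-filtered `MethylomeTrack`.
#' @param min_covered minimum covered CpGs for a testable window
#'   (default 10).
#' @return `data.table` with `window_id`, `n_covered`, `mean_level`
#'   (percent or `NA`), one row per window in window order.
#' @export
window_means <- function(win, track, min_covered = 10) {
  lev <- .window_cpg_levels(win, track)
  agg <- lev[, .(n_covered = .N, mean_level = mean(level)), by = window_id]
  out <- agg[win$windows[, .(window_id)], on = "window_id"]
  out[is.na(n_covered), n_covered := 0L]
  out[n_covered < min_covered, mean_level := NA_real_]
  out[]
}

#' Classify per-window methylation changes between two samples
#'
#' For every window testable in both samples (>= `min_covered` covered
#' CpGs each) the change `delta = mean_b - mean_a` is tested with
#' Student's t-test on the per-CpG level vectors, p-values are
#' Benjamini-Hochberg adjusted across all testable windows of the
#' comparison, and the window is called `increasing` when
#' `delta > min_delta` and `q < alpha`, `decreasing` when
#' `delta < -min_delta` and `q < alpha`, and `stable` otherwise.
#' Windows untestable in either sample are `untestable`.
#'
#' Windows where both level vectors are constant are assigned p = 1 when
#' the means agree and p = 0 (flagged, the t-statistic limit) when they
#' differ.
#'
#' @param win window set from [build_cpg_windows()].
#' @param track_a,track_b depth-filtered `MethylomeTrack`s (change is
#'   measured from `track_a` to `track_b`).
#' @param min_covered testability threshold per sample (default 10).
#' @param min_delta minimum absolute change in percentage points
#'   (default 20, exclusive).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param mode `"unpaired_equal_var"` (default) or `"paired"` (per-CpG
#'   pairing on CpGs covered in both samples).
#' @return `data.table` with `window_id`, `mean_a`, `mean_b`, `delta`,
#'   `p`, `q`, `call`, one row per window.
#' @export
classify_window_changes <- function(win, track_a, track_b, min_covered = 10,
                                    min_delta = 20, alpha = 0.05,
                                    mode = c("unpaired_equal_var", "paired")) {
  mode <- match.arg(mode)
  la <- .window_cpg_levels(win, track_a)
  lb <- .window_cpg_levels(win, track_b)
  if (mode == "paired") {
    pr <- la[lb, on = c("window_id", "cpg_idx"), nomatch = NULL]
    setnames(pr, c("level", "i.level"), c("lev_a", "lev_b"))
    st <- pr[, {
      d <- lev_b - lev_a
      .(n_a = .N, n_b = .N, mean_a = mean(lev_a), mean_b = mean(lev_b),
        vd = if (.N > 1) stats::var(d) else NA_real_, md = mean(d))
    }, by = window_id]
    st[, testable := n_a >= min_covered]
    st[, p := NA_real_]
    st[testable == TRUE & vd == 0 & md == 0, p := 1]
    st[testable == TRUE & vd == 0 & md != 0, p := 0]
    idx <- st$testable & !is.na(st$vd) & st$vd > 0
    st[idx, p := {
      tstat <- md / sqrt(vd / n_a)
      2 * stats::pt(-abs(tstat), df = n_a - 1)
    }]
  } else {
    sa <- la[, .(n_a = .N, mean_a = mean(level),
                 va = if (.N > 1) stats::var(level) else NA_real_),
             by = window_id]
    sb <- lb[, .(n_b = .N, mean_b = mean(level),
                 vb = if (.N > 1) stats::var(level) else NA_real_),
             by = window_id]
    st <- sa[sb, on = "window_id", nomatch = NULL]
    st[, testable := n_a >= min_covered & n_b >= min_covered]
    st[, p := NA_real_]
    st[testable == TRUE & va == 0 & vb == 0 & mean_a == mean_b, p := 1]
    st[testable == TRUE & va == 0 & vb == 0 & mean_a != mean_b, p := 0]
    idx <- st$testable & !is.na(st$va) & !is.na(st$vb) & (st$va + st$vb) > 0
    st[idx, p := {
      sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
      tstat <- (mean_b - mean_a) / sqrt(sp2 * (1 / n_a + 1 / n_b))
      2 * stats::pt(-abs(tstat), df = n_a + n_b - 2)
    }]
  }
  st[, delta := mean_b - mean_a]
  st[, q := NA_real_]
  testable_idx <- which(st$testable & !is.na(st$p))
  if (length(testable_idx) > 0)
    st[testable_idx, q := bh_adjust(st$p[testable_idx])]
  st[, call := "untestable"]
  st[testable == TRUE, call := "stable"]
  st[testable == TRUE & delta > min_delta & q < alpha, call := "increasing"]
  st[testable == TRUE & delta < -min_delta & q < alpha, call := "decreasing"]
  out <- st[win$windows[, .(window_id)], on = "window_id"]
  out[is.na(call), call := "untestable"]
  out[, .(window_id, mean_a, mean_b, delta, p, q, call)]
}
utils::globalVariables(c("lev_a", "lev_b", "vd", "md", "testable"))

#' Categorise windows by gamete-specific methylation
#'
#' Using the global hyper/hypo definitions (>=80% methylated is
#' hypermethylated, <=20% is hypomethylated), a window is
#' `oocyte_specific` when hypermethylated in oocytes and hypomethylated
#' in sperm, `sperm_specific` for the mirror pattern, `both_hyper` /
#' `both_hypo` when both gametes agree, and `other` otherwise. Windows
#' untestable in either gamete are dropped.
#'
#' @param oocyte_means,sperm_means outputs of [window_means()] (any
#'   table with `window_id` and `mean_level`).
#' @param hyper,hypo inclusive thresholds (defaults 80 and 20).
#' @return `data.table` with `window_id`, `oocyte`, `sperm`, `category`.
#' @export
categorize_gamete_windows <- function(oocyte_means, sperm_means,
                                      hyper = 80, hypo = 20) {
  oo <- as.data.table(oocyte_means)[, .(window_id, oocyte = mean_level)]
  sp <- as.data.table(sperm_means)[, .(window_id, sperm = mean_level)]
  j <- oo[sp, on = "window_id", nomatch = NULL]
  j <- j[!is.na(oocyte) & !is.na(sperm)]
  j[, category := "other"]
  j[oocyte >= hyper & sperm <= hypo, category := "oocyte_specific"]
  j[sperm >= hyper & oocyte <= hypo, category := "sperm_specific"]
  j[oocyte >= hyper & sperm >= hyper, category := "both_hyper"]
  j[oocyte <= hypo & sperm <= hypo, category := "both_hypo"]
  j[]
}
utils::globalVariables(c("oocyte", "sperm"))

#' Summarise a third sample per gamete category
#'
#' Median (and quartiles) of e.g. blastocyst window means within each
#' gamete-specific category — the readout used to compare maternal and
#' paternal demethylation dynamics.
#'
#' @param categories output of [categorize_gamete_windows()].
#' @param other_means [window_means()] table for the third sample.
#' @return `data.table` with `category`, `n`, `q25`, `median`, `q75`.
#' @export
category_summary <- function(categories, other_means) {
  om <- as.data.table(other_means)[, .(window_id, mean_level)]
  j <- as.data.table(categories)[om, on = "window_id", nomatch = NULL]
  j <- j[!is.na(mean_level)]
  j[, .(n = .N,
        q25 = unname(quantile(mean_level, 0.25)),
        median = median(mean_level),
        q75 = unname(quantile(mean_level, 0.75))),
    by = category][order(category)]
}

#' Screen windows above a methylation threshold
#'
#' Returns testable windows whose mean level strictly exceeds
#' `threshold` — used with blastocyst methylomes at 70% to find
#' demethylation-protected loci. The fraction of all testable windows
#' passing is attached as attribute `fraction_of_testable`.
#'
#' @param means a [window_means()] table.
#' @param threshold strict lower bound in percent (default 70).
#' @return subset of rows with `mean_level > threshold`.
#' @export
screen_windows_above <- function(means, threshold = 70) {
  m <- as.data.table(means)
  testable <- m[!is.na(mean_level)]
  hit <- testable[mean_level > threshold]
  attr(hit, "fraction_of_testable") <-
    if (nrow(testable) > 0) nrow(hit) / nrow(testable) else NA_real_
  hit
}

#' Assign each window a genomic location label
#'
#' Any-overlap semantics with the priority promoter > exon > intron >
#' intergenic: a window overlapping both a promoter and an exon is
#' labelled `promoter`.
#'
#' @param windows region table with `chrom`, `start`, `end` (e.g.
#'   `win$windows`).
#' @param promoters promoter region table (see [define_promoters()]).
#' @param transcripts BED12 transcript table (with `exon_starts`,
#'   `exon_sizes`) for exon and gene-span intervals.
#' @return character vector of labels, one per window row.
#' @export
assign_window_location <- function(windows, promoters, transcripts) {
  w_gr <- .regions_gr(windows)
  exons <- .transcript_exons(transcripts)
  lab <- rep("intergenic", length(w_gr))
  span_hit <- IRanges::overlapsAny(w_gr, .regions_gr(transcripts),
                                   ignore.strand = TRUE)
  lab[span_hit] <- "intron"
  exon_hit <- IRanges::overlapsAny(w_gr, .regions_gr(exons),
                                   ignore.strand = TRUE)
  lab[exon_hit] <- "exon"
  prom_hit <- IRanges::overlapsAny(w_gr, .regions_gr(promoters),
                                   ignore.strand = TRUE)
  lab[prom_hit] <- "promoter"
  lab
}

# internal: exon intervals from a BED12-derived transcript table
.transcript_exons <- function(transcripts) {
  tr <- as.data.table(transcripts)
  rbindlist(lapply(seq_len(nrow(tr)), function(i) {
    es <- tr$exon_starts[[i]]; sz <- tr$exon_sizes[[i]]
    data.table(chrom = tr$chrom[i], start = tr$start[i] + es,
               end = tr$start[i] + es + sz, strand = tr$strand[i],
               kind = "exon", name = tr$name[i])
  }))
}

#' Smooth a methylome into fixed-width genomic bins
#'
#' Mean of per-CpG levels within non-overlapping bins of `bin_width` bp
#' (default 50 kb); bins without covered CpGs are absent from the output.
#'
#' @param track a depth-filtered `MethylomeTrack`.
#' @param bin_width bin width in bp.
#' @return `data.table` with `chrom`, `start`, `end`, `n_cpgs`,
#'   `mean_level`.
#' @export
bin_smooth <- function(track, bin_width = 50000) {
  lev <- track_levels(track)
  lev <- lev[!is.na(level)]
  lev[, bin := pos %/% as.integer(bin_width)]
  out <- lev[, .(n_cpgs = .N, mean_level = mean(level)), by = .(chrom, bin)]
  out[, `:=`(start = bin * as.integer(bin_width),
             end = (bin + 1L) * as.integer(bin_width))]
  setorder(out, chrom, start)
  out[, .(chrom, start, end, n_cpgs, mean_level)]
}

#' Average methylation profile around transcription start sites
#'
#' Mean methylation of CpGs within `flank` bp of each TSS, averaged
#' across genes in strand-aware relative coordinates (upstream is
#' negative; minus-strand genes are flipped) and smoothed into
#' non-overlapping `bin_width` bp bins.
#'
#' @param track a depth-filtered `MethylomeTrack`.
#' @param transcripts transcript region table with `strand`.
#' @param flank half-width of the profile in bp (default 5000).
#' @param bin_width bin width in bp (default 5).
#' @return `data.table` with `bin_start` (relative to TSS), `n_cpgs`,
#'   `mean_level`; `2 * flank / bin_width` possible bins, empty bins
#'   omitted.
#' @export
tss_meta_profile <- function(track, transcripts, flank = 5000, bin_width = 5) {
  tr <- as.data.table(transcripts)
  if (nrow(tr) == 0) stop("empty gene set")
  tss <- ifelse(tr$strand == "-", tr$end - 1L, tr$start)
  lev <- track_levels(track)
  lev <- lev[!is.na(level)]
  pieces <- lapply(seq_len(nrow(tr)), function(i) {
    x <- lev[chrom == tr$chrom[i] & pos >= tss[i] - flank &
               pos < tss[i] + flank]
    if (nrow(x) == 0) return(NULL)
    rel <- x$pos - tss[i]
    if (tr$strand[i] == "-") rel <- -rel - 1L
    data.table(rel = rel, level = x$level)
  })
  all <- rbindlist(pieces)
  if (is.null(all) || nrow(all) == 0)
    return(data.table(bin_start = integer(), n_cpgs = integer(),
                      mean_level = numeric()))
  all[, bin := (rel + as.integer(flank)) %/% as.integer(bin_width)]
  out <- all[, .(n_cpgs = .N, mean_level = mean(level)), by = bin]
  out[, bin_start := bin * as.integer(bin_width) - as.integer(flank)]
  setorder(out, bin_start)
  out[, .(bin_start, n_cpgs, mean_level)]
}
utils::globalVariables(c("bin_start"))

#' Per-CpG density and the methylation-by-density curve
#'
#' The CpG density of a reference CpG is the number of reference CpGs
#' (including itself) within 100 bp upstream and downstream, divided by
#' 200. The curve reports, for each density value, the mean methylation
#' level in each track, restricted to density values carrying more than
#' `min_sites` CpGs covered in every track, and optionally to CpGs
#' inside a region set (e.g. one repeat family).
#'
#' @param tracks named list of depth-filtered `MethylomeTrack`s.
#' @param cpg_map reference CpG map (`chrom`, `pos`).
#' @param flank density half-window in bp (default 100).
#' @param min_sites minimum CpGs covered in all tracks per density value
#'   (strict, default 1000).
#' @param regions optional region table restricting the CpGs considered.
#' @return list with `density` (per-CpG table) and `curve`
#'   (`density`, `n_sites`, one mean-level column per track).
#' @export
cpg_density_curve <- function(tracks, cpg_map, flank = 100, min_sites = 1000,
                              regions = NULL) {
  map <- as.data.table(cpg_map)[, .(chrom, pos)]
  setorder(map, chrom, pos)
  map[, density := {
    p <- pos
    (findInterval(p + flank, p) - findInterval(p - flank - 1L, p)) / (2 * flank)
  }, by = chrom]
  if (!is.null(regions)) {
    keep <- IRanges::overlapsAny(.points_gr(map$chrom, map$pos),
                                 .regions_gr(regions))
    map <- map[keep]
  }
  cov_tabs <- lapply(tracks, function(tk) {
    lev <- track_levels(tk)[!is.na(level), .(chrom, pos, level)]
    lev[map, on = c("chrom", "pos"), nomatch = NULL]
  })
  covered_all <- Reduce(function(a, b) {
    a[b[, .(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]
  }, c(list(map[, .(chrom, pos, density)]),
       lapply(cov_tabs, function(x) x[, .(chrom, pos)])))
  dens_n <- covered_all[, .(n_sites = .N), by = density]
  keep_dens <- dens_n[n_sites > min_sites, density]
  curve <- dens_n[density %in% keep_dens]
  for (nm in names(tracks)) {
    tab <- cov_tabs[[nm]][covered_all[, .(chrom, pos, density)],
                          on = c("chrom", "pos"), nomatch = NULL]
    mm <- tab[density %in% keep_dens, .(m = mean(level)), by = density]
    curve[mm, on = "density", (nm) := m]
  }
  setorder(curve, density)
  list(density = map[], curve = curve[])
}
utils::globalVariables(c("m", "n_sites"))
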