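test_that("window construction follows the closed-form count and spans", {
  map20 <- data.table(chrom = "chr1", pos = seq_len(20) * 10L)
  expect_equal(nrow(build_cpg_windows(map20)$windows), 1)

  map45 <- data.table(chrom = "chr1", pos = seq_len(45) * 10L)
  w <- build_cpg_windows(map45)$windows
  expect_equal(nrow(w), 3)
  expect_equal(w$first_idx, c(1L, 11L, 21L))
  expect_equal(w$last_idx, c(20L, 30L, 40L))
  expect_equal(w$start, c(10L, 110L, 210L))
  expect_equal(w$end, c(202L, 302L, 402L))   # last dyad spans 2 bp

  set.seed(3)
  for (i in 1:10) {
    N <- sample(25:400, 1); W <- sample(5:25, 1)
    step <- sample(seq_len(W), 1)
    map <- data.table(chrom = "c", pos = sort(sample.int(1e5, N)))
    nw <- nrow(build_cpg_windows(map, W = W, step = step)$windows)
    expect_equal(nw, floor((N - W) / step) + 1)
  }

  # interior CpGs belong to exactly two windows at step = W/2
  w2 <- build_cpg_windows(data.table(chrom = "c", pos = seq_len(100) * 5L))
  counts <- table(unlist(mapply(seq, w2$windows$first_idx,
                                w2$windows$last_idx)))
  interior <- counts[as.integer(names(counts)) > 10 &
                       as.integer(names(counts)) <= 90]
  expect_true(all(interior == 2))

  expect_error(build_cpg_windows(data.table(chrom = "c", pos = 1:5 * 10L)),
               "enough CpGs")
})

test_that("window means require sufficient covered CpGs and match region means", {
  map <- data.table(chrom = "chr1", pos = seq_len(20) * 10L)
  win <- build_cpg_windows(map)
  tr12 <- make_track("chr1", (1:12) * 10L, rep(4, 12), rep(4, 12))
  expect_equal(window_means(win, tr12)$mean_level, 100.0)
  expect_equal(window_means(win, tr12)$n_covered, 12L)
  tr9 <- make_track("chr1", (1:9) * 10L, rep(4, 9), rep(4, 9))
  expect_true(is.na(window_means(win, tr9)$mean_level))

  # cross-module oracle: window mean equals region_mean_level on its span
  tr <- random_track(6, n = 20, spacing = 10)
  wm <- window_means(win, tr, min_covered = 1)
  expect_equal(wm$mean_level,
               region_mean_level(tr$calls$meth, tr$calls$total))
})

test_that("change classification is stable on identity and antisymmetric on swap", {
  sc <- simulate_window_shift_scenario(19, n_windows = 100, n_planted = 10)
  cc_self <- classify_window_changes(sc$win, sc$track_a, sc$track_a)
  expect_true(all(cc_self$call %in% c("stable", "untestable")))
  expect_true(all(cc_self[call == "stable", delta] == 0))

  ab <- classify_window_changes(sc$win, sc$track_a, sc$track_b)
  ba <- classify_window_changes(sc$win, sc$track_b, sc$track_a)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p, ba$p)
  expect_equal(sum(ab$call == "increasing"), sum(ba$call == "decreasing"))
  expect_equal(sum(ab$call == "decreasing"), sum(ba$call == "increasing"))

  # calls partition testable windows
  expect_true(all(ab$call %in% c("increasing", "decreasing", "stable",
                                 "untestable")))
})

test_that("per-window t-tests agree with the scalar implementation", {
  sc <- simulate_window_shift_scenario(29, n_windows = 50, n_planted = 5,
                                       depth = 15)
  cc <- classify_window_changes(sc$win, sc$track_a, sc$track_b)
  la <- track_levels(sc$track_a)
  lb <- track_levels(sc$track_b)
  w <- sc$win$windows
  set.seed(1)
  for (i in sample(nrow(w), 10)) {
    pos_range <- sc$win$cpg_map[w$first_idx[i]:w$last_idx[i], pos]
    va <- la[pos %in% pos_range & total > 0, level]
    vb <- lb[pos %in% pos_range & total > 0, level]
    r <- student_t_test(va, vb)
    expect_equal(cc[window_id == w$window_id[i], p], r$p_value,
                 tolerance = 1e-12)
  }
})

test_that("gamete window categories use inclusive 80/20 thresholds", {
  mk <- function(oo, sp) categorize_gamete_windows(
    data.table(window_id = "w", mean_level = oo),
    data.table(window_id = "w", mean_level = sp))$category
  expect_equal(mk(90, 10), "oocyte_specific")
  expect_equal(mk(80, 20), "oocyte_specific")   # inclusive thresholds
  expect_equal(mk(79.9, 10), "other")
  expect_equal(mk(10, 90), "sperm_specific")
  expect_equal(mk(85, 95), "both_hyper")
  expect_equal(mk(5, 15), "both_hypo")
  expect_equal(mk(50, 50), "other")

  # untestable in either gamete drops the window
  out <- categorize_gamete_windows(
    data.table(window_id = c("w1", "w2"), mean_level = c(90, NA)),
    data.table(window_id = c("w1", "w2"), mean_level = c(10, 50)))
  expect_equal(out$window_id, "w1")
})

test_that("protection screen is strict and reports the testable fraction", {
  m <- data.table(window_id = paste0("w", 1:4), n_covered = 12L,
                  mean_level = c(70.0, 70.1, 90, NA))
  hit <- screen_windows_above(m, 70)
  expect_equal(hit$window_id, c("w2", "w3"))
  expect_equal(attr(hit, "fraction_of_testable"), 2 / 3)
  m0 <- data.table(window_id = "w", n_covered = 12L, mean_level = 0)
  expect_equal(nrow(screen_windows_above(m0, 70)), 0)
})

test_that("window location labels follow the promoter > exon > intron priority", {
  tr <- data.table(chrom = "chr1", start = 10000L, end = 30000L,
                   strand = "+", kind = "transcript", name = "G1",
                   gene_id = "G1",
                   exon_starts = list(c(0L, 9000L, 19500L)),
                   exon_sizes = list(c(500L, 1000L, 500L)))
  prom <- define_promoters(tr)
  wins <- data.table(chrom = "chr1",
                     start = c(10500L, 19200L, 15000L, 50000L, 9500L),
                     end = c(11500L, 20200L, 15500L, 51000L, 10400L))
  lab <- assign_window_location(wins, prom, tr)
  # w1 overlaps promoter [9000,11000) and exon 1 -> promoter wins
  expect_equal(lab, c("promoter", "exon", "intron", "intergenic",
                      "promoter"))

  # randomized fixtures against a brute-force any-overlap checker
  set.seed(41)
  rw <- data.table(chrom = "chr1",
                   start = st <- sample.int(60000, 60),
                   end = st + sample(200:3000, 60, replace = TRUE))
  got <- assign_window_location(rw, prom, tr)
  overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  exons <- data.table(start = tr$start + tr$exon_starts[[1]],
                      end = tr$start + tr$exon_starts[[1]] +
                        tr$exon_sizes[[1]])
  want <- vapply(seq_len(nrow(rw)), function(i) {
    if (any(overlap(rw$start[i], rw$end[i], prom$start, prom$end)))
      "promoter"
    else if (any(overlap(rw$start[i], rw$end[i], exons$start, exons$end)))
      "exon"
    else if (overlap(rw$start[i], rw$end[i], tr$start, tr$end)) "intron"
    else "intergenic"
  }, "")
  expect_equal(got, want)
})

test_that("bin smoothing averages per-CpG levels within fixed bins", {
  tr <- make_track("chr1", c(1000, 2000, 60000), c(3, 3, 3), c(5, 5, 5))
  b <- bin_smooth(tr, bin_width = 50000)
  expect_equal(b$mean_level, c(60, 60))
  expect_equal(b$n_cpgs, c(2L, 1L))
  expect_equal(b$start, c(0L, 50000L))

  # chromosome processing order does not matter
  t2 <- make_track(c("chr2", "chr1"), c(100, 100), c(1, 4), c(5, 5))
  b2 <- bin_smooth(t2)
  expect_equal(b2$chrom, c("chr1", "chr2"))
  expect_equal(b2$mean_level, c(80, 20))
})

test_that("TSS profiles are strand-aware and flat on flat methylomes", {
  tr_plus <- data.table(chrom = "chr1", start = 20000L, end = 40000L,
                        strand = "+", kind = "transcript", name = "G",
                        gene_id = "G", exon_starts = list(0L),
                        exon_sizes = list(20000L))
  flat <- make_track("chr1", seq(15000, 45000, by = 100),
                     rep(4, 301), rep(5, 301))
  prof <- tss_meta_profile(flat, tr_plus)
  expect_true(all(abs(prof$mean_level - 80) < 1e-9))
  expect_true(all(prof$bin_start >= -5000 & prof$bin_start < 5000))

  # a minus-strand gene whose CpG layout mirrors the plus-strand gene
  # produces the identical profile
  set.seed(13)
  rel <- sort(sample(seq(-4995, 4995, by = 10), 120))
  meth <- rbinom(120, 10, seq(0.1, 0.9, length.out = 120))
  tr_p <- make_track("chr1", 20000 + rel, meth, rep(10, 120))
  tr_m <- make_track("chr1", 60000 - rel - 1, meth, rep(10, 120))
  g_p <- data.table(chrom = "chr1", start = 20000L, end = 30000L,
                    strand = "+", kind = "transcript", name = "P",
                    gene_id = "P", exon_starts = list(0L),
                    exon_sizes = list(10000L))
  g_m <- data.table(chrom = "chr1", start = 50001L, end = 60001L,
                    strand = "-", kind = "transcript", name = "M",
                    gene_id = "M", exon_starts = list(0L),
                    exon_sizes = list(10000L))
  expect_equal(tss_meta_profile(tr_p, g_p), tss_meta_profile(tr_m, g_m))

  expect_error(tss_meta_profile(flat, tr_plus[0]), "empty gene set")
})

test_that("CpG density matches brute-force counting and self-inclusion", {
  pos <- c(500L, 5000L, 5050L, 5100L, 5120L, 9000L)
  map <- data.table(chrom = "chr1", pos = pos)
  tr <- make_track("chr1", pos, rep(2, 6), rep(4, 6))
  out <- cpg_density_curve(list(s = tr), map, min_sites = 0)
  expect_equal(out$density$density, brute_density(pos))
  expect_equal(out$density[pos == 500, density], 1 / 200)  # isolated CpG
  expect_equal(out$density[pos == 5050, density], 4 / 200)

  # a CpG with 9 neighbours inside +-100 bp has density 10/200
  pos10 <- c(0L, seq(1000L, 1090L, by = 10L))
  map10 <- data.table(chrom = "chr1", pos = pos10)
  tr10 <- make_track("chr1", pos10, rep(1, 11), rep(2, 11))
  d10 <- cpg_density_curve(list(s = tr10), map10, min_sites = 0)
  expect_equal(d10$density[pos == 1040, density], 10 / 200)

  # curve restricted to densities covered in all tracks
  tr_b <- make_track("chr1", pos[1:3], rep(4, 3), rep(4, 3))
  curve <- cpg_density_curve(list(a = tr, b = tr_b), map,
                             min_sites = 0)$curve
  expect_true(all(curve$n_sites >= 1))
  expect_true(all(c("a", "b") %in% names(curve)))
})
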