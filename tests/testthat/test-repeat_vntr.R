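test_that("family methylation pools CpGs across copies", {
  reps <- data.table(chrom = "chr1", start = c(0L, 1000L), end = c(500L, 1500L),
                     strand = "+", kind = "repeat_copy", name = "FAM1",
                     rep_class = "SVA")
  tr <- make_track("chr1", c(100, 200, 1100), c(4, 4, 4), c(4, 4, 4))
  expect_equal(family_methylation(tr, reps)$mean_level, 100.0)

  # equal CpG counts, copies at 0 and 100 -> 50
  tr2 <- make_track("chr1", c(100, 200, 1100, 1200),
                    c(0, 0, 4, 4), c(4, 4, 4, 4))
  expect_equal(family_methylation(tr2, reps)$mean_level, 50.0)

  # unequal CpG counts: pooled value weights the CpG-rich copy
  tr3 <- make_track("chr1", c(100, 150, 200, 1100),
                    c(0, 0, 0, 4), c(4, 4, 4, 4))
  out <- family_methylation(tr3, reps)
  expect_equal(out$mean_level, 25.0)      # pooled: (0+0+0+100)/4
  expect_equal(out$n_cpgs, 4L)            # copy-averaged would be 50
})

test_that("protection screen ranks by overlap proportion above the copy floor", {
  mk_copies <- function(name, n, chrom = "chr1", offset = 0L)
    data.table(chrom = chrom, start = offset + (0:(n - 1)) * 1000L,
               end = offset + (0:(n - 1)) * 1000L + 300L, strand = "+",
               kind = "repeat_copy", name = name, rep_class = "X")
  reps <- rbind(mk_copies("BIG", 150), mk_copies("SMALL", 99, offset = 500L))
  prot <- data.table(chrom = "chr1", start = c(0L, 1000L, 1500L),
                     end = c(100L, 1100L, 1600L))
  out <- protection_screen(reps, prot)
  expect_equal(out[name == "BIG", n_protected], 2L)
  expect_equal(out[name == "SMALL", proportion_protected], 1 / 99)
  expect_false(out[name == "SMALL", ranked])   # <=100 copies excluded
  expect_true(out[name == "BIG", ranked])
  expect_equal(out[1, name], "BIG")

  none <- protection_screen(reps, prot[0])
  expect_true(all(none$proportion_protected == 0))
})

test_that("raising the screen threshold never raises protection proportions", {
  truth <- build_reference(61, n_chroms = 2, chrom_len = 5e5)
  tracks <- simulate_methylomes(truth, seed = 62)
  bl <- filter_study(tracks)$blastocyst
  win <- build_cpg_windows(truth$cpg_map)
  m <- window_means(win, bl)
  for (th in c(70, 80, 90)) {
    hit <- screen_windows_above(m, th)
    regions <- win$windows[hit, on = "window_id", nomatch = NULL]
    scr <- protection_screen(truth$repeats, regions)
    if (th == 70) prev <- scr else {
      j <- scr[prev, on = "name"]
      expect_true(all(j$proportion_protected <=
                        j$i.proportion_protected + 1e-12))
      prev <- scr
    }
  }
})

test_that("naive tandem detector scores perfect arrays at 2 per base", {
  seq160 <- paste(rep("ACGT", 40), collapse = "")
  hit <- detect_tandem_repeats_naive(seq160)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$period, 4L)
  expect_equal(hit$copies, 40)
  expect_equal(hit$score, 320L)
  expect_equal(hit$consensus, "ACGT")

  # below the score threshold
  expect_equal(nrow(detect_tandem_repeats_naive(
    paste(rep("ACGT", 10), collapse = ""))), 0)

  # random non-repetitive sequence yields nothing
  set.seed(3)
  for (i in 1:3) {
    rnd <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")
    expect_equal(nrow(detect_tandem_repeats_naive(rnd)), 0)
  }

  expect_error(detect_tandem_repeats_naive("ACGU"), "non-ACGTN")
})

test_that("naive tandem detector finds every planted array in context", {
  set.seed(9)
  planted <- list(c(period = 7, copies = 30), c(period = 25, copies = 9),
                  c(period = 120, copies = 3))
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
  pieces <- character(0); truth_pos <- integer(0); cursor <- 0L
  for (pl in planted) {
    gap <- flank(400)
    unit <- flank(pl["period"])
    arr <- paste(rep(unit, pl["copies"]), collapse = "")
    pieces <- c(pieces, gap, arr)
    truth_pos <- c(truth_pos, cursor + 400L)
    cursor <- cursor + 400L + nchar(arr)
  }
  s <- paste(c(pieces, flank(400)), collapse = "")
  hits <- detect_tandem_repeats_naive(s)
  for (i in seq_along(planted)) {
    ov <- hits[start < truth_pos[i] + planted[[i]]["period"] *
                 planted[[i]]["copies"] & end > truth_pos[i]]
    expect_gte(nrow(ov), 1)
    expect_equal(ov$period[1], unname(planted[[i]]["period"]))
  }
})

test_that("top-VNTR selection maximises score with length then position tiebreaks", {
  v <- data.table(chrom = "chr1", start = c(10L, 100L, 300L),
                  end = c(50L, 260L, 380L), strand = ".", kind = "VNTR",
                  name = c("a", "b", "c"), period = c(10L, 20L, 20L),
                  copies = c(4, 8, 4), score = c(150L, 600L, 600L),
                  consensus = "X")
  region <- data.table(chrom = "chr1", start = 0L, end = 1000L)
  top <- select_top_vntr(region, v)
  expect_equal(top$name, "b")        # tie on 600 -> longer array wins

  far <- data.table(chrom = "chr1", start = 5000L, end = 6000L)
  expect_null(select_top_vntr(far, v))
  expect_null(select_top_vntr(region, v[0]))
})

test_that("VNTR enrichment builds conserved 2x2 counts and detects planted rates", {
  v <- data.table(chrom = "chr1", start = c(100L, 900L), end = c(200L, 950L),
                  strand = ".", kind = "VNTR", name = c("v1", "v2"),
                  period = 10L, copies = 5, score = 200L, consensus = "X")
  grp <- data.table(chrom = "chr1", start = c(150L, 400L), end = c(250L, 500L))
  out <- vntr_enrichment(grp, grp, v)
  expect_equal(unname(out$counts["group_with"]), 1)
  expect_equal(out$test$p_value, 1)   # group == background
  expect_equal(out$counts[["group_with"]] + (out$counts[["group_total"]] -
                                               out$counts[["group_with"]]),
               nrow(grp))
  expect_error(vntr_enrichment(grp[0], grp, v), "empty")

  # exact planting at 25% vs 6% rates and the catalogue sizes is always
  # detected: the group carries round(0.25 * 44) = 11 VNTRs, the large
  # background fluctuates binomially around 6%
  set.seed(15)
  sig <- vapply(1:50, function(i) {
    b <- rbinom(1, 27718, 0.06)
    chi_square_2x2(11, 33, b, 27718 - b)$p_value < 1e-4
  }, NA)
  expect_gte(mean(sig), 0.99)
})

test_that("CGI protection contingency uses a strict 70% threshold", {
  cgis <- data.table(chrom = "chr1", start = (0:3) * 1000L,
                     end = (0:3) * 1000L + 500L, strand = ".",
                     kind = "CGI", name = paste0("c", 1:4))
  v <- data.table(chrom = "chr1", start = c(100L, 1100L),
                  end = c(200L, 1200L), strand = ".", kind = "VNTR",
                  name = c("v1", "v2"), period = 10L, copies = 5,
                  score = 200L, consensus = "X")
  out <- cgi_protection_by_vntr(cgis, c(90, 70.0, 60, 80), v)
  # 70.0 exactly is NOT protected (strict >)
  expect_equal(out$counts["VNTR", "protected"], 1L)
  expect_equal(out$counts["VNTR", "not_protected"], 1L)
  expect_equal(out$counts["no_VNTR", "protected"], 1L)

  # all below threshold: clean NULL test with zero protected margin
  expect_message(
    out0 <- cgi_protection_by_vntr(cgis, c(10, 20, 30, 40), v),
    "not computable")
  expect_null(out0$test)
  expect_equal(sum(out0$counts[, "protected"]), 0L)

  # generator-planted protection effect gives odds ratio > 1
  truth <- build_reference(71, n_chroms = 2, chrom_len = 5e5)
  tracks <- simulate_methylomes(truth, seed = 72)
  f <- filter_study(tracks)
  bh <- truth$cgis[category == "both_hyper" & chrom != "chrX"]
  bl <- region_means(bh, f$blastocyst, 10)
  res <- cgi_protection_by_vntr(bh, bl$mean_level, admit_vntrs(truth$vntrs))
  or <- (res$counts[1, 1] * res$counts[2, 2]) /
    max(1, res$counts[1, 2] * res$counts[2, 1])
  expect_gt(or, 1)
})

test_that("VNTR feature comparison isolates the shifted feature", {
  mk <- function(n, period, copies) data.table(
    chrom = "chr1", start = 0L, end = 100L, strand = ".", kind = "VNTR",
    name = paste0("v", seq_len(n)), period = period, copies = copies,
    score = as.integer(2 * period * copies), consensus = "X")
  set.seed(27)
  a <- mk(100, sample(30:50, 100, TRUE), rnorm(100, 14, 2))
  b <- mk(100, sample(30:50, 100, TRUE), rnorm(100, 8, 2))
  out <- compare_vntr_features(a, b)
  expect_lt(out[feature == "copies", p], 0.05)
  expect_gt(out[feature == "period", p], 0.05)

  same <- compare_vntr_features(a, a)
  expect_true(all(same$p == 1))

  single <- compare_vntr_features(a[1], b[1])
  expect_equal(nrow(single), 3)
  expect_true(all(single$p >= 0 & single$p <= 1))
  expect_error(compare_vntr_features(a[0], b), "non-empty")
})
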