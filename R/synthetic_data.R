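# Synthetic multi-sample methylome generator with planted ground truth.
#
# The generator builds a miniature genome (CpG map with CGI-like dense
# clusters, genes, repeat families including a VNTR-bearing protected
# family, an imprinted-DMR catalogue) and simulates bisulfite read
# counts for oocyte, sperm, blastocyst, blood and ES samples under one
# of two contrasting maternal-genome models:
#
# * human_retention — maternal methylation largely retained in the
#   blastocyst (retention factor applied uniformly), paternal genome
#   globally demethylated; paternal gDMRs maintained.
# * mouse_passive — maternal methylation halved per replication round
#   (replication-dependent passive demethylation), gDMRs exempt through
#   maintenance of the methylated allele.
#
# Every planted label (gamete category, DMR class, protected family,
# expression class) is recoverable from the simulated tracks, which is
# what the recovery tests assert.

.SAMPLES <- c("oocyte", "sperm", "blood", "ES")

#' Build a synthetic reference genome with planted truth
#'
#' Lays out, per chromosome, a gene zone (genes 8-16 kb with 3 exons)
#' and a feature zone of CGIs, imprinted DMRs, a VNTR-bearing
#' SVA-like repeat family, and a VNTR-free Alu-like control family.
#' Background CpGs sit every ~100 bp; CpG-rich features carry one CpG
#' per 10 bp. The third chromosome is `chrX` so X-linked behaviour of
#' oocyte-methylated CGIs in pooled blastocysts can be emulated. The
#' DMR catalogue mirrors the published human imprinted-DMR census:
#' 29 blood-maintained maternal gDMRs, 2 paternal gDMRs, 15
#' placenta-specific maternal gDMRs and 21 secondary DMRs (67 records).
#'
#' @param seed integer seed; the scaffold is deterministic given it.
#' @param n_chroms number of chromosomes (default 3; the last is
#'   `chrX`).
#' @param chrom_len chromosome length in bp (default 2e6).
#' @param cgi_per_chrom CGIs per chromosome (default 60), split across
#'   planted gamete categories.
#' @param sva_per_chrom,alu_per_chrom repeat copies per chromosome
#'   (defaults 40 and 50; both families exceed 100 copies genome-wide).
#' @return a `SyntheticTruth` list: `cpg_map`, `truth_p` (per-CpG true
#'   methylation per sample with `maintained`/`protected` roles),
#'   `cgis`, `dmr_catalogue`, `repeats`, `vntrs`, `transcripts`,
#'   `expression`, `noncpg`, `spike`, `params`.
#' @export
build_reference <- function(seed, n_chroms = 3, chrom_len = 2e6,
                            cgi_per_chrom = 60, sva_per_chrom = 40,
                            alu_per_chrom = 50) {
  stopifnot(n_chroms >= 1, chrom_len >= 2e5)
  set.seed(seed)
  chroms <- if (n_chroms >= 3)
    c(paste0("chr", seq_len(n_chroms - 1)), "chrX")
  else paste0("chr", seq_len(n_chroms))

  # baseline per-sample methylation by compartment
  base_p <- c(oocyte = 0.55, sperm = 0.85, blood = 0.80, ES = 0.80)

  # DMR catalogue counts mirror the published census, spread over chroms
  dmr_classes <- c(rep("M_gDMR", 29), rep("P_gDMR", 2),
                   rep("placenta_specific_M_gDMR", 15), rep("sDMR", 21))
  dmr_classes <- sample(dmr_classes)
  dmr_chrom <- rep(chroms[chroms != "chrX"], length.out = length(dmr_classes))

  cgi_cats <- c(rep("both_hypo", 20), rep("oocyte_specific", 16),
                rep("sperm_specific", 8), rep("both_hyper", 16))
  stopifnot(length(cgi_cats) <= cgi_per_chrom)

  all_cpgs <- list(); all_cgis <- list(); all_dmrs <- list()
  all_reps <- list(); all_vntrs <- list(); all_tr <- list()
  truth_rows <- list()
  dmr_i <- 0L

  add_cpgs <- function(chrom, pos, p_oo, p_sp, p_bl, p_es,
                       maintained = "none", protected = FALSE) {
    data.table(chrom = chrom, pos = as.integer(pos),
               p_oocyte = p_oo, p_sperm = p_sp, p_blood = p_bl, p_ES = p_es,
               maintained = maintained, protected = protected)
  }

  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    gene_zone_end <- round(0.4 * chrom_len)

    # --- genes -----------------------------------------------------------
    cursor <- 2000
    gi <- 0L
    while (cursor + 20000 < gene_zone_end) {
      gi <- gi + 1L
      glen <- round(stats::runif(1, 8000, 16000))
      gstart <- cursor
      gend <- gstart + glen
      strand <- sample(c("+", "-"), 1)
      # 3 exons: first/last 500 bp plus a middle 1 kb
      ex_st <- c(0L, as.integer(glen %/% 2 - 500L), as.integer(glen - 500L))
      ex_sz <- c(500L, 1000L, 500L)
      name <- sprintf("%s_gene%03d", ch, gi)
      all_tr[[length(all_tr) + 1]] <- data.table(
        chrom = ch, start = gstart, end = gend, strand = strand,
        kind = "transcript", name = name, gene_id = name,
        exon_starts = list(ex_st), exon_sizes = list(ex_sz))
      cursor <- gend + 4000
    }

    # --- feature zone slots ---------------------------------------------
    # slot width adapts to the feature demand; 1.2 kb is the minimum that
    # holds the widest feature (800 bp repeat copy) with flanking margin
    need <- cgi_per_chrom + sum(dmr_chrom == ch) + sva_per_chrom +
      alu_per_chrom
    zone <- chrom_len - gene_zone_end
    slot_w <- min(3000, max(1200, zone %/% (need + 1)))
    slots <- seq(gene_zone_end, chrom_len - slot_w, by = slot_w)
    if (length(slots) < need)
      stop("chromosome too short for the requested feature counts: ",
           need, " features need >= ", need * 1200 + gene_zone_end, " bp")
    slots <- sample(slots, need)
    s_at <- 0L
    take_slot <- function() {
      s_at <<- s_at + 1L
      slots[s_at]
    }

    # CGIs (600 bp, CpG every 10 bp -> 60 CpGs)
    cats <- c(cgi_cats, rep("both_hypo", cgi_per_chrom - length(cgi_cats)))
    for (k in seq_len(cgi_per_chrom)) {
      st <- take_slot() + 150L
      en <- st + 600L
      cat_k <- cats[k]
      nm <- sprintf("%s_CGI%03d", ch, k)
      has_vntr <- (cat_k == "both_hyper" && k %% 2 == 0) ||
        (cat_k != "both_hyper" && stats::runif(1) < 0.05)
      all_cgis[[length(all_cgis) + 1]] <- data.table(
        chrom = ch, start = st, end = en, strand = ".", kind = "CGI",
        name = nm, category = cat_k, has_vntr = has_vntr)
      p <- switch(cat_k,
                  both_hypo = c(0.03, 0.03),
                  oocyte_specific = c(0.90, 0.05),
                  sperm_specific = c(0.05, 0.90),
                  both_hyper = c(0.90, 0.90))
      # somatic levels: hyper CGIs stay methylated in soma, others low
      p_soma <- if (cat_k == "both_hypo") 0.05 else 0.85
      pos <- seq(st, en - 10L, by = 10L)
      truth_rows[[length(truth_rows) + 1]] <- add_cpgs(
        ch, pos, p[1], p[2], p_soma, p_soma,
        protected = has_vntr && cat_k == "both_hyper")
      if (has_vntr) {
        period <- 40L
        copies <- if (cat_k == "both_hyper") round(stats::runif(1, 12, 18), 1)
        else round(stats::runif(1, 5, 9), 1)
        vst <- st + 100L
        ven <- vst + as.integer(round(period * copies))
        all_vntrs[[length(all_vntrs) + 1]] <- data.table(
          chrom = ch, start = vst, end = ven, strand = ".", kind = "VNTR",
          name = sprintf("%s:%d-%d", ch, vst, ven), period = period,
          copies = copies, score = as.integer(2 * period * copies),
          consensus = paste(sample(c("A", "C", "G", "T"), period,
                                   replace = TRUE), collapse = ""))
      }
    }

    # imprinted DMRs (600 bp, CpG every 10 bp)
    for (k in which(dmr_chrom == ch)) {
      dmr_i <- dmr_i + 1L
      st <- take_slot() + 150L
      en <- st + 600L
      cls <- dmr_classes[k]
      nm <- sprintf("DMR%02d", dmr_i)
      p <- switch(cls,
                  M_gDMR = c(oo = 0.92, sp = 0.05, bl = 0.50),
                  P_gDMR = c(oo = 0.05, sp = 0.92, bl = 0.50),
                  placenta_specific_M_gDMR = c(oo = 0.92, sp = 0.05, bl = 0.05),
                  sDMR = c(oo = 0.55, sp = 0.50, bl = 0.50))
      maintained <- switch(cls,
                           M_gDMR = "maternal_gdmr",
                           placenta_specific_M_gDMR = "maternal_gdmr",
                           P_gDMR = "paternal_gdmr",
                           sDMR = "none")
      # ~1/3 of maintained gDMRs lose intermediate methylation in ES
      es_lost <- cls %in% c("M_gDMR", "P_gDMR") && stats::runif(1) < 11 / 31
      p_es <- if (es_lost) 0.92 else p[["bl"]]
      has_vntr <- cls %in% c("M_gDMR", "placenta_specific_M_gDMR") &&
        stats::runif(1) < 0.25
      has_vntr <- has_vntr || cls == "P_gDMR"   # both paternal gDMRs carry one
      all_dmrs[[length(all_dmrs) + 1]] <- data.table(
        chrom = ch, start = st, end = en, strand = ".", kind = "DMR",
        name = nm, true_class = cls,
        placenta_maintained = cls == "placenta_specific_M_gDMR",
        es_lost = es_lost, has_vntr = has_vntr)
      pos <- seq(st, en - 10L, by = 10L)
      truth_rows[[length(truth_rows) + 1]] <- add_cpgs(
        ch, pos, p[["oo"]], p[["sp"]], p[["bl"]], p_es,
        maintained = maintained)
      if (has_vntr) {
        period <- 30L
        copies <- round(stats::runif(1, 6, 12), 1)
        vst <- st + 80L
        ven <- vst + as.integer(round(period * copies))
        all_vntrs[[length(all_vntrs) + 1]] <- data.table(
          chrom = ch, start = vst, end = ven, strand = ".", kind = "VNTR",
          name = sprintf("%s:%d-%d", ch, vst, ven), period = period,
          copies = copies, score = as.integer(2 * period * copies),
          consensus = paste(sample(c("A", "C", "G", "T"), period,
                                   replace = TRUE), collapse = ""))
      }
    }

    # SVA-like protected family (800 bp copy; VNTR in the middle 480 bp)
    for (k in seq_len(sva_per_chrom)) {
      st <- take_slot() + 150L
      en <- st + 800L
      nm <- "SVA_SYN"
      all_reps[[length(all_reps) + 1]] <- data.table(
        chrom = ch, start = st, end = en, strand = "+",
        kind = "repeat_copy", name = nm, rep_class = "SVA",
        rep_family = "SVA", protected = TRUE)
      vst <- st + 160L
      ven <- vst + 480L
      all_vntrs[[length(all_vntrs) + 1]] <- data.table(
        chrom = ch, start = vst, end = ven, strand = ".", kind = "VNTR",
        name = sprintf("%s:%d-%d", ch, vst, ven), period = 40L,
        copies = 12, score = 960L,
        consensus = paste(sample(c("A", "C", "G", "T"), 40,
                                 replace = TRUE), collapse = ""))
      pos <- c(seq(st, vst - 30L, by = 30L), seq(vst, ven - 10L, by = 10L),
               seq(ven, en - 30L, by = 30L))
      truth_rows[[length(truth_rows) + 1]] <- add_cpgs(
        ch, pos, 0.85, 0.85, 0.85, 0.85, protected = TRUE)
    }

    # Alu-like control family (300 bp copy, CpG every 35 bp)
    for (k in seq_len(alu_per_chrom)) {
      st <- take_slot() + 150L
      en <- st + 300L
      all_reps[[length(all_reps) + 1]] <- data.table(
        chrom = ch, start = st, end = en, strand = "+",
        kind = "repeat_copy", name = "ALU_SYN", rep_class = "SINE",
        rep_family = "Alu", protected = FALSE)
      pos <- seq(st, en - 35L, by = 35L)
      truth_rows[[length(truth_rows) + 1]] <- add_cpgs(
        ch, pos, 0.60, 0.85, 0.80, 0.80)
    }
  }

  transcripts <- rbindlist(all_tr)
  cgis <- rbindlist(all_cgis)
  dmrs <- rbindlist(all_dmrs)
  repeats <- rbindlist(all_reps)
  vntrs <- rbindlist(all_vntrs)

  # expression classes on genes: active genes carry oocyte gene-body
  # methylation, silent genes do not (the bimodal pattern)
  n_genes <- nrow(transcripts)
  active <- stats::runif(n_genes) < 0.6
  rpkm <- ifelse(active, 2^stats::rnorm(n_genes, 3.3, 1.5),
                 stats::runif(n_genes, 0.0005, 0.005))
  expression <- data.table(gene_id = transcripts$gene_id, rpkm = rpkm,
                           expr_class = ifelse(active, "active", "inactive"))

  # gene-body CpGs (every 100 bp inside the body) with expression-coupled
  # oocyte methylation
  bodies <- define_gene_bodies(transcripts)
  for (i in seq_len(nrow(bodies))) {
    g <- bodies[i]
    a <- active[match(g$gene_id, transcripts$gene_id)]
    pos <- seq(g$start + 7L, g$end - 1L, by = 100L)
    if (length(pos) == 0) next
    truth_rows[[length(truth_rows) + 1]] <- add_cpgs(
      g$chrom, pos, if (a) 0.85 else 0.10, 0.85, 0.80, 0.80)
  }

  # background CpGs every ~100 bp outside planted features
  feat <- rbindlist(list(cgis[, .(chrom, start, end)],
                         dmrs[, .(chrom, start, end)],
                         repeats[, .(chrom, start, end)],
                         transcripts[, .(chrom, start, end)]))
  for (ch in chroms) {
    pos <- seq(53L, chrom_len - 2L, by = 101L)
    f <- feat[chrom == ch]
    if (nrow(f) > 0) {
      inside <- IRanges::overlapsAny(
        IRanges::IRanges(pos + 1L, width = 1L),
        IRanges::IRanges(f$start + 1L, f$end))
      pos <- pos[!inside]
    }
    truth_rows[[length(truth_rows) + 1]] <- add_cpgs(
      ch, pos, base_p[["oocyte"]], base_p[["sperm"]],
      base_p[["blood"]], base_p[["ES"]])
  }

  truth_p <- rbindlist(truth_rows)
  setorder(truth_p, chrom, pos)
  truth_p <- unique(truth_p, by = c("chrom", "pos"))
  cpg_map <- truth_p[, .(chrom, pos)]

  # non-CpG cytosines: low CpA-like methylation, oocyte only
  noncpg <- rbindlist(lapply(chroms, function(ch) {
    pos <- sort(sample.int(chrom_len - 2L, 2000))
    data.table(chrom = ch, pos = pos,
               context = sample(c("CHH", "CHG"), 2000, replace = TRUE,
                                prob = c(0.8, 0.2)),
               p_oocyte = 0.056, p_other = 0.005)
  }))
  noncpg <- unique(noncpg, by = c("chrom", "pos"))
  # drop non-CpG positions colliding with CpG dyads
  noncpg <- noncpg[!cpg_map, on = c("chrom", "pos")]

  # unmethylated spike-in contig (lambda-like)
  spike <- data.table(chrom = "lambda_spike",
                      pos = seq(10L, 48000L, by = 48L), context = "CHH")

  structure(list(
    seed = seed, chroms = chroms, chrom_len = chrom_len,
    cpg_map = cpg_map, truth_p = truth_p, cgis = cgis,
    dmr_catalogue = dmrs, repeats = repeats, vntrs = vntrs,
    transcripts = transcripts, expression = expression,
    noncpg = noncpg, spike = spike,
    params = list(n_chroms = n_chroms, chrom_len = chrom_len,
                  cgi_per_chrom = cgi_per_chrom,
                  sva_per_chrom = sva_per_chrom,
                  alu_per_chrom = alu_per_chrom, base_p = as.list(base_p))),
    class = "SyntheticTruth")
}
utils::globalVariables(c("p_oocyte", "p_sperm", "p_blood", "p_ES",
                         "maintained", "protected", "true_class",
                         "es_lost", "has_vntr", "expr_class", "p_other",
                         "p_true", "depth"))

#' True blastocyst methylation under a demethylation model
#'
#' The blastocyst level of a CpG is the average of its maternal and
#' paternal allele contributions. Under `human_retention` the maternal
#' level is multiplied by a retention factor (default 0.85) and the
#' paternal level by a residual factor (default 0.1; the paternal genome
#' is actively demethylated), uniformly — imprinted maternal gDMRs are
#' not treated specially, which is what makes oocyte-specific CGIs and
#' gDMRs indistinguishable in the blastocyst. Under `mouse_passive` the
#' maternal level is instead halved per replication round
#' (`2^-rounds`), with gDMRs exempt: their methylated allele is
#' maintained at full level. Paternal gDMRs are maintained under both
#' models. Demethylation-protected CpGs (the SVA-like family and
#' VNTR-bearing hypermethylated CGIs) keep their gametic level. On
#' `chrX` the pooled-blastocyst composition (male X entirely maternal)
#' weights the maternal contribution 3:1.
#'
#' @param truth a `SyntheticTruth`.
#' @param model `"human_retention"` or `"mouse_passive"`.
#' @param retention_maternal,residual_paternal human_retention factors.
#' @param rounds mouse_passive replication rounds (default 1).
#' @return numeric vector of true blastocyst levels, one per CpG of
#'   `truth$cpg_map`.
#' @export
blastocyst_truth <- function(truth, model = c("human_retention",
                                              "mouse_passive"),
                             retention_maternal = 0.85,
                             residual_paternal = 0.1, rounds = 1) {
  model <- match.arg(model)
  tp <- truth$truth_p
  m_fac <- if (model == "human_retention") retention_maternal else 2^(-rounds)
  mat <- tp$p_oocyte * m_fac
  pat <- tp$p_sperm * residual_paternal
  if (model == "mouse_passive") {
    exempt <- tp$maintained == "maternal_gdmr"
    mat[exempt] <- tp$p_oocyte[exempt]
  }
  pat_g <- tp$maintained == "paternal_gdmr"
  pat[pat_g] <- tp$p_sperm[pat_g]
  is_x <- tp$chrom == "chrX"
  p_bl <- ifelse(is_x, 0.75 * mat + 0.25 * pat, (mat + pat) / 2)
  p_bl[tp$protected] <- pmax(p_bl[tp$protected],
                             tp$p_oocyte[tp$protected] *
                               (tp$p_oocyte[tp$protected] > 0.5))
  pmin(pmax(p_bl, 0), 1)
}

#' Simulate bisulfite methylome tracks from planted truth
#'
#' Per CpG and sample, read depth is Poisson with the sample's mean
#' depth and methylated reads are Binomial(depth, true level). Default
#' depths scale the study's coverage structure down (oocyte 7, sperm
#' and blastocyst 24, blood and ES 16). `noise_free = TRUE` replaces
#' sampling with `depth = 1000`, `meth = round(p * depth)` so observed
#' levels equal the truth. Each track also carries non-CpG cytosines
#' (oocyte CpA-like methylation ~5.6%, <1% elsewhere) and an
#' unmethylated spike-in contig `lambda_spike` whose apparent
#' methylation is the bisulfite non-conversion rate.
#'
#' @param truth a `SyntheticTruth` from [build_reference()].
#' @param seed integer seed for the read sampling.
#' @param model,retention_maternal,residual_paternal,rounds see
#'   [blastocyst_truth()].
#' @param depths named mean depths for oocyte, sperm, blastocyst,
#'   blood, ES.
#' @param non_conversion per-read bisulfite non-conversion probability
#'   (default 0.005).
#' @param noise_free disable sampling noise (default `FALSE`).
#' @return named list of `MethylomeTrack`s (unfiltered; apply
#'   [filter_depth()] with 3 for oocyte and 5 for the others to follow
#'   the study conventions).
#' @export
simulate_methylomes <- function(truth, seed,
                                model = c("human_retention", "mouse_passive"),
                                depths = c(oocyte = 7, sperm = 24,
                                           blastocyst = 24, blood = 16,
                                           ES = 16),
                                retention_maternal = 0.85,
                                residual_paternal = 0.1, rounds = 1,
                                non_conversion = 0.005,
                                noise_free = FALSE) {
  model <- match.arg(model)
  set.seed(seed)
  tp <- truth$truth_p
  p_bl <- blastocyst_truth(truth, model, retention_maternal,
                           residual_paternal, rounds)
  p_by_sample <- list(oocyte = tp$p_oocyte, sperm = tp$p_sperm,
                      blastocyst = p_bl, blood = tp$p_blood, ES = tp$p_ES)
  draw <- function(p, d) {
    n <- length(p)
    depth <- if (noise_free) rep(1000L, n) else rpois(n, d)
    # residual non-conversion adds false methylated calls
    p_obs <- pmin(p + (1 - p) * non_conversion, 1)
    meth <- if (noise_free) as.integer(round(p_obs * depth))
    else rbinom(n, depth, p_obs)
    list(depth = depth, meth = meth)
  }
  out <- lapply(names(p_by_sample), function(sm) {
    d <- depths[[sm]]
    cg <- draw(p_by_sample[[sm]], d)
    calls <- data.table(chrom = tp$chrom, pos = tp$pos, strand = "+",
                        context = "CG", meth = cg$meth, total = cg$depth)
    nc_p <- if (sm == "oocyte") truth$noncpg$p_oocyte else
      truth$noncpg$p_other
    nc <- draw(nc_p, d)
    nc_calls <- data.table(chrom = truth$noncpg$chrom,
                           pos = truth$noncpg$pos, strand = "+",
                           context = truth$noncpg$context,
                           meth = nc$meth, total = nc$depth)
    sp <- draw(rep(0, nrow(truth$spike)), d)
    sp_calls <- data.table(chrom = truth$spike$chrom, pos = truth$spike$pos,
                           strand = "+", context = truth$spike$context,
                           meth = sp$meth, total = sp$depth)
    methylome_track(rbindlist(list(calls, nc_calls, sp_calls)),
                    sample_id = sm,
                    cell_type = if (sm %in% c("oocyte", "sperm",
                                              "blastocyst", "blood", "ES"))
                      sm else "other")
  })
  names(out) <- names(p_by_sample)
  out
}

#' Extract the spike-in contig of a track
#'
#' @param track a `MethylomeTrack` carrying spike-in calls.
#' @param spike_chrom spike contig name (default `"lambda_spike"`).
#' @return a `MethylomeTrack` restricted to the spike contig.
#' @export
spike_subset <- function(track, spike_chrom = "lambda_spike") {
  methylome_track(track$calls[chrom == spike_chrom],
                  sample_id = paste0(track$sample_id, "_spike"),
                  cell_type = track$cell_type)
}

#' Drop the spike-in contig from a track
#'
#' @inheritParams spike_subset
#' @return the track without spike calls.
#' @export
drop_spike <- function(track, spike_chrom = "lambda_spike") {
  methylome_track(track$calls[chrom != spike_chrom],
                  sample_id = track$sample_id, cell_type = track$cell_type,
                  min_depth_applied = track$min_depth_applied)
}

#' Write the planted-truth tables of a synthetic scenario
#'
#' Emits plain-text files keyed by region/gene id for recovery scoring:
#' the CpG map and per-CpG truth levels, CGI/DMR/repeat/VNTR tables,
#' transcripts as BED12, expression table, and a manifest JSON carrying
#' the seed, parameters and package version.
#'
#' @param truth a `SyntheticTruth`.
#' @param outdir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
emit_truth_tables <- function(truth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(x, nm) {
    p <- file.path(outdir, nm)
    data.table::fwrite(x, p, sep = "\t")
    paths <<- c(paths, p)
  }
  wr(truth$cpg_map, "cpg_map.tsv")
  wr(truth$truth_p, "truth_levels.tsv")
  wr(truth$cgis, "cgis.tsv")
  wr(truth$dmr_catalogue, "dmr_catalogue.tsv")
  wr(truth$repeats, "repeats.tsv")
  wr(truth$vntrs[, .(chrom, start, end, period, copies, score, consensus)],
     "vntrs.tsv")
  wr(truth$expression, "expression.tsv")
  tr <- truth$transcripts
  bed12 <- data.table(
    tr$chrom, tr$start, tr$end, tr$name, 0L, tr$strand, tr$start, tr$end,
    "0", lengths(tr$exon_sizes),
    vapply(tr$exon_sizes, function(x) paste0(paste(x, collapse = ","), ","), ""),
    vapply(tr$exon_starts, function(x) paste0(paste(x, collapse = ","), ","), ""))
  p12 <- file.path(outdir, "transcripts.bed12")
  data.table::fwrite(bed12, p12, sep = "\t", col.names = FALSE, quote = FALSE)
  paths <- c(paths, p12)
  manifest <- list(seed = truth$seed, params = truth$params,
                   package_version =
                     as.character(utils::packageVersion("methreprog")))
  pm <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, pm)
  invisible(paths)
}

#' Simulate a planted window-shift scenario
#'
#' A focused generator for change-classifier calibration: a uniform CpG
#' map yielding `n_windows` sliding windows, a baseline methylation
#' level everywhere, and `n_planted` disjoint 20-CpG blocks (aligned to
#' window boundaries, separated by unshifted buffer windows) whose
#' second-sample level is shifted by `shift` percentage points. Returns
#' the two simulated tracks, the window set, and the ids of windows
#' fully inside planted blocks (`planted`) and of windows sharing no
#' CpG with any planted block (`null`).
#'
#' @param seed integer seed.
#' @param n_windows total sliding windows (default 1000).
#' @param n_planted planted shifted blocks (default 100).
#' @param shift planted shift in percentage points (default +50).
#' @param depth mean Poisson read depth per CpG (default 30).
#' @param base_p baseline methylation fraction (default 0.2).
#' @param W,step window geometry (defaults 20/10).
#' @return list with `win`, `track_a`, `track_b`, `planted_ids`,
#'   `null_ids`.
#' @export
simulate_window_shift_scenario <- function(seed, n_windows = 1000,
                                           n_planted = 100, shift = 50,
                                           depth = 30, base_p = 0.2,
                                           W = 20, step = 10) {
  set.seed(seed)
  n_cpgs <- (n_windows - 1) * step + W
  map <- data.table(chrom = "chrS", pos = seq_len(n_cpgs) * 50L)
  win <- build_cpg_windows(map, W = W, step = step)
  # planted blocks: W CpGs starting at every (n_windows %/% n_planted)-th
  # window boundary, so blocks are disjoint and separated by null windows
  stride <- n_windows %/% n_planted
  stopifnot(stride >= 3)
  block_first_win <- (seq_len(n_planted) - 1L) * stride + 1L
  block_cpg_start <- (block_first_win - 1L) * step + 1L
  planted_cpg <- unlist(lapply(block_cpg_start, function(s) s:(s + W - 1L)))
  p_a <- rep(base_p, n_cpgs)
  p_b <- p_a
  p_b[planted_cpg] <- base_p + shift / 100
  sim <- function(p) {
    d <- rpois(n_cpgs, depth)
    data.table(chrom = "chrS", pos = map$pos, strand = "+", context = "CG",
               meth = rbinom(n_cpgs, d, p), total = d)
  }
  track_a <- methylome_track(sim(p_a), sample_id = "a")
  track_b <- methylome_track(sim(p_b), sample_id = "b")
  w <- win$windows
  touches <- vapply(seq_len(nrow(w)), function(i) {
    any(w$first_idx[i]:w$last_idx[i] %in% planted_cpg)
  }, logical(1))
  inside <- vapply(seq_len(nrow(w)), function(i) {
    all(w$first_idx[i]:w$last_idx[i] %in% planted_cpg)
  }, logical(1))
  list(win = win, track_a = track_a, track_b = track_b,
       planted_ids = w$window_id[inside],
       null_ids = w$window_id[!touches])
}
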