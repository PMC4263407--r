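# Configuration-driven orchestration: one call runs the full analysis
# (synthetic scenario or user-supplied cytosine reports) and writes
# plain-text outputs plus a collated report JSON. The exported stage
# functions are the "subcommands"; a thin Rscript wrapper is installed
# under inst/scripts/run_pipeline.R for shell use.

#' Default pipeline configuration
#'
#' Returns the full parameter set with the study's conventions: window
#' geometry 20/10 with >=10 covered CpGs, depth thresholds 3 (oocyte)
#' and 5 (others), hyper/hypo thresholds 80/20, protection screen 70,
#' ES-loss threshold 75, blood maintenance interval \[35, 65\],
#' unpaired equal-variance t-test, uncorrected chi-square.
#'
#' @param seed integer seed used for every stochastic stage.
#' @param outdir output directory.
#' @return a named list; override entries before passing to
#'   [run_full_analysis()].
#' @export
default_config <- function(seed = 1, outdir = tempfile("methreprog_run_")) {
  list(
    seed = seed, outdir = outdir, input = "synthetic",
    model = "human_retention",
    samples = NULL,                  # data.frame(id, cell_type, path, min_depth)
    synthetic = list(n_chroms = 3, chrom_len = 2e6),
    window = list(W = 20, step = 10, min_covered = 10),
    thresholds = list(hyper = 80, hypo = 20, protect = 70, es_loss = 75,
                      blood_interval = c(35, 65), min_delta = 20,
                      alpha = 0.05),
    stats = list(t_test_mode = "unpaired_equal_var",
                 chi_square_correction = "none"),
    depth = list(oocyte = 3, default = 5))
}

.validate_config <- function(config) {
  th <- config$thresholds
  w <- config$window
  if (th$hyper < th$hypo) stop("config error: hyper threshold below hypo")
  vals <- c(th$hyper, th$hypo, th$protect, th$es_loss, th$blood_interval)
  if (any(vals < 0 | vals > 100))
    stop("config error: thresholds must lie in [0, 100]")
  if (!(w$W > w$step && w$step > 0))
    stop("config error: require W > step > 0")
  if (identical(config$input, "files")) {
    if (is.null(config$samples)) stop("config error: no sample table")
    missing <- config$samples$path[!file.exists(config$samples$path)]
    if (length(missing) > 0)
      stop("config error: sample file(s) not found: ",
           paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override [default_config()] defaults.
#'
#' @param path YAML file.
#' @return a config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  modify <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        modify(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  modify(cfg, user)
}

#' Run the full methylome analysis
#'
#' Validates the configuration up front (fail-fast: no outputs are
#' written on a config error), then executes simulation/ingest, depth
#' filtering, window construction and change calls, gamete window and
#' CGI categories, imprinted-DMR classification, repeat-family
#' protection screening, VNTR analyses and the expression join, and
#' writes TSV outputs plus a collated `report.json` to
#' `config$outdir`.
#'
#' @param config list from [default_config()] / [read_config()].
#' @return invisibly, a result bundle (list of the stage outputs and
#'   the report).
#' @export
run_full_analysis <- function(config = default_config()) {
  .validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[methreprog] ", sprintf(...))

  if (identical(config$input, "synthetic")) {
    log_msg("building synthetic reference (seed %d)", config$seed)
    truth <- build_reference(config$seed,
                             n_chroms = config$synthetic$n_chroms,
                             chrom_len = config$synthetic$chrom_len)
    tracks <- simulate_methylomes(truth, seed = config$seed + 1,
                                  model = config$model)
    cpg_map <- truth$cpg_map
  } else {
    truth <- NULL
    st <- config$samples
    tracks <- lapply(seq_len(nrow(st)), function(i)
      read_cx_report(st$path[i], sample_id = st$id[i],
                     cell_type = st$cell_type[i]))
    names(tracks) <- st$id
    cpg_map <- unique(rbindlist(
      lapply(tracks, function(t) t$calls[context == "CG", .(chrom, pos)])))
  }

  conv <- vapply(tracks, function(t) {
    sp <- spike_subset(t)
    if (n_calls(sp) == 0) return(NA_real_)
    estimate_conversion_rate(sp)
  }, numeric(1))
  tracks <- lapply(tracks, drop_spike)

  min_depth_of <- function(ct)
    if (ct == "oocyte") config$depth$oocyte else config$depth$default
  filtered <- lapply(tracks, function(t) filter_depth(t, min_depth_of(t$cell_type)))

  log_msg("building windows and per-sample means")
  win <- build_cpg_windows(cpg_map, W = config$window$W,
                          step = config$window$step)
  means <- lapply(filtered, window_means, win = win,
                  min_covered = config$window$min_covered)

  th <- config$thresholds
  report <- list(seed = config$seed, model = config$model,
                 conversion_rates = as.list(conv))
  bundle <- list(truth = truth, win = win, window_means = means)

  if (all(c("oocyte", "sperm", "blastocyst") %in% names(filtered))) {
    calls_ob <- classify_window_changes(
      win, filtered$oocyte, filtered$blastocyst,
      min_covered = config$window$min_covered, min_delta = th$min_delta,
      alpha = th$alpha, mode = config$stats$t_test_mode)
    calls_sb <- classify_window_changes(
      win, filtered$sperm, filtered$blastocyst,
      min_covered = config$window$min_covered, min_delta = th$min_delta,
      alpha = th$alpha, mode = config$stats$t_test_mode)
    prop <- function(calls) {
      testable <- calls[call != "untestable"]
      as.list(table(testable$call) / nrow(testable))
    }
    report$window_change_proportions <- list(
      oocyte_to_blastocyst = prop(calls_ob),
      sperm_to_blastocyst = prop(calls_sb))
    gw <- categorize_gamete_windows(means$oocyte, means$sperm,
                                    hyper = th$hyper, hypo = th$hypo)
    gw_sum <- category_summary(gw, means$blastocyst)
    report$gamete_window_blastocyst_medians <-
      stats::setNames(as.list(gw_sum$median), gw_sum$category)
    protected <- screen_windows_above(means$blastocyst,
                                      threshold = th$protect)
    prot_regions <- win$windows[protected, on = "window_id", nomatch = NULL]
    report$protected_window_fraction <-
      attr(protected, "fraction_of_testable")
    bundle$window_calls <- list(oocyte_blastocyst = calls_ob,
                                sperm_blastocyst = calls_sb)
    bundle$gamete_windows <- gw
    bundle$protected_windows <- prot_regions
    data.table::fwrite(calls_ob, file.path(config$outdir,
                                           "window_calls_oocyte_blastocyst.tsv"),
                       sep = "\t")
    data.table::fwrite(calls_sb, file.path(config$outdir,
                                           "window_calls_sperm_blastocyst.tsv"),
                       sep = "\t")
  }

  if (!is.null(truth)) {
    log_msg("region, DMR, repeat and expression stages")
    cgi_means <- lapply(filtered, function(t)
      region_means(truth$cgis, t, min_cpgs = 10))
    cgi_cat <- categorize_gamete_regions(cgi_means$oocyte, cgi_means$sperm,
                                         hyper = th$hyper, hypo = th$hypo)
    dmr_tab <- copy(truth$dmr_catalogue)
    for (sm in c("oocyte", "sperm", "blood", "blastocyst", "ES")) {
      rm_ <- region_means(truth$dmr_catalogue, filtered[[sm]], min_cpgs = 10)
      dmr_tab[, (sm) := rm_$mean_level]
    }
    classified <- classify_dmr(dmr_tab, hyper = th$hyper, hypo = th$hypo,
                               blood_interval = th$blood_interval)
    report$dmr_class_counts <- as.list(dmr_class_counts(classified))
    es_sum <- es_stability_summary(classified, classified$ES,
                                   threshold = th$es_loss)
    report$es_instability <- as.list(es_sum[1])
    oc_cgis <- cgi_cat[category == "oocyte_specific", name]
    gdmr_bl <- classified[assigned_class == "M_gDMR", blastocyst]
    cgi_bl_tab <- as.data.table(cgi_means$blastocyst)[name %in% oc_cgis]
    pers <- persistence_comparison(gdmr_bl, cgi_bl_tab$mean_level,
                                   cgi_chrom = cgi_bl_tab$chrom)
    report$persistence <- list(gdmr_median = unname(pers$gdmr["median"]),
                               cgi_median = unname(pers$cgi["median"]),
                               median_diff = pers$median_diff,
                               p = pers$test$p_value)
    fam <- family_methylation(filtered$blastocyst, truth$repeats)
    screen <- protection_screen(truth$repeats, bundle$protected_windows)
    report$top_protected_family <- screen[ranked == TRUE][1, name]
    vntrs <- admit_vntrs(truth$vntrs)
    enr <- vntr_enrichment(
      truth$dmr_catalogue[true_class %in% c("M_gDMR",
                                            "placenta_specific_M_gDMR")],
      truth$cgis, vntrs,
      correction = config$stats$chi_square_correction)
    report$vntr_enrichment <- c(as.list(enr$counts),
                                list(p = enr$test$p_value))
    bh_cgis <- cgi_cat[category == "both_hyper" & !grepl("^chrX", name)]
    bh_tab <- truth$cgis[name %in% bh_cgis$name & chrom != "chrX"]
    bh_bl <- as.data.table(cgi_means$blastocyst)[bh_tab[, .(name)],
                                                 on = "name"]
    prot_test <- cgi_protection_by_vntr(bh_tab, bh_bl$mean_level, vntrs,
                                        threshold = th$protect)
    report$cgi_vntr_protection <- list(
      counts = as.list(as.vector(prot_test$counts)),
      p = if (!is.null(prot_test$test)) prot_test$test$p_value else NA_real_)
    bodies <- define_gene_bodies(truth$transcripts)
    body_means <- region_means(bodies, filtered$oocyte, min_cpgs = 10)
    expr <- expression_records(truth$expression$gene_id,
                               truth$expression$rpkm)
    joined <- genebody_expression_join(body_means, expr)
    states <- classify_transcriptional_state(joined)
    report$genebody_expression <- list(
      n_genes = nrow(states),
      r_meth_vs_active = pearson_r(states$mean_level,
                                   as.numeric(states$state == "active")))
    bundle$dmr <- classified
    bundle$family_methylation <- fam
    bundle$protection_screen <- screen
    bundle$genebody <- states
    data.table::fwrite(classified, file.path(config$outdir,
                                             "dmr_classification.tsv"),
                       sep = "\t")
    data.table::fwrite(screen, file.path(config$outdir,
                                         "protection_screen.tsv"),
                       sep = "\t")
    data.table::fwrite(states, file.path(config$outdir,
                                         "genebody_expression.tsv"),
                       sep = "\t")
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  bundle$report <- report
  log_msg("done; outputs in %s", config$outdir)
  invisible(bundle)
}
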