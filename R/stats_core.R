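# Statistical primitives shared by all stages. Standard tests are
# delegated to base R (t.test, chisq.test, wilcox.test, p.adjust, cor);
# the wrappers fix the conventions used throughout the pipeline and
# handle the degenerate inputs window-level data produce.

#' @importFrom stats t.test chisq.test wilcox.test p.adjust cor median
#'   quantile rbinom rpois runif rnorm setNames
NULL

.test_result <- function(statistic, p_value, method, n1, n2 = NA_integer_,
                         flag = NA_character_) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n1 = n1, n2 = n2, flag = flag),
            class = "meth_test")
}

#' @export
print.meth_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %s)\n",
              x$method, x$statistic, x$p_value, x$n1,
              ifelse(is.na(x$n2), "-", x$n2)))
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Mean methylation level of a set of CpG calls
#'
#' The region mean is the unweighted average of per-CpG levels
#' (`meth/total` per CpG, averaged across CpGs), expressed in percent.
#' Each covered CpG counts equally regardless of its read depth;
#' coverage weighting (pooling reads before dividing) is available via
#' `weighted = TRUE`.
#'
#' @param meth,total integer vectors of methylated and total read counts,
#'   one entry per CpG; entries with `total == 0` are ignored.
#' @param weighted if `TRUE`, return `100 * sum(meth)/sum(total)` instead.
#' @return percentage in `[0, 100]`, or `NA_real_` if no eligible CpG.
#' @export
region_mean_level <- function(meth, total, weighted = FALSE) {
  keep <- !is.na(total) & total > 0
  if (!any(keep)) return(NA_real_)
  if (weighted) return(100 * sum(meth[keep]) / sum(total[keep]))
  mean(100 * meth[keep] / total[keep])
}

#' Two-sample Student's t-test on per-CpG methylation levels
#'
#' Default mode is the unpaired equal-variance two-sided test. Paired
#' mode restricts to CpGs covered in both samples (the caller supplies
#' already-paired vectors). Windows where both groups have zero variance
#' but unequal means are assigned p = 0 with a flag — the limit of the t
#' statistic — rather than propagating `NaN`; equal constant groups give
#' p = 1.
#'
#' @param levels_a,levels_b numeric vectors of per-CpG levels (percent).
#' @param mode `"unpaired_equal_var"` (default) or `"paired"`; paired
#'   vectors must have equal length.
#' @return a `meth_test` result, or `NULL` (untestable) when a group has
#'   fewer than 2 values (or fewer than 2 pairs).
#' @export
student_t_test <- function(levels_a, levels_b,
                           mode = c("unpaired_equal_var", "paired")) {
  mode <- match.arg(mode)
  levels_a <- levels_a[!is.na(levels_a)]
  levels_b <- levels_b[!is.na(levels_b)]
  if (mode == "paired") {
    if (length(levels_a) != length(levels_b))
      stop("paired mode requires equal-length vectors")
    if (length(levels_a) < 2) return(NULL)
    d <- levels_a - levels_b
    if (stats::var(d) == 0) {
      pv <- if (all(d == 0)) 1 else 0
      return(.test_result(if (pv == 1) 0 else Inf, pv, "paired t-test",
                          length(levels_a), length(levels_b),
                          flag = if (pv == 0) "zero_variance" else NA_character_))
    }
    tt <- t.test(levels_a, levels_b, paired = TRUE)
    return(.test_result(tt$statistic, tt$p.value, "paired t-test",
                        length(levels_a), length(levels_b)))
  }
  if (length(levels_a) < 2 || length(levels_b) < 2) return(NULL)
  va <- stats::var(levels_a); vb <- stats::var(levels_b)
  if (va == 0 && vb == 0) {
    if (mean(levels_a) == mean(levels_b))
      return(.test_result(0, 1, "Student's t-test",
                          length(levels_a), length(levels_b)))
    return(.test_result(Inf, 0, "Student's t-test",
                        length(levels_a), length(levels_b),
                        flag = "zero_variance"))
  }
  tt <- t.test(levels_a, levels_b, var.equal = TRUE)
  .test_result(tt$statistic, tt$p.value, "Student's t-test",
               length(levels_a), length(levels_b))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment. Each adjusted value
#' satisfies `q >= p` and `q <= 1`, and reapplying the adjustment to its
#' own output is idempotent.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = outcome (`a/b` group 1, `c/d` group 2).
#' @param correction `"none"` (default) or `"yates"` continuity
#'   correction.
#' @return a `meth_test` with the chi-square statistic (1 df) and its
#'   upper-tail p-value.
#' @export
chi_square_2x2 <- function(a, b, c, d, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square undefined: a marginal total is zero")
  ct <- suppressWarnings(chisq.test(m, correct = correction == "yates"))
  .test_result(ct$statistic, ct$p.value,
               paste0("chi-square (", correction, ")"),
               a + b, c + d)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when both groups have at most `exact_max`
#' observations and there are no ties; the tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y numeric vectors, each with at least one observation.
#' @param exact_max largest per-group size for the exact path (default 20).
#' @return a `meth_test`; `statistic` is the U of the first group.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("Mann-Whitney test requires non-empty groups")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = !use_exact))
  .test_result(wt$statistic, wt$p.value,
               paste0("Mann-Whitney U (",
                      if (use_exact) "exact" else "normal approx.", ")"),
               length(x), length(y))
}

#' Pearson product-moment correlation
#'
#' Pairs with a missing value in either vector are dropped listwise.
#'
#' @param x,y equal-length numeric vectors with at least 3 complete pairs.
#' @return correlation coefficient in `[-1, 1]`, or `NA_real_` when
#'   either vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  cor(x, y, method = "pearson")
}

#' Expected methylation under replication-dependent (passive) dilution
#'
#' After fertilization the zygote carries one maternal and one paternal
#' allele, so the starting level is the allele average
#' `(m_maternal + m_paternal) / 2`. Passive demethylation halves the
#' methylation carried by an allele at each replication round when
#' maintenance methylation fails; by default only the maternally
#' contributed methylation is diluted (the paternal contribution is held
#' at its input value), with `codilute_paternal = TRUE` applying the
#' same dilution to both. A region fully methylated on the maternal
#' allele and unmethylated on the paternal allele therefore evaluates to
#' 25% after a single round — the bound against which observed
#' blastocyst levels are compared.
#'
#' @param m_maternal,m_paternal allele methylation fractions in `[0, 1]`.
#' @param rounds non-negative integer number of replication-dependent
#'   dilution events.
#' @param codilute_paternal if `TRUE` the paternal contribution is
#'   halved per round as well.
#' @return expected zygotic methylation level in percent.
#' @export
passive_demethylation_expectation <- function(m_maternal, m_paternal,
                                              rounds = 1,
                                              codilute_paternal = FALSE) {
  stopifnot(m_maternal >= 0, m_maternal <= 1,
            m_paternal >= 0, m_paternal <= 1,
            rounds >= 0, rounds == round(rounds))
  dil <- 2^(-rounds)
  pat <- if (codilute_paternal) m_paternal * dil else m_paternal
  100 * (m_maternal * dil + pat) / 2
}

#' Median and quartiles of a group
#'
#' Convenience summary used by the persistence and VNTR comparisons.
#'
#' @param x numeric vector.
#' @return named numeric vector `q25`, `median`, `q75`, `n`.
#' @export
group_summary <- function(x) {
  x <- x[!is.na(x)]
  c(q25 = unname(quantile(x, 0.25)), median = median(x),
    q75 = unname(quantile(x, 0.75)), n = length(x))
}
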