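contrast_result <- function(contrast, estimate, statistic, df, p_raw,
                            m = 1L, method = "t") {
  data.frame(contrast = contrast, method = method, estimate = estimate,
             statistic = statistic, df = df, p_raw = p_raw,
             p_adj = pmin(1, m * p_raw), m = m,
             stringsAsFactors = FALSE)
}

#' One-sample t-test against a reference value
#'
#' Used to compare preference scores to the chance level of 0.5, one test
#' per condition within each treatment within each group.
#'
#' @param values numeric vector, `n >= 2`, nonzero variance.
#' @param mu reference value (default 0.5).
#' @param m Bonferroni family size applied to the adjusted p (default 1).
#' @return A one-row data.frame: `contrast`, `method`, `estimate` (mean
#'   minus `mu`), `statistic` (t), `df`, `p_raw`, `p_adj`, `m`.
#' @export
one_sample_t <- function(values, mu = 0.5, m = 1L) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 2L) stop("one_sample_t needs at least 2 values")
  if (stats::var(values) == 0) stop("zero variance")
  tt <- stats::t.test(values, mu = mu)
  contrast_result(sprintf("mean vs %g", mu), mean(values) - mu,
                  unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  m = m)
}

#' Paired t-test
#'
#' Within-subject comparison (e.g. time in female zone vs time in male
#' zone, or CNO vs vehicle): a one-sample t-test on the paired differences
#' against 0.
#'
#' @param a,b numeric vectors of equal length (`n >= 2` complete pairs).
#' @param m Bonferroni family size (default 1).
#' @return A one-row data.frame as in [one_sample_t()]; `estimate` is the
#'   mean difference `a - b`.
#' @export
paired_t <- function(a, b, m = 1L) {
  if (length(a) != length(b)) stop("paired_t needs equal-length vectors")
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2L) stop("paired_t needs at least 2 complete pairs")
  if (stats::var(d) == 0) stop("zero variance of differences")
  tt <- stats::t.test(d, mu = 0)
  contrast_result("paired a - b", mean(d), unname(tt$statistic),
                  unname(tt$parameter), tt$p.value, m = m)
}

two_sample_t <- function(a, b, welch = FALSE,
                         alternative = "two.sided") {
  stats::t.test(a, b, var.equal = !welch, alternative = alternative)
}

#' Post-hoc contrast family for a virus x treatment design
#'
#' Emits the standard post-hoc family run after a significant
#' virus-by-treatment interaction: within-group paired contrasts (CNO vs
#' vehicle, one per virus group) and between-group independent contrasts
#' on the CNO cells (Gi vs Sham and Gq vs Sham only). All p-values are
#' Bonferroni-adjusted over the family actually emitted (m = 5 with the
#' full design) unless `m` overrides the family size.
#'
#' @param design a data.frame with columns `subject`, `virus` (levels
#'   `Sham`, `Gi`, `Gq`), `treatment` (levels `VEH`, `CNO`) and the
#'   outcome column named by `outcome`; one row per subject x treatment.
#' @param outcome name of the outcome column.
#' @param m Bonferroni family size; default `NULL` = number of contrasts
#'   emitted.
#' @param welch use Welch's correction for the between-group tests
#'   (default `FALSE`, pooled variance).
#' @return A data.frame with one row per contrast, columns as in
#'   [one_sample_t()].
#' @export
posthoc_family <- function(design, outcome, m = NULL, welch = FALSE) {
  need <- c("subject", "virus", "treatment", outcome)
  if (!all(need %in% names(design)))
    stop("design must have columns subject, virus, treatment, ", outcome)
  y <- design[[outcome]]
  res <- list()
  for (v in intersect(c("Sham", "Gi", "Gq"), unique(design$virus))) {
    dv <- design[design$virus == v, , drop = FALSE]
    cno <- dv[dv$treatment == "CNO", , drop = FALSE]
    veh <- dv[dv$treatment == "VEH", , drop = FALSE]
    if (!nrow(cno) || !nrow(veh))
      stop("virus group ", v, ": empty treatment cell")
    shared <- intersect(cno$subject, veh$subject)
    a <- cno[[outcome]][match(shared, cno$subject)]
    b <- veh[[outcome]][match(shared, veh$subject)]
    r <- paired_t(a, b)
    r$contrast <- paste0(v, ": CNO vs VEH")
    res[[length(res) + 1L]] <- r
  }
  cno_cells <- design[design$treatment == "CNO", , drop = FALSE]
  sham <- cno_cells[[outcome]][cno_cells$virus == "Sham"]
  for (v in intersect(c("Gi", "Gq"), unique(design$virus))) {
    g <- cno_cells[[outcome]][cno_cells$virus == v]
    if (!length(g) || !length(sham)) stop("empty cell for ", v, " vs Sham")
    tt <- two_sample_t(g, sham, welch = welch)
    res[[length(res) + 1L]] <- contrast_result(
      paste0(v, " vs Sham (CNO)"), mean(g) - mean(sham),
      unname(tt$statistic), unname(tt$parameter), tt$p.value)
  }
  out <- do.call(rbind, res)
  fam <- if (is.null(m)) nrow(out) else m
  out$m <- fam
  out$p_adj <- pmin(1, fam * out$p_raw)
  rownames(out) <- NULL
  out
}

#' One-tailed independent-samples comparison with rank-based fallback
#'
#' Independent-samples t-test (pooled variance) with a one-tailed p in
#' the stated direction, as used for c-Fos+ cell densities. When an F-test
#' of variance equality rejects at `f_alpha`, a one-tailed Mann-Whitney U
#' test is used instead.
#'
#' @param a,b numeric vectors (`n >= 2` each).
#' @param direction `"greater"` (tests a > b) or `"less"`.
#' @param f_alpha alpha for the variance-ratio F-test gate (default 0.05).
#' @param m Bonferroni family size (default 1).
#' @return A one-row data.frame as in [one_sample_t()]; `method` is
#'   `"t"` or `"mann-whitney"`, `statistic` the t or U statistic.
#' @export
one_tailed_comparison <- function(a, b, direction = c("greater", "less"),
                                  f_alpha = 0.05, m = 1L) {
  direction <- match.arg(direction)
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both groups degenerate (zero variance)")
  ftest <- stats::var.test(a, b)
  if (ftest$p.value < f_alpha) {
    wt <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = direction))
    contrast_result("a vs b (one-tailed)", stats::median(a) -
                      stats::median(b),
                    unname(wt$statistic), NA_real_, wt$p.value,
                    m = m, method = "mann-whitney")
  } else {
    tt <- two_sample_t(a, b, welch = FALSE, alternative = direction)
    contrast_result("a vs b (one-tailed)", mean(a) - mean(b),
                    unname(tt$statistic), unname(tt$parameter),
                    tt$p.value, m = m)
  }
}
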