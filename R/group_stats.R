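#' Normality-gated paired comparison of two conditions
#'
#' The adaptive procedure used for condition contrasts: a Shapiro-Wilk test
#' on the paired differences decides the test — if its p-value is at or
#' above `alpha`, a paired t-test; otherwise a Wilcoxon signed-rank test
#' (zero differences dropped, average ranks for ties, exact distribution
#' for n <= 25 without ties, else normal approximation with continuity
#' correction). The returned row carries mean and SD per condition, the
#' test used, its statistic, and the two-sided p-value.
#'
#' All differences equal to zero is a degenerate case: the row is returned
#' with p = 1 and `degenerate = TRUE` rather than erroring.
#'
#' @param values_a,values_b numeric vectors, one value per subject, paired
#'   by position; length >= 3, no missing values.
#' @param parameter label for the compared quantity.
#' @param alpha significance level gating the normality decision.
#' @return one-row data.frame of class `crp_comparison`: `parameter`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `test`, `statistic`, `p`, `n`,
#'   `degenerate`.
#' @export
compare_paired <- function(values_a, values_b, parameter = "parameter",
                           alpha = 0.05) {
  if (length(values_a) != length(values_b)) stop("unequal condition lengths")
  n <- length(values_a)
  if (n < 3) stop("need at least 3 pairs")
  if (anyNA(values_a) || anyNA(values_b)) stop("missing values not allowed")
  d <- values_a - values_b
  row <- function(test, statistic, p, degenerate = FALSE) {
    structure(data.frame(
      parameter = parameter,
      mean_a = mean(values_a), sd_a = stats::sd(values_a),
      mean_b = mean(values_b), sd_b = stats::sd(values_b),
      test = test, statistic = statistic, p = p, n = n,
      degenerate = degenerate, stringsAsFactors = FALSE
    ), class = c("crp_comparison", "data.frame"))
  }
  if (all(d == 0)) return(row("paired_t", NA_real_, 1, degenerate = TRUE))
  if (stats::sd(d) == 0) {
    # nonzero constant difference: t statistic is infinite; report the
    # Wilcoxon instead, which is well defined
    nz <- d[d != 0]
    wt <- suppressWarnings(stats::wilcox.test(nz, exact = length(nz) <= 25,
                                              correct = TRUE))
    return(row("wilcoxon", unname(wt$statistic), wt$p.value))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    row("paired_t", unname(tt$statistic), tt$p.value)
  } else {
    nz <- d[d != 0]
    use_exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(stats::wilcox.test(nz, exact = use_exact,
                                              correct = TRUE))
    row("wilcoxon", unname(wt$statistic), wt$p.value)
  }
}

#' Paired comparison table over several parameters
#'
#' One [compare_paired()] row per parameter, order preserved, with no
#' multiplicity adjustment by default (each parameter judged at `alpha` on
#' its own). Holm adjustment is available as an option.
#'
#' @param samples named list: each element a list or data.frame with
#'   `values_a` and `values_b` (one value per subject).
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"holm"`; when `"holm"`, a
#'   `p_adj` column is appended.
#' @return data.frame, one row per parameter.
#' @export
build_comparison_table <- function(samples, alpha = 0.05,
                                   adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!length(samples)) stop("samples must be nonempty")
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be named by parameter")
  if (anyDuplicated(names(samples))) stop("duplicate parameter names")
  rows <- do.call(rbind, lapply(names(samples), function(pm) {
    s <- samples[[pm]]
    compare_paired(s$values_a, s$values_b, parameter = pm, alpha = alpha)
  }))
  if (adjust == "holm") rows$p_adj <- stats::p.adjust(rows$p, method = "holm")
  rownames(rows) <- NULL
  rows
}
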