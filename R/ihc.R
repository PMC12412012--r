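# The IHC H-score model and its association statistics. The H-score is the
# product of a staining-intensity score (0 = negative, 1 = weak,
# 2 = moderate, 3 = strong) and a positivity-percentage category
# (1: 0-25%, 2: 26-50%, 3: 51-75%, 4: 76-100%), range 0-12; tumors with
# H-score >= 8 are GALNT7-High, otherwise GALNT7-Low.

#' Positivity category from the percentage of positive cells
#'
#' @param pct Percent positive cells in `[0, 100]`; non-integer values are
#'   floored before binning (scores are whole-percent estimates).
#' @return Integer category: 0-25 -> 1, 26-50 -> 2, 51-75 -> 3,
#'   76-100 -> 4. Vectorized.
#' @export
positivity_category <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0 | pct > 100))
    stop("pct must be in [0, 100]")
  p <- floor(pct)
  as.integer(ifelse(p <= 25, 1L, ifelse(p <= 50, 2L, ifelse(p <= 75, 3L, 4L))))
}

#' IHC H-score
#'
#' @param intensity Staining intensity in `{0, 1, 2, 3}`.
#' @param positivity Positivity category in `{1, 2, 3, 4}` (see
#'   [positivity_category()]).
#' @return `intensity * positivity`, an integer in 0-12; only the nine
#'   values \{0, 1, 2, 3, 4, 6, 8, 9, 12\} are achievable. Vectorized.
#' @export
h_score <- function(intensity, positivity) {
  if (any(!intensity %in% 0:3)) stop("intensity must be in {0, 1, 2, 3}")
  if (any(!positivity %in% 1:4)) stop("positivity must be in {1, 2, 3, 4}")
  as.integer(intensity) * as.integer(positivity)
}

#' GALNT7 High/Low classification from the H-score
#'
#' H-score 8-12 is `"High"`, 0-7 is `"Low"`. The cut accepts any integer
#' 0-12 (not only the nine achievable products) so that averaged or
#' externally supplied H-scores remain classifiable.
#'
#' @param h Integer H-score(s) in 0-12.
#' @return `"High"` or `"Low"`, vectorized.
#' @export
classify_galnt7 <- function(h) {
  if (any(!is.finite(h)) || any(h < 0 | h > 12))
    stop("H-score must be in [0, 12]")
  ifelse(h >= 8, "High", "Low")
}

#' Fisher exact test for a 2x2 table
#'
#' Exact conditional test with both margins fixed. The two-sided p-value is
#' the minimum-likelihood sum: over all tables with the observed margins,
#' the total hypergeometric probability of tables no more probable than the
#' observed one. The odds ratio reported is the sample odds ratio
#' `(a d) / (b c)` (`Inf`/`0` at zero cells).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List of class `"fisher_result"` with `odds_ratio`, `p_value`,
#'   `table`.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2))$p_value  # 1/3
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("all-zero table")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance guards against ties broken by floating-point error
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  structure(list(odds_ratio = or, p_value = p, table = table),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher exact test: OR = %.4g, two-sided p = %.4g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Pearson chi-square test for an r x c table
#'
#' @param table Matrix of counts; all expected counts must be positive.
#' @param correct Apply the Yates continuity correction (2x2 only);
#'   default `FALSE`.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stop("zero expected count")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = as.numeric(ht$statistic), df = as.integer(ht$parameter),
       p_value = ht$p.value, expected = expected)
}

#' Mann-Whitney U test
#'
#' The U statistic counts pairs with `x > y` plus half the tied pairs
#' (computed by midranks, so `U = AUC * n_x * n_y` exactly, consistent with
#' [roc_auc()]); the two-sided p-value uses the tie-corrected normal
#' approximation.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `u_statistic`, `p_value`, `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  r <- rank(c(x, y), ties.method = "average")
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                           correct = FALSE)$p.value)
  list(u_statistic = u, p_value = p,
       n_x = length(x), n_y = length(y))
}

#' Stratified summary of an IHC cohort
#'
#' Per MMR stratum (dMMR/MSI and pMMR/MSS): the GALNT7-High proportion; the
#' 2x2 GALNT7 class x tumor-cell PD-L1 table with its Fisher exact test;
#' and Mann-Whitney comparisons of the Tn-antigen H-score and each TIL
#' count between GALNT7-High and -Low tumors. Tests that cannot run (an
#' empty class, missing columns) are reported with status
#' `"insufficient data"` rather than failing the summary; an empty stratum
#' is absent from the output.
#'
#' @param records `data.frame` of IHC records as produced by
#'   [generate_ihc_cohort()] (columns `mmr_status`, `galnt7_class` or
#'   `h_score`, and optionally `pdl1_tumor`, `tn_h_score`, `cd8`, `cd4`,
#'   `foxp3`, `cd163`).
#' @return Named list, one element per present MMR stratum, each with
#'   `n`, `n_high`, `prop_high`, `pdl1` (table, per-class positivity,
#'   Fisher result or status), and `comparisons` (per marker: Mann-Whitney
#'   result or status).
#' @export
summarize_ihc_cohort <- function(records) {
  if (nrow(records) == 0) stop("no records")
  if (!"galnt7_class" %in% names(records)) {
    if (!"h_score" %in% names(records))
      stop("records need 'galnt7_class' or 'h_score'")
    records$galnt7_class <- classify_galnt7(records$h_score)
  }
  markers <- intersect(c("tn_h_score", "cd8", "cd4", "foxp3", "cd163"),
                       names(records))
  strata <- split(records, records$mmr_status)
  lapply(strata, function(s) {
    hi <- s$galnt7_class == "High"
    out <- list(n = nrow(s), n_high = sum(hi), prop_high = mean(hi))
    if ("pdl1_tumor" %in% names(s)) {
      tab <- matrix(c(sum(hi & s$pdl1_tumor == 1), sum(hi & s$pdl1_tumor == 0),
                      sum(!hi & s$pdl1_tumor == 1), sum(!hi & s$pdl1_tumor == 0)),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(galnt7 = c("High", "Low"),
                                    pdl1 = c("pos", "neg")))
      out$pdl1 <- list(
        table = tab,
        prop_pos_high = if (sum(hi)) mean(s$pdl1_tumor[hi] == 1) else NA_real_,
        prop_pos_low = if (sum(!hi)) mean(s$pdl1_tumor[!hi] == 1) else NA_real_,
        fisher = if (all(rowSums(tab) > 0) && sum(tab) > 1)
          fisher_exact(tab) else "insufficient data")
    }
    out$comparisons <- stats::setNames(lapply(markers, function(mk) {
      x <- s[[mk]][hi]; y <- s[[mk]][!hi]
      if (length(x) == 0 || length(y) == 0) "insufficient data"
      else mann_whitney(x, y)
    }), markers)
    out
  })
}
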