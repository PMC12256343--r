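# Rank-difference consistency between two score sets and the Spearman /
# simple-regression association analysis.

#' Absolute rank difference between two score tables
#'
#' Both score sets are ranked from high to low (rank 1 = highest score,
#' average ranks on ties); only groups present in both sets enter the
#' ranking. Small absolute differences indicate a consistent contamination
#' pattern across the two sets.
#'
#' @param scores_a,scores_b Tibbles with `group_id` and `score` columns.
#' @return Tibble `group_id`, `rank_a`, `rank_b`, `abs_rank_diff`.
#' @export
rank_difference <- function(scores_a, scores_b) {
  common <- dplyr::inner_join(scores_a[, c("group_id", "score")],
                              scores_b[, c("group_id", "score")],
                              by = "group_id", suffix = c("_a", "_b"))
  if (nrow(common) < 2) {
    stop("fewer than 2 groups present in both score sets", call. = FALSE)
  }
  tibble::tibble(
    group_id = common$group_id,
    rank_a = rank(-common$score_a, ties.method = "average"),
    rank_b = rank(-common$score_b, ties.method = "average"),
    abs_rank_diff = abs(rank(-common$score_a, ties.method = "average") -
                          rank(-common$score_b, ties.method = "average"))
  )
}

#' Spearman correlation and simple linear regression between score sets
#'
#' Pairs the two score sets on common groups, then computes Spearman's rank
#' correlation (two-sided; exact permutation p-value for n <= 9, large-sample
#' approximation otherwise) and the ordinary least-squares regression of the
#' second score on the first. Significance labels use p < 0.1 for the
#' correlation and p < 0.05 for the regression slope; they are attached, not
#' enforced.
#'
#' @param scores_a Independent-variable score table (`group_id`, `score`).
#' @param scores_b Dependent-variable score table.
#' @return One-row tibble: `n`, `spearman_r`, `spearman_p`, `slope`,
#'   `intercept`, `r_squared`, `regression_p`, `spearman_sig_010`,
#'   `regression_sig_005`.
#' @export
associate_scores <- function(scores_a, scores_b) {
  common <- dplyr::inner_join(scores_a[, c("group_id", "score")],
                              scores_b[, c("group_id", "score")],
                              by = "group_id", suffix = c("_a", "_b"))
  n <- nrow(common)
  if (n < 3) stop("need at least 3 common groups", call. = FALSE)
  x <- common$score_a
  y <- common$score_b
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant score vector: correlation undefined", call. = FALSE)
    return(tibble::tibble(n = n, spearman_r = NA_real_, spearman_p = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, regression_p = NA_real_,
                          spearman_sig_010 = NA, regression_sig_005 = NA))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 9)
  )
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly collinear pairing; the fit itself is fine
  sm <- suppressWarnings(summary(fit))
  tibble::tibble(
    n = n,
    spearman_r = unname(ct$estimate),
    spearman_p = ct$p.value,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    regression_p = sm$coefficients[2, 4],
    spearman_sig_010 = ct$p.value < 0.1,
    regression_sig_005 = sm$coefficients[2, 4] < 0.05
  )
}
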