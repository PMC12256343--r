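# Percentile bootstrap confidence intervals for a group's contamination
# score. The resampling unit is the sampling site, the score's atomic
# observation.

#' Bootstrap confidence interval for one group's contamination score
#'
#' Resamples the group's M sites with replacement `B` times and recomputes
#' the score for each replicate. By default the global central tendencies are
#' held fixed at their full-data values, isolating within-group sampling
#' variability; set `recompute_ct = TRUE` (and supply `background_records`)
#' to rebuild the reference central tendencies from each resampled dataset.
#' The interval is the percentile interval of the replicate scores.
#'
#' @param group_records Records of one group (one water body), one row per
#'   site-pesticide pair.
#' @param ct Central tendencies from [central_tendency()] on the full
#'   reference population.
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the result is fully reproducible from it.
#' @param group_id Label carried into the result.
#' @param recompute_ct Recompute central tendencies per replicate.
#' @param background_records Records of all other groups in the reference
#'   population; required when `recompute_ct = TRUE`.
#' @return One-row tibble: `group_id`, `point`, `ci_low`, `ci_high`, `level`,
#'   `n_replicates`, `seed`.
#' @export
bootstrap_score <- function(group_records, ct, B = 1000, level = 0.95,
                            seed = NULL, group_id = NA_character_,
                            recompute_ct = FALSE,
                            background_records = NULL) {
  stopifnot(B >= 1, level > 0, level < 1)
  sites <- unique(group_records$site_id)
  m <- length(sites)
  if (m < 2) stop("degenerate bootstrap: group has fewer than 2 sites",
                  call. = FALSE)
  point <- score_group(group_records, ct)$score

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }

  if (!recompute_ct) {
    # Site deviations are fixed given the central tendencies, so a replicate
    # score is just the mean of a with-replacement sample of site values.
    group_records$.log_value <- effective_log_concentration(group_records)
    usable <- group_records |>
      dplyr::filter(!is.na(.data$.log_value)) |>
      dplyr::inner_join(ct[, c("pesticide_cas", "mean_log10")],
                        by = "pesticide_cas")
    site_vals <- usable |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(site_dev = mean(.data$.log_value - .data$mean_log10),
                       .groups = "drop")
    v <- site_vals$site_dev
    reps <- vapply(seq_len(B), function(b) {
      mean(v[sample.int(length(v), length(v), replace = TRUE)])
    }, numeric(1))
  } else {
    if (is.null(background_records)) {
      stop("recompute_ct = TRUE requires background_records", call. = FALSE)
    }
    by_site <- split(group_records, group_records$site_id)
    reps <- vapply(seq_len(B), function(b) {
      draw <- sample.int(m, m, replace = TRUE)
      res <- dplyr::bind_rows(by_site[draw], .id = ".draw")
      # resampled copies of a site must stay distinct sites
      res$site_id <- paste(res$site_id, res$.draw, sep = "#")
      res$.draw <- NULL
      pool <- dplyr::bind_rows(background_records, res)
      score_group(res, central_tendency(pool))$score
    }, numeric(1))
  }

  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(group_id = group_id, point = point,
                 ci_low = qs[1], ci_high = qs[2],
                 level = level, n_replicates = as.integer(B),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
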