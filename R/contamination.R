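# Deviation-from-central-tendency contamination scoring.
#
# The score of a group (country or region) is the mean over its M sampling
# sites of the per-site mean deviation of log10 concentrations from each
# pesticide's global central tendency. Non-detects enter at log10(LOD),
# falling back to log10(LOQ) when no LOD is reported.

#' Effective log10 concentration of each record
#'
#' Detected records contribute `log10(concentration)`; non-detects contribute
#' `log10(LOD)` or, when no LOD is reported, `log10(LOQ)`. Records with no
#' usable value yield `NA` (such records are normally removed by
#' [harmonize_records()]).
#'
#' @param records Concentration record tibble.
#' @return Numeric vector, one value per record.
#' @export
effective_log_concentration <- function(records) {
  det <- records$detected
  conc <- records$concentration
  if (any(det & (is.na(conc) | conc <= 0))) {
    stop("non-positive detect: detected records must have concentration > 0",
         call. = FALSE)
  }
  limit <- dplyr::coalesce(records$lod, records$loq)
  ifelse(det, log10(conc), log10(limit))
}

#' Per-pesticide global central tendency of log10 concentration
#'
#' For each pesticide, the flat mean of effective log10 values over every
#' sampling site in the reference population that reports it; each site
#' counts once regardless of which country it belongs to.
#'
#' @param records Concentration records (one row per site-pesticide pair; use
#'   [collapse_site_duplicates()] first when sources overlap).
#' @param min_sites Minimum number of sites a pesticide needs to receive a
#'   central tendency (default 1: a pesticide seen at a single site is
#'   retained and contributes deviation zero at that site).
#' @return Tibble with `pesticide_cas`, `mean_log10`, `n_sites`.
#' @export
central_tendency <- function(records, min_sites = 1) {
  if (nrow(records) == 0) {
    stop("no records: cannot compute central tendencies", call. = FALSE)
  }
  records$.log_value <- effective_log_concentration(records)
  records |>
    dplyr::filter(!is.na(.data$.log_value)) |>
    dplyr::group_by(.data$pesticide_cas) |>
    dplyr::summarise(mean_log10 = mean(.data$.log_value),
                     n_sites = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_sites >= min_sites)
}

#' Classification band of a contamination score
#'
#' Scores at or below 0 indicate levels similar to or below the global
#' average; scores strictly between 0 and 2 indicate slightly higher levels;
#' scores at or above 2 indicate concentrations orders of magnitude above the
#' global average.
#'
#' @param score Numeric vector of scores.
#' @return Character vector with values `at_or_below_global`,
#'   `slightly_higher` or `significantly_higher`.
#' @export
score_band <- function(score) {
  dplyr::case_when(
    score <= 0 ~ "at_or_below_global",
    score < 2 ~ "slightly_higher",
    TRUE ~ "significantly_higher"
  )
}

#' Score one group of sites against fixed central tendencies
#'
#' @param records Records of a single group (one country or region, one water
#'   body).
#' @param ct Central tendency table from [central_tendency()]. Records whose
#'   pesticide has no central tendency are ignored.
#' @return One-row tibble with `score`, `n_sites`, `n_pairs`, `band`; a
#'   zero-row tibble when the group has no usable site (no score is
#'   fabricated).
#' @export
score_group <- function(records, ct) {
  records$.log_value <- effective_log_concentration(records)
  usable <- records |>
    dplyr::filter(!is.na(.data$.log_value)) |>
    dplyr::inner_join(ct[, c("pesticide_cas", "mean_log10")],
                      by = "pesticide_cas")
  if (nrow(usable) == 0) {
    return(tibble::tibble(score = double(), n_sites = integer(),
                          n_pairs = integer(), band = character()))
  }
  site_means <- usable |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      site_dev = mean(.data$.log_value - .data$mean_log10),
      .groups = "drop"
    )
  s <- mean(site_means$site_dev)
  tibble::tibble(score = s,
                 n_sites = nrow(site_means),
                 n_pairs = nrow(usable),
                 band = score_band(s))
}

#' Contamination scores for all groups
#'
#' Computes one score per group and water body. With `grouping = "country"`
#' the reference population for the central tendencies is the full dataset of
#' the water body ("global"). With `grouping = "region"` the analysis shifts
#' to the admin-1 level; the default reference `"within_country"` compares
#' each region against its own country's central tendencies (internal
#' pollution pattern), while `"global"` retains the worldwide reference.
#'
#' @param records Harmonized concentration records.
#' @param grouping `"country"` or `"region"`.
#' @param reference `"global"` or `"within_country"`.
#' @param water_body Optional filter, `"surface"` or `"ground"`; by default
#'   each water body present is scored separately.
#' @param min_sites Passed to [central_tendency()].
#' @param collapse Collapse duplicate (site, pesticide) rows first
#'   (default TRUE).
#' @return Tibble with `group_id`, `country`, `water_body`, `score`,
#'   `n_sites`, `n_pairs`, `band`, ordered by descending score then group id.
#' @export
score_all <- function(records,
                      grouping = c("country", "region"),
                      reference = NULL,
                      water_body = NULL,
                      min_sites = 1,
                      collapse = TRUE) {
  grouping <- match.arg(grouping)
  if (is.null(reference)) {
    reference <- if (grouping == "region") "within_country" else "global"
  }
  reference <- match.arg(reference, c("global", "within_country"))
  if (grouping == "region" && all(is.na(records$region))) {
    stop("region grouping requires a populated region field", call. = FALSE)
  }
  if (!is.null(water_body)) {
    records <- records[records$water_body %in% water_body, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no usable records", call. = FALSE)
  if (collapse) records <- collapse_site_duplicates(records)

  score_one_wb <- function(recs) {
    if (grouping == "region") {
      recs <- recs[!is.na(recs$region), , drop = FALSE]
      grp_key <- paste(recs$country, recs$region, sep = "\r")
    } else {
      grp_key <- recs$country
    }
    pop_key <- if (reference == "within_country") recs$country
               else rep("__all__", nrow(recs))
    out <- lapply(split(seq_len(nrow(recs)), pop_key), function(pop_idx) {
      pop <- recs[pop_idx, , drop = FALSE]
      ct <- central_tendency(pop, min_sites = min_sites)
      groups <- split(seq_len(nrow(pop)), grp_key[pop_idx])
      dplyr::bind_rows(lapply(names(groups), function(g) {
        sc <- score_group(pop[groups[[g]], , drop = FALSE], ct)
        if (nrow(sc) == 0) return(NULL)
        key <- strsplit(g, "\r", fixed = TRUE)[[1]]
        tibble::tibble(
          group_id = key[length(key)],
          country = key[1],
          water_body = pop$water_body[1],
          sc
        )
      }))
    })
    dplyr::bind_rows(out)
  }

  res <- dplyr::bind_rows(lapply(split(records, records$water_body),
                                 score_one_wb))
  if (nrow(res) == 0) stop("no usable records", call. = FALSE)
  dplyr::arrange(res, .data$water_body, dplyr::desc(.data$score),
                 .data$group_id)
}
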