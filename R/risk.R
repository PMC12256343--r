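# Hazard-quotient screening of high-scoring countries and drinking-water
# standard exceedance rates with WHO guideline fallback.

#' The five drinking-water panel pesticides
#'
#' CAS numbers of the commonly detected and regulated pesticides used for
#' drinking-water exceedance screening: aldrin, dieldrin, 2,4-D, heptachlor
#' and lindane.
#'
#' @return Named character vector of CAS numbers.
#' @export
drinking_water_panel <- function() {
  c(aldrin = "309-00-2", dieldrin = "60-57-1", `2,4-D` = "94-75-7",
    heptachlor = "76-44-8", lindane = "58-89-9")
}

#' Chronic drinking-water exposure parameters
#'
#' Standard adult residential ingestion defaults: 2 L/day intake over a
#' 70 kg body weight, 350 days/year for 30 years, averaged over the exposure
#' duration (non-carcinogenic averaging time `ED * 365` days).
#'
#' @param intake_rate Water intake rate, L/day.
#' @param body_weight Body weight, kg.
#' @param exposure_frequency Exposure days per year (at most 366).
#' @param exposure_duration Exposure duration, years.
#' @param averaging_time Averaging time, days.
#' @return A list of class `exposure_params`.
#' @export
exposure_params <- function(intake_rate = 2, body_weight = 70,
                            exposure_frequency = 350,
                            exposure_duration = 30,
                            averaging_time = exposure_duration * 365) {
  p <- list(intake_rate = intake_rate, body_weight = body_weight,
            exposure_frequency = exposure_frequency,
            exposure_duration = exposure_duration,
            averaging_time = averaging_time)
  if (any(unlist(p) <= 0)) stop("exposure parameters must be positive",
                                call. = FALSE)
  if (exposure_frequency > 366) stop("exposure_frequency exceeds 366 days",
                                     call. = FALSE)
  structure(p, class = "exposure_params")
}

#' Countries whose contamination score exceeds a threshold
#'
#' Health risk assessment is restricted to groups whose contamination score
#' exceeds the threshold (default 2, the band boundary for scores orders of
#' magnitude above the global level).
#'
#' @param scores Score table from [score_all()].
#' @param threshold Score threshold (default 2).
#' @return Character vector of group ids, sorted by descending score.
#' @export
screen_high_scores <- function(scores, threshold = 2) {
  hi <- scores[scores$score > threshold, , drop = FALSE]
  hi$group_id[order(-hi$score)]
}

#' Hazard quotient for chronic drinking-water ingestion
#'
#' Chronic daily intake `CDI = (C_mg/L * IR * EF * ED) / (BW * AT)` in
#' mg/(kg day), divided by the oral reference dose. HQ above 1 signals
#' potential non-carcinogenic risk.
#'
#' @param concentration Water concentration(s), ug/L.
#' @param rfd Oral reference dose(s), mg/(kg day); must be positive.
#' @param params An [exposure_params()] object.
#' @return Tibble with `concentration_used`, `cdi`, `rfd`, `hq`.
#' @export
hazard_quotient <- function(concentration, rfd, params = exposure_params()) {
  if (any(rfd <= 0)) stop("rfd must be positive", call. = FALSE)
  if (any(concentration < 0)) stop("concentration must be non-negative",
                                   call. = FALSE)
  cdi <- (concentration / 1000 * params$intake_rate *
            params$exposure_frequency * params$exposure_duration) /
    (params$body_weight * params$averaging_time)
  tibble::tibble(concentration_used = concentration, cdi = cdi,
                 rfd = rfd, hq = cdi / rfd)
}

#' Hazard-quotient screening for high-scoring countries
#'
#' For every group above the score threshold, computes the hazard quotient
#' of each pesticide with a reference dose, using the maximum (default) or
#' mean detected site concentration in that group.
#'
#' @param records Harmonized concentration records.
#' @param scores Score table from [score_all()] on the same water body.
#' @param rfd_table Tibble `pesticide_cas`, `rfd` (mg/(kg day)).
#' @param threshold Score threshold (default 2).
#' @param statistic `"max"` (default) or `"mean"` detected concentration.
#' @param params An [exposure_params()] object.
#' @return Tibble `country`, `pesticide_cas`, `concentration_used`, `cdi`,
#'   `rfd`, `hq`, ordered by descending hazard quotient.
#' @export
hq_screen <- function(records, scores, rfd_table, threshold = 2,
                      statistic = c("max", "mean"),
                      params = exposure_params()) {
  statistic <- match.arg(statistic)
  high <- screen_high_scores(scores, threshold)
  empty <- tibble::tibble(country = character(), pesticide_cas = character(),
                          concentration_used = double(), cdi = double(),
                          rfd = double(), hq = double())
  if (length(high) == 0) return(empty)
  agg <- records |>
    dplyr::filter(.data$country %in% high, .data$detected) |>
    dplyr::group_by(.data$country, .data$pesticide_cas) |>
    dplyr::summarise(
      concentration_used = if (statistic == "max") max(.data$concentration)
                           else mean(.data$concentration),
      .groups = "drop"
    ) |>
    dplyr::inner_join(rfd_table[, c("pesticide_cas", "rfd")],
                      by = "pesticide_cas")
  if (nrow(agg) == 0) return(empty)
  hq <- hazard_quotient(agg$concentration_used, agg$rfd, params)
  dplyr::arrange(
    tibble::tibble(country = agg$country, pesticide_cas = agg$pesticide_cas,
                   hq),
    dplyr::desc(.data$hq)
  )
}

#' Drinking-water standard exceedance rates
#'
#' Compares freshwater concentrations of the panel pesticides with each
#' country's drinking-water standard, falling back to the WHO guideline when
#' no national standard exists. A record exceeds when it is a detect with
#' concentration strictly greater than the applicable standard; non-detects
#' count in the denominator as non-exceeding, unless their reporting limit
#' itself exceeds the standard, in which case the record is indeterminate
#' and excluded entirely. Countries lacking both a national and a WHO
#' standard for a pesticide are excluded for that pesticide (reported in the
#' `excluded` attribute). A `"global"` row per pesticide pools all included
#' countries, so the global rate is the record-count-weighted mean of
#' country rates.
#'
#' @param records Harmonized concentration records (surface and/or ground).
#' @param standards Drinking-water standards tibble (`jurisdiction`,
#'   `pesticide_cas`, `value` in ug/L; rows with `medium` other than
#'   `"drinking"` are ignored if a `medium` column is present).
#' @param who Optional WHO guideline tibble `pesticide_cas`, `value` (ug/L).
#' @param pesticides CAS vector to assess, default [drinking_water_panel()].
#' @param exclude Optional country codes to drop from the assessment (for
#'   example EU members, whose drinking water is treated rather than taken
#'   raw from freshwater).
#' @return Tibble `pesticide_cas`, `scope`, `n_samples`, `n_exceed`, `rate`,
#'   `standard_source`, plus attributes `excluded` and `indeterminate`.
#' @export
exceedance_rates <- function(records, standards, who = NULL,
                             pesticides = drinking_water_panel(),
                             exclude = NULL) {
  if ("medium" %in% names(standards)) {
    standards <- standards[standards$medium == "drinking", , drop = FALSE]
  }
  recs <- records |>
    dplyr::filter(.data$pesticide_cas %in% pesticides,
                  !.data$country %in% exclude)
  nat <- standards |>
    dplyr::group_by(.data$jurisdiction, .data$pesticide_cas) |>
    dplyr::summarise(std = min(.data$value), .groups = "drop")
  recs <- recs |>
    dplyr::left_join(nat, by = c(country = "jurisdiction", "pesticide_cas"))
  recs$standard_source <- ifelse(is.na(recs$std), NA_character_, "national")
  if (!is.null(who)) {
    w <- stats::setNames(who$value, who$pesticide_cas)
    fallback <- is.na(recs$std) & recs$pesticide_cas %in% names(w)
    recs$std[fallback] <- w[recs$pesticide_cas[fallback]]
    recs$standard_source[fallback] <- "WHO"
  }
  excluded <- recs |>
    dplyr::filter(is.na(.data$std)) |>
    dplyr::distinct(.data$pesticide_cas, .data$country) |>
    dplyr::mutate(reason = "no national or WHO standard")
  recs <- recs[!is.na(recs$std), , drop = FALSE]

  limit <- dplyr::coalesce(recs$lod, recs$loq)
  indeterminate <- !recs$detected & !is.na(limit) & limit > recs$std
  indet <- recs[indeterminate, , drop = FALSE]
  recs <- recs[!indeterminate, , drop = FALSE]
  recs$exceed <- recs$detected & recs$concentration > recs$std

  by_country <- recs |>
    dplyr::group_by(.data$pesticide_cas, scope = .data$country) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_exceed = sum(.data$exceed),
      rate = mean(.data$exceed),
      standard_source = if (dplyr::n_distinct(.data$standard_source) == 1)
        .data$standard_source[1] else "mixed",
      .groups = "drop"
    )
  global <- recs |>
    dplyr::group_by(.data$pesticide_cas) |>
    dplyr::summarise(
      scope = "global",
      n_samples = dplyr::n(),
      n_exceed = sum(.data$exceed),
      rate = mean(.data$exceed),
      standard_source = if (dplyr::n_distinct(.data$standard_source) == 1)
        .data$standard_source[1] else "mixed",
      .groups = "drop"
    )
  out <- dplyr::bind_rows(by_country, global) |>
    dplyr::arrange(.data$pesticide_cas, .data$scope)
  attr(out, "excluded") <- excluded
  attr(out, "indeterminate") <- indet
  out
}
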