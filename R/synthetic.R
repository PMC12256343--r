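# Seeded synthetic-data generators with analytically known ground truth.
#
# The generator emulates the statistical structure the contamination score
# assumes: per-site log10 concentrations normal around pesticide-specific
# global baselines shifted by a country effect, with optional left-censoring
# reported as a stated LOD, uneven site counts and incomplete per-site
# pesticide panels.

#' Configuration for the synthetic monitoring-data generator
#'
#' Defaults describe a well-behaved five-country monitoring network: 30
#' sites per country, country offsets spanning -1 to +1 log10 units around
#' five pesticide baselines with residual spread 0.3 log10 units, a full
#' per-site panel and no censoring.
#'
#' @param seed Integer seed; all generators derive their randomness from it.
#' @param countries Tibble with `code`, `n_sites`, `offset` (country shift,
#'   log10 units).
#' @param pesticides Tibble with `cas`, `name`, `baseline_log10` (global
#'   mean log10 concentration, ug/L) and `sd` (residual spread, log10
#'   units).
#' @param panel_coverage Probability that a site reports a given pesticide.
#' @param censor_quantile Fraction of each concentration distribution
#'   reported as a non-detect: a value falling below its own distribution's
#'   quantile at this level is replaced by a non-detect carrying the stated
#'   LOD.
#' @param lod_log10 log10 of the reported limit of detection (ug/L).
#' @param wqs_sd Spread (log10 units) of synthetic water-quality standards
#'   across jurisdictions.
#' @param water_body `"surface"` or `"ground"`.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             countries = tibble::tibble(
                               code = c("AAA", "BBB", "CCC", "DDD", "EEE"),
                               n_sites = 30L,
                               offset = c(1, 0.5, 0, -0.5, -1)
                             ),
                             pesticides = tibble::tibble(
                               cas = c("1912-24-9", "2921-88-2", "1071-83-6",
                                       "121-75-5", "138261-41-3"),
                               name = c("atrazine", "chlorpyrifos",
                                        "glyphosate", "malathion",
                                        "imidacloprid"),
                               baseline_log10 = c(-1, -1.5, -2, -2.5, -3),
                               sd = 0.3
                             ),
                             panel_coverage = 1,
                             censor_quantile = 0,
                             lod_log10 = -3,
                             wqs_sd = 0.5,
                             water_body = c("surface", "ground")) {
  water_body <- match.arg(water_body)
  stopifnot(
    panel_coverage >= 0, panel_coverage <= 1,
    censor_quantile >= 0, censor_quantile <= 1,
    all(countries$n_sites >= 1),
    all(pesticides$sd >= 0),
    wqs_sd >= 0
  )
  structure(list(seed = as.integer(seed), countries = countries,
                 pesticides = pesticides, panel_coverage = panel_coverage,
                 censor_quantile = censor_quantile, lod_log10 = lod_log10,
                 wqs_sd = wqs_sd, water_body = water_body),
            class = "synthetic_config")
}

.with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic concentration record table
#'
#' Site m in country j reports pesticide n with probability
#' `panel_coverage`; its log10 concentration is drawn from
#' `Normal(baseline_n + offset_j, sd_n)`. A draw falling below its
#' distribution's `censor_quantile` quantile is reported as a non-detect
#' carrying the configured LOD. Byte-identical output for identical
#' configurations.
#'
#' @param config A [synthetic_config()].
#' @return A concentration record tibble (see [concentration_columns()]).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- tidyr::expand_grid(
    config$countries |>
      dplyr::rowwise() |>
      dplyr::reframe(code = .data$code, offset = .data$offset,
                     site = seq_len(.data$n_sites)),
    config$pesticides
  )
  n <- nrow(grid)
  .with_seed(config$seed, {
    include <- stats::runif(n) < config$panel_coverage
    z <- stats::rnorm(n)
    log10c <- grid$baseline_log10 + grid$offset + grid$sd * z
    censored <- stats::pnorm(z) < config$censor_quantile
    out <- tibble::tibble(
      country = grid$code,
      region = NA_character_,
      water_body = config$water_body,
      site_id = sprintf("%s_s%03d", grid$code, grid$site),
      pesticide_cas = grid$cas,
      pesticide_name = grid$name,
      concentration = ifelse(censored, NA_real_, 10^log10c),
      detected = !censored,
      lod = ifelse(censored, 10^config$lod_log10, NA_real_),
      loq = NA_real_,
      year_start = 2015L,
      year_end = 2015L,
      source_id = "synthetic",
      is_mixture = FALSE
    )
    out[include, , drop = FALSE]
  })
}

#' Analytic expected contamination scores of a synthetic configuration
#'
#' With censoring off and a full panel, the expected score of country j is
#' its offset minus the site-share-weighted mean offset across countries
#' (the score removes the site-weighted global mean); exact in the
#' noise-free case, and the target for parameter-recovery checks otherwise.
#'
#' @param config A [synthetic_config()].
#' @return Tibble `country`, `expected_score`.
#' @export
expected_scores <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$censor_quantile > 0 || config$panel_coverage < 1) {
    stop("expected scores have no closed form with censoring or partial ",
         "panel coverage", call. = FALSE)
  }
  w <- config$countries$n_sites / sum(config$countries$n_sites)
  tibble::tibble(
    country = config$countries$code,
    expected_score = config$countries$offset -
      sum(w * config$countries$offset)
  )
}

#' Generate a synthetic water-quality-standard table
#'
#' Draws per-pesticide log-normal standards across synthetic jurisdictions:
#' log10 values normal around each pesticide's standard baseline (one log10
#' unit above its concentration baseline) with spread `config$wqs_sd`.
#' A spread of zero yields identical standards in every jurisdiction.
#'
#' @param config A [synthetic_config()].
#' @param jurisdictions Jurisdiction codes (default eight, `J01..J08`).
#' @param medium Standard medium (default `"surface"`).
#' @return A standards tibble (`jurisdiction`, `pesticide_cas`, `medium`,
#'   `value`, `system_id`).
#' @export
generate_wqs <- function(config,
                         jurisdictions = sprintf("J%02d", 1:8),
                         medium = "surface") {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- tidyr::expand_grid(jurisdiction = jurisdictions,
                             config$pesticides)
  .with_seed(config$seed + 1000L, {
    lw <- grid$baseline_log10 + 1 + config$wqs_sd * stats::rnorm(nrow(grid))
    tibble::tibble(
      jurisdiction = grid$jurisdiction,
      pesticide_cas = grid$cas,
      medium = medium,
      value = 10^lw,
      system_id = "synthetic"
    )
  })
}

#' Generate a synthetic pesticide-usage table
#'
#' Annual usage proportional to a per-country intensity with multiplicative
#' log-normal year-to-year noise over a fixed land area.
#'
#' @param config A [synthetic_config()].
#' @param years Years to generate (default `2010:2021`).
#' @param base_intensity Mean intensity per country, t/km2 (recycled).
#' @param land_km2 Agricultural land per country, km2 (recycled).
#' @return A usage tibble (`country`, `year`, `pesticide_use`,
#'   `agricultural_land`).
#' @export
generate_usage <- function(config, years = 2010:2021,
                           base_intensity = c(0.1, 0.3, 0.5, 0.8, 1.2),
                           land_km2 = 1e4) {
  stopifnot(inherits(config, "synthetic_config"))
  codes <- config$countries$code
  grid <- tidyr::expand_grid(country = codes, year = years)
  intensity <- stats::setNames(rep_len(base_intensity, length(codes)), codes)
  land <- stats::setNames(rep_len(land_km2, length(codes)), codes)
  .with_seed(config$seed + 2000L, {
    noise <- 10^(0.05 * stats::rnorm(nrow(grid)))
    tibble::tibble(
      country = grid$country,
      year = as.integer(grid$year),
      pesticide_use = intensity[grid$country] * land[grid$country] * noise,
      agricultural_land = unname(land[grid$country])
    )
  })
}
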