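# Mean pesticide usage intensity per country: tonnes applied per km2 of
# agricultural land, averaged over the reporting window.

#' Mean pesticide usage intensity
#'
#' For each country, the mean over available in-range years of annual
#' pesticide use divided by agricultural land area (t/km2 per year). Years
#' missing either quantity are dropped and the mean is taken over the years
#' actually available; countries with no usable year are omitted (and listed
#' in the `skipped` attribute).
#'
#' @param usage Usage tibble from [read_usage_csv()]: `country`, `year`,
#'   `pesticide_use` (t), `agricultural_land` (km2).
#' @param years Inclusive year range, default `2010:2021`.
#' @return Tibble with `country`, `mean_pui`, `n_years`.
#' @export
compute_pui <- function(usage, years = 2010:2021) {
  usable <- usage |>
    dplyr::filter(.data$year %in% years,
                  !is.na(.data$pesticide_use),
                  !is.na(.data$agricultural_land))
  if (any(usable$agricultural_land <= 0)) {
    stop("agricultural_land must be positive", call. = FALSE)
  }
  out <- usable |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      mean_pui = mean(.data$pesticide_use / .data$agricultural_land),
      n_years = dplyr::n(),
      .groups = "drop"
    )
  skipped <- setdiff(unique(usage$country), out$country)
  if (length(skipped) > 0) {
    message("no usable years in range for: ", paste(skipped, collapse = ", "))
  }
  attr(out, "skipped") <- skipped
  out
}
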