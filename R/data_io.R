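# Reading, validation and harmonization of monitoring, standards and usage
# tables. All concentrations are carried internally in micrograms per litre.

#' Canonical column set of a concentration record table
#'
#' A concentration record holds one site-level mean concentration (or
#' non-detect) of one pesticide in one country and water body.
#'
#' @return Character vector of canonical column names.
#' @export
concentration_columns <- function() {
  c("country", "region", "water_body", "site_id", "pesticide_cas",
    "pesticide_name", "concentration", "detected", "lod", "loq",
    "year_start", "year_end", "source_id", "is_mixture")
}

# Multiplicative factors to micrograms per litre. ppb is treated as ug/L and
# ppm as mg/L, assuming water density 1 kg/L.
.unit_factors <- c(
  1, 1, 1, 1e3, 1e-3, 1e6, 1, 1e3
)
names(.unit_factors) <- c("ug/l", "\u00b5g/l", "\u03bcg/l",
                          "mg/l", "ng/l", "g/l", "ppb", "ppm")

.parse_unit <- function(unit) {
  key <- tolower(trimws(unit))
  unname(.unit_factors[key])
}

.parse_num <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

.parse_flag <- function(x, default = NA) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(default, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Validate a CAS registry number
#'
#' Checks the `NN..NN-NN-N` layout and the modulo-10 check digit of the
#' Chemical Abstracts Service registry number.
#'
#' @param cas Character vector of CAS strings (whitespace tolerated).
#' @return Logical vector; `NA` for missing input.
#' @examples
#' cas_check("1912-24-9")  # atrazine, TRUE
#' cas_check("1912-24-8")  # wrong check digit, FALSE
#' @export
cas_check <- function(cas) {
  cas <- gsub("\\s+", "", as.character(cas))
  ok <- rep(NA, length(cas))
  well_formed <- !is.na(cas) & grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)
  ok[!is.na(cas) & !well_formed] <- FALSE
  for (i in which(well_formed)) {
    digits <- as.integer(strsplit(gsub("-", "", cas[i]), "")[[1]])
    n <- length(digits)
    body <- digits[-n]
    check <- sum(rev(body) * seq_along(body)) %% 10
    ok[i] <- check == digits[n]
  }
  ok
}

#' Read a pesticide concentration monitoring table
#'
#' Reads a CSV of site-level mean concentrations, maps columns through an
#' optional dialect, converts all concentration-like values to micrograms per
#' litre, and collects rows that fail validation into a rejects report rather
#' than dropping them silently.
#'
#' Required columns (after dialect mapping): `country`, `water_body`,
#' `site_id`, `pesticide_cas`, `concentration`, `unit`, `year_start`.
#' Optional: `region`, `pesticide_name`, `detected`, `lod`, `loq`,
#' `year_end`, `source_id`, `is_mixture`. When `detected` is absent a row is
#' taken as detected exactly when `concentration` is present.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(country = "Country_Name")`.
#' @return A list with `records` (tibble in canonical columns, concentrations
#'   in ug/L) and `rejects` (tibble with `row` and `reason`).
#' @export
read_concentration_csv <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw)) {
        stop("dialect column not found in file: ", src, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  required <- c("country", "water_body", "site_id", "pesticide_cas",
                "concentration", "unit", "year_start")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  optional <- setdiff(concentration_columns(), names(raw))
  for (col in optional) raw[[col]] <- rep("", nrow(raw))

  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  note <- function(idx, why) {
    new <- idx & is.na(reason)
    reason[new] <<- why
  }

  num_cols <- c("concentration", "lod", "loq", "year_start", "year_end")
  parsed <- lapply(raw[num_cols], .parse_num)
  for (col in num_cols) {
    bad <- trimws(raw[[col]]) != "" & is.na(parsed[[col]])
    note(bad, paste0("unparseable numeric: ", col))
  }
  factor <- .parse_unit(raw$unit)
  note(is.na(factor), "unknown unit")
  note(!is.na(parsed$concentration) & parsed$concentration < 0,
       "negative concentration")
  note(!is.na(parsed$lod) & parsed$lod <= 0, "non-positive lod")
  note(!is.na(parsed$loq) & parsed$loq <= 0, "non-positive loq")
  wb <- tolower(trimws(raw$water_body))
  note(!wb %in% c("surface", "ground"), "invalid water_body")

  detected <- .parse_flag(raw$detected)
  detected[is.na(detected)] <- !is.na(parsed$concentration[is.na(detected)])
  note(detected & is.na(parsed$concentration),
       "detected without concentration")

  cas <- gsub("\\s+", "", raw$pesticide_cas)
  note(cas == "", "missing pesticide_cas")
  bad_cas <- !isTRUE(all(cas_check(cas[is.na(reason)]) %in% TRUE))
  if (bad_cas) {
    warning("one or more CAS numbers fail the check-digit test; ",
            "records kept", call. = FALSE)
  }

  keep <- is.na(reason)
  records <- tibble::tibble(
    country = trimws(raw$country[keep]),
    region = dplyr::na_if(trimws(raw$region[keep]), ""),
    water_body = wb[keep],
    site_id = trimws(raw$site_id[keep]),
    pesticide_cas = cas[keep],
    pesticide_name = dplyr::na_if(trimws(raw$pesticide_name[keep]), ""),
    concentration = parsed$concentration[keep] * factor[keep],
    detected = detected[keep],
    lod = parsed$lod[keep] * factor[keep],
    loq = parsed$loq[keep] * factor[keep],
    year_start = as.integer(parsed$year_start[keep]),
    year_end = as.integer(parsed$year_end[keep]),
    source_id = dplyr::na_if(trimws(raw$source_id[keep]), ""),
    is_mixture = .parse_flag(raw$is_mixture[keep], default = FALSE)
  )
  rejects <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  list(records = records, rejects = rejects)
}

#' Read a water-quality-standard table
#'
#' @param path CSV with columns `jurisdiction`, `pesticide_cas`, `medium`
#'   (`surface`, `ground` or `drinking`), `value`, `unit`, `system_id`.
#' @return A list with `records` (values converted to ug/L) and `rejects`.
#' @export
read_wqs_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  required <- c("jurisdiction", "pesticide_cas", "medium", "value", "unit")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"system_id" %in% names(raw)) raw$system_id <- "default"
  value <- .parse_num(raw$value)
  factor <- .parse_unit(raw$unit)
  medium <- tolower(trimws(raw$medium))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(value)] <- "unparseable numeric: value"
  reason[is.na(reason) & value <= 0] <- "non-positive standard value"
  reason[is.na(reason) & is.na(factor)] <- "unknown unit"
  reason[is.na(reason) & !medium %in% c("surface", "ground", "drinking")] <-
    "invalid medium"
  keep <- is.na(reason)
  records <- tibble::tibble(
    jurisdiction = trimws(raw$jurisdiction[keep]),
    pesticide_cas = gsub("\\s+", "", raw$pesticide_cas[keep]),
    medium = medium[keep],
    value = value[keep] * factor[keep],
    system_id = trimws(raw$system_id[keep])
  )
  list(records = records,
       rejects = tibble::tibble(row = which(!keep), reason = reason[!keep]))
}

#' Read an annual pesticide-usage table
#'
#' @param path CSV with columns `country`, `year`, `pesticide_use_t` and one
#'   of `agri_land_km2` or `agri_land_ha` (FAOSTAT exports use hectares;
#'   1 km2 = 100 ha).
#' @return A tibble with `country`, `year`, `pesticide_use` (tonnes) and
#'   `agricultural_land` (km2).
#' @export
read_usage_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  required <- c("country", "year", "pesticide_use_t")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("agri_land_km2" %in% names(raw)) {
    land <- .parse_num(raw$agri_land_km2)
  } else if ("agri_land_ha" %in% names(raw)) {
    land <- .parse_num(raw$agri_land_ha) / 100
  } else {
    stop("missing required column(s): agri_land_km2 (or agri_land_ha)",
         call. = FALSE)
  }
  out <- tibble::tibble(
    country = trimws(raw$country),
    year = as.integer(.parse_num(raw$year)),
    pesticide_use = .parse_num(raw$pesticide_use_t),
    agricultural_land = land
  )
  bad <- !is.na(out$agricultural_land) & out$agricultural_land <= 0
  if (any(bad)) {
    stop("agricultural_land must be positive (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  out
}

#' Partition concentration records into usable and excluded sets
#'
#' Applies the analysis-level exclusion rules: mixture entries (for example
#' summed DDTs or HCHs, whose component shares are unknown), records whose
#' sampling started before 2010, and non-detects that carry neither a limit
#' of detection nor a limit of quantification. Every excluded record carries
#' a machine-readable reason; the two outputs partition the input exactly.
#'
#' @param records Concentration record tibble (see
#'   [read_concentration_csv()]).
#' @return A list with `kept` and `excluded` (the latter with a `reason`
#'   column).
#' @export
harmonize_records <- function(records) {
  name <- ifelse(is.na(records$pesticide_name), "", records$pesticide_name)
  mixture <- (records$is_mixture %in% TRUE) |
    grepl("^\\s*(\u2211|\u03a3|sum(s)?\\b|total\\b)", name,
          ignore.case = TRUE)
  pre2010 <- !is.na(records$year_start) & records$year_start < 2010
  no_limit <- !records$detected & is.na(records$lod) & is.na(records$loq)

  reason <- rep(NA_character_, nrow(records))
  reason[no_limit] <- "nondetect_without_limit"
  reason[pre2010] <- "pre_2010_sampling"
  reason[mixture] <- "mixture"

  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  list(kept = records[is.na(reason), , drop = FALSE], excluded = excluded)
}

#' Collapse duplicate site-by-pesticide rows by geometric mean
#'
#' The contamination score treats one (site, pesticide) pair as one
#' observation. When several rows report the same pair they are averaged on
#' the log10 scale: detected rows are combined into the geometric mean of
#' their concentrations; pairs with no detected row remain non-detects with
#' the geometric mean of their reporting limits.
#'
#' @param records Concentration record tibble after [harmonize_records()].
#' @return A tibble with one row per (country, water body, site, pesticide).
#' @export
collapse_site_duplicates <- function(records) {
  records |>
    dplyr::group_by(.data$country, .data$water_body, .data$site_id,
                    .data$pesticide_cas) |>
    dplyr::summarise(
      region = dplyr::first(.data$region),
      pesticide_name = dplyr::first(.data$pesticide_name),
      concentration = if (any(.data$detected)) {
        10^mean(log10(.data$concentration[.data$detected]))
      } else NA_real_,
      lod = if (any(.data$detected)) NA_real_ else {
        lim <- dplyr::coalesce(.data$lod, .data$loq)
        10^mean(log10(lim))
      },
      loq = NA_real_,
      detected = any(.data$detected),
      year_start = min(.data$year_start),
      year_end = suppressWarnings(max(.data$year_end)),
      source_id = dplyr::first(.data$source_id),
      is_mixture = FALSE,
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(concentration_columns()))
}

#' Write a result table as CSV with deterministic ordering
#'
#' Rows are sorted ascending by the first (identifier) column so that
#' repeated runs produce byte-identical, diff-friendly files; numeric columns
#' round-trip losslessly.
#'
#' @param rows A data frame of results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (ncol(rows) == 0) stop("result table has no columns", call. = FALSE)
  rows <- rows[order(rows[[1]]), , drop = FALSE]
  out <- as.data.frame(rows)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 17)
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
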