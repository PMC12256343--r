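# National regulation scores over a fixed pesticide panel: completeness
# (how many panel pesticides a jurisdiction regulates) and three stringency
# indices computed from the cross-jurisdiction distribution of log10
# standard values.

#' Inherit bloc-level standards into member states
#'
#' Jurisdiction blocs (for example the EU) publish uniform water-quality
#' standards that member states adopt. For every member listed, pesticides
#' with no national row inherit the bloc's row; bloc rows themselves are
#' removed so that scores are reported per country.
#'
#' @param wqs Standards tibble (`jurisdiction`, `pesticide_cas`, `medium`,
#'   `value`, `system_id`).
#' @param bloc_members Named list mapping a bloc jurisdiction id to its
#'   member codes, e.g. `list(EU = c("DEU", "FRA"))`.
#' @return Standards tibble with bloc rows expanded.
#' @export
expand_bloc_standards <- function(wqs, bloc_members) {
  if (is.null(bloc_members) || length(bloc_members) == 0) return(wqs)
  out <- wqs[!wqs$jurisdiction %in% names(bloc_members), , drop = FALSE]
  for (bloc in names(bloc_members)) {
    bloc_rows <- wqs[wqs$jurisdiction == bloc, , drop = FALSE]
    if (nrow(bloc_rows) == 0) next
    for (member in bloc_members[[bloc]]) {
      have <- out[out$jurisdiction == member, c("pesticide_cas", "medium")]
      add <- bloc_rows[!paste(bloc_rows$pesticide_cas, bloc_rows$medium) %in%
                         paste(have$pesticide_cas, have$medium), ,
                       drop = FALSE]
      if (nrow(add) == 0) next
      add$jurisdiction <- member
      add$system_id <- paste0(bloc, ":", add$system_id)
      out <- dplyr::bind_rows(out, add)
    }
  }
  out
}

#' Keep only the most conservative standards system per jurisdiction
#'
#' Some jurisdictions maintain several standards systems for the same water
#' medium; only the most conservative (lowest-valued) one enters the
#' analysis. Systems are compared by their mean log10 standard value over
#' the pesticides common to all of the jurisdiction's systems (falling back
#' to each system's own pesticides when none are shared); ties break by
#' lexical `system_id`.
#'
#' @param wqs Standards tibble; may span multiple jurisdictions and media.
#' @return The rows of the selected system for each jurisdiction and medium.
#' @export
select_conservative_system <- function(wqs) {
  if (nrow(wqs) == 0) return(wqs)
  pick <- function(block) {
    systems <- unique(block$system_id)
    if (length(systems) == 1) return(block)
    shared <- Reduce(intersect,
                     lapply(split(block$pesticide_cas, block$system_id),
                            unique))
    stat <- vapply(sort(systems), function(s) {
      rows <- block[block$system_id == s, , drop = FALSE]
      if (length(shared) > 0) {
        rows <- rows[rows$pesticide_cas %in% shared, , drop = FALSE]
      }
      mean(log10(rows$value))
    }, numeric(1))
    best <- names(stat)[which.min(stat)]  # which.min: first (lexical) on tie
    block[block$system_id == best, , drop = FALSE]
  }
  key <- paste(wqs$jurisdiction, wqs$medium, sep = "\r")
  dplyr::bind_rows(lapply(split(wqs, key), pick))
}

#' Cross-jurisdiction distribution of log10 standard values
#'
#' One value per jurisdiction per pesticide (several rows collapse to their
#' geometric mean); the jurisdiction under scoring is included.
#'
#' @param wqs Standards tibble after system selection.
#' @return Tibble with `pesticide_cas`, `mu_log10`, `sigma_log10`,
#'   `min_log10`, `max_log10`, `n_jurisdictions`.
#' @export
wqs_global_stats <- function(wqs) {
  wqs |>
    dplyr::group_by(.data$jurisdiction, .data$pesticide_cas) |>
    dplyr::summarise(lw = mean(log10(.data$value)), .groups = "drop") |>
    dplyr::group_by(.data$pesticide_cas) |>
    dplyr::summarise(
      mu_log10 = mean(.data$lw),
      sigma_log10 = stats::sd(.data$lw),
      min_log10 = min(.data$lw),
      max_log10 = max(.data$lw),
      n_jurisdictions = dplyr::n(),
      .groups = "drop"
    )
}

.jurisdiction_values <- function(wqs, jurisdiction, panel) {
  wqs[wqs$jurisdiction == jurisdiction &
        wqs$pesticide_cas %in% panel, , drop = FALSE] |>
    dplyr::group_by(.data$pesticide_cas) |>
    dplyr::summarise(lw = mean(log10(.data$value)), .groups = "drop")
}

#' Completeness score: regulated panel pesticides
#'
#' @param wqs Standards tibble (after system selection) of one or more
#'   jurisdictions.
#' @param panel Character vector of panel CAS numbers (30 by convention).
#' @param jurisdiction Jurisdiction to score.
#' @return Integer count in `0..length(panel)`.
#' @export
completeness_score <- function(wqs, panel, jurisdiction) {
  vals <- .jurisdiction_values(wqs, jurisdiction, panel)
  as.integer(nrow(vals))
}

#' Stringency score 1: summed exceedance probability
#'
#' For each regulated panel pesticide, the probability that a standard drawn
#' from the fitted log-normal cross-jurisdiction distribution exceeds the
#' jurisdiction's own standard, summed over pesticides. Valid only when the
#' log10 standards are compatible with normality (see [wqs_normality()]).
#'
#' @param wqs Standards after system selection (all jurisdictions).
#' @param panel Panel CAS vector.
#' @param jurisdiction Jurisdiction to score.
#' @param stats Optional precomputed [wqs_global_stats()] table.
#' @return Numeric sum; pesticides with zero or undefined spread are skipped
#'   with a warning. `NA` when the jurisdiction regulates nothing.
#' @export
ns1_score <- function(wqs, panel, jurisdiction, stats = NULL) {
  if (is.null(stats)) stats <- wqs_global_stats(wqs)
  vals <- .jurisdiction_values(wqs, jurisdiction, panel)
  if (nrow(vals) == 0) return(NA_real_)
  vals <- dplyr::inner_join(vals, stats, by = "pesticide_cas")
  usable <- !is.na(vals$sigma_log10) & vals$sigma_log10 > 0
  if (any(!usable)) {
    warning("skipping ", sum(!usable),
            " pesticide(s) with zero/undefined standard spread in NS1",
            call. = FALSE)
  }
  v <- vals[usable, , drop = FALSE]
  sum(1 - stats::pnorm((v$lw - v$mu_log10) / v$sigma_log10))
}

#' Stringency score 2: summed min-max relative position
#'
#' Each regulated pesticide contributes `1 - (log10 WQS - min)/(max - min)`
#' (1 when the jurisdiction holds the strictest standard worldwide, 0 at the
#' laxest), clamped to `[0, 1]`; pesticides whose global standards are all
#' identical contribute the neutral value 0.5 with a warning.
#'
#' @inheritParams ns1_score
#' @return Numeric sum; `NA` when nothing is regulated.
#' @export
ns2_score <- function(wqs, panel, jurisdiction, stats = NULL) {
  if (is.null(stats)) stats <- wqs_global_stats(wqs)
  vals <- .jurisdiction_values(wqs, jurisdiction, panel)
  if (nrow(vals) == 0) return(NA_real_)
  vals <- dplyr::inner_join(vals, stats, by = "pesticide_cas")
  degenerate <- vals$max_log10 == vals$min_log10
  if (any(degenerate)) {
    warning("NS2: ", sum(degenerate),
            " pesticide(s) have identical standards everywhere; ",
            "neutral term 0.5 used", call. = FALSE)
  }
  term <- ifelse(degenerate, 0.5,
                 1 - (vals$lw - vals$min_log10) /
                   (vals$max_log10 - vals$min_log10))
  sum(pmin(pmax(term, 0), 1))
}

#' Stringency score 3: mean log deviation from the global mean standard
#'
#' The average over the N regulated pesticides of
#' `log10 WQS - mean(log10 global standards)`; negative values mean standards
#' stricter than the global central tendency.
#'
#' @inheritParams ns1_score
#' @return Numeric mean; `NA` when nothing is regulated.
#' @export
ns3_score <- function(wqs, panel, jurisdiction, stats = NULL) {
  if (is.null(stats)) stats <- wqs_global_stats(wqs)
  vals <- .jurisdiction_values(wqs, jurisdiction, panel)
  if (nrow(vals) == 0) return(NA_real_)
  vals <- dplyr::inner_join(vals, stats, by = "pesticide_cas")
  mean(vals$lw - vals$mu_log10)
}

#' Shapiro-Wilk normality screen of log10 standard values
#'
#' The exceedance-probability stringency score assumes log-normal standards;
#' this screen runs the Shapiro-Wilk test on the log10 values, by default per
#' pesticide (pooling would mix scales). Pesticides with fewer than 3 values
#' or zero variance are skipped with a note.
#'
#' @param wqs Standards after system selection.
#' @param panel Optional panel restriction.
#' @param per_pesticide Test each pesticide separately (default) or pool all
#'   log10 values into one test.
#' @param alpha Rejection level (default 0.05).
#' @return Tibble with `pesticide_cas`, `n_values`, `p_value`,
#'   `normal_at_005`, `note`.
#' @export
wqs_normality <- function(wqs, panel = NULL, per_pesticide = TRUE,
                          alpha = 0.05) {
  if (!is.null(panel)) {
    wqs <- wqs[wqs$pesticide_cas %in% panel, , drop = FALSE]
  }
  one <- wqs |>
    dplyr::group_by(.data$jurisdiction, .data$pesticide_cas) |>
    dplyr::summarise(lw = mean(log10(.data$value)), .groups = "drop")
  run <- function(x, label) {
    if (length(x) < 3) {
      return(tibble::tibble(pesticide_cas = label,
                            n_values = length(x), p_value = NA_real_,
                            normal_at_005 = NA, note = "fewer than 3 values"))
    }
    if (stats::sd(x) == 0) {
      return(tibble::tibble(pesticide_cas = label,
                            n_values = length(x), p_value = NA_real_,
                            normal_at_005 = NA, note = "zero variance"))
    }
    p <- stats::shapiro.test(x)$p.value
    tibble::tibble(pesticide_cas = label, n_values = length(x),
                   p_value = p, normal_at_005 = p >= alpha,
                   note = NA_character_)
  }
  if (per_pesticide) {
    dplyr::bind_rows(lapply(split(one$lw, one$pesticide_cas),
                            run, label = NA)) |>
      dplyr::mutate(pesticide_cas = sort(unique(one$pesticide_cas))) |>
      dplyr::select(dplyr::all_of(c("pesticide_cas", "n_values", "p_value",
                                    "normal_at_005", "note")))
  } else {
    run(one$lw, "pooled")
  }
}

#' Regulation completeness and stringency scores for every jurisdiction
#'
#' End-to-end wrapper: optional bloc expansion, conservative-system
#' selection, the normality prerequisite screen, and the per-jurisdiction
#' scores over the pesticide panel. `ns1_valid` is `FALSE` for all rows when
#' any tested pesticide rejects normality of its log10 standards (the
#' exceedance-probability score then should not be interpreted).
#'
#' @param wqs Standards tibble.
#' @param panel Panel CAS vector (30 pesticides by convention).
#' @param medium `"surface"` or `"ground"`.
#' @param bloc_members Optional bloc expansion, see
#'   [expand_bloc_standards()].
#' @return Tibble with one row per jurisdiction: `jurisdiction`, `medium`,
#'   `cs`, `ns1`, `ns1_valid`, `ns2`, `ns3`, `n_regulated`.
#' @export
regulation_scores <- function(wqs, panel, medium = c("surface", "ground"),
                              bloc_members = NULL) {
  medium <- match.arg(medium)
  wqs <- wqs[wqs$medium == medium, , drop = FALSE]
  # select each jurisdiction's (and each bloc's) own conservative system
  # first, then fill member-state gaps, so inherited bloc rows never compete
  # with national systems
  wqs <- select_conservative_system(wqs)
  wqs <- expand_bloc_standards(wqs, bloc_members)
  wqs <- wqs[wqs$pesticide_cas %in% panel, , drop = FALSE]
  if (nrow(wqs) == 0) {
    return(tibble::tibble(jurisdiction = character(), medium = character(),
                          cs = integer(), ns1 = double(), ns1_valid = logical(),
                          ns2 = double(), ns3 = double(),
                          n_regulated = integer()))
  }
  gstats <- wqs_global_stats(wqs)
  normality <- wqs_normality(wqs, panel = panel)
  tested <- !is.na(normality$normal_at_005)
  ns1_valid <- !any(tested) || all(normality$normal_at_005[tested])

  jurisdictions <- sort(unique(wqs$jurisdiction))
  res <- lapply(jurisdictions, function(j) {
    n_reg <- completeness_score(wqs, panel, j)
    tibble::tibble(
      jurisdiction = j,
      medium = medium,
      cs = n_reg,
      ns1 = suppressWarnings(ns1_score(wqs, panel, j, stats = gstats)),
      ns1_valid = ns1_valid,
      ns2 = suppressWarnings(ns2_score(wqs, panel, j, stats = gstats)),
      ns3 = ns3_score(wqs, panel, j, stats = gstats),
      n_regulated = n_reg
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "normality") <- normality
  out
}
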