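# Shared fixtures and independent brute-force oracles. The oracles use only
# base-R loops so they stay independent of the package's vectorized paths.

rec <- function(country, site, cas, conc = NA_real_, detected = TRUE,
                lod = NA_real_, loq = NA_real_, wb = "surface",
                region = NA_character_, name = NA_character_,
                year = 2015L, mixture = FALSE) {
  tibble::tibble(
    country = country, region = region, water_body = wb,
    site_id = site, pesticide_cas = cas, pesticide_name = name,
    concentration = conc, detected = detected, lod = lod, loq = loq,
    year_start = year, year_end = year, source_id = "test",
    is_mixture = mixture
  )
}

# Direct evaluation of the contamination score: per-pesticide global mean of
# log10 values over all sites, then per-site mean deviation, then per-group
# mean over sites. Pure loops.
brute_scores <- function(records) {
  val <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (records$detected[i]) {
      val[i] <- log10(records$concentration[i])
    } else {
      lim <- records$lod[i]
      if (is.na(lim)) lim <- records$loq[i]
      val[i] <- log10(lim)
    }
  }
  keep <- !is.na(val)
  records <- records[keep, , drop = FALSE]
  val <- val[keep]
  ct <- list()
  for (p in unique(records$pesticide_cas)) {
    ct[[p]] <- mean(val[records$pesticide_cas == p])
  }
  out <- c()
  for (g in unique(records$country)) {
    idx <- which(records$country == g)
    site_devs <- c()
    for (s in unique(records$site_id[idx])) {
      rows <- idx[records$site_id[idx] == s]
      devs <- c()
      for (i in rows) devs <- c(devs, val[i] - ct[[records$pesticide_cas[i]]])
      site_devs <- c(site_devs, mean(devs))
    }
    out[g] <- mean(site_devs)
  }
  out
}

# Direct evaluation of the regulation scores for one jurisdiction from a
# long table (jurisdiction, pesticide_cas, value), one value per pair.
brute_regulation <- function(wqs, panel, j) {
  mu <- sigma <- lo <- hi <- list()
  for (p in unique(wqs$pesticide_cas)) {
    lw <- log10(wqs$value[wqs$pesticide_cas == p])
    mu[[p]] <- mean(lw); sigma[[p]] <- stats::sd(lw)
    lo[[p]] <- min(lw); hi[[p]] <- max(lw)
  }
  own <- wqs[wqs$jurisdiction == j & wqs$pesticide_cas %in% panel, ,
             drop = FALSE]
  cs <- nrow(own)
  ns1 <- ns2 <- 0
  ns3_terms <- c()
  for (i in seq_len(nrow(own))) {
    p <- own$pesticide_cas[i]
    lw <- log10(own$value[i])
    if (!is.na(sigma[[p]]) && sigma[[p]] > 0) {
      ns1 <- ns1 + (1 - stats::pnorm((lw - mu[[p]]) / sigma[[p]]))
    }
    if (hi[[p]] == lo[[p]]) {
      ns2 <- ns2 + 0.5
    } else {
      t <- 1 - (lw - lo[[p]]) / (hi[[p]] - lo[[p]])
      ns2 <- ns2 + min(max(t, 0), 1)
    }
    ns3_terms <- c(ns3_terms, lw - mu[[p]])
  }
  list(cs = cs, ns1 = ns1, ns2 = ns2,
       ns3 = if (cs == 0) NA_real_ else mean(ns3_terms))
}

brute_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Random small scoring instance for property tests; includes non-detects
# carrying an LOD and heterogeneous per-site panels.
random_instance <- function(seed) {
  set.seed(seed)
  n_countries <- sample(2:5, 1)
  n_pest <- sample(1:3, 1)
  cas <- sprintf("100-00-%d", seq_len(n_pest))
  rows <- list()
  for (ci in seq_len(n_countries)) {
    n_sites <- sample(1:4, 1)
    for (si in seq_len(n_sites)) {
      panel <- which(stats::runif(n_pest) < 0.8)
      if (length(panel) == 0) panel <- sample(n_pest, 1)
      for (p in panel) {
        nd <- stats::runif(1) < 0.25
        conc <- 10^stats::rnorm(1, -2 + 0.5 * p, 1)
        rows[[length(rows) + 1]] <- rec(
          country = sprintf("C%02d", ci),
          site = sprintf("C%02d_s%d", ci, si),
          cas = cas[p],
          conc = if (nd) NA_real_ else conc,
          detected = !nd,
          lod = if (nd) 10^stats::rnorm(1, -3, 0.5) else NA_real_
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

write_conc_csv <- function(path, lines) {
  header <- paste("country,region,water_body,site_id,pesticide_cas",
                  "pesticide_name,concentration,unit,detected,lod,loq",
                  "year_start,year_end,source_id", sep = ",")
  writeLines(c(header, lines), path)
}
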