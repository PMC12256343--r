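wqs_row <- function(jurisdiction, cas, value, system_id = "default",
                    medium = "surface") {
  tibble::tibble(jurisdiction = jurisdiction, pesticide_cas = cas,
                 medium = medium, value = value, system_id = system_id)
}

test_that("conservative-system selection keeps the strictest system", {
  one <- dplyr::bind_rows(wqs_row("IRL", "p1", 0.1), wqs_row("IRL", "p2", 1))
  expect_equal(select_conservative_system(one), one)

  dominated <- dplyr::bind_rows(
    wqs_row("IRL", "p1", 0.1, "A"), wqs_row("IRL", "p2", 0.5, "A"),
    wqs_row("IRL", "p1", 1, "B"), wqs_row("IRL", "p2", 5, "B")
  )
  expect_equal(unique(select_conservative_system(dominated)$system_id), "A")

  # non-dominating systems: lower mean log10 over shared pesticides wins
  crossed <- dplyr::bind_rows(
    wqs_row("IRL", "p1", 0.001, "A"), wqs_row("IRL", "p2", 10, "A"),
    wqs_row("IRL", "p1", 1, "B"), wqs_row("IRL", "p2", 0.1, "B")
  )
  # mean log10: A = (-3 + 1)/2 = -1; B = (0 - 1)/2 = -0.5 -> A
  expect_equal(unique(select_conservative_system(crossed)$system_id), "A")

  tie <- dplyr::bind_rows(
    wqs_row("IRL", "p1", 0.1, "Zeta"), wqs_row("IRL", "p1", 0.1, "Alpha")
  )
  expect_equal(unique(select_conservative_system(tie)$system_id), "Alpha")
  expect_equal(nrow(select_conservative_system(tie[0, ])), 0)
})

test_that("completeness counts the regulated panel pesticides", {
  panel <- sprintf("p%02d", 1:30)
  full <- dplyr::bind_rows(lapply(panel, function(p) wqs_row("IRL", p, 0.1)))
  expect_identical(completeness_score(full, panel, "IRL"), 30L)
  expect_identical(completeness_score(full, panel, "EGY"), 0L)
  seven <- full[1:7, ]
  expect_identical(completeness_score(seven, panel, "IRL"), 7L)
  # off-panel standards do not count
  extra <- dplyr::bind_rows(seven, wqs_row("IRL", "offpanel", 1))
  expect_identical(completeness_score(extra, panel, "IRL"), 7L)
})

test_that("stringency terms behave at the distribution's center and extremes", {
  panel <- c("p1", "p2")
  # three jurisdictions, log10 values -1, 0, 1 for p1; B sits at the mean
  tab <- dplyr::bind_rows(
    wqs_row("A", "p1", 0.1), wqs_row("B", "p1", 1), wqs_row("C", "p1", 10)
  )
  expect_equal(ns1_score(tab, panel, "B"), 0.5)   # Phi(0) symmetry
  # a vanishing standard drives the exceedance term to 1
  fixed <- tibble::tibble(pesticide_cas = "p1", mu_log10 = 0,
                          sigma_log10 = 1, min_log10 = -1, max_log10 = 1,
                          n_jurisdictions = 3L)
  tiny <- wqs_row("D", "p1", 1e-30)
  expect_gt(ns1_score(tiny, panel, "D", stats = fixed), 1 - 1e-6)
  # min-max position: strictest 1, laxest 0
  expect_equal(ns2_score(tab, panel, "A"), 1)
  expect_equal(ns2_score(tab, panel, "C"), 0)
  expect_equal(ns2_score(tab, panel, "B"), 0.5)
  # mean deviation from the global mean standard
  expect_equal(ns3_score(tab, panel, "B"), 0)
  stats10 <- tibble::tibble(pesticide_cas = c("p1", "p2"),
                            mu_log10 = c(0, -1), sigma_log10 = 1,
                            min_log10 = -3, max_log10 = 3,
                            n_jurisdictions = 3L)
  shifted <- dplyr::bind_rows(wqs_row("J", "p1", 0.1),
                              wqs_row("J", "p2", 0.01))
  expect_equal(ns3_score(shifted, panel, "J", stats = stats10), -1)
})

test_that("regulation scores match the brute-force oracle on toy tables", {
  set.seed(2024)
  panel <- c("p1", "p2", "p3")
  for (i in 1:8) {
    rows <- list()
    for (j in c("AAA", "BBB", "CCC", "DDD")) {
      for (p in panel) {
        if (runif(1) < 0.75) {
          rows[[length(rows) + 1]] <- wqs_row(j, p, 10^rnorm(1))
        }
      }
    }
    tab <- dplyr::bind_rows(rows)
    for (j in unique(tab$jurisdiction)) {
      oracle <- brute_regulation(tab, panel, j)
      expect_identical(completeness_score(tab, panel, j),
                       as.integer(oracle$cs))
      expect_equal(suppressWarnings(ns1_score(tab, panel, j)), oracle$ns1,
                   tolerance = 1e-12)
      expect_equal(suppressWarnings(ns2_score(tab, panel, j)), oracle$ns2,
                   tolerance = 1e-12)
      expect_equal(ns3_score(tab, panel, j), oracle$ns3, tolerance = 1e-12)
    }
  }
})

test_that("an exceedance-probability term checks out against numeric integration", {
  tab <- dplyr::bind_rows(
    wqs_row("A", "p1", 0.05), wqs_row("B", "p1", 1), wqs_row("C", "p1", 30)
  )
  lw <- log10(c(0.05, 1, 30))
  z <- (lw[1] - mean(lw)) / sd(lw)
  tail_prob <- stats::integrate(stats::dnorm, lower = z,
                                upper = Inf)$value
  expect_equal(ns1_score(tab, "p1", "A"), tail_prob, tolerance = 1e-7)
})

test_that("degenerate spreads fall back with warnings", {
  tab <- dplyr::bind_rows(
    wqs_row("A", "p1", 1), wqs_row("B", "p1", 1), wqs_row("C", "p1", 1)
  )
  expect_warning(v2 <- ns2_score(tab, "p1", "A"), "identical standards")
  expect_equal(v2, 0.5)
  expect_warning(v1 <- ns1_score(tab, "p1", "A"), "spread")
  expect_equal(v1, 0)  # every term skipped
})

test_that("tightening a non-extreme standard raises stringency", {
  tab <- dplyr::bind_rows(
    wqs_row("A", "p1", 0.1), wqs_row("B", "p1", 1), wqs_row("C", "p1", 10)
  )
  tighter <- tab
  tighter$value[tighter$jurisdiction == "B"] <- 0.5
  for (f in list(ns1_score, ns2_score)) {
    expect_gte(f(tighter, "p1", "B"), f(tab, "p1", "B"))
  }
  expect_lte(ns3_score(tighter, "p1", "B"), ns3_score(tab, "p1", "B"))
  # per-term bounds: sums stay within [0, N]
  for (j in c("A", "B", "C")) {
    expect_gte(ns1_score(tab, "p1", j), 0)
    expect_lte(ns1_score(tab, "p1", j), 1)
    expect_gte(ns2_score(tab, "p1", j), 0)
    expect_lte(ns2_score(tab, "p1", j), 1)
  }
})

test_that("the Shapiro-Wilk screen accepts log-normal and rejects bimodal standards", {
  set.seed(11)
  lognormal <- dplyr::bind_rows(lapply(1:50, function(i) {
    wqs_row(sprintf("J%02d", i), "p1", 10^rnorm(1))
  }))
  rep1 <- wqs_normality(lognormal)
  expect_equal(rep1$n_values, 50L)
  expect_gt(rep1$p_value, 0.05)
  expect_true(rep1$normal_at_005)

  identical_vals <- dplyr::bind_rows(lapply(1:5, function(i) {
    wqs_row(sprintf("J%02d", i), "p1", 1)
  }))
  rep2 <- wqs_normality(identical_vals)
  expect_true(is.na(rep2$p_value))
  expect_equal(rep2$note, "zero variance")

  bimodal <- dplyr::bind_rows(lapply(1:20, function(i) {
    wqs_row(sprintf("J%02d", i), "p1",
            if (i <= 10) 10^rnorm(1, -6, 0.05) else 10^rnorm(1, 6, 0.05))
  }))
  rep3 <- wqs_normality(bimodal)
  expect_lt(rep3$p_value, 0.05)
  expect_false(rep3$normal_at_005)

  pooled <- wqs_normality(lognormal, per_pesticide = FALSE)
  expect_equal(pooled$pesticide_cas, "pooled")
})

test_that("bloc members inherit standards and share identical scores", {
  panel <- c("p1", "p2")
  tab <- dplyr::bind_rows(
    wqs_row("EU", "p1", 0.1, medium = "ground"),
    wqs_row("EU", "p2", 0.1, medium = "ground"),
    wqs_row("DEU", "p1", 0.05, medium = "ground"),  # national row wins
    wqs_row("USA", "p1", 1, medium = "ground"),
    wqs_row("USA", "p2", 2, medium = "ground")
  )
  members <- list(EU = c("DEU", "FRA", "ITA"))
  res <- regulation_scores(tab, panel, medium = "ground",
                           bloc_members = members)
  expect_false("EU" %in% res$jurisdiction)
  expect_setequal(res$jurisdiction, c("DEU", "FRA", "ITA", "USA"))
  fra <- res[res$jurisdiction == "FRA", ]
  ita <- res[res$jurisdiction == "ITA", ]
  expect_equal(fra$ns2, ita$ns2)
  expect_equal(fra$ns3, ita$ns3)
  expect_equal(fra$cs, 2L)
  deu <- res[res$jurisdiction == "DEU", ]
  expect_gte(deu$ns2, fra$ns2)  # stricter national p1 standard
})

test_that("the wrapper reports CS = N and invalidates NS1 under non-normality", {
  panel <- c("p1", "p2")
  set.seed(5)
  rows <- lapply(1:20, function(i) {
    dplyr::bind_rows(
      wqs_row(sprintf("J%02d", i), "p1",
              if (i <= 10) 10^rnorm(1, -6, 0.05) else 10^rnorm(1, 6, 0.05)),
      wqs_row(sprintf("J%02d", i), "p2", 10^rnorm(1))
    )
  })
  tab <- dplyr::bind_rows(rows)
  res <- regulation_scores(tab, panel, medium = "surface")
  expect_equal(res$cs, res$n_regulated)
  expect_true(all(res$cs == 2L))
  expect_false(any(res$ns1_valid))  # p1 standards are bimodal
  norm <- attr(res, "normality")
  expect_equal(nrow(norm), 2)
})
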