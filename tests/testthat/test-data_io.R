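test_that("a well-formed file reads into records with no rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_conc_csv(path, c(
    "CHN,,surface,s1,1912-24-9,atrazine,0.5,ug/L,true,,,2015,2016,src1",
    "CHN,,surface,s2,1912-24-9,atrazine,,ug/L,false,0.01,,2015,,src1",
    "FRA,,ground,s1,2921-88-2,chlorpyrifos,1.2,ug/L,true,,,2012,,src2"
  ))
  rd <- read_concentration_csv(path)
  expect_equal(nrow(rd$records), 3)
  expect_equal(nrow(rd$rejects), 0)
  expect_equal(rd$records$concentration[1], 0.5)
  expect_false(rd$records$detected[2])
  expect_equal(rd$records$lod[2], 0.01)
  expect_equal(rd$records$year_start, c(2015L, 2015L, 2012L))
})

test_that("units are harmonized to ug/L with fixed factors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_conc_csv(path, c(
    "CHN,,surface,s1,1912-24-9,a,0.005,mg/L,true,,,2015,,x",
    "CHN,,surface,s2,1912-24-9,a,5000,ng/L,true,,,2015,,x",
    "CHN,,surface,s3,1912-24-9,a,5,ppb,true,,,2015,,x",
    "CHN,,surface,s4,1912-24-9,a,0.005,ppm,true,,,2015,,x"
  ))
  rd <- read_concentration_csv(path)
  expect_equal(rd$records$concentration, rep(5.0, 4))
})

test_that("invalid rows become rejects with machine-readable reasons", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_conc_csv(path, c(
    "CHN,,surface,s1,1912-24-9,a,-0.5,ug/L,true,,,2015,,x",
    "CHN,,surface,s2,1912-24-9,a,0.5,furlongs,true,,,2015,,x",
    "CHN,,surface,s3,1912-24-9,a,abc,ug/L,true,,,2015,,x",
    "CHN,,lake,s4,1912-24-9,a,0.5,ug/L,true,,,2015,,x",
    "CHN,,surface,s5,1912-24-9,a,0.5,ug/L,true,,,2015,,x"
  ))
  rd <- read_concentration_csv(path)
  expect_equal(nrow(rd$records), 1)
  expect_setequal(rd$rejects$reason,
                  c("negative concentration", "unknown unit",
                    "unparseable numeric: concentration",
                    "invalid water_body"))
  expect_equal(rd$rejects$row, 1:4)
})

test_that("a missing required column raises a schema error naming it", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,water_body,site_id,concentration,unit,year_start",
               "CHN,surface,s1,0.5,ug/L,2015"), path)
  expect_error(read_concentration_csv(path), "pesticide_cas")
})

test_that("dialect maps foreign column names onto the canonical schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Nation,water_body,site_id,pesticide_cas,Conc,unit,year_start",
    "CHN,surface,s1,1912-24-9,0.5,ug/L,2015"
  ), path)
  rd <- read_concentration_csv(
    path, dialect = c(country = "Nation", concentration = "Conc"))
  expect_equal(rd$records$country, "CHN")
  expect_equal(rd$records$concentration, 0.5)
  expect_error(read_concentration_csv(path, dialect = c(country = "Nope")),
               "Nope")
})

test_that("CAS check digits validate and invalid ones only warn at read", {
  expect_true(cas_check("1912-24-9"))
  expect_true(cas_check(" 60-57-1 "))
  expect_false(cas_check("1912-24-8"))
  expect_false(cas_check("not-a-cas"))
  expect_true(is.na(cas_check(NA)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_conc_csv(path,
    "CHN,,surface,s1,1912-24-8,a,0.5,ug/L,true,,,2015,,x")
  expect_warning(rd <- read_concentration_csv(path), "check-digit")
  expect_equal(nrow(rd$records), 1)
})

test_that("harmonization excludes mixtures, pre-2010 sampling and limitless non-detects", {
  records <- dplyr::bind_rows(
    rec("CHN", "s1", "50-29-3", name = "∑DDTs", conc = 1),
    rec("CHN", "s2", "50-29-3", name = "Total HCHs", conc = 1),
    rec("CHN", "s3", "50-29-3", name = "DDT", conc = 1, mixture = TRUE),
    rec("CHN", "s4", "1912-24-9", conc = 2),
    rec("CHN", "s5", "1912-24-9", conc = 2, year = 2009L),
    rec("CHN", "s6", "1912-24-9", detected = FALSE),
    rec("CHN", "s7", "1912-24-9", detected = FALSE, loq = 0.02)
  )
  h <- harmonize_records(records)
  expect_equal(h$excluded$reason,
               c("mixture", "mixture", "mixture", "pre_2010_sampling",
                 "nondetect_without_limit"))
  expect_setequal(h$kept$site_id, c("s4", "s7"))
  # partition: nothing lost, nothing duplicated
  expect_equal(nrow(h$kept) + nrow(h$excluded), nrow(records))
  # idempotence: a second pass excludes nothing
  h2 <- harmonize_records(h$kept)
  expect_equal(nrow(h2$excluded), 0)
  expect_equal(h2$kept, h$kept)
})

test_that("duplicate site-pesticide rows collapse to the geometric mean", {
  records <- dplyr::bind_rows(
    rec("CHN", "s1", "1912-24-9", conc = 1),
    rec("CHN", "s1", "1912-24-9", conc = 100),
    rec("CHN", "s2", "1912-24-9", detected = FALSE, lod = 0.01),
    rec("CHN", "s2", "1912-24-9", detected = FALSE, loq = 1)
  )
  out <- collapse_site_duplicates(records)
  expect_equal(nrow(out), 2)
  s1 <- out[out$site_id == "s1", ]
  expect_equal(s1$concentration, 10)  # geometric mean of 1 and 100
  s2 <- out[out$site_id == "s2", ]
  expect_false(s2$detected)
  expect_equal(s2$lod, 0.1)  # geometric mean of the reporting limits
  # a detected row wins over duplicate non-detects
  mixed <- dplyr::bind_rows(
    rec("CHN", "s3", "1912-24-9", conc = 4),
    rec("CHN", "s3", "1912-24-9", detected = FALSE, lod = 0.01)
  )
  m <- collapse_site_duplicates(mixed)
  expect_true(m$detected)
  expect_equal(m$concentration, 4)
})

test_that("result tables round-trip losslessly through write and re-read", {
  tbl <- tibble::tibble(
    group_id = c("CHN", "ALB", "THA"),
    score = c(-0.5893716428371829, 2.78, pi),
    n_sites = c(10L, 2L, 3L)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(tbl, path)
  back <- utils::read.csv(path)
  expect_equal(back$group_id, sort(tbl$group_id))
  expect_equal(back$score[back$group_id == "CHN"], tbl$score[1])
  expect_equal(back$score[back$group_id == "THA"], pi)
  expect_error(write_results_table(tbl[, 0], path), "no columns")
})

test_that("standards and usage tables read with unit conversion", {
  wpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "jurisdiction,pesticide_cas,medium,value,unit,system_id",
    "IRL,1912-24-9,surface,0.1,ug/L,nat",
    "IRL,1912-24-9,surface,0.0001,mg/L,env",
    "XXX,1912-24-9,surface,-1,ug/L,nat",
    "YYY,1912-24-9,pond,1,ug/L,nat"
  ), wpath)
  w <- read_wqs_csv(wpath)
  expect_equal(nrow(w$records), 2)
  expect_equal(w$records$value, c(0.1, 0.1))
  expect_setequal(w$rejects$reason,
                  c("non-positive standard value", "invalid medium"))

  upath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,year,pesticide_use_t,agri_land_ha",
               "CHN,2015,100,1000000"), upath)
  u <- read_usage_csv(upath)
  expect_equal(u$agricultural_land, 10000)  # 1e6 ha = 1e4 km2
})
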