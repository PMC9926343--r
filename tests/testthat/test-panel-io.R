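test_that("wide CSV round-trips through the long panel, preserving suppression", {
  path <- write_wide_csv(list(
    list(county_fips = "01001", date = "2020-01-01", anxiety = 1.5, cough = 2),
    list(county_fips = "01003", date = "2020-01-01", anxiety = 3, cough = 4)
  ))
  p <- read_symptom_panel(path)
  expect_s3_class(p, "symptom_panel")
  expect_equal(nrow(p), 4L)
  expect_equal(sum(is.na(p$weight)), 0L)
  expect_setequal(attr(p, "registry")$symptom_id, c("anxiety", "cough"))

  # one suppressed cell: missing, not zero
  path2 <- write_wide_csv(list(
    list(county_fips = "01001", date = "2020-01-01", anxiety = 1.5, cough = 2),
    list(county_fips = "01003", date = "2020-01-01", anxiety = NA, cough = 4)
  ))
  p2 <- read_symptom_panel(path2)
  expect_equal(nrow(p2), 4L)
  expect_equal(sum(is.na(p2$weight)), 1L)
  expect_true(is.na(p2$weight[p2$county_fips == "01003" &
                                p2$symptom_id == "anxiety"]))

  # write_panel round trip reproduces numeric content (incl. the NA cell)
  out <- tempfile(fileext = ".csv")
  write_panel(p2, out)
  p3 <- read_symptom_panel(out)
  expect_equal(
    as.data.frame(p3)[order(p3$county_fips, p3$symptom_id), ],
    as.data.frame(p2)[order(p2$county_fips, p2$symptom_id), ],
    ignore_attr = TRUE
  )
})

test_that("leading-zero FIPS codes survive numeric-looking input", {
  path <- write_wide_csv(list(
    list(county_fips = 1001, date = "2020-01-01", anxiety = 1),
    list(county_fips = 9, date = "2020-01-01", anxiety = 2)
  ))
  p <- read_symptom_panel(path)
  expect_setequal(unique(p$county_fips), c("01001", "00009"))
})

test_that("panel validation errors identify the offending cell", {
  path <- write_wide_csv(list(
    list(county_fips = "01001", date = "2020-01-01", anxiety = -0.1)
  ))
  expect_error(read_symptom_panel(path), "01001.*anxiety|anxiety.*01001")

  dup <- write_wide_csv(list(
    list(county_fips = "01001", date = "2020-01-01", anxiety = 1),
    list(county_fips = "01001", date = "2020-01-01", anxiety = 2)
  ))
  expect_error(read_symptom_panel(dup), "duplicate")

  nokey <- tempfile(fileext = ".csv")
  write.csv(data.frame(region = "x", anxiety = 1), nokey, row.names = FALSE)
  expect_error(read_symptom_panel(nokey), "format error")
})

test_that("strict registry mode rejects unknown symptom columns", {
  path <- write_wide_csv(list(
    list(county_fips = "01001", date = "2020-01-01", anxiety = 1, cough = 2)
  ))
  reg <- symptom_registry("anxiety")
  expect_error(read_symptom_panel(path, "strict", registry = reg), "cough")
  ok <- read_symptom_panel(path, "strict",
                           registry = symptom_registry(c("anxiety", "cough")))
  expect_equal(nrow(ok), 2L)
})

test_that("designation merge applies the urbanization collapse rule", {
  sp <- tempfile(fileext = ".csv")
  np <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    fips = c("01001", "01003", "01005"),
    status = c("shortage", "partial", "nonshortage"),
    designation_type = c("Geographic Area", "Geographic Area",
                         "Geographic Area")
  ), sp, row.names = FALSE)
  write.csv(data.frame(fips = c("01001", "01003", "01005", "01007"),
                       nchs6 = c(6, 1, 5, 3)), np, row.names = FALSE)
  d <- read_designations(sp, np)
  d <- as.data.frame(d)
  rownames(d) <- d$county_fips
  expect_equal(d["01001", "shortage_status"], "shortage")
  expect_equal(d["01001", "urban3"], "rural")
  expect_false(d["01001", "is_large_central_metro"])
  expect_equal(d["01003", "urban3"], "metro")
  expect_true(d["01003", "is_large_central_metro"])
  expect_equal(d["01005", "urban3"], "micropolitan")
  # county only in the urbanization file is retained with unknown status
  expect_true(is.na(d["01007", "shortage_status"]))
  expect_equal(d["01007", "urban3"], "metro")
})

test_that("facility/population designations are ignored; bad values error", {
  sp <- tempfile(fileext = ".csv")
  np <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    fips = c("01001", "01001"),
    status = c("shortage", "nonshortage"),
    designation_type = c("Geographic Area", "Correctional Facility")
  ), sp, row.names = FALSE)
  write.csv(data.frame(fips = "01001", nchs6 = 6), np, row.names = FALSE)
  d <- read_designations(sp, np)
  expect_equal(nrow(d), 1L)
  expect_equal(d$shortage_status, "shortage")

  write.csv(data.frame(fips = "01001", status = "sorta"), sp,
            row.names = FALSE)
  expect_error(read_designations(sp, np), "unparseable")
  write.csv(data.frame(fips = "01001", status = "shortage"), sp,
            row.names = FALSE)
  write.csv(data.frame(fips = "01001", nchs6 = 7), np, row.names = FALSE)
  expect_error(read_designations(sp, np), "outside 1-6")
})

test_that("suppression accounting matches the absent-county count", {
  p <- make_panel(matrix(1, 3, 2), counties = c("00001", "00002", "00003"))
  all_counties <- sprintf("%05d", 1:5)
  prov <- panel_provenance(p, all_counties)
  expect_equal(prov$n_counties_expected, 5L)
  expect_equal(prov$n_counties_present, 3L)
  expect_setequal(prov$suppressed_counties, c("00004", "00005"))
  expect_equal(prov$n_counties_present + length(prov$suppressed_counties),
               prov$n_counties_expected)
})
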