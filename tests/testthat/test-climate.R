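test_that("saturation vapour pressure matches the physical anchor", {
  expect_lt(abs(saturation_vp(0) - 611) / 611, 0.02)
  expect_gt(saturation_vp(30), saturation_vp(20))
})

test_that("VPD and daytime temperature follow the stated estimators", {
  e <- estimate_vpd_srad(30, 10, 0, latitude_deg = 34, doy = 180)
  expect_equal(e$tday, 20 + 0.45 * 10)
  expect_equal(e$vpd, saturation_vp(24.5) - saturation_vp(10))
  # zero diurnal range: dewpoint equals daytime temperature
  e0 <- estimate_vpd_srad(10, 10, 0, 34, doy = 180)
  expect_equal(e0$vpd, 0)
  expect_error(estimate_vpd_srad(5, 10, 0, 34, doy = 1), "tmax")
})

test_that("VPD grows with the diurnal range at fixed tmin", {
  v <- vapply(c(12, 16, 20, 24), function(tm)
    estimate_vpd_srad(tm, 10, 0, 34, doy = 150)$vpd, numeric(1))
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0))
})

test_that("daylength follows solar geometry limits", {
  expect_equal(daylength_s(0, 81), 43200, tolerance = 120)
  expect_equal(daylength_s(0, 172), 43200, tolerance = 1)  # equator always
  expect_gt(daylength_s(34, 172), daylength_s(34, 355))
  dl <- daylength_s(34, 1:365)
  expect_true(all(dl > 0 & dl < 86400))
})

test_that("estimated radiation is a plausible daylight average", {
  f <- test_forcing()
  expect_true(all(f$srad >= 0))
  gs <- f$phase > 0
  expect_gt(mean(f$srad[gs]), 150)
  expect_lt(max(f$srad), 600)
  # wet days are dimmer than dry neighbours on average
  expect_lt(mean(f$srad[f$prcp_cm > 0]), mean(f$srad[f$prcp_cm == 0]))
})

test_that("GSOD reader converts units, interpolates and flags long gaps", {
  td <- tempfile(); dir.create(td)
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  d <- data.frame(date = dates, tmax = 20, tmin = 10, prcp = 1)
  p1 <- file.path(td, "ok.csv")
  write.csv(d, p1, row.names = FALSE)
  out <- read_gsod_csv(p1, temp_unit = "C", prcp_unit = "mm")
  expect_equal(nrow(out), 365)
  expect_equal(out$prcp_cm[1], 0.1)

  d2 <- d; d2$tmax[100] <- NA; d2$tmax[99] <- 10; d2$tmax[101] <- 12
  p2 <- file.path(td, "gap1.csv")
  write.csv(d2, p2, row.names = FALSE)
  out2 <- read_gsod_csv(p2)
  expect_equal(out2$tmax[100], 11)

  d3 <- d; d3$tmin[200:204] <- NA
  p3 <- file.path(td, "gap5.csv")
  write.csv(d3, p3, row.names = FALSE)
  expect_error(read_gsod_csv(p3), "2001-07-19.*2001-07-23")

  # Fahrenheit/inch conversion
  d4 <- data.frame(date = dates, tmax = 68, tmin = 50, prcp = 1)
  p4 <- file.path(td, "f.csv")
  write.csv(d4, p4, row.names = FALSE)
  out4 <- read_gsod_csv(p4, temp_unit = "F", prcp_unit = "in")
  expect_equal(out4$tmax[1], 20, tolerance = 1e-9)
  expect_equal(out4$prcp_cm[1], 2.54)

  expect_error(read_gsod_csv(file.path(td, "absent.csv")), "not found")
})

test_that("leap days are dropped so years stay 365 days long", {
  td <- tempfile(); dir.create(td)
  dates <- seq(as.Date("2004-01-01"), as.Date("2004-12-31"), by = "day")
  d <- data.frame(date = dates, tmax = 20, tmin = 10, prcp = 0)
  p <- file.path(td, "leap.csv")
  write.csv(d, p, row.names = FALSE)
  expect_equal(nrow(read_gsod_csv(p)), 365)
})

test_that("cyclic rotation permutes whole years and preserves them", {
  f3 <- data.frame(tmax = rep(c(1, 2, 3), each = 365),
                   tmin = 0, prcp_cm = 0)
  expect_equal(cyclic_forcing(f3, 0), f3)
  r1 <- cyclic_forcing(f3, 1)
  expect_equal(unique(r1$tmax[1:365]), 2)
  expect_equal(unique(r1$tmax[731:1095]), 1)
  # multiset of years preserved (bijection)
  expect_equal(sort(unique(r1$tmax)), c(1, 2, 3))
  expect_equal(table(r1$tmax), table(f3$tmax))
  # identical years: rotation invisible
  fsame <- data.frame(tmax = rep(7, 730), tmin = 0, prcp_cm = 0)
  expect_equal(cyclic_forcing(fsame, 1), fsame)
  expect_error(cyclic_forcing(f3[1:400, ], 0), "whole")
  expect_error(cyclic_forcing(f3, 3), "start_year_index")
})

test_that("prepared forcing has consistent phenology per year", {
  f <- test_forcing()
  expect_true(all(f$phase %in% 0:3))
  for (y in unique(f$year)) {
    ph <- f$phase[f$year == y]
    expect_true(any(ph == 2))                # a growth phase exists
    r <- rle(ph)$values
    expect_equal(r[r != 0], c(1, 2, 3))      # transfer -> growth -> senescence
  }
  expect_equal(sum(f$onset), length(unique(f$year)))
})
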