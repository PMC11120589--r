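test_that("packaged run table loads with the published values", {
  d <- load_design_table("table1")
  expect_s3_class(d, "od_design")
  expect_equal(nrow(d), 15L)
  expect_equal(d$DMC[d$run == 8], 50.149)
  expect_equal(d$betaine[d$run == 8], 3828.18)
  expect_equal(d$run[which.min(d$WL)], 5)
  expect_equal(min(d$WL), 0.333)
  expect_equal(d$run[which.max(d$WL)], 12)
  expect_equal(max(d$WL), 0.710)
  # center replicates share the same factor settings
  centers <- d[d$run %in% 13:15, c("T", "Conc", "t")]
  expect_true(all(centers$T == 40 & centers$Conc == 70 & centers$t == 3))
  expect_equal(attr(d, "units")[["betaine"]], "mg/100 g d.m.")
})

test_that("fixture extrema match the quoted response ranges", {
  d <- load_design_table("table1")
  expect_equal(range(d$DMC), c(16.574, 50.149))
  expect_equal(range(d$Mg), c(147.66, 504.62))
  expect_equal(range(d$K), c(7861.18, 18174.63))
  expect_equal(range(d$Na), c(3037.02, 7038.92))
  expect_equal(range(d$Ca), c(380.86, 1706.96))
  expect_equal(range(d$DPPH), c(2.84, 8.34))
  expect_equal(range(d$ABTS), c(0.80, 3.14))
  expect_equal(range(d$acidity), c(1.06, 1.52))
  expect_equal(range(d$betaine), c(1111.45, 3828.18))
})

test_that("loader rejects malformed tables with row/column diagnostics", {
  expect_error(load_design_table(corrupt_table1(3, "DMC", "abc")),
               "row 3.*column 'DMC'")
  expect_error(load_design_table(corrupt_table1(2, "run", "1")),
               "duplicate run id")
  # missing column
  path <- tempfile(fileext = ".csv")
  d <- read.csv(system.file("extdata", "table1.csv", package = "osmodry"))
  write.csv(d[, setdiff(names(d), "betaine")], path, row.names = FALSE)
  expect_error(load_design_table(path), "missing column.*betaine")
  expect_error(load_design_table(corrupt_table1(1, "WL", "1.5")), "WL")
})

test_that("write/read round-trip preserves every cell and is stable", {
  d <- load_design_table("table1")
  f1 <- tempfile(fileext = ".csv")
  write_design_table(d, f1)
  d2 <- load_design_table(f1)
  expect_equal(as.data.frame(d2), as.data.frame(d))
  f2 <- tempfile(fileext = ".csv")
  write_design_table(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("storage series loads both arms with published values", {
  s <- load_storage_series("table4")
  expect_named(s, c("OD", "ODC"))
  expect_equal(s$OD$phenols[s$OD$day == 0], 1016.05)
  expect_equal(s$ODC$betaine[s$ODC$day == 28], 3082.87)
  expect_equal(s$OD$day, c(0, 7, 14, 21, 28))
})

test_that("storage series with a missing day is rejected, naming the day", {
  path <- tempfile(fileext = ".csv")
  raw <- read.csv(system.file("extdata", "table4.csv", package = "osmodry"))
  write.csv(raw[!(raw$arm == "OD" & raw$day == 14), ], path, row.names = FALSE)
  expect_error(load_storage_series(path), "arm OD is missing day\\(s\\): 14")
})

test_that("retention summary gives percent change from the day-0 baseline", {
  s <- load_storage_series("table4")
  od <- retention_summary(s$OD)
  odc <- retention_summary(s$ODC)
  # day-0 row is identically zero
  expect_equal(unlist(od[od$day == 0, -1]), rep(0, 6), ignore_attr = TRUE)
  expect_equal(od$phenols[od$day == 28],
               100 * (458.09 - 1016.05) / 1016.05, tolerance = 1e-12)
  expect_equal(round(od$phenols[od$day == 28], 2), -54.91)
  expect_equal(round(odc$betaine[odc$day == 28], 2), -7.78)
  # zero baseline is an error
  bad <- s$OD
  bad$phenols[bad$day == 0] <- 0
  expect_error(retention_summary(bad), "zero day-0 baseline.*phenols")
})
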