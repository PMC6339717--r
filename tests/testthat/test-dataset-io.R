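test_that("packaged profiles have the published shapes and values", {
  dox <- load_fixture("dox")
  expect_s3_class(dox, "release_dataset")
  expect_equal(nrow(dox), 10L)
  expect_identical(time_unit(dox), "hour")
  expect_equal(unlist(dox[1, ], use.names = FALSE), c(1, 10, 7))
  expect_equal(unlist(dox[10, ], use.names = FALSE), c(48, 70, 1))
  expect_equal(sum(dox$dissolution_percent), 433)

  mtx <- load_fixture("mtx")
  expect_equal(nrow(mtx), 10L)
  expect_true(all(mtx$error == 1))

  plga <- load_fixture("plga")
  expect_equal(nrow(plga), 12L)
  expect_identical(time_unit(plga), "day")
  expect_equal(unlist(plga[12, ], use.names = FALSE), c(30, 46, 2.5))
  expect_equal(nrow(load_fixture("ca_plga")), 12L)

  pcl <- load_fixture("pd_pcl_nc")
  expect_equal(nrow(pcl), 8L)
  expect_equal(unlist(pcl[1, ], use.names = FALSE), c(0, 0, 1))
  expect_equal(sum(pcl$dissolution_percent), 572.5)

  expect_error(load_fixture("nope"), "unknown fixture")
})

test_that("write/read round-trips every packaged profile exactly", {
  for (nm in c("dox", "mtx", "plga", "ca_plga", "pd_pcl_nc")) {
    ds <- load_fixture(nm)
    path <- withr::local_tempfile(fileext = ".csv")
    write_profile(ds, path)
    back <- read_profile(path)
    expect_identical(as.data.frame(back), as.data.frame(ds), label = nm)
    expect_identical(time_unit(back), time_unit(ds))
    expect_identical(attr(back, "label"), attr(ds, "label"))
  }
})

test_that("profile validation names the offending row", {
  csv <- function(rows, meta = "# time_unit=hour") {
    path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    writeLines(c(meta, "time,dissolution_percent,error", rows), path)
    path
  }
  expect_equal(nrow(read_profile(csv(c("0,0,1", "1,10,1")))), 2L)
  expect_error(read_profile(csv(c("2,10,1", "2,20,1"))), "strictly increasing.*row 2")
  expect_error(read_profile(csv(c("1,10,1", "2,20,0"))), "positive.*row 2")
  expect_error(read_profile(csv(c("1,10,1", "2,20,-1"))), "positive.*row 2")
  expect_error(read_profile(csv("1,10,1")), "at least 2 points")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# time_unit=hour", "time,error", "1,1", "2,1"), path)
  expect_error(read_profile(path), "missing column.*dissolution_percent")
})

test_that("time unit is carried out-of-band and can be overridden", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,dissolution_percent,error", "1,10,1", "2,20,1"), path)
  expect_error(read_profile(path), "no time unit")
  expect_identical(time_unit(read_profile(path, time_unit = "day")), "day")
  ds <- release_dataset(1:3, c(5, 10, 20), c(1, 1, 1), time_unit = "day")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_profile(ds, path2)
  expect_identical(time_unit(read_profile(path2)), "day")
})

test_that("constructor enforces invariants but only warns outside [0, 100]", {
  expect_error(release_dataset(1, 10, 1), "at least 2")
  expect_error(release_dataset(c(-1, 1), c(1, 2), c(1, 1)), "negative time")
  expect_error(release_dataset(c(1, 2), c(1, 2), c(1, NA)), "finite")
  expect_warning(release_dataset(c(1, 2), c(50, 104), c(1, 1)), "outside")
  expect_silent(release_dataset(c(1, 2), c(50, 100), c(1, 1)))
})
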