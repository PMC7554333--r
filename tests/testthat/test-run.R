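test_that("the end-to-end driver produces the documented artifact set", {
  csv <- withr::local_tempfile(fileext = ".csv")
  make_design(2, 2, path = csv)
  base <- tmp_base("run")
  m <- suppressMessages(
    plotshpcreate(A = c(500000, 3000000), B = c(500000, 3000100),
                  UTMzone = 14, infile = csv, outfile = base))
  expect_equal(m$n_polygons, 4)
  expect_equal(m$epsg, 32614L)
  expect_equal(m$bearing_deg, 0)
  expect_length(m$files, 10)  # 2 families x 4 sidecars + 2 PDFs
  expect_true(all(file.exists(m$files)))
})

test_that("mandatory arguments are enforced", {
  expect_error(plotshpcreate(B = c(0, 1), infile = make_design(1, 1),
                             outfile = tmp_base()), "'A'")
  expect_error(plotshpcreate(A = c(0, 0), B = c(0, 1),
                             infile = make_design(1, 1)), "'outfile'")
})

test_that("a metric run reproduces an imperial run to millimeters", {
  csv <- withr::local_tempfile(fileext = ".csv")
  make_design(2, 2, path = csv)
  common <- list(A = c(746000, 3382000), B = c(746030, 3382100),
                 UTMzone = 14, infile = csv,
                 SquarePlot = FALSE, RotatePlot = FALSE)
  m_ft <- suppressMessages(do.call(plotshpcreate,
    c(common, list(outfile = tmp_base("ft"), unit = "feet",
                   rowspc = 2.5, rowbuf = 0.1, rangespc = 25,
                   rangebuf = 2))))
  m_m <- suppressMessages(do.call(plotshpcreate,
    c(common, list(outfile = tmp_base("m"), unit = "meter",
                   rowspc = 0.76, rowbuf = 0.03, rangespc = 7.62,
                   rangebuf = 0.61))))
  for (i in seq_along(m_ft$geo$polygons)) {
    d <- abs(m_ft$geo$polygons[[i]]$full - m_m$geo$polygons[[i]]$full)
    expect_lt(max(d), 0.025)  # 2.5 ft = 0.762 m vs rounded 0.76 m
  }
})

test_that("identical configurations give byte-identical outputs", {
  csv <- withr::local_tempfile(fileext = ".csv")
  make_design(2, 4, nrowplot = 2, path = csv)
  args <- list(A = c(746000, 3382000), B = c(746030, 3382100), UTMzone = 14,
               infile = csv, nrowplot = 2, multirowind = TRUE,
               SquarePlot = FALSE, RotatePlot = FALSE)
  b1 <- tmp_base("d1"); b2 <- tmp_base("d2")
  suppressMessages(do.call(plotshpcreate, c(args, list(outfile = b1))))
  suppressMessages(do.call(plotshpcreate, c(args, list(outfile = b2))))
  for (ext in c(".shp", ".shx", ".dbf", "_buffer.shp", "_buffer.dbf")) {
    expect_identical(readBin(paste0(b1, ext), "raw", 1e6),
                     readBin(paste0(b2, ext), "raw", 1e6))
  }
})

test_that("the CLI parses flags, runs demos, and signals usage errors", {
  csv <- withr::local_tempfile(fileext = ".csv")
  make_design(2, 2, path = csv)
  base <- tmp_base("cli")
  status <- suppressMessages(cli_run(c(
    "--infile", csv, "--outfile", base, "--A", "500000,3000000",
    "--B", "500000,3000100", "--UTMzone", "14",
    "--SquarePlot", "FALSE", "--RotatePlot", "FALSE", "--quiet")))
  expect_equal(status, 0L)
  expect_true(file.exists(paste0(base, ".shp")))

  expect_equal(suppressMessages(cli_run(c("--outfile", base))), 2L)
  expect_equal(suppressMessages(cli_run(c("--bogus", "1"))), 2L)
  # data errors (not usage) exit 1
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Plot,Range,Row", "1,1,1"), bad)
  expect_equal(suppressMessages(cli_run(c(
    "--infile", bad, "--outfile", base, "--A", "0,0", "--B", "0,1"))), 1L)

  # config file supplies flags; command line wins
  cfgf <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(paste0("infile=", csv), "A=500000,3000000",
               "B=500010,3000100", "UTMzone=14", "SquarePlot=FALSE",
               "RotatePlot=FALSE", "quiet=TRUE"), cfgf)
  base2 <- tmp_base("cfg")
  expect_equal(suppressMessages(cli_run(
    c("--config", cfgf, "--outfile", base2))), 0L)
  expect_true(file.exists(paste0(base2, ".prj")))

  # bundled demo scenarios run end to end
  base3 <- tmp_base("demo")
  expect_equal(suppressMessages(cli_run(
    c("--demo", "fig2C", "--outfile", base3, "--quiet"))), 0L)
  rt <- read_shapefile(base3)
  expect_equal(nrow(rt$attributes), 8)  # 4 six-row plots, inner 2 rows each
})
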