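test_that("to_meters converts feet exactly and passes meters through", {
  expect_equal(to_meters(2.5, "feet"), 0.762)
  expect_equal(to_meters(25, "feet"), 7.62)
  expect_equal(to_meters(5, "meter"), 5)
  expect_error(to_meters(1, "furlong"), "unknown unit")
  expect_error(to_meters(Inf, "meter"), "finite")
})

test_that("cell_rect places cells on the grid with A at the origin", {
  r <- cell_rect(1, 1, 0.762, 7.62)
  expect_equal(unname(r), c(0, 0, 0.762, 7.62))
  r <- cell_rect(2, 3, 0.762, 7.62)
  expect_equal(unname(r), c(1.524, 7.62, 2.286, 15.24))
  expect_equal(unname(cell_rect(1, 1, 1, 1)), c(0, 0, 1, 1))
})

test_that("shrink_rect contracts per axis, preserving the center", {
  full <- cell_rect(1, 1, 0.762, 7.62)
  buf <- shrink_rect(full, 0.03048, 0.6096)
  expect_equal(unname(buf), c(0.03048, 0.6096, 0.73152, 7.0104))
  # center preserved
  expect_equal(mean(buf[c("xmin", "xmax")]), mean(full[c("xmin", "xmax")]))
  expect_equal(mean(buf[c("ymin", "ymax")]), mean(full[c("ymin", "ymax")]))
  # zero buffers are the identity
  expect_equal(shrink_rect(full, 0, 0), full)
  # a 1.22 m alley (0.61 m at each plot end) is fully removed
  alley_half <- 1.22 / 2
  b2 <- shrink_rect(full, 0, alley_half)
  expect_equal(unname(full[["ymax"]] - b2[["ymax"]]), 0.61)
  expect_equal(unname(b2[["ymin"]] - full[["ymin"]]), 0.61)
  expect_error(shrink_rect(cell_rect(1, 1, 1, 1), 0.6, 0), "area")
})

test_that("stagger_offset shifts alternating planter passes from row i", {
  st <- c(5, 4, 3.8)
  expect_equal(stagger_offset(4, st), 0)
  expect_equal(stagger_offset(5, st), 3.8)
  expect_equal(stagger_offset(8, st), 3.8)
  expect_equal(stagger_offset(9, st), 0)
  expect_equal(stagger_offset(12, st), 0)
  expect_equal(stagger_offset(13, st), 3.8)
  expect_equal(stagger_offset(1, NULL), 0)
})

test_that("build_plot_unit subsets, merges, suffixes and staggers", {
  p_ind <- metric_params(nrowplot = 6, multirowind = TRUE, plotsubset = 2)
  unit6 <- list(barcode = "CS17-G2F-018", plot = 18L, range = 1L, rows = 1:6)
  polys <- build_plot_unit(unit6, p_ind)
  expect_length(polys, 2)  # inner two rows survive
  expect_equal(vapply(polys, `[[`, 1L, "row_first"), c(3L, 4L))
  expect_equal(vapply(polys, `[[`, "", "unique_id"),
               c("CS17-G2F-018_1", "CS17-G2F-018_2"))

  # two-row plot, individual: left-to-right suffixes
  p2 <- metric_params(nrowplot = 2, multirowind = TRUE)
  unit2 <- list(barcode = "CS17-G2F-018", plot = 18L, range = 1L, rows = 1:2)
  ids <- vapply(build_plot_unit(unit2, p2), `[[`, "", "unique_id")
  expect_equal(ids, c("CS17-G2F-018_1", "CS17-G2F-018_2"))

  # merged: one polygon spanning n*rowspc
  pm <- metric_params(nrowplot = 2, multirowind = FALSE)
  merged <- build_plot_unit(unit2, pm)
  expect_length(merged, 1)
  expect_equal(unname(merged[[1]]$full[["xmax"]] -
                        merged[[1]]$full[["xmin"]]), 2 * 0.762)
  expect_equal(merged[[1]]$unique_id, "CS17-G2F-018")

  # merged plot split across differently staggered passes is fatal
  ps <- metric_params(nrowplot = 2, multirowind = FALSE,
                      stagger = c(2, 4, 3.8))
  expect_error(build_plot_unit(unit2, ps), "planter passes")
  # ... but the same plot aligned with passes staggers cleanly
  ps2 <- metric_params(nrowplot = 2, multirowind = FALSE,
                       stagger = c(1, 4, 3.8))
  m2 <- build_plot_unit(unit2, ps2)
  expect_equal(unname(m2[[1]]$full[["ymin"]]), 3.8)
})

test_that("build_layout obeys area, containment, disjointness and counts", {
  layout <- simple_layout(2, 2)
  expect_length(layout, 4)
  for (p in layout) {
    full_area <- (p$full[["xmax"]] - p$full[["xmin"]]) *
      (p$full[["ymax"]] - p$full[["ymin"]])
    expect_equal(full_area, 0.762 * 7.62)
    # buffer strictly inside
    expect_true(p$buffer[["xmin"]] > p$full[["xmin"]])
    expect_true(p$buffer[["xmax"]] < p$full[["xmax"]])
    expect_true(p$buffer[["ymin"]] > p$full[["ymin"]])
    expect_true(p$buffer[["ymax"]] < p$full[["ymax"]])
  }
  # pairwise disjoint interiors without stagger
  for (i in seq_along(layout)) {
    for (j in seq_len(i - 1L)) {
      expect_equal(rect_overlap_area(layout[[i]]$full, layout[[j]]$full), 0)
    }
  }

  # merged six-row plots: area n * rowspc * rangespc
  df6 <- make_design(1, 6, nrowplot = 6)
  lay6 <- build_layout(read_design(df6),
                       metric_params(nrowplot = 6, multirowind = FALSE))
  expect_length(lay6, 1)
  w <- lay6[[1]]$full[["xmax"]] - lay6[[1]]$full[["xmin"]]
  h <- lay6[[1]]$full[["ymax"]] - lay6[[1]]$full[["ymin"]]
  expect_equal(unname(w * h), 6 * 0.762 * 7.62)

  # count conservation across merge/subset combinations
  df <- make_design(2, 12, nrowplot = 6)
  tab <- read_design(df)
  n_units <- 4L
  cases <- list(
    list(multirowind = TRUE, plotsubset = 0L, expect = 6L * n_units),
    list(multirowind = TRUE, plotsubset = 2L, expect = 2L * n_units),
    list(multirowind = FALSE, plotsubset = 0L, expect = n_units),
    list(multirowind = FALSE, plotsubset = 2L, expect = n_units))
  for (cs in cases) {
    lay <- build_layout(tab, metric_params(nrowplot = 6,
                                           multirowind = cs$multirowind,
                                           plotsubset = cs$plotsubset))
    expect_length(lay, cs$expect)
  }

  # nrowplot = 1, plotsubset = 0 is the identity grid with bare barcodes
  ids <- vapply(simple_layout(2, 3), `[[`, "", "unique_id")
  expect_false(any(grepl("_", ids, fixed = TRUE)))
  expect_length(ids, 6)
})
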