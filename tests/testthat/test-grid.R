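test_that("write/read round trip reproduces values and mask bit-exactly", {
  set.seed(42)
  v <- matrix(rnorm(20) * 1e3, 4, 5)
  v[2, 3] <- NA
  g <- grid2d(v, origin_lat = 2, origin_lon = -1.5, resolution = 0.5,
              name = "BD", units = "kg m-3")
  p <- tempfile(fileext = ".asc")
  on.exit(unlink(p))
  write_grid(g, p)
  g2 <- read_grid(p, variable = "BD")
  expect_identical(g2$values[!g2$mask], g$values[!g$mask])
  expect_identical(g2$mask, g$mask)
  expect_equal(g2$origin_lat, g$origin_lat)
  expect_equal(g2$origin_lon, g$origin_lon)
  expect_equal(g2$resolution, g$resolution)
  # write the re-read grid again: still identical
  p2 <- tempfile(fileext = ".asc")
  on.exit(unlink(p2), add = TRUE)
  write_grid(g2, p2)
  g3 <- read_grid(p2)
  expect_identical(g3$values[!g3$mask], g$values[!g$mask])
})

test_that("a literal 2x2 fixture parses row-major with header georeference", {
  p <- tempfile(fileext = ".asc")
  on.exit(unlink(p))
  writeLines(c("ncols 2", "nrows 2", "xllcorner 10", "yllcorner 40",
               "cellsize 0.5", "nodata_value -9999",
               "1 2", "3 4"), p)
  g <- read_grid(p)
  expect_equal(g$values, matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(g$origin_lat, 41)     # yllcorner + nrows * cellsize
  expect_equal(g$origin_lon, 10)
  expect_false(any(g$mask))
})

test_that("nodata sentinels become masked cells", {
  p <- tempfile(fileext = ".asc")
  on.exit(unlink(p))
  writeLines(c("ncols 3", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "nodata_value -9999",
               "5 -9999 7"), p)
  g <- read_grid(p)
  expect_equal(sum(g$mask), 1L)
  expect_true(g$mask[1, 2])
  expect_true(is.na(g$values[1, 2]))
})

test_that("reading a missing file names the path", {
  expect_error(read_grid("/no/such/file.asc"), "no/such/file")
})

test_that("stack assembly enforces co-registration and mask union", {
  a <- mk_grid(1:4, nrow = 2, name = "a")
  b <- mk_grid(5:8, nrow = 2, name = "b")
  s <- assemble_stack(list(a = a, b = b))
  expect_equal(length(s$grids), 2L)

  bad <- grid2d(matrix(1:4, 2, 2), origin_lat = 0.2, origin_lon = 0,
                resolution = 0.2, name = "bad")
  expect_error(assemble_stack(list(a = a, bad = bad)), "alignment error")

  am <- mk_grid(1:4, nrow = 2, mask = matrix(c(TRUE, FALSE, FALSE, FALSE), 2))
  bm <- mk_grid(5:8, nrow = 2, mask = matrix(c(FALSE, FALSE, FALSE, TRUE), 2))
  s2 <- assemble_stack(list(a = am, b = bm))
  expect_equal(sum(stack_mask(s2)), 2L)
  # adding a layer never unmasks a pixel: each member mask is contained
  expect_true(all(stack_mask(s2) | !stack_mask(s2, "a")))
  expect_true(all(stack_mask(s2) | !stack_mask(s2, "b")))
  expect_error(stack_mask(s2, "zzz"), "available")
})

test_that("grid invariants are enforced at construction", {
  expect_error(grid2d(matrix(1, 2, 2), mask = matrix(FALSE, 1, 2),
                      origin_lat = 1, origin_lon = 0, resolution = 0.1),
               "identical shape")
  expect_error(grid2d(matrix(1, 2, 2), origin_lat = 1, origin_lon = 0,
                      resolution = 0), "positive")
  expect_error(grid2d(matrix(1, 200, 2), origin_lat = 10, origin_lon = 0,
                      resolution = 1), "latitude")
})
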