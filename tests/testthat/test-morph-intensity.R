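test_that("size features of simple shapes match hand geometry", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  f <- size_features(sq, 0.5)
  expect_equal(unname(f["size.area_mm2"]), 25)  # 100 px * 0.25 mm^2
  # single row of 5 pixels at 1 mm: longest diameter between centers = 4 mm
  bar <- matrix(FALSE, 7, 9); bar[4, 3:7] <- TRUE
  expect_equal(unname(size_features(bar, 1)["size.longest_diameter_mm"]), 4)
  # disc: equivalent diameter close to the Feret diameter
  d <- disc_mask(20, 64)
  fd <- size_features(d, 1)
  expect_lt(abs(fd["size.equivalent_diameter_mm"] -
                fd["size.longest_diameter_mm"]) /
            fd["size.longest_diameter_mm"], 0.05)
  # moment-ellipse axes of a disc are close to its diameter
  expect_equal(unname(fd["size.major_axis_mm"]), 40, tolerance = 0.05)
  expect_equal(unname(fd["size.minor_axis_mm"]), 40, tolerance = 0.05)
})

test_that("size features scale correctly with pixel spacing", {
  m <- disc_mask(12, 40)
  f1 <- size_features(m, 1)
  f2 <- size_features(m, 2)
  expect_equal(unname(f2["size.area_mm2"]), unname(4 * f1["size.area_mm2"]))
  for (nm in c("size.perimeter_mm", "size.longest_diameter_mm",
               "size.equivalent_diameter_mm", "size.major_axis_mm",
               "size.minor_axis_mm"))
    expect_equal(unname(f2[nm]), unname(2 * f1[nm]), tolerance = 1e-12)
})

test_that("shape features match analytic values on canonical shapes", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  fs <- shape_features(sq)
  expect_equal(unname(fs["shape.extent"]), 1)
  expect_equal(unname(fs["shape.solidity"]), 1)
  d <- disc_mask(20, 64)
  fd <- shape_features(d)
  expect_gte(unname(fd["shape.solidity"]), 0.98)
  expect_lte(unname(fd["shape.eccentricity"]), 0.1)
  expect_gt(unname(fd["shape.circularity"]), 0.85)
  expect_lte(unname(fd["shape.circularity"]), 1.05)
  # 2:1 axis-aligned moment ellipse
  rows <- matrix(seq_len(81), 81, 81); cols <- t(rows)
  ell <- ((rows - 41) / 20)^2 + ((cols - 41) / 40)^2 <= 1
  fe <- shape_features(ell)
  expect_equal(unname(fe["shape.elongation"]), 0.5, tolerance = 0.02)
  expect_equal(unname(fe["shape.eccentricity"]), sqrt(3) / 2,
               tolerance = 0.02)
})

test_that("shape features are invariant to translation and 90-degree rotation", {
  set.seed(14)
  m <- generate_mask(c(32, 32), 10, 0.3, 5, 1, 64)
  f0 <- shape_features(m)
  # translate by padding shift
  shifted <- matrix(FALSE, 64, 64)
  shifted[6:64, 6:64] <- m[1:59, 1:59]
  expect_equal(shape_features(shifted), f0, tolerance = 1e-10)
  # rotate 90 degrees
  rot <- t(m)[ncol(m):1, ]
  expect_equal(shape_features(rot), f0, tolerance = 1e-10)
})

test_that("degenerate masks are rejected", {
  expect_error(size_features(matrix(FALSE, 4, 4), 1), "empty")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_error(shape_features(one), "single-pixel")
})

test_that("intensity features match hand arithmetic", {
  f <- intensity_features(c(2, 4, 6, 8))
  expect_equal(unname(f["hist.mean"]), 5)
  expect_equal(unname(f["hist.median"]), 5)
  expect_equal(unname(f["hist.skewness"]), 0)
  expect_equal(unname(f["hist.energy"]), 120)
  expect_equal(unname(f["hist.variance"]), 5)  # population variance
  expect_equal(unname(f["hist.minimum"]), 2)
  expect_equal(unname(f["hist.range"]), 6)
})

test_that("histogram entropy and uniformity cover the degenerate cases", {
  f <- intensity_features(rep(3, 10))
  expect_equal(unname(f["hist.entropy256"]), 0)
  expect_equal(unname(f["hist.uniformity256"]), 1)
  expect_equal(unname(f["hist.variance"]), 0)
  # four equally frequent well-separated values: 2 bits
  f4 <- intensity_features(rep(c(0, 10, 20, 30), 25))
  expect_equal(unname(f4["hist.entropy256"]), 2)
  expect_equal(unname(f4["hist.uniformity256"]), 0.25)
})

test_that("entropy and uniformity respect their theoretical bounds", {
  set.seed(15)
  for (rep in 1:20) {
    v <- rnorm(50, sd = runif(1, 0.1, 100))
    f <- intensity_features(v)
    expect_gte(unname(f["hist.entropy256"]), 0)
    expect_lte(unname(f["hist.entropy256"]), 8)
    expect_gte(unname(f["hist.uniformity256"]), 1 / 256)
    expect_lte(unname(f["hist.uniformity256"]), 1)
  }
})
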