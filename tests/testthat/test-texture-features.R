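test_that("GLCM of a constant full-mask image is degenerate as expected", {
  q <- as_quantized(matrix(1L, 4, 4), 2)
  m <- compute_glcm(q, "0")
  expect_equal(m$matrix[1, 1], 1)
  f <- glcm_features(m)
  expect_equal(unname(f["glcm.contrast"]), 0)
  expect_equal(unname(f["glcm.energy"]), 1)
  expect_equal(unname(f["glcm.entropy"]), 0)
  expect_equal(unname(f["glcm.max_probability"]), 1)
  # zero marginal variance: correlation defined as 0
  expect_equal(unname(f["glcm.correlation"]), 0)
})

test_that("GLCM of a two-level checkerboard matches hand enumeration", {
  cb <- (outer(1:4, 1:4, "+") %% 2) + 1
  q <- as_quantized(cb, 2)
  m <- compute_glcm(q, "0")
  expect_equal(m$matrix[1, 2], 0.5)
  expect_equal(m$matrix[2, 1], 0.5)
  f <- glcm_features(m)
  expect_equal(unname(f["glcm.contrast"]), 1)
  expect_equal(unname(f["glcm.energy"]), 0.5)
  expect_equal(unname(f["glcm.correlation"]), -1)
  expect_equal(unname(f["glcm.dissimilarity"]), 1)
})

test_that("a direction with no in-mask pair raises an error", {
  lab <- matrix(0L, 5, 5)
  lab[, 3] <- 1L  # 1-pixel-wide vertical bar: no horizontal pair
  q <- as_quantized(lab, 2)
  expect_error(compute_glcm(q, "0"), "no in-mask pixel pair")
  expect_no_error(compute_glcm(q, "90"))
})

test_that("GLRLM runs of a simple row match hand enumeration", {
  q <- as_quantized(matrix(c(1L, 1L, 2L, 2L), 1, 4), 2)
  f <- glrlm_features(compute_glrlm(q, "0"))
  expect_equal(unname(f["glrlm.sre"]), 0.25)
  expect_equal(unname(f["glrlm.lre"]), 4)
  expect_equal(unname(f["glrlm.rp"]), 0.5)
  # constant n-pixel row: one run, RP = 1/n
  qc <- as_quantized(matrix(1L, 1, 6), 2)
  expect_equal(unname(glrlm_features(compute_glrlm(qc, "0"))["glrlm.rp"]),
               1 / 6)
  # checkerboard: all runs length 1
  cb <- (outer(1:4, 1:4, "+") %% 2) + 1
  fcb <- glrlm_features(compute_glrlm(as_quantized(cb, 2), "0"))
  expect_equal(unname(fcb["glrlm.sre"]), 1)
  expect_equal(unname(fcb["glrlm.lre"]), 1)
})

test_that("GLSZM zones use 8-connectivity", {
  # constant 4x4 image: one zone of 16 px, zone percentage 1/16
  f <- glszm_features(compute_glszm(as_quantized(matrix(1L, 4, 4), 2)))
  expect_equal(unname(f["glszm.zp"]), 1 / 16)
  # two diagonal same-level pixels form a single zone
  lab <- matrix(0L, 4, 4); lab[1, 1] <- 1L; lab[2, 2] <- 1L
  m <- compute_glszm(as_quantized(lab, 2))
  expect_equal(sum(m$matrix), 1)
  expect_equal(m$matrix[1, 2], 1)
})

test_that("zone labelling agrees with an independent flood-fill oracle", {
  set.seed(5)
  for (rep in 1:20) {
    lab <- rand_labels(10, 10, 3)
    z <- lipomics:::cpp_zones(lab)
    ref <- oracle_zones(lab)
    # compare multisets of (level, size) pairs
    expect_equal(sort(paste(z[, 1], z[, 2])), sort(paste(ref[, 1], ref[, 2])))
  }
})

test_that("NGTDM handles degenerate and hand-computed cases", {
  # constant image: all s_i = 0, coarseness hits the 1/eps guard
  f <- ngtdm_features(compute_ngtdm(as_quantized(matrix(1L, 4, 4), 2)))
  expect_equal(unname(f["ngtdm.coarseness"]), 1e6)
  expect_equal(unname(f["ngtdm.contrast"]), 0)
  # 3x3 image, center level 2 amid level 1
  lab <- matrix(1L, 3, 3); lab[2, 2] <- 2L
  m <- compute_ngtdm(as_quantized(lab, 2))
  expect_equal(m$s[2], 1)          # center: |2 - mean(eight 1s)| = 1
  expect_equal(m$n[2], 1)
  expect_equal(m$n[1], 8)
  # border level-1 pixels: each sees the center 2 among its neighbors
  expect_equal(m$s[1], sum(abs(1 - c(rep((1 * 2 + 2) / 3, 4),
                                     rep((1 * 4 + 2) / 5, 4)))))
})

test_that("all matrix families match naive-enumeration oracles on random images", {
  set.seed(101)
  for (rep in 1:25) {
    L <- sample(c(2, 4, 8), 1)
    lab <- rand_labels(8, 8, L)
    mine <- texture_features_single_level(as_quantized(lab, L))
    ref <- oracle_texture52(lab, L)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
  # also under a ragged mask
  for (rep in 1:10) {
    mask <- disc_mask(3, 9)
    lab <- rand_labels(9, 9, 4, mask)
    mine <- texture_features_single_level(as_quantized(lab, 4))
    ref <- oracle_texture52(lab, 4)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("features are invariant to transposition (direction relabelling)", {
  set.seed(7)
  lab <- rand_labels(8, 8, 4)
  f1 <- texture_features_single_level(as_quantized(lab, 4))
  f2 <- texture_features_single_level(as_quantized(t(lab), 4))
  # transposition swaps 0<->90 and 45<->135; the direction average is blind
  # to the relabelling, and GLSZM/NGTDM are orientation-free
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("texture aggregation averages per-level features over the sweep", {
  set.seed(21)
  img <- matrix(rnorm(32 * 32), 32, 32)
  mask <- matrix(TRUE, 32, 32)
  agg <- aggregate_texture(img, mask)
  per_level <- vapply(level_sweep(img, mask), texture_features_single_level,
                      numeric(52))
  expect_equal(agg, rowMeans(per_level), tolerance = 1e-12)
  # single-level sweep is the identity
  agg8 <- aggregate_texture(img, mask, 8)
  expect_equal(agg8, texture_features_single_level(
    equal_probability_quantize(img, mask, 8)), tolerance = 1e-12)
})

test_that("GLCM features are invariant to constant intensity shifts", {
  set.seed(3)
  img <- matrix(rnorm(24 * 24), 24, 24)
  mask <- disc_mask(9, 24)
  f1 <- aggregate_texture(img, mask, c(8, 16))
  f2 <- aggregate_texture(img + 100, mask, c(8, 16))
  expect_equal(f1, f2, tolerance = 1e-12)
})
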