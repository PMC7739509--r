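test_that("descriptor blocks meet their per-component dimensional contracts", {
  co <- fixture_coeffs()
  blocks <- texture_blocks(co,
                           descriptors = c("cm", "lbp", "losib", "sfta",
                                           "cmdot"))
  expect_length(blocks[["cm.magnitude"]], 640)
  expect_length(blocks[["lbp.rp"]], 320)
  expect_length(blocks[["losib.magnitude"]], 256)
  expect_length(blocks[["sfta.rp"]], 672)
  expect_length(blocks[["cmdot.magnitude"]], 32 * 8)
  for (b in blocks) {
    expect_identical(anyDuplicated(names(b$values)), 0L)
    expect_true(all(is.finite(b$values)))
  }
})

test_that("toy systems scale the block lengths with the sub-band count", {
  sys <- shearlet_system(64, 64, scales = 1, directions_per_scale = 2)
  co <- shearlet_transform(generate_texture(10, 6, 64, noise_sd = 0.1,
                                            seed = 3), sys)
  stacks <- component_stacks(co)
  expect_length(cm_features(stacks$magnitude, "magnitude", co$index), 40)
  expect_length(lbp_features(stacks$rp, "rp", co$index), 20)
  expect_length(losib_features(stacks$magnitude, "magnitude", co$index), 16)
  expect_length(sfta_features(stacks$rp, "rp", co$index), 42)
})

test_that("descriptor families are deterministic and scale-covariant", {
  co <- fixture_coeffs()
  stacks <- component_stacks(co)
  mag <- stacks$magnitude
  scaled <- lapply(mag, function(m) 2.5 * m)

  cm1 <- cm_features(mag, "magnitude", co$index)
  expect_identical(cm_features(mag, "magnitude", co$index)$values, cm1$values)
  # min-max quantization removes the gain before the co-occurrence step
  expect_equal(cm_features(scaled, "magnitude", co$index)$values, cm1$values,
               tolerance = 1e-12)

  lbp1 <- lbp_features(mag, "magnitude", co$index)
  expect_equal(lbp_features(scaled, "magnitude", co$index)$values,
               lbp1$values, tolerance = 1e-12)

  lo1 <- losib_features(mag, "magnitude", co$index)
  expect_equal(losib_features(scaled, "magnitude", co$index)$values,
               2.5 * lo1$values, tolerance = 1e-12)
})

test_that("LBP of all-constant sub-bands concentrates one bin per sub-band", {
  sys <- fixture_system()
  zero <- shearlet_transform(matrix(0, 64, 64), sys)
  blk <- lbp_features(zero$magnitude, "magnitude", zero$index)
  expect_equal(sum(blk$values != 0), 32)
  lo <- losib_features(zero$magnitude, "magnitude", zero$index)
  expect_true(all(lo$values == 0))
  sf <- sfta_features(zero$magnitude, "magnitude", zero$index)
  expect_true(all(sf$values == 0))
})

test_that("CM-dot pairs the co-occurrence matrix with pooled magnitudes", {
  co <- fixture_coeffs()
  blk <- cmdot_features(co$magnitude, "magnitude", co$index)
  expect_length(blk, 32 * 8)
  expect_error(cmdot_features(relative_phase(co), "rp", co$index),
               "magnitude component only")

  # zero stack: product with zero magnitudes vanishes
  zero <- lapply(1:32, function(i) matrix(0, 16, 16))
  blk0 <- cmdot_features(zero, "magnitude", co$index)
  expect_true(all(blk0$values == 0))

  # reference oracle on a fixed toy sub-band: quantize, average the four
  # directional co-occurrence matrices, pool the band to ng x ng block
  # means, multiply entrywise, take column maxima
  set.seed(51)
  band <- matrix(runif(64), 8, 8)
  got <- shearltex:::cmdot_subband(band, ng = 4, pd = 1)
  q <- quantize_subband(band, 4)
  cmref <- cooccurrence_mean(q, ng = 4)$p
  pool <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    pool[i, j] <- mean(band[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(got, apply(cmref * pool, 2, max), tolerance = 1e-12)
})
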