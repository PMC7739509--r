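test_that("system construction honors sub-band counts and sizing limits", {
  sys <- fixture_system()
  expect_equal(n_subbands(sys), 32)
  expect_equal(nrow(sys$index), 32)
  expect_identical(anyDuplicated(sys$index[, c("scale", "direction")]), 0L)

  tiny <- shearlet_system(64, 64, scales = 1, directions_per_scale = 2)
  expect_equal(n_subbands(tiny), 2)

  expect_error(shearlet_system(16, 16, 4, 8), "too small")
  expect_error(shearlet_system(64, 64, 4, 7), "even")
})

test_that("transform is linear and populates magnitude and phase stacks", {
  sys <- fixture_system()
  zero <- shearlet_transform(matrix(0, 64, 64), sys)
  expect_true(all(vapply(zero$magnitude, max, numeric(1)) == 0))

  set.seed(5)
  img <- matrix(runif(64 * 64), 64)
  co <- shearlet_transform(img, sys)
  co3 <- shearlet_transform(3 * img, sys)
  for (b in c(1, 17, 32)) {
    expect_equal(co3$coeffs[[b]], 3 * co$coeffs[[b]], tolerance = 1e-12)
    expect_equal(co$magnitude[[b]], Mod(co$coeffs[[b]]))
    expect_true(all(co$phase[[b]] > -pi & co$phase[[b]] <= pi))
    expect_true(all(co$magnitude[[b]] >= 0))
  }
  expect_error(shearlet_transform(matrix(0, 32, 32), sys), "built for")
})

test_that("magnitude obeys the Pythagorean identity", {
  z <- 3 + 4i
  expect_equal(Mod(z), 5)
  co <- fixture_coeffs()
  b <- co$coeffs[[7]]
  expect_equal(co$magnitude[[7]], sqrt(Re(b)^2 + Im(b)^2), tolerance = 1e-12)
})

test_that("forward/inverse round trip reconstructs images (frame property)", {
  sys <- fixture_system()
  set.seed(9)
  for (i in 1:3) {
    img <- matrix(runif(64 * 64), 64)
    rec <- inverse_shearlet_transform(shearlet_transform(img, sys), sys)
    expect_lt(max(abs(rec - img)), 1e-6)
  }
  # zero image round trip and rectangular support
  z <- inverse_shearlet_transform(shearlet_transform(matrix(0, 64, 64), sys), sys)
  expect_equal(max(abs(z)), 0)
  rsys <- shearlet_system(96, 64, 4, 8)
  img <- matrix(runif(96 * 64), 96)
  rec <- inverse_shearlet_transform(shearlet_transform(img, rsys), rsys)
  expect_lt(max(abs(rec - img)), 1e-6)
})

test_that("reconstruction refuses incomplete coefficient stacks", {
  sys <- fixture_system()
  co <- fixture_coeffs()
  broken <- co
  broken$coeffs <- broken$coeffs[1:30]
  expect_error(inverse_shearlet_transform(broken, sys), "30")
  nolow <- co
  nolow$lowpass <- NULL
  expect_error(inverse_shearlet_transform(nolow, sys), "low-pass")
})

test_that("relative phase follows the cone-dependent difference rule", {
  # horizontal-cone sub-band (k = 1): column-neighbor difference
  theta <- matrix(0.1, 4, 4)
  theta[2, 2] <- 0.3
  rp <- relative_phase(list(theta, theta), directions_per_scale = 2)[[1]]
  expect_equal(rp[2, 1], 0.1 - 0.3)
  expect_equal(rp[2, 2], 0.3 - 0.1)

  # vertical-cone sub-band (k = K): row-neighbor difference with wrapping
  theta2 <- matrix(0, 4, 4)
  theta2[1, 1] <- -3.0
  theta2[2, 1] <- 3.0
  rp2 <- relative_phase(list(theta2, theta2),
                        directions_per_scale = 2)[[2]]
  expect_equal(rp2[1, 1], -6 - 2 * pi * round(-6 / (2 * pi)),
               tolerance = 1e-12)
  expect_equal(rp2[1, 1], 2 * pi - 6, tolerance = 1e-12)

  # constant phase field -> zero RP, full shape retained
  const <- matrix(1.2, 5, 7)
  rp3 <- relative_phase(list(const, const), directions_per_scale = 2)[[1]]
  expect_equal(dim(rp3), c(5, 7))
  expect_true(all(rp3 == 0))
})

test_that("relative phase is invariant under a global phase shift", {
  co <- fixture_coeffs()
  shifted <- lapply(co$phase, function(th) {
    w <- th + 0.7
    w - 2 * pi * round(w / (2 * pi))
  })
  rp0 <- relative_phase(co$phase, 8)
  rp1 <- relative_phase(shifted, 8)
  for (b in c(2, 15, 31)) {
    d <- rp1[[b]] - rp0[[b]]
    d <- d - 2 * pi * round(d / (2 * pi))
    expect_lt(max(abs(d)), 1e-9)
  }
  expect_true(all(vapply(rp0, function(m) all(m > -pi & m <= pi), logical(1))))
})

test_that("sub-band energy tracks grating orientation (filter support oracle)", {
  sys <- fixture_system(128)
  freq <- 24
  # probe at the 8 wedge-center orientations; boundary angles are shared
  # equally between two adjacent wedges and have no unique maximizer
  for (ang in seq(11.25, 168.75, by = 22.5)) {
    img <- generate_texture(ang, freq, 128, contrast = 1, noise_sd = 0,
                            seed = 1)
    co <- shearlet_transform(img, sys)
    energy <- vapply(co$magnitude, function(m) sum(m^2), numeric(1))
    got <- which.max(energy)
    # oracle: the grating's spectral peak sits at +/- freq along its
    # orientation; the expected sub-band is the filter with the largest
    # frequency response there
    theta <- ang * pi / 180
    fx <- freq * cos(theta) / 128
    fy <- freq * sin(theta) / 128
    gx <- shearltex:::fft_freqs(128)
    ix <- which.min(abs(gx - fx)); ixn <- which.min(abs(gx + fx))
    iy <- which.min(abs(gx - fy)); iyn <- which.min(abs(gx + fy))
    support <- vapply(sys$filters, function(filt) {
      max(filt[iy, ix], filt[iyn, ixn])
    }, numeric(1))
    expected <- which.max(support)
    expect_equal(sys$index$orientation_deg[got],
                 sys$index$orientation_deg[expected])
    # cross-orientation leakage is small
    dang <- (sys$index$orientation_deg -
               sys$index$orientation_deg[got]) %% 180
    ortho <- which(abs(dang - 90) < 1e-6 &
                     sys$index$scale == sys$index$scale[got])
    expect_lt(max(energy[ortho]), 0.1 * energy[got])
  }
})
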