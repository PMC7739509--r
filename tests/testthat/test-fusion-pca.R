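make_sample_blocks <- function(n = 6, seed = 61) {
  sys <- shearlet_system(64, 64, 4, 8)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    img <- generate_texture(sample(0:179, 1), 8, 64, noise_sd = 0.2,
                            seed = seed + i)
    texture_blocks(shearlet_transform(img, sys),
                   descriptors = c("cm", "lbp", "losib", "sfta", "cmdot"))
  })
}

test_that("fusion recipes concatenate blocks in the documented order", {
  samples <- fixture_env$fusion_samples
  if (is.null(samples)) {
    samples <- make_sample_blocks()
    fixture_env$fusion_samples <- samples
  }
  x1 <- fuse(samples, fusion_spec("fusion1"))
  expect_equal(ncol(x1), 3776)
  expect_equal(nrow(x1), length(samples))
  x2 <- fuse(samples, fusion_spec("fusion2"))
  expect_equal(ncol(x2), 1792)
  x3 <- fuse(samples, fusion_spec("fusion3"))
  expect_equal(ncol(x3), 640 + 320 + 256 + 640 + 320 + 672 + 256)

  # single-block passthrough is bit-for-bit
  xs <- fuse(samples, fusion_spec("custom", mag_blocks = "cm"))
  expect_equal(ncol(xs), 640)
  expect_identical(xs[3, ], samples[[3]][["cm.magnitude"]]$values)
  # RP blocks come first, then magnitude
  expect_identical(x1[1, ], c(samples[[1]][["cm.rp"]]$values,
                              samples[[1]][["lbp.rp"]]$values,
                              samples[[1]][["losib.rp"]]$values,
                              samples[[1]][["sfta.rp"]]$values,
                              samples[[1]][["cm.magnitude"]]$values,
                              samples[[1]][["lbp.magnitude"]]$values,
                              samples[[1]][["losib.magnitude"]]$values,
                              samples[[1]][["sfta.magnitude"]]$values))
  expect_identical(anyDuplicated(colnames(x1)), 0L)

  missing <- samples
  missing[[2]][["losib.rp"]] <- NULL
  expect_error(fuse(missing, fusion_spec("fusion1")), "sample 2.*losib.rp")
  expect_error(fusion_spec("custom"), "no blocks")
})

test_that("standardization uses training statistics only", {
  set.seed(62)
  x <- cbind(matrix(rnorm(40, mean = 3, sd = 2), 10), const = 1)
  colnames(x) <- c(paste0("f", 1:4), "const")
  expect_warning(s <- standardize_fit(x), "zero-variance")
  expect_identical(s$dropped, "const")
  z <- standardize_apply(x, s)
  expect_equal(ncol(z), 4)
  expect_lt(max(abs(colMeans(z))), 1e-8)
  expect_lt(max(abs(apply(z, 2, stats::sd) - 1)), 1e-8)
  # a test row equal to the training mean maps to zero
  mrow <- matrix(c(s$mean, 1), 1, dimnames = list(NULL, colnames(x)))
  expect_lt(max(abs(standardize_apply(mrow, s))), 1e-12)
})

test_that("varimax-rotated PCA keeps an orthonormal basis", {
  set.seed(63)
  # dominant axis of perfectly diagonal 2-D data
  t <- rnorm(50)
  x <- cbind(a = t, b = t) + 1e-6 * matrix(rnorm(100), 50)
  m1 <- pca_fit(x, 1)
  expect_equal(unname(abs(m1$basis[, 1])), c(1, 1) / sqrt(2),
               tolerance = 1e-3)

  x <- matrix(rnorm(30 * 8), 30)
  colnames(x) <- paste0("f", 1:8)
  m <- pca_fit(x, 8)
  gram <- crossprod(m$basis)
  expect_lt(max(abs(gram - diag(8))), 1e-8)
  # full-rank projection is an orthogonal map: distances preserved
  p <- pca_project(x, m)
  expect_lt(max(abs(dist(x) - dist(p))), 1e-8)
  # projecting the training mean gives the zero vector
  mu <- matrix(colMeans(x), 1)
  expect_lt(max(abs(pca_project(mu, m))), 1e-10)
  # round trip through the full basis
  back <- p %*% t(m$basis)
  back <- sweep(back, 2, m$center, "+")
  expect_lt(max(abs(back - x)), 1e-8)

  expect_error(pca_fit(x, 31), "out of range")
  expect_error(pca_project(x[, 1:5], m), "fitted on")
})

test_that("varimax is a fixed point on an already-optimal basis", {
  # axis-aligned loadings maximize the varimax criterion already
  L <- diag(1, 6)[, 1:3]
  r <- shearltex:::varimax_rotate(L)
  expect_equal(abs(r$loadings), L, tolerance = 1e-8)
})

test_that("corrupting held-out rows never changes fitted parameters", {
  set.seed(64)
  x <- matrix(rnorm(40 * 6), 40)
  colnames(x) <- paste0("f", 1:6)
  tr <- 1:30; te <- 31:40
  fit_params <- function(data) {
    s <- standardize_fit(data[tr, ])
    m <- pca_fit(standardize_apply(data[tr, ], s), 3)
    list(mean = s$mean, sd = s$sd, basis = m$basis, center = m$center)
  }
  ref <- fit_params(x)
  corrupted <- x
  corrupted[te, ] <- 1e6 * matrix(rnorm(60), 10)
  expect_identical(fit_params(corrupted), ref)
})
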