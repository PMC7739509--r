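# Shared fixtures and independent oracle implementations used across tests.

# one cached default system + decomposition of a noisy grating
fixture_env <- new.env()

fixture_system <- function(n = 64) {
  key <- paste0("sys", n)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- shearlet_system(n, n, 4, 8)
  }
  fixture_env[[key]]
}

fixture_coeffs <- function(n = 64) {
  key <- paste0("co", n)
  if (is.null(fixture_env[[key]])) {
    img <- generate_texture(30, 8, n, contrast = 1, noise_sd = 0.2, seed = 42)
    fixture_env[[key]] <- shearlet_transform(img, fixture_system(n))
  }
  fixture_env[[key]]
}

# random symmetric normalized co-occurrence matrix
random_cooc <- function(ng = 4) {
  m <- matrix(stats::runif(ng * ng), ng)
  m <- m + t(m)
  m / sum(m)
}

# literal double-sum implementation of the 20 co-occurrence statistics,
# kept deliberately loop-based and independent of haralick20()
brute_haralick <- function(p) {
  ng <- nrow(p)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]; py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  vx <- 0; vy <- 0
  for (i in 1:ng) {
    vx <- vx + (i - mux)^2 * px[i]; vy <- vy + (i - muy)^2 * py[i]
  }
  psum <- numeric(2 * ng); pdif <- numeric(ng)   # index k+... offsets below
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  ent <- function(v) { s <- 0; for (q in v) if (q > 0) s <- s - q * log(q); s }
  contrast <- 0; corr_num <- 0; energy <- 0; autoc <- 0; cprom <- 0
  cshad <- 0; dissi <- 0; homog <- 0; sos <- 0; idn <- 0; idmn <- 0
  hxy1 <- 0
  mu_cm <- (mux + muy) / 2
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    contrast <- contrast + (i - j)^2 * v
    corr_num <- corr_num + (i - mux) * (j - muy) * v
    energy <- energy + v^2
    autoc <- autoc + i * j * v
    cprom <- cprom + (i + j - mux - muy)^4 * v
    cshad <- cshad + (i + j - mux - muy)^3 * v
    dissi <- dissi + abs(i - j) * v
    homog <- homog + v / (1 + abs(i - j))
    sos <- sos + (i - mu_cm)^2 * v
    idn <- idn + v / (1 + abs(i - j) / ng)
    idmn <- idmn + v / (1 + (i - j)^2 / ng^2)
    if (v > 0) hxy1 <- hxy1 - v * log(px[i] * py[j])
  }
  sa <- 0; for (k in 2:(2 * ng)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * ng)) sv <- sv + (k - sa)^2 * psum[k]
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pdif[k + 1]
  dv <- 0; for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  hxy <- ent(as.vector(p)); hx <- ent(px); hy <- ent(py)
  c(
    contrast = contrast,
    correlation = if (vx > 0 && vy > 0) corr_num / sqrt(vx * vy) else 0,
    energy = energy, autocorrelation = autoc,
    cluster_prominence = cprom, cluster_shade = cshad,
    dissimilarity = dissi, entropy = hxy, homogeneity = homog,
    max_probability = max(p), sum_of_squares = sos, variance = vx,
    sum_average = sa, sum_variance = sv, sum_entropy = ent(psum),
    difference_variance = dv, difference_entropy = ent(pdif),
    imc = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    idn = idn, idmn = idmn
  )
}

# direct LOSIB oracle: loop over interior centers and the 8 unit offsets
brute_losib <- function(band) {
  nr <- nrow(band); nc <- ncol(band)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  out <- numeric(8)
  for (q in 1:8) {
    tot <- 0
    for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
      tot <- tot + abs(band[i, j] - band[i + offs[[q]][1], j + offs[[q]][2]])
    }
    out[q] <- tot / ((nr - 2) * (nc - 2))
  }
  out
}
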