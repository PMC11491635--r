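# Deformation algebra: PCA effect models, masking, Log-Euclidean
# exponentiation and warping.

gd <- c(12L, 12L, 12L)

test_that("fitEffectModel recovers degenerate and low-rank structure", {
  base <- syntheticField(gd, seed = 1)
  # two identical fields: mean is that field, no variance
  m <- fitEffectModel(list(base, base), nComponents = 1)
  expect_equal(meanField(m), base)
  expect_lt(max(componentScales(m)), 1e-10)
  # three scalar multiples of one field: exactly one nonzero component
  m <- fitEffectModel(list(base, 2 * base, 3 * base), nComponents = 2)
  sc <- componentScales(m)
  expect_gt(sc[1], 0)
  expect_lt(sc[2] / sc[1], 1e-10)
  # error cases
  expect_error(fitEffectModel(list(base), 1), "at least 2")
  expect_error(fitEffectModel(list(base, base[1:8, , , , drop = FALSE]), 1),
               "same grid")
  expect_error(fitEffectModel(list(base, 2 * base), 2), "at most")
})

test_that("full-rank PCA reconstructs training fields (SVD oracle)", {
  fields <- lapply(1:5, function(s) syntheticField(gd, seed = s))
  m <- fitEffectModel(fields, nComponents = 4)
  X <- t(vapply(fields, as.vector, numeric(prod(gd) * 3)))
  mu <- colMeans(X)
  # independent oracle: direct SVD of the centered data matrix
  sv <- svd(sweep(X, 2, mu))
  expect_equal(componentScales(m), (sv$d / sqrt(4))[1:4], tolerance = 1e-10)
  for (i in 1:5) {
    coefs <- as.numeric((X[i, ] - mu) %*% m@basis)
    rec <- mu + as.vector(m@basis %*% coefs)
    relerr <- sqrt(sum((rec - X[i, ])^2)) / sqrt(sum(X[i, ]^2))
    expect_lt(relerr, 1e-6)
  }
  # orthonormality is part of the validity contract
  expect_true(validObject(m))
})

test_that("sampleEffect honors seed, target magnitude and the sampler law", {
  fields <- lapply(1:6, function(s) syntheticField(gd, seed = s + 10))
  m <- fitEffectModel(fields, nComponents = 3)
  s1 <- sampleEffect(m, seed = 42)
  s2 <- sampleEffect(m, seed = 42)
  expect_identical(coef(s1), coef(s2))
  expect_identical(effectField(s1), effectField(s2))
  # target magnitude 0: field equals the mean field
  s0 <- sampleEffect(m, seed = 1, targetMagnitude = 0)
  expect_equal(effectField(s0), meanField(m))
  expect_identical(magnitude(s0), 0)
  # rescaling hits the target exactly
  st <- sampleEffect(m, seed = 3, targetMagnitude = 2.5)
  expect_equal(magnitude(st), 2.5, tolerance = 1e-12)
  expect_error(sampleEffect(m, seed = 1, targetMagnitude = -1), ">= 0")
  # law of large numbers on a hand-built 2-component model
  k <- 2
  basis <- qr.Q(qr(matrix(rnorm(prod(gd) * 3 * k), ncol = k)))
  m2 <- new("EffectModel", meanField = array(0, c(gd, 3L)), basis = basis,
            scales = c(2, 1), gridDim = gd, supportMask = NULL)
  co <- synthbias:::sampleCoefficientMatrix(m2, 10000, seed = 9)
  expect_equal(apply(co, 2, sd), c(2, 1), tolerance = 0.05)
})

test_that("restrictToRegion masks hard, soft and idempotently", {
  f <- syntheticField(gd, seed = 5)
  mask <- array(0, gd); mask[4:8, 4:8, 4:8] <- 1
  hard <- restrictToRegion(f, mask, 0)
  expect_equal(hard[4:8, 4:8, 4:8, ], f[4:8, 4:8, 4:8, ])
  out <- hard; out[4:8, 4:8, 4:8, ] <- 0
  expect_true(all(out == 0))
  # idempotent with the same mask
  expect_identical(restrictToRegion(hard, mask, 0), hard)
  # all-ones mask is the identity
  expect_identical(restrictToRegion(f, array(1, gd), 0), f)
  # single-voxel mask, sigma 1: weight profile is the normalized Gaussian
  ind <- array(0, gd); ind[6, 6, 6] <- 1
  soft <- restrictToRegion(f, ind, 1)
  g <- gaussianSmooth(ind, 1); g <- g / max(g); g[g < 1e-8] <- 0
  expect_equal(soft[, , , 2], f[, , , 2] * g, tolerance = 1e-12)
  expect_error(restrictToRegion(f, array(0, gd), 0), "empty")
})

test_that("exponentiate: identity, translation and inverse consistency", {
  zero <- array(0, c(gd, 3L))
  expect_true(all(exponentiate(zero) == 0))
  # spatially constant field = pure translation in the interior
  tr <- zero; tr[, , , 1] <- 0.7; tr[, , , 3] <- -0.4
  d <- exponentiate(tr)
  inner <- 4:9
  expect_lt(max(abs(d[inner, inner, inner, 1] - 0.7)), 1e-4)
  expect_lt(max(abs(d[inner, inner, inner, 3] + 0.4)), 1e-4)
  expect_lt(max(abs(d[inner, inner, inner, 2])), 1e-4)
  # inverse consistency at phantom scale (amplitude ~1 voxel at this
  # resolution corresponds to a few-mm full-resolution deformation)
  tpl <- makePhantomTemplate(c(32, 32, 32), seed = 0)
  bank <- makePhantomFieldBank(tpl, nFields = 3, smoothnessSigma = 4,
                               amplitude = 0.8, seed = 2)
  for (v in bank) {
    comp <- composeDisplacements(exponentiate(v), exponentiate(-v))
    mag <- sqrt(comp[, , , 1]^2 + comp[, , , 2]^2 + comp[, , , 3]^2)
    expect_lt(max(mag[7:26, 7:26, 7:26]), 0.05)
    # diffeomorphism: strictly positive Jacobian determinant
    expect_gt(min(jacobianDeterminant(exponentiate(v))), 0)
  }
})

test_that("composeEffectFields adds velocities (disjoint-support oracle)", {
  s <- syntheticField(gd, seed = 20)
  expect_identical(composeEffectFields(s), s)
  expect_identical(composeEffectFields(s, disease = s * 0), s)
  m1 <- array(0, gd); m1[2:5, , ] <- 1
  m2 <- array(0, gd); m2[8:11, , ] <- 1
  a <- restrictToRegion(syntheticField(gd, seed = 21), m1, 0)
  b <- restrictToRegion(syntheticField(gd, seed = 22), m2, 0)
  comp <- composeEffectFields(s * 0, disease = a, bias = b)
  expect_equal(comp[2:5, , , ], a[2:5, , , ])
  expect_equal(comp[8:11, , , ], b[8:11, , , ])
})

test_that("warpVolume: identity, integer shift and intensity conservation", {
  tpl <- tinyTemplate()
  vol <- intensityVolume(tpl)
  zero <- array(0, c(dim(vol), 3L))
  expect_identical(warpVolume(vol, zero), vol)
  # +1 voxel along axis 1: output(x) = input(x + 1)
  sh <- zero; sh[, , , 1] <- 1
  w <- warpVolume(vol, sh)
  expect_equal(w[1:15, , ], vol[2:16, , ])
  # mean intensity conserved within 2% under a small smooth deformation
  v <- syntheticField(dim(vol), seed = 31, sigma = 3, amplitude = 1.5)
  wv <- warpVolume(vol, exponentiate(v))
  expect_lt(abs(mean(wv) - mean(vol)) / mean(vol), 0.02)
})

test_that("effect model archives round-trip through NIfTI + YAML", {
  fields <- lapply(1:4, function(s) syntheticField(gd, seed = s + 40))
  m <- fitEffectModel(fields, nComponents = 3)
  path <- file.path(tempdir(), "model.tar")
  writeEffectModel(m, path)
  m2 <- readEffectModel(path)
  expect_equal(m2@gridDim, m@gridDim)
  expect_equal(componentScales(m2), componentScales(m), tolerance = 1e-6)
  expect_equal(meanField(m2), meanField(m), tolerance = 1e-6)
  expect_equal(m2@basis, m@basis, tolerance = 1e-6)
  unlink(path)
})
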