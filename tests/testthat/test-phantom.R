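test_that("phantom generation is bit-identical under a fixed seed and differs across seeds", {
  p <- phantomParams(seed = 11L)
  rp <- tinyRefProfile(nf = 32L, ns = 12L, nd = 96L, looks = 12)
  a <- generateEye(p, rp)
  b <- generateEye(p, rp)
  expect_identical(volData(referenceVolume(a)), volData(referenceVolume(b)))
  expect_identical(lumenMask(a), lumenMask(b))
  c <- generateEye(phantomParams(seed = 12L), rp)
  expect_false(identical(volData(referenceVolume(a)),
                         volData(referenceVolume(c))))
})

test_that("vessel-free phantom has an empty lumen mask and zero ground-truth CVI", {
  eye <- generateEye(phantomParams(seed = 2L, vessel_fraction = 0),
                     tinyRefProfile(nf = 24L, ns = 12L, nd = 96L))
  expect_false(any(lumenMask(eye)))
  gt <- groundTruthMetrics(eye)
  expect_identical(gt@cvi, 0)
  expect_identical(gt@la, 0)
})

test_that("flat-surface phantom reproduces the configured choroidal thickness analytically", {
  p <- phantomParams(seed = 1L, surface_undulation = c(0, 1),
                     retinal_thickness_mm = c(0.22, 0),
                     choroidal_thickness_mm = c(0.25, 0),
                     vessel_fraction = 0)
  # odd lateral grid: the volume centre (pit centre) is a voxel centre
  eye <- generateEye(p, tinyRefProfile(nf = 33L, ns = 33L, nd = 256L))
  ct <- csiSurface(eye) - rpeSurface(eye)
  expect_equal(range(ct), c(0.25, 0.25), tolerance = 1e-12)
  rt <- rpeSurface(eye)[foveaIndex(eye)[1], foveaIndex(eye)[2]] -
    ilmSurface(eye)[foveaIndex(eye)[1], foveaIndex(eye)[2]]
  expect_equal(rt, 0.22, tolerance = 1e-9)
})

test_that("boundary ordering, lumen containment and fovea location hold across seeds", {
  rp <- tinyRefProfile(nf = 32L, ns = 12L, nd = 96L)
  for (seed in 1:8) {
    eye <- generateEye(phantomParams(seed = seed), rp)
    expect_true(all(ilmSurface(eye) < rpeSurface(eye)))
    expect_true(all(rpeSurface(eye) < csiSurface(eye)))
    d <- dim(volData(referenceVolume(eye)))
    vox <- fovMM(referenceVolume(eye))[1] / d[1]
    dmm <- (seq_len(d[1]) - 0.5) * vox
    D <- array(dmm, d)
    band <- D > octsynth:::.lateralToVolume(rpeSurface(eye), d[1]) &
      D <= octsynth:::.lateralToVolume(csiSurface(eye), d[1])
    expect_true(all(band[lumenMask(eye)]))
    rt <- rpeSurface(eye) - ilmSurface(eye)
    expect_equal(rt[foveaIndex(eye)[1], foveaIndex(eye)[2]], min(rt))
  }
})

test_that("ground-truth CVI equals the realized lumen fraction on the foveal B-scan exactly", {
  eye <- noiseFreeEye()
  gt <- groundTruthMetrics(eye)
  d <- dim(volData(referenceVolume(eye)))
  vox <- fovMM(referenceVolume(eye))[1] / d[1]
  fv <- foveaIndex(eye)
  dmm <- (seq_len(d[1]) - 0.5) * vox
  band <- outer(dmm, rpeSurface(eye)[, fv[2]], `>`) &
    outer(dmm, csiSurface(eye)[, fv[2]], `<=`)
  lum <- lumenMask(eye)[, , fv[2]] & band
  expect_equal(gt@cvi, sum(lum) / sum(band), tolerance = 1e-15)
  expect_true(phantomLumenFraction(eye) > 0.6)
})

test_that("mean realized subfoveal retinal thickness matches the configured center", {
  rp <- tinyRefProfile(nf = 32L, ns = 32L, nd = 48L)
  rts <- vapply(1:100, function(seed) {
    eye <- generateEye(phantomParams(seed = seed, vessel_fraction = 0), rp)
    groundTruthMetrics(eye)@rt
  }, numeric(1))
  # 3 standard errors of the mean around the configured 0.22 mm
  expect_lt(abs(mean(rts) - 0.22), 3 * 0.02 / sqrt(100))
})

test_that("degradation resamples to the shallow-device grid and attenuates sub-RPE signal", {
  p <- phantomParams(seed = 3L, surface_undulation = c(0, 1),
                     retinal_thickness_mm = c(0.22, 0),
                     choroidal_thickness_mm = c(0.9, 0),
                     vessel_fraction = 0, lateral_offset_mm = c(0, 0))
  eye <- generateEye(p, tinyRefProfile(nf = 48L, ns = 16L, nd = 256L))

  # printed shallow-device lateral grid
  sdp <- tinySDProfile(nf = 245L, ns = 245L, nd = 48L, attenuation = 0)
  dv <- degradeEye(eye, sdp, speckle = FALSE)
  expect_identical(dim(dv)[2:3], c(245L, 245L))

  # identity degradation: same grid, no attenuation/speckle/offset
  idp <- deviceProfile("id", 48L, 16L, 256L, c(3, 3, 3))
  dv0 <- degradeEye(eye, idp, speckle = FALSE)
  expect_equal(volData(dv0), eye@scene, tolerance = 1e-6)

  # closed-form exponential decay, alpha = 2 per mm
  adp <- deviceProfile("att", 48L, 16L, 256L, c(3, 3, 3),
                       attenuation_below_rpe = 2)
  dva <- degradeEye(eye, adp, speckle = FALSE)
  vox <- 3 / 256
  rpeRow <- mean(rpeSurface(eye)) / vox
  rowAt <- function(mm) round(rpeRow + mm / vox)
  v <- volData(dva)
  ratio <- mean(v[rowAt(0.5), , ]) / mean(v[rowAt(0.1), , ])
  expect_equal(ratio, exp(-2 * 0.4), tolerance = 0.05)
})

test_that("impossible vessel or offset requests are rejected with clear errors", {
  p <- phantomParams(seed = 1L, choroidal_thickness_mm = c(0.09, 0),
                     vessel_radius_px = c(4, 6))
  expect_error(generateEye(p, tinyRefProfile(nf = 16L, ns = 8L, nd = 48L)),
               "too thin")
  eye <- noiseFreeEye()
  eye@params$lateral_offset_mm <- c(2, 0)
  expect_error(degradeEye(eye, tinySDProfile()), "offset")
})

test_that("degenerate choroid band flags CVI as undefined rather than zero", {
  res <- computeCVI(matrix(runif(64 * 32), 64, 32),
                    rpe_row = rep(30, 32), csi_row = rep(30, 32),
                    vox_mm = c(0.01, 0.01), window = 15L)
  expect_true(is.na(res$cvi))
  expect_identical(res$ca_mm2, 0)
})
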