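mkVol <- function(arr, fov = c(2, 3, 3), ss = NA_integer_)
  octVolume(arr, fov = fov, signalStrength = ss)

test_that("quality filter retains a pair only when both volumes meet the minimum", {
  mk <- function(ssIn, ssRef) list(
    input = mkVol(array(0, c(8, 8, 4)), ss = ssIn),
    reference = mkVol(array(0, c(8, 8, 4)), ss = ssRef))
  res <- qualityFilter(list(mk(7L, 6L)), 6L)
  expect_length(res$retained, 1L)

  res <- qualityFilter(list(mk(9L, 5L)), 6L)
  expect_length(res$retained, 0L)
  expect_match(res$log$reason[1], "reference")

  # enumeration: exactly 3 of 10 pairs fail
  strengths <- cbind(c(6, 7, 8, 9, 10, 6, 7, 8, 9, 10),
                     c(6, 7, 5, 9, 10, 4, 7, 8, 3, 10))
  pairs <- lapply(seq_len(10), function(i) mk(strengths[i, 1],
                                              strengths[i, 2]))
  res <- qualityFilter(pairs, 6L)
  expect_length(res$retained, 7L)
  expect_identical(sum(!res$log$retained), 3L)
})

test_that("Lanczos resampling is an identity at the source shape and preserves constants", {
  v <- mkVol(array(runif(16 * 12 * 10), c(16, 12, 10)))
  same <- lanczosResample(v, c(16, 12, 10))
  expect_equal(volData(same), volData(v), tolerance = 1e-6)

  cv <- mkVol(array(0.7, c(16, 12, 10)))
  r <- lanczosResample(cv, c(23, 17, 31))
  expect_equal(max(abs(volData(r) - 0.7)), 0, tolerance = 1e-12)

  v245 <- mkVol(array(runif(12 * 10 * 245), c(12, 10, 245)))
  r256 <- lanczosResample(v245, c(12, 10, 256))
  expect_identical(dim(r256)[3], 256L)
  expect_error(lanczosResample(v, c(0, 12, 10)))
})

test_that("despeckling preserves constants and the intensity range, and reduces intra-band variance without moving edges", {
  const <- mkVol(array(0.4, c(24, 24, 2)))
  expect_equal(volData(despeckle(const, 20)), volData(const))
  v <- mkVol(array(runif(24 * 24 * 2), c(24, 24, 2)))
  expect_identical(despeckle(v, 0L), v)
  expect_error(despeckle(v, 10L, step = 0.3), "step")

  # two-band speckled B-scan: band edge at row 40
  set.seed(7)
  clean <- matrix(0.2, 80, 64); clean[40:80, ] <- 0.7
  noisy <- clean * matrix(rgamma(80 * 64, 20, 20), 80, 64)
  vol <- mkVol(array(noisy, c(80, 64, 1)))
  out <- volData(despeckle(vol, 20L))[, , 1]
  expect_gte(min(out), min(noisy) - 1e-9)
  expect_lte(max(out), max(noisy) + 1e-9)
  bandVar <- function(m) var(as.vector(m[1:35, ])) +
    var(as.vector(m[45:80, ]))
  expect_lt(bandVar(out), 0.5 * bandVar(noisy))
  edge <- function(m) which.max(diff(rowMeans(m)))
  expect_lte(abs(edge(out) - edge(noisy)), 1)
})

test_that("RPE estimation finds a single bright band and the phantom RPE", {
  # single Gaussian band at row 100
  rows <- 1:128
  prof <- 0.1 + 0.8 * exp(-(rows - 100)^2 / 8)
  v <- mkVol(array(rep(prof, 20 * 6), c(128, 20, 6)))
  sur <- estimateRPE(v)
  expect_lt(max(abs(sur$depth_row - 100)), 0.5)

  # noise-free two-band phantom: ILM 60, RPE 92
  prof2 <- 0.05 + 0.55 * exp(-(rows - 60)^2 / 8) +
    0.8 * exp(-(rows - 92)^2 / 8)
  v2 <- mkVol(array(rep(prof2, 20 * 6), c(128, 20, 6)))
  sur2 <- estimateRPE(v2)
  expect_lt(max(abs(sur2$depth_row - 92)), 2)

  # speckled phantom at the quality floor: median error <= 2 rows
  eye <- generateEye(phantomParams(seed = 21L, signal_strength = 6L),
                     tinyRefProfile(looks = 15))
  dsp <- despeckle(referenceVolume(eye))
  sur3 <- estimateRPE(dsp)
  vox <- fovMM(referenceVolume(eye))[1] / dim(referenceVolume(eye))[1]
  truth <- rpeSurface(eye) / vox + 0.5
  expect_lte(median(abs(sur3$depth_row - truth)), 2)
})

test_that("flattening is exact for already-flat surfaces, idempotent, and intensity-preserving", {
  eye <- noiseFreeEye()
  ref <- referenceVolume(eye)
  sur <- estimateRPE(ref)

  flatSurf <- matrix(80, dim(ref)[2], dim(ref)[3])
  same <- flattenVolume(ref, flatSurf, 80)
  expect_identical(volData(same), volData(ref))

  fl <- flattenVolume(ref, sur, 80)
  re <- estimateRPE(fl)
  expect_lte(sd(re$depth_row), 0.5)

  # integer shifts preserve each A-scan's multiset away from margins
  shift <- fl@meta$flatten_shift
  f <- 10; s <- 3
  src <- volData(ref)[, f, s]; dst <- volData(fl)[, f, s]
  k <- shift[f, s]
  kept <- if (k >= 0) src[seq_len(length(src) - k)] else src[(1 - k):length(src)]
  expect_true(all(kept %in% dst))
  expect_error(flattenVolume(ref, sur, 1e6), "target_row")
})

test_that("enface registration recovers injected integer shifts exactly and sub-pixel shifts within half a voxel", {
  eye <- noiseFreeEye()
  ref <- referenceVolume(eye)
  vox <- fovMM(ref)[1] / dim(ref)[1]
  tr <- round(mean(rpeSurface(eye)) / vox)

  idr <- registerEnface(ref, ref, tr)
  expect_equal(idr$shift, c(0, 0), tolerance = 1e-9)
  expect_gt(idr$score, 0.999)

  mv <- rollVolumeLateral(ref, c(5L, -3L))
  reg <- registerEnface(ref, mv, tr)
  expect_identical(round(reg$shift), c(-5, 3))
  expect_equal(reg$shift, c(-5, 3), tolerance = 1e-9)

  mv2 <- octsynth:::.shiftLateral(ref, c(2.5, 0))
  reg2 <- registerEnface(ref, mv2, tr)
  expect_lt(max(abs(reg2$shift - c(-2.5, 0))), 0.5)

  # shifts beyond a quarter of the extent flag a registration failure
  big <- rollVolumeLateral(ref, c(30L, 0L))
  regBig <- registerEnface(ref, big, tr, max_shift_frac = 0.25)
  expect_false(regBig$success)
})

test_that("phase-correlation recovery holds across random sub-voxel shifts", {
  eye <- generateEye(phantomParams(seed = 19L),
                     tinyRefProfile(nf = 96L, ns = 96L, nd = 128L))
  ref <- referenceVolume(eye)
  vox <- fovMM(ref)[1] / dim(ref)[1]
  tr <- round(mean(rpeSurface(eye)) / vox)
  set.seed(42)
  for (i in 1:20) {
    s <- round(runif(2, -10, 10) * 2) / 2   # half-voxel lattice
    mv <- octsynth:::.shiftLateral(ref, s)
    reg <- registerEnface(ref, mv, tr)
    expect_lt(max(abs(reg$shift + s)), 0.5)
  }
})

test_that("finalizePair enforces the shared grid contract and is an identity at matching fov", {
  eye <- generatePairedEye(phantomParams(seed = 9L),
                           tinyRefProfile(nf = 48L, ns = 24L, nd = 96L),
                           tinySDProfile(nf = 40L, ns = 20L, nd = 64L),
                           speckle = FALSE)
  pair <- finalizePair(degradedVolume(eye), referenceVolume(eye),
                       grid = c(48L, 48L, 32L), fov = c(2.6, 2.6, 2.0))
  expect_identical(dim(pair), c(48L, 48L, 32L))
  expect_equal(unname(fovMM(inputVolume(pair))), c(2.0, 2.6, 2.6))
  expect_identical(dim(inputVolume(pair)), dim(referenceVolume(pair)))

  v <- mkVol(array(runif(16 * 12 * 10), c(16, 12, 10)), fov = c(2, 2.6, 2.6))
  idp <- finalizePair(v, v, grid = c(16L, 12L, 10L), fov = c(2.6, 2.6, 2.0))
  expect_identical(volData(inputVolume(idp)), volData(v))
  expect_error(finalizePair(v, v, grid = c(8L, 8L, 8L), fov = c(9, 9, 9)),
               "exceeds")
})

test_that("the full preprocessing stack is deterministic", {
  eye <- generatePairedEye(phantomParams(seed = 31L),
                           tinyRefProfile(nf = 48L, ns = 48L, nd = 96L,
                                          looks = 15, floor = 0.01),
                           tinySDProfile(nf = 40L, ns = 40L, nd = 64L,
                                         looks = 15, floor = 0.05))
  cfg <- preprocessConfig(grid = c(48L, 48L, 32L),
                          despeckle = list(n_iter = 5L, kappa = 30,
                                           step = 0.2),
                          register = list(halfband = 4L,
                                          max_shift_frac = 0.25))
  a <- preprocessPair(degradedVolume(eye), referenceVolume(eye), cfg)
  b <- preprocessPair(degradedVolume(eye), referenceVolume(eye), cfg)
  expect_true(a$success)
  expect_identical(volData(inputVolume(a$pair)),
                   volData(inputVolume(b$pair)))
  expect_identical(a$log$register$shift, b$log$register$shift)
})
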