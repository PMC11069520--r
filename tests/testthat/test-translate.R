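test_that("generator preserves shape and realizes the 3/9/3 block census", {
  gen <- buildGenerator(generatorConfig(base_width = 4L))
  x <- array(runif(64 * 64), c(64, 64, 1))
  y <- octsynth:::.genForward(gen, x)
  expect_identical(dim(y), c(64L, 64L, 1L))
  expect_identical(generatorBlocks(gen),
                   c(encode = 3L, residual = 9L, decode = 3L))
  expect_error(octsynth:::.genForward(gen, array(0, c(66, 66, 1))),
               "divisible")
})

test_that("generator parameter count matches the layer-by-layer hand tally at base width 64", {
  w <- 64
  hand <- (7 * 7 * 1 * w + w) +                      # 7x7 stem
    (3 * 3 * w * 2 * w + 2 * w) +                    # down 1
    (3 * 3 * 2 * w * 4 * w + 4 * w) +                # down 2
    9 * 2 * (3 * 3 * 4 * w * 4 * w + 4 * w) +        # residual convs
    (3 * 3 * 4 * w * 2 * w + 2 * w) +                # up 1
    (3 * 3 * 2 * w * 1 * w + 1 * w) +                # up 2
    (7 * 7 * w * 1 + 1)                              # output stem
  gen <- buildGenerator(generatorConfig(base_width = 64L))
  expect_identical(numParameters(gen), hand)
})

test_that("patch discriminator has 5 conv layers, a 70x70 receptive field, and a 30x30 map on 256x256", {
  disc <- buildDiscriminator(discriminatorConfig(base_width = 8L))
  expect_identical(disc$receptive_field, 70L)
  nConv <- sum(vapply(disc$layers, function(L) L$type == "conv", logical(1)))
  expect_identical(nConv, 5L)
  z <- octsynth:::.discForward(disc, array(runif(256 * 256), c(256, 256, 1)),
                               array(runif(256 * 256), c(256, 256, 1)))
  expect_identical(dim(z), c(30L, 30L, 1L))
  # closed-form recursion for the receptive field
  expect_identical(patchReceptiveField(rep(4L, 5), c(2L, 2L, 2L, 1L, 1L)),
                   70L)
  # a stack whose realized field cannot match the configured patch errors
  expect_error(buildDiscriminator(discriminatorConfig(n_layers = 4L)),
               "receptive field")
})

test_that("zero-epoch training returns the seeded initialization untouched", {
  gcfg <- generatorConfig(base_width = 4L)
  dcfg <- discriminatorConfig(base_width = 4L)
  tcfg <- trainConfig(epochs = 0L, seed = 5L)
  pairs <- list(list(input = matrix(0.5, 16, 16),
                     reference = matrix(0.5, 16, 16)))
  model <- trainPix2pix(pairs, tcfg, gcfg, dcfg)
  ref <- octsynth:::.withSeed(5L, {
    g <- buildGenerator(gcfg); d <- buildDiscriminator(dcfg)
    list(g = octsynth:::.nnStateGet(g$layers),
         d = octsynth:::.nnStateGet(d$layers))
  })
  expect_identical(octsynth:::.nnStateGet(model$generator$layers), ref$g)
  expect_identical(octsynth:::.nnStateGet(model$discriminator$layers), ref$d)
  expect_identical(nrow(model$history), 0L)
  expect_error(trainPix2pix(list(), tcfg, gcfg, dcfg), "at least one")
})

test_that("pure L1 training on one pair drives the reconstruction loss toward zero", {
  set.seed(3)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- pmin(x * 1.4 + 0.1, 1)
  tcfg <- trainConfig(epochs = 60L, lr = 2e-3, lambda_l1 = 1,
                      adv_weight = 0, seed = 2L)
  model <- trainPix2pix(list(list(input = x, reference = y)), tcfg,
                        generatorConfig(base_width = 4L, dropout_rate = 0),
                        discriminatorConfig(base_width = 4L))
  h <- model$history$l1
  expect_lt(h[length(h)], 0.5 * h[1])
})

test_that("training records the configured optimizer settings in the state snapshot", {
  tcfg <- trainConfig()
  expect_identical(tcfg$lr, 1e-4)
  expect_identical(tcfg$epochs, 15L)
  pairs <- list(list(input = matrix(0.5, 16, 16),
                     reference = matrix(0.5, 16, 16)))
  model <- trainPix2pix(pairs, trainConfig(epochs = 0L),
                        generatorConfig(base_width = 4L),
                        discriminatorConfig(base_width = 4L))
  expect_identical(model$configs$train$lr, 1e-4)
})

test_that("enhancement is deterministic and shape-preserving, and models survive a save/load round trip", {
  set.seed(4)
  pairs <- lapply(1:2, function(i) {
    a <- matrix(runif(32 * 32), 32, 32)
    list(input = a, reference = pmin(a * 1.2, 1))
  })
  model <- trainPix2pix(pairs, trainConfig(epochs = 1L, seed = 3L),
                        generatorConfig(base_width = 4L),
                        discriminatorConfig(base_width = 4L))
  b <- pairs[[1]]$input
  o1 <- enhance(b, model)
  o2 <- enhance(b, model)
  expect_identical(o1, o2)
  expect_identical(dim(o1), dim(b))
  expect_true(all(o1 >= 0 & o1 <= 1))

  vol <- octVolume(array(runif(32 * 32 * 3), c(32, 32, 3)),
                   fov = c(2, 2.6, 2.6))
  ev <- enhance(vol, model)
  expect_identical(dim(ev), dim(vol))

  dir <- tempfile()
  saveModelState(model, dir)
  model2 <- readModelState(dir)
  expect_identical(enhance(b, model2), o1)
  expect_identical(model2$configs$train$lr, model$configs$train$lr)
})
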