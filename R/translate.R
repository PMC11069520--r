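#' @include nn.R
NULL

#' Generator configuration (ResNet-9)
#'
#' The translator's generator follows the residual encoder-decoder used
#' for paired image translation: a 7x7 stem plus two stride-2 encoding
#' blocks (convolution, instance norm, ReLU), nine residual blocks
#' (convolution-InstanceNorm-ReLU-Dropout-convolution-InstanceNorm with an
#' additive skip), and three decoding blocks that mirror the encoder with
#' nearest-neighbour upsampling, ending in a 7x7 convolution and tanh.
#' Block counts are configurable only for deliberately scaled-down runs.
#'
#' @param n_encode,n_residual,n_decode block counts (defaults 3, 9, 3).
#' @param base_width stem channel count (doubles at each downsampling).
#' @param dropout_rate residual-block dropout rate in [0, 1), active only
#'   during training.
#' @param padding \code{"reflect"} (default) or \code{"zero"} padding for
#'   the stem and residual convolutions.
#' @return A list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(n_encode = 3L, n_residual = 9L, n_decode = 3L,
                            base_width = 64L, dropout_rate = 0.5,
                            padding = "reflect") {
  if (n_encode != n_decode)
    stop("encoder and decoder must mirror (n_encode == n_decode)")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  structure(list(n_encode = as.integer(n_encode),
                 n_residual = as.integer(n_residual),
                 n_decode = as.integer(n_decode),
                 base_width = as.integer(base_width),
                 dropout_rate = dropout_rate, padding = padding,
                 norm = "instance"),
            class = "GeneratorConfig")
}

#' Discriminator configuration (70x70 PatchGAN)
#'
#' Five 4x4 convolution layers with strides 2, 2, 2, 1, 1: the canonical
#' patch discriminator whose single output unit sees a 70x70 receptive
#' field. Construction fails if the realized stack's receptive field does
#' not equal \code{patch_receptive_field}.
#'
#' @param n_layers number of convolution layers (default 5).
#' @param base_width first-layer channel count (doubles per layer, capped
#'   at 8x).
#' @param patch_receptive_field required effective receptive field.
#' @return A list of class \code{"DiscriminatorConfig"}.
#' @export
discriminatorConfig <- function(n_layers = 5L, base_width = 64L,
                                patch_receptive_field = 70L) {
  structure(list(n_layers = as.integer(n_layers),
                 base_width = as.integer(base_width),
                 patch_receptive_field = as.integer(patch_receptive_field)),
            class = "DiscriminatorConfig")
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-4).
#' @param beta1,beta2 Adam moment decays (0.5 / 0.999, the standard
#'   adversarial-training choice).
#' @param epochs training epochs (default 15).
#' @param batch_size images per update (default 1, instance-norm friendly).
#' @param lambda_l1 weight of the L1 reconstruction term (default 100).
#' @param adv_weight weight of the adversarial generator term (default 1;
#'   0 reduces training to plain L1 regression).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param device informational execution label (this implementation is CPU).
#' @return A list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(lr = 1e-4, beta1 = 0.5, beta2 = 0.999,
                        epochs = 15L, batch_size = 1L, lambda_l1 = 100,
                        adv_weight = 1, seed = 7L, device = "cpu") {
  if (lr <= 0) stop("lr must be > 0")
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lambda_l1 = lambda_l1, adv_weight = adv_weight,
                 seed = as.integer(seed), device = device),
            class = "TrainConfig")
}

#' Build the generator network
#'
#' @param cfg a [generatorConfig()].
#' @return An object of class \code{"pix2pixGenerator"} with elements
#'   \code{layers}, \code{blocks} (block census) and \code{cfg}.
#' @export
buildGenerator <- function(cfg = generatorConfig()) {
  w <- cfg$base_width
  pm <- if (cfg$padding == "reflect") "reflect" else "zero"
  layers <- list(); blocks <- character()
  addBlock <- function(ls, label) {
    layers <<- c(layers, ls)
    blocks <<- c(blocks, label)
  }
  # encode: 7x7 stem + (n_encode - 1) stride-2 downsamplers
  addBlock(list(.convLayer(1L, w, 7L, 1L, 3L, pm), .nnLayer("inorm"),
                .nnLayer("relu")), "encode")
  cw <- w
  for (i in seq_len(cfg$n_encode - 1L)) {
    addBlock(list(.convLayer(cw, cw * 2L, 3L, 2L, 1L, "zero"),
                  .nnLayer("inorm"), .nnLayer("relu")), "encode")
    cw <- cw * 2L
  }
  for (i in seq_len(cfg$n_residual)) {
    sub <- list(.convLayer(cw, cw, 3L, 1L, 1L, pm), .nnLayer("inorm"),
                .nnLayer("relu"),
                .nnLayer("dropout", rate = cfg$dropout_rate),
                .convLayer(cw, cw, 3L, 1L, 1L, pm), .nnLayer("inorm"))
    addBlock(list(.nnLayer("resblock", layers = sub)), "residual")
  }
  for (i in seq_len(cfg$n_decode - 1L)) {
    addBlock(list(.nnLayer("upsample"),
                  .convLayer(cw, cw %/% 2L, 3L, 1L, 1L, "zero"),
                  .nnLayer("inorm"), .nnLayer("relu")), "decode")
    cw <- cw %/% 2L
  }
  addBlock(list(.convLayer(cw, 1L, 7L, 1L, 3L, pm), .nnLayer("tanh")),
           "decode")
  structure(list(layers = layers, blocks = blocks, cfg = cfg),
            class = "pix2pixGenerator")
}

#' Block census of a generator
#'
#' @param gen a \code{pix2pixGenerator}.
#' @return Named integer vector: encode / residual / decode block counts.
#' @export
generatorBlocks <- function(gen) {
  c(encode = sum(gen$blocks == "encode"),
    residual = sum(gen$blocks == "residual"),
    decode = sum(gen$blocks == "decode"))
}

#' Parameter count of a generator or discriminator
#'
#' @param net a \code{pix2pixGenerator} or \code{pix2pixDiscriminator}.
#' @return Total number of trainable weights and biases.
#' @export
numParameters <- function(net) .nnParameterCount(net$layers)

#' Build the patch discriminator
#'
#' @param cfg a [discriminatorConfig()].
#' @return An object of class \code{"pix2pixDiscriminator"} with elements
#'   \code{layers}, \code{cfg}, \code{strides}, \code{kernels} and
#'   \code{receptive_field}.
#' @export
buildDiscriminator <- function(cfg = discriminatorConfig()) {
  n <- cfg$n_layers
  strides <- c(rep(2L, max(n - 2L, 0L)), rep(1L, min(2L, n)))
  kernels <- rep(4L, n)
  rf <- patchReceptiveField(kernels, strides)
  if (rf != cfg$patch_receptive_field)
    stop(sprintf("realized receptive field %d != configured %d",
                 rf, cfg$patch_receptive_field))
  w <- cfg$base_width
  widths <- pmin(w * 2L^(seq_len(n - 1L) - 1L), w * 8L)
  layers <- list(.convLayer(2L, widths[1], 4L, strides[1], 1L, "zero"),
                 .nnLayer("lrelu", slope = 0.2))
  for (i in seq_len(n - 2L)) {
    layers <- c(layers,
                list(.convLayer(widths[i], widths[i + 1], 4L,
                                strides[i + 1], 1L, "zero"),
                     .nnLayer("inorm"), .nnLayer("lrelu", slope = 0.2)))
  }
  layers <- c(layers, list(.convLayer(widths[n - 1L], 1L, 4L, strides[n],
                                      1L, "zero")))
  structure(list(layers = layers, cfg = cfg, strides = strides,
                 kernels = kernels, receptive_field = rf),
            class = "pix2pixDiscriminator")
}

#' Effective receptive field of a strided convolution stack
#'
#' Computed by the standard backward recursion
#' \code{rf <- rf * stride + (kernel - stride)} from the deepest layer up.
#'
#' @param kernels,strides integer vectors, one entry per layer.
#' @return The receptive field (pixels) of one output unit.
#' @export
patchReceptiveField <- function(kernels, strides) {
  rf <- 1L
  for (i in rev(seq_along(kernels)))
    rf <- rf * strides[i] + (kernels[i] - strides[i])
  rf
}

.genForward <- function(gen, x, train = FALSE) {
  d <- dim(x)
  down <- 2^(gen$cfg$n_encode - 1L)
  if (d[1] %% down != 0 || d[2] %% down != 0)
    stop(sprintf("input size must be divisible by %d", down))
  .netForward(gen$layers, x, train)
}

.discForward <- function(disc, xin, xcand, train = FALSE) {
  x <- array(c(xin, xcand), c(dim(xin)[1], dim(xin)[2], 2L))
  .netForward(disc$layers, x, train)
}

#' Train the paired image translator
#'
#' Alternating adversarial training of the generator and patch
#' discriminator on paired B-scans loaded pairwise: each step updates the
#' discriminator on one (input, reference) / (input, fake) pair with the
#' vanilla cross-entropy GAN objective, then updates the generator with
#' adversarial + lambda_l1 * L1(output, reference). Images must be
#' matrices in [0, 1]; they are internally rescaled to [-1, 1]. Training
#' is seeded and reproducible on fixed thread settings.
#'
#' @param pairs list of pairs; each element a list with matrices
#'   \code{input} and \code{reference} in [0, 1] of equal size.
#' @param tcfg,gcfg,dcfg configurations ([trainConfig()],
#'   [generatorConfig()], [discriminatorConfig()]).
#' @param verbose print a per-epoch loss line.
#' @return A list of class \code{"pix2pixModel"}: \code{generator},
#'   \code{discriminator}, \code{history} (per-epoch data.frame with mean
#'   adversarial, L1 and discriminator losses), \code{configs},
#'   \code{seed}, \code{epochs}.
#' @export
trainPix2pix <- function(pairs, tcfg = trainConfig(),
                         gcfg = generatorConfig(),
                         dcfg = discriminatorConfig(), verbose = FALSE) {
  if (length(pairs) < 1L) stop("need at least one training pair")
  .withSeed(tcfg$seed, {
    gen <- buildGenerator(gcfg)
    disc <- buildDiscriminator(dcfg)
    .adamInit(gen$layers); .adamInit(disc$layers)
    hist <- data.frame(epoch = integer(), adv = numeric(), l1 = numeric(),
                       d = numeric())
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(length(pairs))
      accA <- accL <- accD <- 0
      for (i in ord) {
        x <- pairs[[i]]$input * 2 - 1
        y <- pairs[[i]]$reference * 2 - 1
        dim(x) <- c(dim(pairs[[i]]$input), 1L)
        dim(y) <- c(dim(pairs[[i]]$reference), 1L)
        fake <- .genForward(gen, x, train = TRUE)

        # --- discriminator update (real then fake, averaged) ---
        zr <- .discForward(disc, x, y, train = TRUE)
        br <- .bceLogits(zr, 1)
        .netBackward(disc$layers, array(0.5 * br$dz, dim(zr)))
        gr <- lapply(.collectConvs(disc$layers),
                     function(L) list(W = L$gW, b = L$gb))
        zf <- .discForward(disc, x, fake, train = TRUE)
        bf <- .bceLogits(zf, 0)
        .netBackward(disc$layers, array(0.5 * bf$dz, dim(zf)))
        cl <- .collectConvs(disc$layers)
        for (j in seq_along(cl)) {
          cl[[j]]$gW <- cl[[j]]$gW + gr[[j]]$W
          cl[[j]]$gb <- cl[[j]]$gb + gr[[j]]$b
        }
        .adamStep(disc$layers, tcfg$lr, tcfg$beta1, tcfg$beta2)
        lossD <- 0.5 * (br$loss + bf$loss)

        # --- generator update ---
        nl1 <- length(fake)
        dl1 <- tcfg$lambda_l1 * sign(fake - y) / nl1
        lossL1 <- mean(abs(fake - y))
        lossAdv <- 0
        if (tcfg$adv_weight > 0) {
          zg <- .discForward(disc, x, fake, train = TRUE)
          bg <- .bceLogits(zg, 1)
          lossAdv <- bg$loss
          dIn <- .netBackward(disc$layers,
                              array(tcfg$adv_weight * bg$dz, dim(zg)))
          dfake <- dIn[, , 2, drop = FALSE] + dl1
        } else dfake <- dl1
        dim(dfake) <- dim(fake)
        .netBackward(gen$layers, dfake)
        .adamStep(gen$layers, tcfg$lr, tcfg$beta1, tcfg$beta2)

        accA <- accA + lossAdv; accL <- accL + lossL1; accD <- accD + lossD
      }
      n <- length(pairs)
      if (!all(is.finite(c(accA, accL, accD))))
        stop("NaN/Inf loss encountered; aborting training")
      hist <- rbind(hist, data.frame(epoch = ep, adv = accA / n,
                                     l1 = accL / n, d = accD / n))
      if (verbose)
        message(sprintf("epoch %d: adv %.4f l1 %.4f d %.4f", ep,
                        accA / n, accL / n, accD / n))
    }
    structure(list(generator = gen, discriminator = disc, history = hist,
                   configs = list(train = tcfg, generator = gcfg,
                                  discriminator = dcfg),
                   seed = tcfg$seed, epochs = tcfg$epochs),
              class = "pix2pixModel")
  })
}

#' Enhance a B-scan or volume with a trained translator
#'
#' Deterministic inference: dropout is disabled and no sampling occurs, so
#' the same input always yields a bit-identical output. Intensities are
#' mapped [0, 1] -> [-1, 1] for the network and back, clipped to [0, 1].
#'
#' @param x a numeric matrix in [0, 1] or an [OCTVolume-class] (every
#'   B-scan is translated).
#' @param model a \code{pix2pixModel} from [trainPix2pix()].
#' @return Same type and shape as the input.
#' @export
enhance <- function(x, model) {
  one <- function(m) {
    xm <- m * 2 - 1
    dim(xm) <- c(dim(m), 1L)
    out <- .genForward(model$generator, xm, train = FALSE)
    m2 <- (out[, , 1] + 1) / 2
    pmin(pmax(m2, 0), 1)
  }
  if (is(x, "OCTVolume")) {
    v <- x@vol
    for (s in seq_len(dim(v)[3])) v[, , s] <- one(x@vol[, , s])
    octVolume(v, fov = x@fov, device = paste0(x@device, "-enhanced"),
              laterality = x@laterality, signalStrength = x@signalStrength,
              meta = c(x@meta, list(enhanced = TRUE)))
  } else one(x)
}

#' Persist / restore a trained model
#'
#' The weights are written as an RDS file next to a JSON snapshot of the
#' configurations, seed and loss history, plus a CSV loss log.
#'
#' @param model a \code{pix2pixModel}.
#' @param dir output directory (created if missing).
#' @return \code{saveModelState}: \code{dir}, invisibly.
#' @export
saveModelState <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(generator = .nnStateGet(model$generator$layers),
                discriminator = .nnStateGet(model$discriminator$layers))
  saveRDS(state, file.path(dir, "weights.rds"))
  snap <- list(configs = lapply(model$configs, unclass),
               seed = model$seed, epochs = model$epochs)
  jsonlite::write_json(snap, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(model$history, file.path(dir, "loss_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname saveModelState
#' @return \code{readModelState}: the restored \code{pix2pixModel}.
#' @export
readModelState <- function(dir) {
  snap <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  gcfg <- do.call(generatorConfig,
                  snap$configs$generator[c("n_encode", "n_residual",
                                           "n_decode", "base_width",
                                           "dropout_rate", "padding")])
  dcfg <- do.call(discriminatorConfig,
                  snap$configs$discriminator[c("n_layers", "base_width",
                                               "patch_receptive_field")])
  tcfg <- do.call(trainConfig,
                  snap$configs$train[c("lr", "beta1", "beta2", "epochs",
                                       "batch_size", "lambda_l1",
                                       "adv_weight", "seed", "device")])
  gen <- buildGenerator(gcfg)
  disc <- buildDiscriminator(dcfg)
  state <- readRDS(file.path(dir, "weights.rds"))
  .nnStateSet(gen$layers, state$generator)
  .nnStateSet(disc$layers, state$discriminator)
  hist <- utils::read.csv(file.path(dir, "loss_log.csv"))
  structure(list(generator = gen, discriminator = disc, history = hist,
                 configs = list(train = tcfg, generator = gcfg,
                                discriminator = dcfg),
                 seed = snap$seed, epochs = snap$epochs),
            class = "pix2pixModel")
}
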