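#' @include agreement.R io.R
NULL

#' Build a subject roster for a phantom cohort
#'
#' Subjects carry one or two eligible eyes; the roster realizes the
#' requested per-stratum subject and eye totals (eyes - subjects subjects
#' contribute both eyes, the rest one).
#'
#' @param subjects named integer vector: subjects per stratum.
#' @param eyes named integer vector: eyes per stratum (same names;
#'   subjects <= eyes <= 2 * subjects).
#' @return data.frame with columns subject_id, stratum, n_eyes.
#' @export
makeCohort <- function(subjects, eyes) {
  stopifnot(identical(names(subjects), names(eyes)),
            all(eyes >= subjects), all(eyes <= 2 * subjects))
  rows <- lapply(names(subjects), function(st) {
    ns <- subjects[[st]]; ne <- eyes[[st]]
    n2 <- ne - ns
    data.frame(subject_id = sprintf("%s_%04d", st, seq_len(ns)),
               stratum = st,
               n_eyes = c(rep(2L, n2), rep(1L, ns - n2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subject-level train/test split
#'
#' Assigns whole subjects to the test split until the requested
#' per-stratum test eye counts are met exactly; all remaining subjects
#' train. Both eyes of a subject always travel together, so the subject
#' sets of the two splits are disjoint by construction.
#'
#' @param subjects roster from [makeCohort()].
#' @param test_eyes named integer vector: test eyes per stratum.
#' @param test_subjects optional named integer vector: test subjects per
#'   stratum (pins the 2-eye / 1-eye composition).
#' @param seed split seed.
#' @return data.frame with one row per eye: eye_id, subject_id, stratum,
#'   split, laterality.
#' @export
splitCohort <- function(subjects, test_eyes, test_subjects = NULL,
                        seed = 1L) {
  .withSeed(seed, {
    out <- list()
    for (st in unique(subjects$stratum)) {
      sub <- subjects[subjects$stratum == st, ]
      two <- sub$subject_id[sub$n_eyes == 2L]
      one <- sub$subject_id[sub$n_eyes == 1L]
      two <- sample(two); one <- sample(one)
      te <- test_eyes[[st]]
      if (!is.null(test_subjects)) {
        k2 <- te - test_subjects[[st]]
        k1 <- test_subjects[[st]] - k2
      } else {
        k2 <- min(length(two), te %/% 2L)
        k1 <- te - 2L * k2
      }
      if (k2 < 0 || k1 < 0 || k2 > length(two) || k1 > length(one))
        stop(sprintf("requested test sizes unsatisfiable for stratum %s",
                     st))
      testIds <- c(two[seq_len(k2)], one[seq_len(k1)])
      sub$split <- ifelse(sub$subject_id %in% testIds, "test", "train")
      out[[st]] <- sub
    }
    sub <- do.call(rbind, out)
    eyes <- sub[rep(seq_len(nrow(sub)), sub$n_eyes), ]
    lat <- unlist(lapply(sub$n_eyes, function(k) c("OD", "OS")[seq_len(k)]))
    eyes$laterality <- lat
    eyes$eye_id <- paste0(eyes$subject_id, "_", eyes$laterality)
    rownames(eyes) <- NULL
    eyes[, c("eye_id", "subject_id", "stratum", "split", "laterality")]
  })
}

#' Study configuration
#'
#' Describes one full phantom study: cohort sizes, device profiles,
#' per-stratum phantom parameters, preprocessing, model and training
#' settings, metric parameters and statistics seeds. Defaults mirror the
#' full-scale study design (362/91 subjects, 589/146 eyes across normal,
#' glaucoma and diabetic-retinopathy strata, 256-cube grids, 15 epochs);
#' [toyStudyConfig()] scales everything to desk size.
#'
#' @param subjects_train,subjects_test named integer vectors per stratum.
#' @param eyes_train,eyes_test named integer vectors per stratum.
#' @param ref_profile,sd_profile [deviceProfile()]s.
#' @param phantom_overrides named list (per stratum) of [phantomParams()]
#'   argument overrides.
#' @param preprocess a [preprocessConfig()].
#' @param gcfg,dcfg,tcfg model and training configurations.
#' @param bscans_per_eye_train training B-scans subsampled per eye
#'   (evenly spaced; NULL = all).
#' @param signal_range inclusive range the per-volume signal strengths
#'   are drawn from.
#' @param niblack list(window, k) for the CVI stage.
#' @param n_boot bootstrap iterations for the agreement report.
#' @param seed master seed; every per-eye seed derives from it.
#' @return A list of class \code{"StudyConfig"}.
#' @export
studyConfig <- function(subjects_train = c(normal = 202L, glaucoma = 97L,
                                           dr = 63L),
                        subjects_test = c(normal = 51L, glaucoma = 25L,
                                          dr = 15L),
                        eyes_train = c(normal = 331L, glaucoma = 153L,
                                       dr = 105L),
                        eyes_test = c(normal = 79L, glaucoma = 39L,
                                      dr = 28L),
                        ref_profile = ssoctProfile(),
                        sd_profile = sdoctProfile(),
                        phantom_overrides = list(
                          glaucoma = list(retinal_thickness_mm = c(0.21, 0.02)),
                          dr = list(choroidal_thickness_mm = c(0.24, 0.08))),
                        preprocess = preprocessConfig(),
                        gcfg = generatorConfig(),
                        dcfg = discriminatorConfig(),
                        tcfg = trainConfig(),
                        bscans_per_eye_train = NULL,
                        signal_range = c(6L, 10L),
                        niblack = list(window = 51L, k = 0.2),
                        n_boot = 1000L, seed = 1L) {
  structure(list(subjects_train = subjects_train,
                 subjects_test = subjects_test,
                 eyes_train = eyes_train, eyes_test = eyes_test,
                 ref_profile = ref_profile, sd_profile = sd_profile,
                 phantom_overrides = phantom_overrides,
                 preprocess = preprocess, gcfg = gcfg, dcfg = dcfg,
                 tcfg = tcfg, bscans_per_eye_train = bscans_per_eye_train,
                 signal_range = signal_range, niblack = niblack,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "StudyConfig")
}

#' Desk-scale study configuration
#'
#' A complete study sized for a single CPU: one stratum, 20 training and
#' 12 test eyes, 64-cube grids, base-width-4 networks, 16 training
#' B-scans per eye and 5 epochs at learning rate 3e-4. The narrow
#' networks and raised rate trade per-step capacity for optimization
#' steps, which is what desk-scale paired-GAN learning needs; the test
#' split is larger than a proportional scale-down because per-eye
#' correlations at n = 6 are statistically uninformative. Used by the
#' examples and the end-to-end checks.
#'
#' @param seed master seed.
#' @param epochs training epochs.
#' @return A \code{"StudyConfig"}.
#' @export
toyStudyConfig <- function(seed = 1L, epochs = 5L) {
  studyConfig(
    subjects_train = c(normal = 13L), subjects_test = c(normal = 8L),
    eyes_train = c(normal = 20L), eyes_test = c(normal = 12L),
    ref_profile = ssoctProfile(n_ascans = 72L, n_bscans = 72L,
                               n_depth = 96L),
    sd_profile = sdoctProfile(n_ascans = 64L, n_bscans = 64L,
                              n_depth = 64L),
    # the coarse toy grid resolves the choroid with ~8 axial voxels, so
    # vessels are thinner and the reachable luminal fraction lower
    phantom_overrides = list(normal = list(vessel_radius_px = c(1, 2),
                                           vessel_fraction = 0.45)),
    preprocess = preprocessConfig(grid = c(64L, 64L, 64L),
                                  despeckle = list(n_iter = 10L,
                                                   kappa = 30, step = 0.2),
                                  register = list(halfband = 4L,
                                                  max_shift_frac = 0.25)),
    gcfg = generatorConfig(base_width = 4L),
    dcfg = discriminatorConfig(base_width = 4L),
    tcfg = trainConfig(lr = 3e-4, epochs = as.integer(epochs),
                       seed = seed),
    bscans_per_eye_train = 16L,
    n_boot = 500L, seed = seed)
}

#' Study manifest: per-eye provenance and count conservation
#'
#' Enumerates the cohort, assigns the subject-level split, draws the
#' per-volume signal strengths, applies the quality rule (both volumes
#' >= min_signal) and declares the number of finalized B-scan pairs each
#' retained eye will contribute (the slow-axis size of the final grid).
#' Counts at every stage boundary are therefore fixed before any image
#' is rendered, exactly as a run ledger requires.
#'
#' @param cfg a [studyConfig()].
#' @return list(eyes = per-eye data.frame, counts = named totals).
#' @export
studyManifest <- function(cfg) {
  roster <- makeCohort(cfg$subjects_train + cfg$subjects_test,
                       cfg$eyes_train + cfg$eyes_test)
  eyes <- splitCohort(roster, cfg$eyes_test,
                      test_subjects = cfg$subjects_test,
                      seed = .deriveSeed(cfg$seed, 11))
  n <- nrow(eyes)
  eyes$phantom_seed <- vapply(seq_len(n), function(i)
    .deriveSeed(cfg$seed, 1000L + i), numeric(1))
  ss <- .withSeed(.deriveSeed(cfg$seed, 17), {
    cbind(input = sample(seq(cfg$signal_range[1], cfg$signal_range[2]),
                         n, replace = TRUE),
          reference = sample(seq(cfg$signal_range[1], cfg$signal_range[2]),
                             n, replace = TRUE))
  })
  eyes$ss_input <- ss[, "input"]; eyes$ss_reference <- ss[, "reference"]
  minS <- cfg$preprocess$min_signal
  eyes$retained <- eyes$ss_input >= minS & eyes$ss_reference >= minS
  eyes$n_bscan_pairs <- ifelse(eyes$retained, cfg$preprocess$grid[3], 0L)
  counts <- c(
    train_eyes = as.numeric(sum(eyes$split == "train" & eyes$retained)),
    test_eyes = as.numeric(sum(eyes$split == "test" & eyes$retained)),
    train_bscan_pairs =
      as.numeric(sum(eyes$n_bscan_pairs[eyes$split == "train"])),
    test_bscan_pairs =
      as.numeric(sum(eyes$n_bscan_pairs[eyes$split == "test"])))
  for (st in unique(eyes$stratum)) {
    counts[paste0(st, "_train_bscan_pairs")] <-
      as.numeric(sum(eyes$n_bscan_pairs[eyes$split == "train" &
                                          eyes$stratum == st]))
  }
  list(eyes = eyes, counts = counts)
}

.phantomParamsFor <- function(cfg, stratum, seed, signal_strength) {
  args <- list(seed = seed, signal_strength = as.integer(signal_strength))
  ov <- cfg$phantom_overrides[[stratum]]
  if (!is.null(ov)) args <- utils::modifyList(args, ov)
  do.call(phantomParams, args)
}

# Generate + degrade + preprocess one manifest row; returns the result of
# preprocessPair() (pair may be NULL on registration failure).
.processEye <- function(cfg, row) {
  params <- .phantomParamsFor(cfg, row$stratum, row$phantom_seed,
                              row$ss_input)
  eye <- generatePairedEye(params, cfg$ref_profile, cfg$sd_profile)
  # reference rendering keeps its own signal strength draw
  eye@reference@signalStrength <- as.integer(row$ss_reference)
  preprocessPair(eye@degraded, eye@reference, cfg$preprocess)
}

.trainBscans <- function(pair, k) {
  ns <- dim(pair)[3]
  idx <- if (is.null(k) || k >= ns) seq_len(ns) else
    round(seq(1, ns, length.out = k))
  lapply(idx, function(s) list(input = pair@input@vol[, , s],
                               reference = pair@reference@vol[, , s]))
}

#' Run a complete phantom study
#'
#' End-to-end orchestration of the study a config describes: phantom
#' generation, quality filtering, paired preprocessing, translator
#' training on the train split, enhancement of the test split, metric
#' extraction on input / enhanced / reference volumes (estimated
#' boundaries throughout), and agreement reports comparing (a) input vs
#' reference and (b) enhanced vs reference. Every stage is seeded from
#' the master seed, so a rerun with the same config reproduces the
#' manifest, model and reports exactly.
#'
#' @param cfg a [studyConfig()].
#' @param out_dir optional output directory for the manifest, metrics,
#'   loss log and agreement reports.
#' @param verbose print stage progress.
#' @return list(manifest, counts, model, metrics (per-eye data.frame),
#'   band_mae (per-test-eye choroid-band reconstruction errors),
#'   reports = list(input_vs_reference, enhanced_vs_reference),
#'   exclusions, config_hash).
#' @export
runStudy <- function(cfg, out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  man <- studyManifest(cfg)
  eyes <- man$eyes
  hash <- .configHash(cfg)

  trainRows <- which(eyes$split == "train" & eyes$retained)
  testRows <- which(eyes$split == "test" & eyes$retained)
  say("study %s: %d train / %d test eyes retained", hash,
      length(trainRows), length(testRows))

  trainPairs <- list(); exclusions <- list()
  for (i in trainRows) {
    res <- .processEye(cfg, eyes[i, ])
    if (!res$success) {
      exclusions[[eyes$eye_id[i]]] <- "registration failure"
      next
    }
    trainPairs <- c(trainPairs,
                    .trainBscans(res$pair, cfg$bscans_per_eye_train))
  }
  say("training on %d B-scan pairs", length(trainPairs))
  model <- trainPix2pix(trainPairs, cfg$tcfg, cfg$gcfg, cfg$dcfg,
                        verbose = verbose)

  metRows <- list(); bandRows <- list()
  for (i in testRows) {
    res <- .processEye(cfg, eyes[i, ])
    if (!res$success) {
      exclusions[[eyes$eye_id[i]]] <- "registration failure"
      next
    }
    pair <- res$pair
    vols <- list(input = pair@input,
                 enhanced = enhance(pair@input, model),
                 reference = pair@reference)
    # choroid-band reconstruction error: rows from the flattened RPE down
    # 0.4 mm, over all B-scans
    voxA <- pair@input@fov[1] / dim(pair)[1]
    tr <- round(cfg$preprocess$flatten_depth_mm / voxA)
    band <- tr:min(dim(pair)[1], tr + round(0.4 / voxA))
    bandRows[[length(bandRows) + 1L]] <- data.frame(
      eye_id = eyes$eye_id[i],
      mae_input = mean(abs(vols$input@vol[band, , ] -
                             vols$reference@vol[band, , ])),
      mae_enhanced = mean(abs(vols$enhanced@vol[band, , ] -
                                vols$reference@vol[band, , ])))
    for (src in names(vols)) {
      b <- estimateBoundaries(vols[[src]])
      met <- choroidMetrics(vols[[src]], b, niblack = cfg$niblack)
      df <- as.data.frame(met)
      df$eye_id <- eyes$eye_id[i]; df$volume <- src
      metRows[[length(metRows) + 1L]] <- df
    }
    say("measured test eye %s", eyes$eye_id[i])
  }
  metrics <- do.call(rbind, metRows)
  bandMAE <- do.call(rbind, bandRows)

  mkReport <- function(srcA, srcB) {
    a <- metrics[metrics$volume == srcA, ]
    b <- metrics[metrics$volume == srcB, ]
    a <- a[order(a$eye_id), ]; b <- b[order(b$eye_id), ]
    agreementReport(a, b, n_boot = cfg$n_boot,
                    seed = .deriveSeed(cfg$seed, 23))
  }
  reports <- list(input_vs_reference = mkReport("input", "reference"),
                  enhanced_vs_reference = mkReport("enhanced", "reference"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(eyes, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(model$history, file.path(out_dir, "loss_log.csv"),
                     row.names = FALSE)
    writeAgreementReport(reports$input_vs_reference, out_dir,
                         "agreement_input_vs_reference")
    writeAgreementReport(reports$enhanced_vs_reference, out_dir,
                         "agreement_enhanced_vs_reference")
  }
  list(manifest = eyes, counts = man$counts, model = model,
       metrics = metrics, band_mae = bandMAE, reports = reports,
       exclusions = exclusions, config_hash = hash)
}

.configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}
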