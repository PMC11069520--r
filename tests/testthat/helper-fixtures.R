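# Shared small fixtures. Profiles are deliberately tiny so tests stay
# fast; all phantom geometry remains at the study's physical scale.

tinyRefProfile <- function(nf = 64L, ns = 16L, nd = 160L, looks = Inf,
                           floor = 0)
  ssoctProfile(n_ascans = nf, n_bscans = ns, n_depth = nd,
               speckle_looks = looks, noise_floor = floor)

tinySDProfile <- function(nf = 48L, ns = 16L, nd = 96L, looks = Inf,
                          floor = 0, attenuation = 10)
  sdoctProfile(n_ascans = nf, n_bscans = ns, n_depth = nd,
               speckle_looks = looks, noise_floor = floor,
               attenuation_below_rpe = attenuation)

# memoized noise-free phantom used by several files
.fixtureEnv <- new.env()
noiseFreeEye <- function(seed = 5L) {
  key <- paste0("eye", seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- generateEye(phantomParams(seed = seed),
                                      tinyRefProfile())
  .fixtureEnv[[key]]
}

# circular lateral roll of a volume (exact, periodic) for registration
# inject-and-recover tests
rollVolumeLateral <- function(volume, by) {
  v <- volData(volume)
  d <- dim(v)
  fi <- ((seq_len(d[2]) - 1L - by[1]) %% d[2]) + 1L
  si <- ((seq_len(d[3]) - 1L - by[2]) %% d[3]) + 1L
  octVolume(v[, fi, si], fov = fovMM(volume), device = deviceLabel(volume))
}
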